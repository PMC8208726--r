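#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Numeric-looking
#' values are converted; everything else stays character.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) abort(sprintf("Malformed config line: '%s'", lines[which(bad)[1]]))
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(out, trimws(vapply(kv, `[[`, character(1), 1)))
}

#' Run the full modeling pipeline
#'
#' Chains the package end to end: obtain data (simulate a benchmark system or
#' read a file), optionally add noise and/or reduce with POD, cluster, fit the
#' order-L transition network, propagate a model trajectory over a requested
#' duration, and validate with autocorrelation curves and cluster probability
#' distributions. Every stage is logged with its parameters and seed. Stage
#' failures are caught, recorded under `$errors` with the stage name, and the
#' outputs produced so far are retained, so a degenerate configuration (e.g.
#' `K = 1`, which admits no intercluster transition) still completes.
#'
#' @param config named list or path to a flat `key = value` file. Recognized
#'   keys: `system` (`lorenz`, `rossler`, `pulse`, `burst`) or `input` (CSV
#'   path); `n`, `dt`, `noise_level`, `use_pod`, `n_modes`, `K`, `L`,
#'   `restarts`, `seed`, `duration` (defaults to the training span),
#'   `max_lag`, `out_dir` (optional; write CSV/JSON outputs there).
#' @param quiet suppress stage logging.
#' @return List with the fitted objects (`data`, `clusters`, `visits`,
#'   `model`, `trajectory`, `report`) and any stage `errors`, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list(errors = list())
  seed <- as.integer(cfg$seed %||% 1)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      out$errors[[name]] <<- conditionMessage(e)
      say("stage %s failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  data <- stage("data", {
    if (!is.null(cfg$input)) {
      say("stage data: reading %s", cfg$input)
      read_snapshots(cfg$input)
    } else {
      sys <- cfg$system %||% abort("Config needs `system` or `input`.")
      n <- as.integer(cfg$n %||% 10000)
      dt <- as.numeric(cfg$dt %||% 0.01)
      say("stage data: simulating %s (n = %d, dt = %g, seed = %d)", sys, n, dt, seed)
      switch(as.character(sys),
             lorenz = simulate_lorenz(n, dt),
             rossler = simulate_rossler(n, dt),
             pulse = generate_surrogate("pulse_train", n, dt,
                                        noise_level = as.numeric(cfg$noise_level %||% 0.05),
                                        seed = seed),
             burst = generate_surrogate("burst_signal", n, dt,
                                        burst_rate = as.numeric(cfg$burst_rate %||% 0.05),
                                        seed = seed),
             abort(sprintf("Unknown system '%s'.", sys)))
    }
  })
  if (is.null(data)) return(invisible(out))
  out$data <- data
  dt <- snapshot_dt(data)

  noise <- as.numeric(cfg$noise_level %||% 0)
  if (noise > 0 && is.null(cfg$system_is_surrogate) && !identical(cfg$system, "pulse")) {
    say("stage noise: level = %g, seed = %d", noise, seed)
    data <- add_uniform_noise(data, noise, seed = seed)
    out$data <- data
  }

  train <- data
  if (isTRUE(as.logical(cfg$use_pod %||% FALSE))) {
    out$pod <- stage("pod", {
      say("stage pod: snapshot POD%s",
          if (!is.null(cfg$n_modes)) sprintf(" (truncated to %d modes)", as.integer(cfg$n_modes)) else "")
      compute_pod(data, n_modes = cfg$n_modes)
    })
    if (!is.null(out$pod)) train <- pod_coefficients(out$pod)
  }

  K <- as.integer(cfg$K %||% 10)
  restarts <- as.integer(cfg$restarts %||% 10)
  out$clusters <- stage("cluster", {
    say("stage cluster: k-means++ K = %d, restarts = %d, seed = %d", K, restarts, seed)
    fit_kmeanspp(train, K = K, restarts = restarts, seed = seed)
  })
  if (is.null(out$clusters)) return(invisible(out))
  out$visits <- extract_visit_sequence(out$clusters)

  L <- as.integer(cfg$L %||% 1)
  out$model <- stage("fit", {
    say("stage fit: order L = %d on %d visits", L, nrow(out$visits))
    fit_transition_model(out$visits, L = L, K = K)
  })

  span <- dt * (nrow(train) - 1)
  duration <- as.numeric(cfg$duration %||% span)
  if (!is.null(out$model)) {
    out$trajectory <- stage("propagate", {
      say("stage propagate: duration = %g, seed = %d", duration, seed)
      propagate(out$model, out$clusters, duration = duration, seed = seed)
    })
  }

  max_lag <- as.numeric(cfg$max_lag %||% (span / 10))
  out$report <- stage("validate", {
    say("stage validate: max_lag = %g", max_lag)
    ref <- autocorrelation(train, max_lag)
    rep <- list(config = cfg,
                ref_autocorrelation = ref,
                data_cpd = cluster_probability(out$clusters))
    if (!is.null(out$trajectory)) {
      model_set <- resample_uniform(out$trajectory, dt)
      mod <- autocorrelation(model_set, max_lag)
      rep$model_autocorrelation <- mod
      rep$model_cpd <- cluster_probability(out$trajectory, out$clusters)
      rep$autocorr_rms_error_pct <- autocorr_rms_error(mod, ref)
      rep$r0_relative_error_pct <- 100 * abs(mod$R[1] - ref$R[1]) / ref$R[1]
    }
    if (!is.null(out$model)) {
      rep$normalized_time_delay <- suppressWarnings(
        normalized_time_delay(out$model, out$visits, ref))
    }
    rep
  })

  if (!is.null(cfg$out_dir)) stage("write", write_pipeline_outputs(out, cfg$out_dir))
  invisible(out)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$clusters)) {
    readr::write_csv(tidy(out$clusters), file.path(dir, "centroids.csv"))
    readr::write_csv(tibble::tibble(label = out$clusters$labels),
                     file.path(dir, "labels.csv"))
  }
  if (!is.null(out$model)) readr::write_csv(out$model$table, file.path(dir, "model.csv"))
  if (!is.null(out$trajectory)) {
    write_snapshots(resample_uniform(out$trajectory), file.path(dir, "trajectory.csv"))
  }
  if (!is.null(out$report)) {
    jsonlite::write_json(out$report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}
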