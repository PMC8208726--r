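# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: fixed-step RK4 instead of the adaptive integrator,
# plain nested loops instead of the grouped table estimator.

# Classical fixed-step RK4, used as an independent check on the adaptive
# fifth-order integrator.
rk4_integrate <- function(f, y0, dt, n_steps) {
  y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

lorenz_rhs <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  function(s) c(sigma * (s[2] - s[1]), s[1] * (rho - s[3]) - s[2], s[1] * s[2] - beta * s[3])
}

rossler_rhs <- function(a = 0.1, b = 0.1, c = 14) {
  function(s) c(-s[2] - s[3], s[1] + a * s[2], b + s[3] * (s[1] - c))
}

# Brute-force window enumeration of Q and T: loops over every length-(L+1)
# window and aggregates with base R only.
oracle_transition_table <- function(v, res, L) {
  hist_key <- character(0)
  succ <- integer(0)
  tau <- numeric(0)
  for (i in (L + 1):length(v)) {
    hist_key <- c(hist_key, paste(v[(i - L):(i - 1)], collapse = "-"))
    succ <- c(succ, v[i])
    tau <- c(tau, (res[i - 1] + res[i]) / 2)
  }
  key <- paste(hist_key, succ, sep = "|")
  uk <- sort(unique(key))
  out <- data.frame(history = sub("\\|.*$", "", uk),
                    successor = as.integer(sub("^.*\\|", "", uk)),
                    count = NA_integer_, q = NA_real_, time = NA_real_,
                    stringsAsFactors = FALSE)
  n_hist <- table(hist_key)
  for (r in seq_len(nrow(out))) {
    sel <- key == uk[r]
    out$count[r] <- sum(sel)
    out$time[r] <- mean(tau[sel])
    out$q[r] <- sum(sel) / n_hist[[out$history[r]]]
  }
  out[order(out$history, out$successor), ]
}

# Random label sequence with K symbols (self-repeats allowed; the visit
# sequence is extracted afterwards).
random_labels <- function(n, K) sample.int(K, n, replace = TRUE)

# Exact stationary visit distribution of a first-order direct-transition
# matrix: solves pi = Q pi by eigen decomposition.
stationary_of_q <- function(model) {
  K <- model$K
  Q <- matrix(0, K, K)
  for (r in seq_len(nrow(model$table))) {
    j <- as.integer(model$table$history[r])
    Q[model$table$successor[r], j] <- model$table$q[r]
  }
  ev <- eigen(Q)
  i <- which.min(abs(ev$values - 1))
  p <- Re(ev$vectors[, i])
  p / sum(p)
}

# Small reusable noisy-Lorenz fixture, built once per session.
.fixture_env <- new.env(parent = emptyenv())
lorenz_small <- function() {
  if (is.null(.fixture_env$lorenz_small)) {
    .fixture_env$lorenz_small <- add_uniform_noise(
      simulate_lorenz(4000, 0.015), 0.1, seed = 7)
  }
  .fixture_env$lorenz_small
}
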