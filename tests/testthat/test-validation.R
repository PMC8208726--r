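test_that("autocorrelation reproduces definitional and closed-form values", {
  set.seed(2)
  x <- matrix(rnorm(5000 * 2), 5000, 2)
  data <- snapshot_set(x, dt = 0.1)
  ac <- autocorrelation(data, max_lag = 2)
  m <- nrow(x)
  expect_equal(ac$R[1], sum(apply(x, 2, var)) * (m - 1) / m, tolerance = 1e-10)
  # i.i.d. noise: away from lag zero the curve is CLT-small
  expect_true(all(abs(ac$R[-1]) < 4 * ac$R[1] / sqrt(m)))

  # sine wave: R(tau) = 0.5 cos(2 pi tau / T0)
  t0 <- 2
  m <- 20000
  tt <- (0:(m - 1)) * 0.005
  sine <- snapshot_set(matrix(sin(2 * pi * tt / t0), ncol = 1), dt = 0.005)
  ac2 <- autocorrelation(sine, max_lag = 4)
  want <- 0.5 * cos(2 * pi * ac2$lag / t0)
  expect_lt(max(abs(ac2$R - want)) / 0.5, 0.01)
  expect_equal(fundamental_period(ac2), t0, tolerance = 0.005 / t0)

  flat <- snapshot_set(matrix(1, 100, 1), dt = 1)
  expect_warning(ac3 <- autocorrelation(flat, 10), "Constant")
  expect_true(all(ac3$R == 0))
})

test_that("cluster probabilities count correctly on data and model sides", {
  p <- cluster_probability(c(1, 2, 2, 3))
  expect_equal(p$p, c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(sum(p$p), 1)
  p1 <- cluster_probability(rep(2L, 5), clusters = NULL)
  expect_equal(p1$p[2], 1)

  # deterministic 3-cycle with equal transit times: equal thirds
  centroids <- rbind(c(0, 0), c(10, 0), c(0, 10))
  cm <- structure(list(centroids = centroids, K = 3L, labels = rep(1:3, 5),
                       sizes = rep(5L, 3), inertia = 0, dt = 0.01, t0 = 0,
                       component_names = c("x", "y")),
                  class = "cluster_model")
  vs <- tibble::tibble(cluster = rep(c(1, 2, 3), 10),
                       entry_time = 0:29, residence_time = rep(1, 30),
                       n_snapshots = 1L)
  tm <- fit_transition_model(vs, L = 1, K = 3)
  traj <- propagate(tm, cm, duration = 300, seed = 1)
  cpd <- cluster_probability(traj, cm, dt = 0.01)
  expect_equal(sum(cpd$p), 1, tolerance = 1e-12)
  expect_true(all(abs(cpd$p - 1 / 3) < 1 / sqrt(30000) + 0.01))
})

test_that("autocorrelation RMS error behaves algebraically", {
  curve <- tibble::tibble(lag = seq(0, 5, 0.1), R = cos(seq(0, 5, 0.1)))
  expect_equal(autocorr_rms_error(curve, curve), 0)
  shifted <- dplyr::mutate(curve, R = R + 0.2)
  r <- sqrt(mean(curve$R^2))
  expect_equal(autocorr_rms_error(shifted, curve), 100 * 0.2 / r, tolerance = 1e-10)
  # symmetric in the sign of the discrepancy
  expect_equal(autocorr_rms_error(dplyr::mutate(curve, R = R - 0.2), curve),
               autocorr_rms_error(shifted, curve), tolerance = 1e-12)
  zero <- dplyr::mutate(curve, R = 0)
  expect_error(autocorr_rms_error(curve, zero), "zero RMS")
})

test_that("normalized time delay follows its construction", {
  vs <- tibble::tibble(cluster = rep(c(1, 2), 10),
                       entry_time = cumsum(c(0, rep(0.25, 19))),
                       residence_time = rep(0.25, 20), n_snapshots = 1L)
  curve <- tibble::tibble(lag = seq(0, 3, 0.01),
                          R = cos(2 * pi * seq(0, 3, 0.01))) # period 1
  expect_equal(normalized_time_delay(2L, vs, curve), 0.5, tolerance = 1e-9)
  expect_equal(normalized_time_delay(0L, vs, curve), 0)
  aperiodic <- tibble::tibble(lag = seq(0, 3, 0.01),
                              R = exp(-seq(0, 3, 0.01)))
  expect_warning(nd <- normalized_time_delay(2L, vs, aperiodic), "No dominant period")
  expect_true(is.na(nd))
})

test_that("scalar PDFs normalize and capture degenerate input", {
  set.seed(4)
  u <- runif(100000)
  pdf <- scalar_pdf(u, bins = 20)
  expect_equal(sum(pdf$density * diff(range(u)) / 20), 1, tolerance = 1e-6)
  expect_true(all(abs(pdf$density - 1) < 0.05))
  single <- scalar_pdf(rep(3, 10), bins = 5)
  expect_equal(sum(single$density > 0), 1)
  expect_error(scalar_pdf(u, bins = 1), "at least 2")
})

test_that("hyperparameter selection returns the grid argmin and tolerates bad cells", {
  # noiseless limit cycle
  tt <- (0:1999) * 0.02
  circ <- snapshot_set(cbind(cos(2 * pi * tt / 4), sin(2 * pi * tt / 4)), dt = 0.02)
  one <- select_hyperparameters(circ, K_grid = 6, L_grid = 1, seed = 1, max_lag = 6)
  expect_equal(one$K, 6L)
  expect_equal(one$L, 1L)
  expect_equal(nrow(one$surface), 1)
  expect_true(is.finite(one$surface$error))

  sel <- select_hyperparameters(circ, K_grid = c(3, 6, 12, 24),
                                L_grid = c(1, 1000), seed = 1, max_lag = 6)
  surf <- sel$surface
  # grid points with too few visits for the order are invalid, not fatal
  expect_true(all(is.na(surf$error[surf$L == 1000])))
  # on a circle the error decreases (then plateaus) with K
  errs <- surf$error[surf$L == 1]
  expect_lt(errs[4], errs[1])
  expect_equal(sel$L, 1L)
})
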