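# a hand-built deterministic 3-cycle: clusters at the corners of a triangle,
# every transition certain with unit transit time
cycle_fixture <- function(T_flight = 1) {
  centroids <- rbind(c(0, 0), c(1, 0), c(0, 1))
  cm <- structure(list(centroids = centroids, K = 3L,
                       labels = rep(1:3, 10), sizes = rep(10L, 3),
                       inertia = 0, dt = 0.1, t0 = 0,
                       component_names = c("x", "y")),
                  class = "cluster_model")
  vs <- tibble::tibble(cluster = rep(c(1, 2, 3), 10),
                       entry_time = cumsum(c(0, rep(T_flight, 29))),
                       residence_time = rep(T_flight, 30),
                       n_snapshots = 1L)
  list(clusters = cm, model = fit_transition_model(vs, L = 1, K = 3))
}

test_that("a deterministic cycle propagates exactly periodically", {
  fx <- cycle_fixture()
  traj <- propagate(fx$model, fx$clusters, duration = 10, seed = 1)
  expect_equal(traj$times, 0:10)
  expect_equal(diff(traj$visits) %% 3, rep(1, 10)) # 1 -> 2 -> 3 -> 1 ...
  # determinism
  again <- propagate(fx$model, fx$clusters, duration = 10, seed = 99)
  expect_identical(traj$visits, again$visits)
})

test_that("flight interpolation hits both endpoints and the midpoint", {
  fx <- cycle_fixture()
  traj <- propagate(fx$model, fx$clusters, duration = 3, seed = 1)
  for (i in seq_along(traj$times)) {
    at <- evaluate_trajectory(traj, traj$times[i])
    expect_equal(as.numeric(snapshot_matrix(at)),
                 as.numeric(fx$clusters$centroids[traj$visits[i], ]),
                 tolerance = 1e-12)
  }
  mid <- evaluate_trajectory(traj, traj$times[1] + 0.5)
  expect_equal(as.numeric(snapshot_matrix(mid)),
               as.numeric((fx$clusters$centroids[traj$visits[1], ] +
                           fx$clusters$centroids[traj$visits[2], ]) / 2),
               tolerance = 1e-12)
  expect_error(evaluate_trajectory(traj, max(traj$times) + 1), "span")
})

test_that("linear evaluation matches explicit segment equations", {
  set.seed(21)
  times <- cumsum(c(0, runif(8, 0.5, 2)))
  states <- matrix(rnorm(9 * 3), 9, 3)
  traj <- cnm_trajectory(times, states)
  tq <- runif(50, min(times), max(times))
  got <- unname(snapshot_matrix(evaluate_trajectory(traj, tq)))
  seg <- findInterval(tq, times, rightmost.closed = TRUE)
  alpha <- (tq - times[seg]) / (times[seg + 1] - times[seg])
  want <- (1 - alpha) * states[seg, ] + alpha * states[seg + 1, ]
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("resampling recovers waypoints and piecewise-linear paths", {
  # single flight of duration T resampled at T/2: start, midpoint, end
  traj <- cnm_trajectory(c(0, 2), rbind(c(0, 0), c(4, 2)))
  rs <- resample_uniform(traj, dt = 1)
  expect_equal(unname(snapshot_matrix(rs)), rbind(c(0, 0), c(2, 1), c(4, 2)))
  expect_error(resample_uniform(traj, dt = -1), "positive")
  expect_error(resample_uniform(traj, dt = 5), "shorter")

  # dense resampling of a two-flight path deviates < 1e-12 from the segments
  traj2 <- cnm_trajectory(c(0, 1, 3), rbind(c(0, 0), c(1, 1), c(5, -1)))
  rs2 <- resample_uniform(traj2, dt = 0.001)
  x <- snapshot_matrix(rs2)
  tq <- rs2$t
  want <- ifelse(tq <= 1, tq, 1 + (tq - 1) * 2)
  expect_lt(max(abs(x[, 1] - want)), 1e-12)
})

test_that("spline mode passes through the waypoints", {
  fx <- cycle_fixture()
  traj <- propagate(fx$model, fx$clusters, duration = 5, seed = 1,
                    interpolation = "spline")
  at <- evaluate_trajectory(traj, traj$times)
  expect_equal(unname(snapshot_matrix(at)),
               unname(fx$clusters$centroids[traj$visits, ]), tolerance = 1e-10)
})

test_that("unknown initial histories error; propagation stays inside the stored network", {
  fx <- cycle_fixture()
  expect_error(propagate(fx$model, fx$clusters, duration = 5,
                         initial_history = 7L, seed = 1), "not a stored history")

  data <- lorenz_small()
  cm <- fit_kmeanspp(data, K = 15, restarts = 2, seed = 5)
  vs <- extract_visit_sequence(cm)
  tm <- fit_transition_model(vs, L = 2, K = 15)
  traj <- suppressMessages(propagate(tm, cm, duration = 100, seed = 2))
  # closure: every generated transition was observed in training
  gen <- paste(head(traj$visits, -1), tail(traj$visits, -1), sep = ">")
  seen <- paste(head(vs$cluster, -1), tail(vs$cluster, -1), sep = ">")
  expect_true(all(gen %in% seen))
  expect_true(all(diff(traj$times) > 0))
})

test_that("long-run visit frequencies match the exact stationary distribution", {
  # a stochastic first-order model on 3 clusters
  set.seed(10)
  labels <- random_labels(4000, 3)
  vs <- extract_visit_sequence(labels, dt = 1)
  tm <- fit_transition_model(vs, L = 1, K = 3)
  cm <- structure(list(centroids = diag(3), K = 3L, labels = labels,
                       sizes = tabulate(labels, 3), inertia = 0, dt = 1, t0 = 0,
                       component_names = c("x", "y", "z")),
                  class = "cluster_model")
  traj <- propagate(tm, cm, duration = 20000, seed = 3)
  freq <- tabulate(traj$visits, 3) / length(traj$visits)
  exact <- stationary_of_q(tm)
  se <- sqrt(exact * (1 - exact) / length(traj$visits))
  expect_true(all(abs(freq - exact) < 3 * pmax(se, 1e-3)))
})
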