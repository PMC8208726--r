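vs_of <- function(v, res) {
  tibble::tibble(cluster = v,
                 entry_time = cumsum(c(0, head(res, -1))),
                 residence_time = res,
                 n_snapshots = NA_integer_)
}

test_that("deterministic cycles and hand-counted sequences are estimated exactly", {
  # periodic 1,2,3,...: every transition is certain
  v <- rep(c(1, 2, 3), 10)
  tm <- fit_transition_model(vs_of(v, rep(1, 30)), L = 1)
  expect_equal(sort(tm$table$q), c(1, 1, 1))
  q <- function(m, h, s) with(m$table, q[history == h & successor == s])
  expect_equal(q(tm, "1", 2), 1)
  expect_equal(q(tm, "2", 3), 1)
  expect_equal(q(tm, "3", 1), 1)

  # order-2 disambiguation of 1,2,1,3,1,2,1,3
  v <- c(1, 2, 1, 3, 1, 2, 1, 3)
  m1 <- fit_transition_model(vs_of(v, rep(1, 8)), L = 1)
  expect_equal(q(m1, "1", 2), 1 / 2)
  expect_equal(q(m1, "1", 3), 1 / 2)
  m2 <- fit_transition_model(vs_of(v, rep(1, 8)), L = 2)
  expect_equal(q(m2, "2-1", 3), 1)
  expect_equal(q(m2, "3-1", 2), 1)
  expect_equal(memory_footprint(m2), 4) # vs dense 27 for K = 3
  expect_equal(memory_footprint(m1), 4) # 1->2, 1->3, 2->1, 3->1 vs dense 9
})

test_that("transition times average half residence sums", {
  # residences (2, 4, 6) over visits (1, 2, 3)
  tm <- fit_transition_model(vs_of(c(1, 2, 3), c(2, 4, 6)), L = 1)
  tt <- function(h, s) with(tm$table, time[history == h & successor == s])
  expect_equal(tt("1", 2), 3)
  expect_equal(tt("2", 3), 5)

  # equal residences: every T equals that residence
  tm2 <- fit_transition_model(vs_of(rep(c(1, 2), 5), rep(0.4, 10)), L = 1)
  expect_true(all(abs(tm2$table$time - 0.4) < 1e-12))

  # repeated transition with individual times {1, 3} averages to 2
  tm3 <- fit_transition_model(vs_of(c(1, 2, 1, 2), c(1, 1, 3, 3)), L = 1)
  expect_equal(tt <- with(tm3$table, time[history == "1" & successor == 2]), 2)
})

test_that("estimator matches the brute-force window oracle on random sequences", {
  set.seed(77)
  for (rep in 1:100) {
    K <- sample(2:5, 1)
    L <- sample(1:3, 1)
    labels <- random_labels(sample(20:200, 1), K)
    vs <- extract_visit_sequence(labels, dt = 0.1)
    if (nrow(vs) <= L) next
    tm <- fit_transition_model(vs, L = L, K = K)
    oracle <- oracle_transition_table(vs$cluster, vs$residence_time, L)
    expect_identical(tm$table$history, oracle$history)
    expect_identical(tm$table$successor, as.integer(oracle$successor))
    expect_identical(tm$table$count, oracle$count)
    expect_equal(tm$table$q, oracle$q, tolerance = 1e-14)
    expect_equal(tm$table$time, oracle$time, tolerance = 1e-14)
  }
})

test_that("model invariants hold: normalization, no self-loops, suffix closure", {
  set.seed(55)
  for (rep in 1:20) {
    labels <- random_labels(300, 4)
    vs <- extract_visit_sequence(labels, dt = 1)
    L <- sample(1:3, 1)
    if (nrow(vs) <= L) next
    tm <- fit_transition_model(vs, L = L)
    sums <- tapply(tm$table$q, tm$table$history, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    last_of_history <- as.integer(sub("^.*-", "", tm$table$history))
    expect_true(all(tm$table$successor != last_of_history))
    expect_true(all(tm$table$time > 0))

    # suffix closure: shifted history stored, at most one terminal exception
    histories <- unique(tm$table$history)
    shifted <- paste(sub("^[0-9]+-?", "", tm$table$history),
                     tm$table$successor, sep = "-")
    shifted <- sub("^-", "", shifted)
    missing <- setdiff(unique(shifted), histories)
    expect_lte(length(missing), 1)
  }
})

test_that("insufficient visit sequences are rejected with the required length", {
  vs <- vs_of(c(1, 2), c(1, 1))
  expect_error(fit_transition_model(vs, L = 2), "at least 3 visits")
})

test_that("Markov baseline reproduces hand counts and converges to a fixed point", {
  mb <- fit_markov_baseline(c(1, 1, 2, 2), dt = 1)
  expect_equal(mb$P[1, 1], 1 / 2)
  expect_equal(mb$P[2, 1], 1 / 2)
  expect_equal(mb$P[2, 2], 1) # the self-loop keeps cluster 2 occupied
  # a cluster that appears only terminally is flagged and made absorbing
  expect_warning(fit_markov_baseline(c(1, 2), dt = 1), "never departed")
  expect_equal(colSums(mb$P), c(1, 1))
  expect_equal(as.numeric(mb$P %*% mb$stationary), mb$stationary, tolerance = 1e-10)

  # constant labels: identity dynamics on that cluster
  mb2 <- fit_markov_baseline(rep(2, 10), dt = 1, K = 3)
  expect_equal(mb2$stationary[2], 1)

  # evolution of q contracts toward the stationary vector
  labels <- lorenz_small() |> fit_kmeanspp(K = 8, restarts = 2, seed = 1)
  mb3 <- fit_markov_baseline(labels)
  q0 <- c(1, rep(0, 7))
  ev <- markov_evolve(mb3, q0, n_steps = 2000)
  q_end <- ev$q[ev$step == 2000]
  expect_equal(q_end, mb3$stationary, tolerance = 1e-4)
})
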