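test_that("per-dimension contributions decompose the squared distance", {
  expect_equal(per_dim_contributions(3, matrix(1)), 4)
  expect_equal(per_dim_contributions(c(0, 0), matrix(c(1, 2), 1)), c(1, 4))
  # gamma = 2 identity: sum of contributions equals the total distance
  set.seed(14)
  ref <- matrix(rnorm(100 * 8), ncol = 8)
  pars <- odit_params(k = 4, s = 3, gamma = 2)
  for (i in 1:20) {
    x <- rnorm(8)
    g <- knn_distances(x, ref, k = 4)
    d2 <- colSums((t(ref) - x)^2)
    nn <- order(d2, seq_along(d2))[2:4]   # the s = 3 summed neighbors
    delta <- per_dim_contributions(x, ref[nn, ])
    expect_equal(sum(delta), total_distance(g, pars))
  }
  expect_error(per_dim_contributions(c(1, 2), matrix(1)), "input-format")
})

test_that("onset estimation scans for the last zero before the alarm", {
  expect_equal(estimate_onset(c(0, 0, 1, 2, 6), 5), 2L)
  expect_equal(estimate_onset(c(1, 2, 3), 3), 0L)   # strictly positive trace
  # random traces against a linear-scan oracle
  set.seed(15)
  for (i in 1:100) {
    tr <- pmax(cumsum(rnorm(50)), 0) * rbinom(50, 1, 0.8)
    t_alarm <- sample(2:50, 1)
    oracle <- 0L
    for (t in seq_len(t_alarm - 1)) if (tr[t] == 0) oracle <- t
    expect_identical(estimate_onset(tr, t_alarm), oracle)
  }
})

test_that("the t threshold is the upper Student-t quantile", {
  expect_equal(t_threshold(0.05, 2), 6.314, tolerance = 1e-4)
  expect_equal(t_threshold(0.5, 7), 0)
  expect_equal(t_threshold(0.05, 3), 2.920, tolerance = 1e-3)
  expect_error(t_threshold(0.05, 1), "invalid-configuration")
})

test_that("localization flags planted dimensions and controls the null level", {
  m <- small_model(n = 4000, d = 20, seed = 19)
  recovered <- 0; trials <- 40
  for (i in seq_len(trials)) {
    stream <- shifted_stream(20, tau = 30, horizon = 80, dims = 1:3,
                             shift = 4, seed = 100 + i)
    det <- odit_detect(m, stream, h = 30)
    if (length(det$alarms) == 0) next
    loc <- odit_localize(det, m, S = 10, beta = 0.05)
    # every planted dimension flagged (false flags occur at rate ~beta by
    # design of the per-dimension test; the null level is checked below)
    if (all(1:3 %in% loc$flagged)) recovered <- recovered + 1
    expect_identical(loc$flagged, which(loc$t_stats >= loc$theta))
  }
  expect_gte(recovered / trials, 0.9)

  # under the null the flag rate stays near beta (slack: contributions are
  # not exactly Gaussian)
  beta <- 0.1; d <- 20
  null_rate <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    stream <- matrix(rnorm(20 * d), ncol = d)
    det <- odit_detect(m, stream, h = Inf)
    fake <- det; fake$alarms <- list(list(t_alarm = 16L, tau_hat = 5L))
    length(odit_localize(fake, m, S = 10, beta = beta)$flagged) / d
  }, numeric(1))
  expect_lte(mean(null_rate), beta + 3 * sqrt(beta * (1 - beta) / d))
})

test_that("growing beta never shrinks the flagged set", {
  m <- small_model(n = 2000, d = 10, seed = 23)
  stream <- shifted_stream(10, tau = 10, horizon = 40, dims = 1:2,
                           shift = 3, seed = 77)
  det <- odit_detect(m, stream, h = 10)
  expect_gte(length(det$alarms), 1)
  prev <- integer(0)
  for (beta in c(0.01, 0.05, 0.1, 0.25)) {
    fl <- odit_localize(det, m, S = 8, beta = beta)$flagged
    expect_true(all(prev %in% fl))
    prev <- fl
  }
})

test_that("degenerate zero-variance contributions flag only exceedances", {
  m <- small_model(n = 500, d = 4, seed = 29)
  det <- structure(list(alarms = list(list(t_alarm = 6L, tau_hat = 0L)),
                        contrib = matrix(rep(c(10, 0, m$mu[3], 5), each = 6), 6, 4),
                        h = 1, restart = FALSE),
                   class = "odit_detection")
  loc <- odit_localize(det, m, S = 6, beta = 0.05)
  expect_true(1 %in% loc$flagged)          # constant 10 > mu_1
  expect_false(2 %in% loc$flagged)         # constant 0 < mu_2
  expect_false(3 %in% loc$flagged)         # constant exactly mu_3: not above
  expect_equal(loc$t_stats[1], Inf)
})

test_that("localization needing samples past the stream end errors clearly", {
  m <- small_model(n = 500, d = 4, seed = 31)
  stream <- shifted_stream(4, tau = 2, horizon = 6, dims = 1:2, shift = 5, seed = 9)
  det <- odit_detect(m, stream, h = 5)
  expect_gte(length(det$alarms), 1)
  expect_error(odit_localize(det, m, S = 10), "post-onset")
})

test_that("an online state localizes identically to the batch path", {
  m <- small_model(n = 1000, d = 6, seed = 37)
  stream <- shifted_stream(6, tau = 15, horizon = 40, dims = 1:2,
                           shift = 3, seed = 55)
  det <- odit_detect(m, stream, h = 25)
  expect_gte(length(det$alarms), 1)
  st <- odit_new_state(m)
  stop_t <- det$alarms[[1]]$tau_hat + 10L
  for (t in seq_len(stop_t)) st <- odit_step(st, stream[t, ], m, h = Inf)$state
  # force the same onset bookkeeping as the batch alarm
  st$last_zero <- det$alarms[[1]]$tau_hat
  loc_state <- odit_localize(st, m, S = 10)
  loc_batch <- odit_localize(det, m, S = 10)
  expect_equal(loc_state$t_stats, loc_batch$t_stats)
})
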