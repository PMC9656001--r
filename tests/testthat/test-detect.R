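test_that("the statistic recursion reflects at zero and crosses at h", {
  m <- small_model()
  # forge evidence by driving the recursion directly through odit_detect on
  # points with known evidence sign: far point -> positive, dense point -> negative
  st <- odit_new_state(m)
  far <- rep(50, m$d)
  res <- odit_step(st, far, m, h = Inf)
  expect_gt(res$D, 0)
  expect_equal(res$state$delta, max(res$D, 0))
  # negative drift keeps the statistic at zero and advances last_zero
  st2 <- odit_new_state(m)
  res2 <- odit_step(st2, rep(0, m$d), m, h = 10)   # dense region, D < 0
  expect_lt(res2$D, 0)
  expect_equal(res2$state$delta, 0)
  expect_equal(res2$state$last_zero, 1L)
  expect_false(res2$alarm)
  # threshold crossing raises the alarm at that step
  st3 <- odit_new_state(m)
  out <- odit_step(st3, far, m, h = res$D / 2)
  expect_true(out$alarm)
})

test_that("dimension mismatches and non-finite inputs are rejected", {
  m <- small_model()
  expect_error(odit_detect(m, matrix(0, 2, m$d + 1)), "input-format")
  bad <- matrix(0, 2, m$d); bad[2, 1] <- NA
  expect_error(odit_detect(m, bad), "input-format")
})

test_that("batch detection matches the stepwise path and obeys Delta >= 0", {
  m <- small_model()
  stream <- shifted_stream(m$d, tau = 20, horizon = 60, dims = 1:2, seed = 3)
  det <- odit_detect(m, stream, h = Inf)
  expect_true(all(det$statistic >= 0))
  expect_equal(length(det$statistic), 60)
  # recursion identity: Delta_t = max(Delta_{t-1} + D_t, 0) at every step
  delta_prev <- c(0, head(det$statistic, -1))
  expect_equal(det$statistic, pmax(delta_prev + det$evidence, 0))
  # stepwise equivalence
  st <- odit_new_state(m)
  for (t in 1:60) st <- odit_step(st, stream[t, ], m, h = Inf)$state
  expect_equal(st$delta, det$statistic[60])
})

test_that("threshold edge cases: h = Inf never alarms, h = 0 alarms at t = 1", {
  m <- small_model()
  stream <- shifted_stream(m$d, tau = 5, horizon = 30, dims = 1, seed = 4)
  expect_length(odit_detect(m, stream, h = Inf)$alarms, 0)
  det0 <- odit_detect(m, stream, h = 0)
  expect_equal(det0$alarms[[1]]$t_alarm, 1L)
  # empty stream gives an empty result
  expect_length(odit_detect(m, matrix(0, 0, m$d), h = 1)$alarms, 0)
})

test_that("restart mode resets and reports multiple alarms with tau_hat < T", {
  m <- small_model()
  # two anomalous bursts separated by nominal data
  set.seed(6)
  stream <- rbind(matrix(rnorm(20 * m$d), ncol = m$d),
                  matrix(rnorm(15 * m$d, mean = 4), ncol = m$d),
                  matrix(rnorm(40 * m$d), ncol = m$d),
                  matrix(rnorm(15 * m$d, mean = 4), ncol = m$d))
  det <- odit_detect(m, stream, h = 30, restart = TRUE)
  expect_gte(length(det$alarms), 2)
  for (a in det$alarms) {
    expect_lt(a$tau_hat, a$t_alarm)
    expect_gte(a$statistic, 30)
  }
  # single-alarm mode reports only the first
  det1 <- odit_detect(m, stream, h = 30, restart = FALSE)
  expect_length(det1$alarms, 1)
  expect_equal(det1$alarms[[1]]$t_alarm, det$alarms[[1]]$t_alarm)
})

test_that("a persistent mean shift yields positive post-change drift", {
  m <- small_model(n = 2000, d = 5)
  set.seed(12)
  pre <- matrix(rnorm(1000 * 5), ncol = 5)
  post <- matrix(rnorm(1000 * 5), ncol = 5)
  post[, 1:2] <- post[, 1:2] + 3
  expect_lt(mean(odit_detect(m, pre, h = Inf)$evidence), 0)
  expect_gt(mean(odit_detect(m, post, h = Inf)$evidence), 0)
})

test_that("calibration is monotone in the target and validates on fresh data", {
  m <- small_model(n = 3000, d = 10)
  set.seed(21)
  nominal <- lapply(1:100, function(i) matrix(rnorm(100 * 10), ncol = 10))
  cal_loose <- odit_calibrate(m, nominal, target_far = 0.5)
  cal_tight <- odit_calibrate(m, nominal, target_far = 0.05)
  expect_gte(cal_tight$h, cal_loose$h)
  expect_equal(odit_calibrate(m, nominal, target_far = 1)$h, 0.01)  # smallest grid h
  # fresh nominal streams: empirical FAR within binomial sampling error
  fresh <- lapply(1:100, function(i) matrix(rnorm(100 * 10), ncol = 10))
  far_fresh <- mean(vapply(fresh, function(s)
    length(odit_detect(m, s, h = cal_tight$h)$alarms) > 0, logical(1)))
  expect_lte(far_fresh, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 100))
  # unachievable target falls back to the top of the grid with a warning
  hot <- list(matrix(rnorm(50 * 10, mean = 8), ncol = 10))
  expect_warning(cal_bad <- odit_calibrate(m, hot, target_far = 0.001),
                 "unachievable")
  expect_equal(cal_bad$h, 1000)
})

test_that("state ring buffer stays within its cap and tracks coverage", {
  m <- odit_fit(gauss_train(400, 2), odit_params(seed = 1, buffer_cap = 5))
  st <- odit_new_state(m)
  set.seed(31)
  for (t in 1:30) st <- odit_step(st, rnorm(2, mean = 5), m, h = Inf)$state
  expect_lte(nrow(st$contrib), 5)
  expect_equal(st$contrib_from + nrow(st$contrib) - 1L, st$t)
})
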