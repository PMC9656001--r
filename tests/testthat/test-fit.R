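test_that("partitioning is disjoint, exhaustive, sized, and seeded", {
  x <- gauss_train(10, 2)
  p <- odit_params(n1_frac = 0.3, seed = 4)
  parts <- partition_training(x, p)
  expect_equal(nrow(parts$x1), 3)
  expect_equal(nrow(parts$x2), 7)
  expect_length(intersect(parts$idx1, parts$idx2), 0)
  expect_setequal(c(parts$idx1, parts$idx2), 1:10)
  # same seed, same split
  parts2 <- partition_training(x, p)
  expect_identical(parts$idx1, parts2$idx1)
  # opt-out uses the full set on both sides
  pnp <- partition_training(x, odit_params(partition = FALSE))
  expect_identical(pnp$x1, x)
  expect_identical(pnp$x2, x)
})

test_that("too-small reference partitions are rejected", {
  x <- gauss_train(5, 2)
  expect_error(partition_training(x, odit_params(k = 10, n1_frac = 0.3)),
               "invalid-configuration")
})

test_that("K is the floor order-statistic index and L_K the K-th smallest", {
  # K = floor(N1 * (1 - alpha)): 100 * 0.95 -> 95
  m <- odit_fit(gauss_train(334, 2), odit_params(alpha = 0.05, seed = 2))
  expect_equal(m$N1, 100)
  expect_equal(m$K, 95)

  # independent order-statistic oracle on a fresh fit
  x <- gauss_train(500, 3, seed = 7)
  pars <- odit_params(alpha = 0.1, seed = 3)
  m2 <- odit_fit(x, pars)
  parts <- partition_training(x, pars)
  L <- apply(parts$x1, 1, function(q)
    total_distance(brute_knn(q, parts$x2, pars$k), pars))
  expect_equal(m2$L_K, sort(L)[m2$K])
  expect_equal(m2$sorted_L, sort(L))
  expect_false(is.unsorted(m2$sorted_L))

  # vanishing alpha: the floor leaves out a single point, so the borderline
  # is the second-largest training total distance
  m3 <- odit_fit(x, odit_params(alpha = 1e-9, seed = 3))
  expect_equal(m3$K, m3$N1 - 1)
  expect_equal(m3$L_K, sort(m3$sorted_L, decreasing = TRUE)[2])
})

test_that("degenerate fits error out", {
  # alpha so large that K = 0
  expect_error(odit_fit(gauss_train(20, 2), odit_params(alpha = 0.9, n1_frac = 0.3)),
               "invalid-configuration")
  # constant training data: borderline distance is zero
  x <- matrix(1, 50, 2)
  expect_error(odit_fit(x, odit_params(seed = 1)), "degenerate")
})

test_that("standardization uses training statistics and warns on constants", {
  x <- cbind(rnorm(200, mean = 5, sd = 10), rnorm(200))
  m <- odit_fit(x, odit_params(standardize = TRUE, seed = 1))
  expect_equal(m$center, colMeans(x))
  expect_equal(m$scale, apply(x, 2, sd))
  xc <- cbind(rnorm(200), rep(2, 200))
  expect_warning(odit_fit(xc, odit_params(standardize = TRUE, seed = 1)),
                 "zero-variance")
})

test_that("nominal contribution means match a direct recomputation", {
  x <- gauss_train(300, 4, seed = 10)
  pars <- odit_params(k = 3, s = 2, seed = 5)
  m <- odit_fit(x, pars)
  parts <- partition_training(x, pars)
  contrib <- t(apply(parts$x1, 1, function(q) {
    d2 <- colSums((t(parts$x2) - q)^2)
    nn <- order(d2, seq_along(d2))[(pars$k - pars$s + 1):pars$k]
    per_dim_contributions(q, parts$x2[nn, , drop = FALSE])
  }))
  expect_equal(m$mu, colMeans(contrib))
})

test_that("anomaly evidence has the sign and scale of the log ratio", {
  m <- small_model()
  expect_equal(anomaly_evidence(m$L_K, m), 0)
  expect_equal(anomaly_evidence(10, structure(list(d = 2, L_K = 1),
                                              class = "odit_model")),
               2 * log(10))
  expect_lt(anomaly_evidence(m$L_K / 2, m), 0)
  # log(0) guard: finite evidence for an exact duplicate of a reference row
  expect_true(is.finite(anomaly_evidence(0, m)))
})

test_that("minimum-volume set covers about 1 - alpha of fresh nominal data", {
  m <- small_model(n = 4000, d = 3, alpha = 0.05)
  fresh <- gauss_train(2000, 3, seed = 99)
  frac <- mean(mvs_contains(fresh, m))
  ci <- 0.95 + c(-1, 1) * 1.96 * sqrt(0.95 * 0.05 / 2000)
  # training-set finiteness widens the spread beyond the binomial CI a bit
  expect_gt(frac, ci[1] - 0.02)
  expect_lt(frac, ci[2] + 0.02)
  # the model's own ranked points with rank <= K are inside by construction
  parts <- partition_training(gauss_train(4000, 3), odit_params(seed = 42))
  inside <- which(mvs_contains(parts$x1, m))
  expect_gte(length(inside), m$K)
  # a far-away point is outside
  expect_false(mvs_contains(rep(100, 3), m))
})
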