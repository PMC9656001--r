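# Simulation designs: change in the mean of a multivariate Gaussian, change
# in its correlation structure (Wishart block), and a surrogate multichannel
# autoregressive stream for demos.

#' Change-in-mean simulation
#'
#' Nominal observations are i.i.d. standard multivariate Gaussian
#' (independent dimensions, unit variance, so a shift of `shift_sd` is a
#' shift in nominal standard deviations). Each trial stream is nominal up to
#' the change point `tau` and afterwards has `+shift_sd` added to a per-trial
#' random subset of `ceiling(frac_dims * d)` dimensions. The default design
#' shifts 5 of 50 dimensions by 3 standard deviations at `tau = 200`.
#'
#' @param d Dimensionality.
#' @param n_train Number of nominal training rows.
#' @param tau Change point (post-change rows are `tau + 1 ... horizon`).
#' @param shift_sd Shift magnitude in nominal standard deviations.
#' @param frac_dims Fraction of dimensions shifted (0 disables the change).
#' @param horizon Stream length per trial.
#' @param n_trials Number of trial streams.
#' @param n_nominal Additional nominal-only streams of length `tau`
#'   (for threshold calibration / FAR measurement); 0 for none.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return List with `train`, `streams` (list of `horizon x d` matrices),
#'   `shifted_dims` (list of integer vectors, the ground truth), `nominal`
#'   (list of `tau x d` nominal-only streams), and the design fields.
#' @export
gen_mean_change <- function(d = 50L, n_train = 50000L, tau = 200L,
                            shift_sd = 3, frac_dims = 0.1, horizon = 400L,
                            n_trials = 50L, n_nominal = 0L, seed = NULL) {
  if (frac_dims < 0 || frac_dims > 1)
    stop("invalid-configuration: 'frac_dims' must lie in [0, 1]", call. = FALSE)
  if (tau >= horizon)
    stop("invalid-configuration: 'tau' must be smaller than 'horizon'", call. = FALSE)
  n_shift <- as.integer(ceiling(frac_dims * d))
  with_seed(seed, {
    train <- matrix(stats::rnorm(n_train * d), n_train, d)
    streams <- vector("list", n_trials)
    shifted <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      x <- matrix(stats::rnorm(horizon * d), horizon, d)
      dims <- if (n_shift > 0L) sort(sample.int(d, n_shift)) else integer(0)
      if (n_shift > 0L && tau < horizon)
        x[(tau + 1L):horizon, dims] <- x[(tau + 1L):horizon, dims] + shift_sd
      streams[[i]] <- x
      shifted[[i]] <- dims
    }
    nominal <- lapply(seq_len(n_nominal), function(i)
      matrix(stats::rnorm(tau * d), tau, d))
    list(train = train, streams = streams, shifted_dims = shifted,
         nominal = nominal, d = d, tau = tau, horizon = horizon,
         shift_sd = shift_sd, n_shift = n_shift)
  })
}

#' Change-in-correlation simulation
#'
#' The nominal distribution is `N(0, Sigma0)` with diagonal covariance
#' `Sigma0 = diag(sigma_i^2)`, the variances drawn log-uniformly on
#' `[0.5, 2]`. After the change point a random `block x block` set of
#' dimensions becomes correlated: a Wishart sample is converted to a
#' correlation matrix and rescaled by the original `sigma_i`, so the
#' marginal variances are preserved exactly and only correlations change.
#' Off-block entries of `Sigma1` equal those of `Sigma0`.
#'
#' @param d Dimensionality (default 100).
#' @param tau Change point (default 100).
#' @param block Size of the correlated block (default 10; 0 for no change).
#' @param wishart_df Wishart degrees of freedom (default `block`, the
#'   smallest giving an almost-surely positive-definite sample and hence
#'   strong correlations).
#' @param n_train Nominal training rows.
#' @param horizon Stream length per trial.
#' @param n_trials Number of trial streams.
#' @param n_nominal Nominal-only streams of length `tau`.
#' @param seed RNG seed.
#' @return List with `train`, `streams`, `nominal`, `Sigma0`, `Sigma1`,
#'   `block_dims`, and the design fields.
#' @export
gen_corr_change <- function(d = 100L, tau = 100L, block = 10L,
                            wishart_df = block, n_train = 10000L,
                            horizon = 300L, n_trials = 50L, n_nominal = 0L,
                            seed = NULL) {
  if (block > d)
    stop("invalid-configuration: 'block' cannot exceed 'd'", call. = FALSE)
  if (block > 0L && wishart_df < block)
    stop("invalid-configuration: 'wishart_df' must be >= block", call. = FALSE)
  if (tau >= horizon)
    stop("invalid-configuration: 'tau' must be smaller than 'horizon'", call. = FALSE)
  with_seed(seed, {
    sigma2 <- exp(stats::runif(d, log(0.5), log(2)))
    sigma <- sqrt(sigma2)
    Sigma0 <- diag(sigma2, d)
    if (block > 0L) {
      block_dims <- sort(sample.int(d, block))
      corr <- diag(d)
      repeat {
        W <- stats::rWishart(1L, df = wishart_df, Sigma = diag(block) / wishart_df)[, , 1L]
        Rb <- stats::cov2cor(W)
        corr[block_dims, block_dims] <- Rb
        ok <- !inherits(try(chol(corr), silent = TRUE), "try-error")
        if (ok) break
      }
      Sigma1 <- corr * outer(sigma, sigma)
      # sqrt/square round trips are not bitwise-exact; the construction
      # guarantees equal variances, so pin the diagonal exactly
      diag(Sigma1) <- sigma2
    } else {
      block_dims <- integer(0)
      Sigma1 <- Sigma0
    }
    R1 <- chol(Sigma1)   # upper triangular: x = z %*% R1 has cov Sigma1
    rnom <- function(n) sweep(matrix(stats::rnorm(n * d), n, d), 2L, sigma, "*")
    train <- rnom(n_train)
    streams <- lapply(seq_len(n_trials), function(i) {
      pre <- rnom(tau)
      post <- matrix(stats::rnorm((horizon - tau) * d), horizon - tau, d) %*% R1
      rbind(pre, post)
    })
    nominal <- lapply(seq_len(n_nominal), function(i) rnom(tau))
    list(train = train, streams = streams, nominal = nominal,
         Sigma0 = Sigma0, Sigma1 = Sigma1, block_dims = block_dims,
         d = d, tau = tau, horizon = horizon)
  })
}

#' Surrogate multichannel physiological stream
#'
#' A synthetic stand-in for multichannel biosignal recordings (e.g. an
#' EEG-like seizure onset): each channel follows a stationary AR(1) process
#' with unit marginal variance; after `onset` the innovation amplitude grows
#' by a factor `1 + effect` and channels acquire a common driving factor, so
#' both per-channel variance and cross-channel coupling increase. This is a
#' synthetic demo generator, not a model of real recordings.
#'
#' @param channels Number of channels.
#' @param horizon Stream length.
#' @param onset Anomaly onset time (0 = anomalous from the start).
#' @param effect Effect size (0 = stationary throughout).
#' @param ar AR(1) coefficient in [0, 1).
#' @param seed RNG seed.
#' @return List with `stream` (`horizon x channels`), `onset`, `effect`.
#' @export
gen_surrogate_stream <- function(channels = 8L, horizon = 600L, onset = 300L,
                                 effect = 1, ar = 0.6, seed = NULL) {
  if (ar < 0 || ar >= 1)
    stop("invalid-configuration: 'ar' must lie in [0, 1)", call. = FALSE)
  if (onset > horizon)
    stop("invalid-configuration: 'onset' cannot exceed 'horizon'", call. = FALSE)
  with_seed(seed, {
    sd_innov <- sqrt(1 - ar^2)
    rho <- if (effect > 0) min(effect / (1 + effect), 0.9) else 0
    x <- matrix(0, horizon, channels)
    prev <- stats::rnorm(channels)
    for (t in seq_len(horizon)) {
      z <- stats::rnorm(channels)
      if (t > onset) {
        shared <- stats::rnorm(1L)
        innov <- (1 + effect) * (sqrt(1 - rho) * z + sqrt(rho) * shared)
      } else {
        innov <- z
      }
      prev <- ar * prev + sd_innov * innov
      x[t, ] <- prev
    }
    list(stream = x, onset = onset, effect = effect, channels = channels)
  })
}
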