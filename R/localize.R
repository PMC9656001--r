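# Anomaly localization: which dimensions drove the alarm? Each observation's
# total distance decomposes (in squared form) into per-dimension
# contributions; a one-sided t-test compares their post-onset means to the
# nominal training means.

#' Per-dimension distance contributions
#'
#' Squared-difference decomposition of the total distance over the summed
#' neighbors: `delta_i = sum_n (x_i - y_{n,i})^2`. With `gamma = 2` the
#' contributions sum exactly to the total distance. Contributions are always
#' computed in this squared form even when detection runs with another
#' `gamma`, because only squared distances decompose additively across
#' dimensions (which the t-test requires).
#'
#' @param x Numeric d-vector.
#' @param neighbors Numeric `s x d` matrix: the summed nearest-neighbor rows.
#' @return Numeric length-d vector of contributions.
#' @examples
#' per_dim_contributions(c(0, 0), matrix(c(1, 2), 1))  # 1 4
#' @export
per_dim_contributions <- function(x, neighbors) {
  if (!is.matrix(neighbors)) neighbors <- matrix(as.numeric(neighbors), nrow = 1L)
  if (length(x) != ncol(neighbors))
    stop("input-format: 'x' and 'neighbors' dimensionality differ", call. = FALSE)
  diff <- sweep(neighbors, 2L, as.numeric(x))
  colSums(diff * diff)
}

#' Estimate the anomaly onset from a statistic trace
#'
#' The onset estimate is the most recent time strictly before the alarm at
#' which the detection statistic was zero: `tau_hat = max(t < T : Delta_t = 0)`,
#' or 0 (the pre-stream sentinel, where `Delta_0 = 0`) if the statistic
#' never touched zero.
#'
#' @param statistic Numeric trace `Delta_1 ... Delta_n`.
#' @param t_alarm Alarm time `T` (index into `statistic`).
#' @return Integer onset estimate in `0 ... T - 1`.
#' @examples
#' estimate_onset(c(0, 0, 1, 2, 6), 5)  # 2
#' @export
estimate_onset <- function(statistic, t_alarm) {
  t_alarm <- as.integer(t_alarm)
  if (t_alarm < 1L || t_alarm > length(statistic))
    stop("input-format: 't_alarm' outside the trace", call. = FALSE)
  zeros <- which(statistic[seq_len(t_alarm - 1L)] == 0)
  if (length(zeros) == 0L) 0L else max(zeros)
}

#' Localization t-test threshold
#'
#' Upper `(1 - beta)` quantile of Student's t distribution with `S - 1`
#' degrees of freedom (e.g. 6.314 for `beta = 0.05`, `S = 2`).
#'
#' @param beta One-sided significance level in (0, 1).
#' @param S Number of post-onset samples (`>= 2`).
#' @return The threshold `theta`.
#' @export
t_threshold <- function(beta, S) {
  S <- as.integer(S)
  if (S < 2L)
    stop("invalid-configuration: 'S' must be >= 2 (at least 1 degree of freedom)",
         call. = FALSE)
  if (!is.numeric(beta) || beta <= 0 || beta >= 1)
    stop("invalid-configuration: 'beta' must lie in (0, 1)", call. = FALSE)
  stats::qt(1 - beta, df = S - 1L)
}

#' Localize the anomalous dimensions after a detection
#'
#' Takes the `S` contribution vectors at times `tau_hat + 1 ... tau_hat + S`
#' (possibly extending past the detection time itself), computes each
#' dimension's sample mean and standard deviation, and flags dimension `i`
#' anomalous iff the one-sided t statistic
#' `(mean_i - mu_i) / (sd_i / sqrt(S))` reaches the `(1 - beta)` Student-t
#' quantile, where `mu_i` is the nominal training contribution mean stored
#' in the model. Dimensions with zero sample standard deviation are flagged
#' iff their mean exceeds `mu_i` (the t statistic is reported as +/-Inf).
#'
#' @param detection An [odit_detect()] result with at least one alarm, or an
#'   `odit_state` whose buffer covers the required times.
#' @param model The fitted model (supplies `mu`).
#' @param S Number of post-onset samples (`>= 2`). Small values react
#'   fastest; the analysis happens at time `tau_hat + S`.
#' @param beta One-sided significance level.
#' @param alarm Which alarm of the detection to localize (default first).
#' @return An `odit_localization` object: `tau_hat`, `S`, `beta`, `theta`,
#'   `t_stats` (length d), `flagged` (integer indices), and the contribution
#'   means `delta_bar`.
#' @export
odit_localize <- function(detection, model, S = 10L, beta = 0.05, alarm = 1L) {
  stopifnot(inherits(model, "odit_model"))
  S <- as.integer(S)
  theta <- t_threshold(beta, S)

  if (inherits(detection, "odit_state")) {
    tau_hat <- detection$last_zero
    need <- (tau_hat + 1L):(tau_hat + S)
    avail <- detection$contrib_from + seq_len(nrow(detection$contrib)) - 1L
    if (!all(need %in% avail))
      stop(sprintf(paste("localization needs contributions for times %d..%d;",
                         "state buffer covers %s"),
                   min(need), max(need),
                   if (length(avail)) sprintf("%d..%d", min(avail), max(avail))
                   else "nothing"), call. = FALSE)
    Q <- detection$contrib[match(need, avail), , drop = FALSE]
  } else if (inherits(detection, "odit_detection")) {
    if (length(detection$alarms) < alarm)
      stop("input-format: detection has no such alarm to localize", call. = FALSE)
    tau_hat <- detection$alarms[[alarm]]$tau_hat
    if (tau_hat + S > nrow(detection$contrib))
      stop(sprintf(paste("localization needs %d post-onset samples but the",
                         "stream ends at t = %d (onset estimate %d); supply",
                         "a longer stream or smaller S"),
                   S, nrow(detection$contrib), tau_hat), call. = FALSE)
    Q <- detection$contrib[(tau_hat + 1L):(tau_hat + S), , drop = FALSE]
  } else {
    stop("input-format: 'detection' must be an odit_detection or odit_state",
         call. = FALSE)
  }

  delta_bar <- colMeans(Q)
  eta <- apply(Q, 2L, stats::sd)
  t_stats <- (delta_bar - model$mu) / (eta / sqrt(S))
  degenerate <- eta == 0
  if (any(degenerate))
    t_stats[degenerate] <- ifelse(delta_bar[degenerate] > model$mu[degenerate],
                                  Inf, -Inf)
  flagged <- which(t_stats >= theta)
  structure(list(tau_hat = tau_hat, S = S, beta = beta, theta = theta,
                 t_stats = t_stats, delta_bar = delta_bar, eta = eta,
                 flagged = flagged),
            class = "odit_localization")
}

#' @export
print.odit_localization <- function(x, ...) {
  cat(sprintf("ODIT localization: onset estimate %d, S = %d, beta = %g (theta = %.4g)\n",
              x$tau_hat, x$S, x$beta, x$theta))
  if (length(x$flagged) == 0L) cat("  no dimensions flagged\n")
  else cat("  flagged dimensions:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
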