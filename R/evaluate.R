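# Trial-based evaluation: average detection delay vs false alarm rate over
# a threshold grid, localization ROC, and the exact Gaussian CUSUM used as
# an optimality reference in matched simulations.

#' ADD/FAR table over a threshold grid
#'
#' For each threshold `h`: the false alarm rate is the fraction of trials
#' whose first alarm precedes the change point `tau`; the detection rate is
#' the fraction of trials with an alarm at `t >= tau` within the horizon
#' (monitoring restarts after a false alarm); the average detection delay
#' is the mean of `T - tau` over detected trials, with `T` the first alarm
#' at or after `tau`.
#'
#' @param model A fitted [odit_fit()] model.
#' @param streams List of trial streams (each `horizon x d`).
#' @param tau True change point shared by the trials.
#' @param h_grid Increasing threshold grid.
#' @return A data frame `(h, far, detection_rate, add, n_detected)`; `add`
#'   is `NA` where no trial detected.
#' @export
run_trials <- function(model, streams, tau, h_grid) {
  stopifnot(inherits(model, "odit_model"))
  if (length(streams) < 1L)
    stop("invalid-configuration: need at least one trial stream", call. = FALSE)
  h_grid <- sort(h_grid)
  traces <- lapply(streams, function(s) odit_detect(model, s, h = Inf)$evidence)
  res <- lapply(h_grid, function(h) {
    per <- vapply(traces, function(D) {
      cur <- 0; first_alarm <- NA_integer_; first_detect <- NA_integer_
      for (t in seq_along(D)) {
        cur <- max(cur + D[t], 0)
        if (cur >= h) {
          if (is.na(first_alarm)) first_alarm <- t
          if (t >= tau) { first_detect <- t; break }
          cur <- 0   # restart after a false alarm, keep monitoring
        }
      }
      c(first_alarm, first_detect)
    }, numeric(2))
    fa <- per[1L, ]; det <- per[2L, ]
    far <- mean(!is.na(fa) & fa < tau)
    detected <- !is.na(det)
    data.frame(h = h, far = far, detection_rate = mean(detected),
               add = if (any(detected)) mean(det[detected] - tau) else NA_real_,
               n_detected = sum(detected))
  })
  do.call(rbind, res)
}

#' Localization ROC curve and AUC
#'
#' Pools per-dimension localization scores (t statistics) and ground-truth
#' anomaly labels over trials, sweeps a threshold, and reports
#' (FPR, TPR) points augmented with (0,0) and (1,1) plus the trapezoidal
#' area under the curve.
#'
#' @param scores Numeric vector (or matrix) of per-dimension scores.
#' @param truth Logical vector (or matrix) of the same shape: `TRUE` for a
#'   genuinely anomalous dimension.
#' @param theta_grid Threshold sweep; defaults to all distinct scores.
#' @return List with `points` (data frame `theta`, `fpr`, `tpr`) and `auc`.
#' @export
localization_roc <- function(scores, truth, theta_grid = NULL) {
  scores <- as.numeric(scores); truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("input-format: 'scores' and 'truth' lengths differ", call. = FALSE)
  if (!any(truth) || all(truth))
    stop("invalid-configuration: need both anomalous and nominal dimensions",
         call. = FALSE)
  if (is.null(theta_grid)) theta_grid <- sort(unique(scores))
  theta_grid <- sort(theta_grid)
  tpr <- vapply(theta_grid, function(th) mean(scores[truth] >= th), numeric(1))
  fpr <- vapply(theta_grid, function(th) mean(scores[!truth] >= th), numeric(1))
  pts <- data.frame(theta = c(Inf, theta_grid, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Exact Gaussian CUSUM (optimality reference)
#'
#' The cumulative-sum test with known pre- and post-change Gaussian
#' parameters: `S_t = max(0, S_{t-1} + l_t)` with the exact log-likelihood
#' ratio `l_t`, stopping when `S_t >= h`. With the true distributions known
#' this is the minimax-optimal benchmark that the nonparametric detector's
#' delay cannot beat. Provided for simulation comparisons, not as a
#' production detector.
#'
#' @param stream Numeric `T x d` matrix.
#' @param mean0,mean1 Pre-/post-change mean vectors (length d).
#' @param cov Common covariance matrix (default identity).
#' @param h Threshold; `Inf` for trace only.
#' @return List with `llr` (per-row log-likelihood ratios), `statistic`
#'   (the CUSUM trace), and `t_alarm` (first crossing, `NA` if none).
#' @export
cusum_gaussian <- function(stream, mean0, mean1, cov = NULL, h = Inf) {
  if (!is.matrix(stream)) stream <- matrix(as.numeric(stream), nrow = 1L)
  d <- ncol(stream)
  mean0 <- rep_len(as.numeric(mean0), d)
  mean1 <- rep_len(as.numeric(mean1), d)
  if (is.null(cov)) cov <- diag(d)
  # l_t = (m1-m0)' Sigma^-1 (x - (m0+m1)/2) for a common covariance
  w <- solve(cov, mean1 - mean0)
  centered <- sweep(stream, 2L, (mean0 + mean1) / 2)
  llr <- drop(centered %*% w)
  s <- numeric(length(llr)); cur <- 0
  for (t in seq_along(llr)) {
    cur <- max(0, cur + llr[t])
    s[t] <- cur
  }
  crossing <- which(s >= h)
  list(llr = llr, statistic = s,
       t_alarm = if (length(crossing)) crossing[1L] else NA_integer_)
}
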