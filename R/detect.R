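# Test phase: CUSUM-like accumulation of the anomaly evidence,
# Delta_t = max(Delta_{t-1} + D_t, 0), alarm when Delta_t >= h.

#' Initialize a running detector state
#'
#' @param model A fitted [odit_fit()] model.
#' @return An `odit_state` object: time index `t = 0`, statistic
#'   `delta = 0`, last-zero time `0` (the pre-stream sentinel, so the onset
#'   estimate is defined even if the statistic never returns to zero), and
#'   an empty contribution buffer (capped at `params$buffer_cap` rows;
#'   truncated from the oldest end).
#' @export
odit_new_state <- function(model) {
  stopifnot(inherits(model, "odit_model"))
  structure(list(t = 0L, delta = 0, last_zero = 0L,
                 contrib = matrix(0, 0L, model$d), contrib_from = 1L,
                 alarmed = FALSE),
            class = "odit_state")
}

#' @export
print.odit_state <- function(x, ...) {
  cat(sprintf("ODIT state: t = %d, Delta = %.4g, last zero at %d, alarmed: %s\n",
              x$t, x$delta, x$last_zero, x$alarmed))
  invisible(x)
}

#' Advance the detector by one observation
#'
#' Computes the kNN total distance of `x_t` against the model reference via
#' the configured backend, converts it to anomaly evidence `D_t`, and
#' updates `Delta_t = max(Delta_{t-1} + D_t, 0)`. Per-dimension
#' contributions are appended to the state's ring buffer for later
#' localization; the buffer covers times `last_zero + 1 ... t`.
#'
#' @param state An `odit_state` from [odit_new_state()] or a previous step.
#' @param x_t Numeric d-vector, the observation at time `t + 1`.
#' @param model The fitted model.
#' @param h Detection threshold; defaults to `model$params$h`.
#' @return List `(state, D, alarm)`; `alarm` is `TRUE` iff `Delta_t >= h`.
#' @export
odit_step <- function(state, x_t, model, h = model$params$h) {
  stopifnot(inherits(state, "odit_state"))
  ev <- evidence_batch(model, x_t, contributions = TRUE)
  t <- state$t + 1L
  delta <- max(state$delta + ev$D, 0)
  contrib <- rbind(state$contrib, ev$contrib)
  contrib_from <- state$contrib_from
  if (delta == 0) {
    state$last_zero <- t
    contrib <- matrix(0, 0L, model$d)   # history before a zero is never used
    contrib_from <- t + 1L
  }
  cap <- model$params$buffer_cap
  if (nrow(contrib) > cap) {
    drop_n <- nrow(contrib) - cap
    contrib <- contrib[-seq_len(drop_n), , drop = FALSE]
    contrib_from <- contrib_from + drop_n
  }
  state$t <- t
  state$delta <- delta
  state$contrib <- contrib
  state$contrib_from <- contrib_from
  alarm <- delta >= h
  state$alarmed <- state$alarmed || alarm
  list(state = state, D = ev$D, alarm = alarm)
}

#' Run the detector over a finite stream
#'
#' Computes the evidence and statistic traces for every row of `stream`
#' (rows are time-ordered observations) and reports alarms. In single-alarm
#' mode (`restart = FALSE`) only the first threshold crossing is reported
#' and the statistic trace continues uninterrupted; with `restart = TRUE`
#' the statistic is reset to zero after each alarm and monitoring continues
#' (multi-anomaly mode).
#'
#' @param model A fitted [odit_fit()] model.
#' @param stream Numeric `T x d` matrix.
#' @param h Detection threshold (`>= 0`); defaults to `model$params$h`.
#' @param restart Reset and continue after an alarm?
#' @return An `odit_detection` object: `evidence` (`D_t`), `statistic`
#'   (`Delta_t`), `alarms` (list of reports with stopping time `t_alarm`,
#'   onset estimate `tau_hat`, and the statistic value), the per-dimension
#'   contribution matrix used by [odit_localize()], `h`, and `restart`.
#' @examples
#' x <- matrix(rnorm(2000), ncol = 2)
#' m <- odit_fit(x, odit_params(seed = 1))
#' det <- odit_detect(m, matrix(rnorm(100, mean = 4), ncol = 2), h = 10)
#' length(det$alarms) >= 1
#' @export
odit_detect <- function(model, stream, h = model$params$h, restart = FALSE) {
  stopifnot(inherits(model, "odit_model"))
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0)
    stop("invalid-configuration: 'h' must be >= 0", call. = FALSE)
  if (!is.matrix(stream)) stream <- matrix(as.numeric(stream), nrow = 1L)
  if (nrow(stream) == 0L) {
    return(structure(list(evidence = numeric(0), statistic = numeric(0),
                          alarms = list(), contrib = matrix(0, 0, model$d),
                          h = h, restart = restart),
                     class = "odit_detection"))
  }
  ev <- evidence_batch(model, stream, contributions = TRUE)
  n <- length(ev$D)
  delta <- numeric(n)
  alarms <- list()
  cur <- 0; lz <- 0L
  for (t in seq_len(n)) {
    cur <- max(cur + ev$D[t], 0)
    delta[t] <- cur
    if (cur >= h && (restart || length(alarms) == 0L)) {
      alarms[[length(alarms) + 1L]] <-
        list(t_alarm = t, tau_hat = lz, statistic = cur)
      if (restart) {
        # trace keeps the crossing value at t; accumulation restarts at 0
        cur <- 0
        lz <- t
        next
      }
    }
    if (cur == 0) lz <- t
  }
  structure(list(evidence = ev$D, statistic = delta, alarms = alarms,
                 contrib = ev$contrib, h = h, restart = restart),
            class = "odit_detection")
}

#' @export
print.odit_detection <- function(x, ...) {
  cat(sprintf("ODIT detection over %d observations (h = %g, %s mode)\n",
              length(x$evidence), x$h,
              if (x$restart) "restart" else "single-alarm"))
  if (length(x$alarms) == 0L) {
    cat("  no alarms\n")
  } else {
    for (a in x$alarms)
      cat(sprintf("  alarm at t = %d (estimated onset %d, Delta = %.4g)\n",
                  a$t_alarm, a$tau_hat, a$statistic))
  }
  invisible(x)
}

#' Calibrate the detection threshold against a false alarm constraint
#'
#' Sweeps a threshold grid and returns the smallest `h` whose empirical
#' false-alarm frequency over nominal-only streams is at most `target_far`.
#' A stream raises a false alarm at threshold `h` iff its statistic trace
#' ever reaches `h`, so the whole sweep needs only the per-stream maximum
#' of `Delta_t`.
#'
#' @param model A fitted [odit_fit()] model.
#' @param nominal_streams A list of nominal `T x d` matrices (or one matrix).
#' @param target_far Target false-alarm fraction in (0, 1].
#' @param h_grid Increasing threshold grid; defaults to 60 points
#'   log-spaced on `[1e-2, 1e3]`.
#' @return An `odit_calibration` object: chosen `h`, the `(h, far)` table,
#'   and the per-stream statistic maxima.
#' @export
odit_calibrate <- function(model, nominal_streams, target_far,
                           h_grid = 10 ^ seq(-2, 3, length.out = 60)) {
  stopifnot(inherits(model, "odit_model"))
  if (!is.list(nominal_streams)) nominal_streams <- list(nominal_streams)
  if (length(nominal_streams) < 1L)
    stop("invalid-configuration: need at least one nominal stream", call. = FALSE)
  if (!is.numeric(target_far) || target_far <= 0 || target_far > 1)
    stop("invalid-configuration: 'target_far' must lie in (0, 1]", call. = FALSE)
  h_grid <- sort(h_grid)
  maxima <- vapply(nominal_streams, function(s) {
    det <- odit_detect(model, s, h = Inf)
    if (length(det$statistic) == 0L) 0 else max(det$statistic)
  }, numeric(1))
  far <- vapply(h_grid, function(h) mean(maxima >= h), numeric(1))
  ok <- which(far <= target_far)
  if (length(ok) == 0L) {
    warning("target FAR unachievable on the grid; returning its maximum")
    h <- h_grid[length(h_grid)]
  } else {
    h <- h_grid[ok[1L]]
  }
  structure(list(h = h, target_far = target_far,
                 table = data.frame(h = h_grid, far = far),
                 maxima = maxima),
            class = "odit_calibration")
}

#' @export
print.odit_calibration <- function(x, ...) {
  cat(sprintf("ODIT threshold calibration: h = %g for target FAR %g (%d nominal streams)\n",
              x$h, x$target_far, length(x$maxima)))
  invisible(x)
}
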