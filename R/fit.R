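# Training phase: estimate the minimum-volume set of the nominal data via
# ranked kNN total distances, and record the per-dimension contribution
# means needed later for localization.

LOG_FLOOR <- 1e-12  # guards log(0) when a test point duplicates a reference row

#' Randomly partition a nominal training set
#'
#' Splits the `N` training rows into a ranked set `X1` (fraction
#' `n1_frac`, rounded) whose total distances define the minimum-volume-set
#' boundary, and a reference set `X2` against which all kNN distances are
#' computed. With `partition = FALSE` both sets are the full matrix.
#'
#' @param x Numeric `N x d` training matrix.
#' @param params An [odit_params()] object (`n1_frac`, `seed`, `partition`, `k`).
#' @return List with matrices `x1`, `x2` and the row indices `idx1`, `idx2`.
#' @export
partition_training <- function(x, params = odit_params()) {
  x <- check_matrix(x, "x")
  N <- nrow(x)
  if (N < 2L) stop("invalid-configuration: need at least 2 training rows",
                   call. = FALSE)
  if (!params$partition) {
    return(list(x1 = x, x2 = x, idx1 = seq_len(N), idx2 = seq_len(N)))
  }
  N1 <- as.integer(round(params$n1_frac * N))
  N2 <- N - N1
  if (N1 < 1L)
    stop("invalid-configuration: n1_frac yields an empty ranked set", call. = FALSE)
  if (N2 < params$k)
    stop(sprintf("invalid-configuration: reference set size %d is smaller than k = %d",
                 N2, params$k), call. = FALSE)
  perm <- with_seed(params$seed, sample.int(N))
  idx1 <- sort(perm[seq_len(N1)])
  idx2 <- sort(perm[(N1 + 1L):N])
  list(x1 = x[idx1, , drop = FALSE], x2 = x[idx2, , drop = FALSE],
       idx1 = idx1, idx2 = idx2)
}

#' Fit the nominal model
#'
#' Training phase of the online discrepancy test. The rows of the ranked
#' partition are ordered by their kNN total distance to the reference
#' partition; the `K = floor(N1 * (1 - alpha))`-th smallest total distance
#' `L_(K)` is the borderline of the estimated minimum-volume set containing
#' roughly mass `1 - alpha` of the nominal distribution. The fit also stores
#' the per-dimension nominal contribution means used by the localization
#' t-test, and (optionally) per-dimension standardization statistics.
#'
#' @param x Numeric `N x d` nominal training matrix (rows = observations).
#' @param params An [odit_params()] object.
#' @return An object of class `odit_model` with elements `reference`
#'   (the reference partition, standardized if requested), `d`, `N1`, `N2`,
#'   `K`, `L_K`, `sorted_L`, `mu` (length-`d` nominal contribution means),
#'   `center`/`scale`, `params`, and `tree` (approximate backend only).
#' @examples
#' x <- matrix(rnorm(400), ncol = 2)
#' m <- odit_fit(x, odit_params(alpha = 0.1, seed = 1))
#' m$K  # floor(0.3 * 200 * 0.9)
#' @export
odit_fit <- function(x, params = odit_params()) {
  x <- check_matrix(x, "x")
  d <- ncol(x)

  center <- rep(0, d); scale <- rep(1, d)
  if (params$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    if (any(scale == 0)) {
      warning("zero-variance dimension(s); scale forced to 1")
      scale[scale == 0] <- 1
    }
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }

  parts <- partition_training(x, params)
  N1 <- nrow(parts$x1); N2 <- nrow(parts$x2)
  K <- floor(N1 * (1 - params$alpha))
  if (K < 1L)
    stop("invalid-configuration: alpha too large, K = floor(N1*(1-alpha)) = 0",
         call. = FALSE)

  tree <- NULL
  if (params$knn_backend == "approximate") {
    tree <- kmeans_tree(parts$x2, C = params$tree_c, imax = params$tree_imax,
                        leaf_size = params$tree_leaf_size, seed = params$seed)
    nn <- tree_query(tree, parts$x1, k = params$k, B = params$tree_b)
  } else {
    nn <- knn_query(parts$x1, parts$x2, k = params$k)
  }

  L <- total_distance(nn$dist, params)
  sorted_L <- sort(L)
  L_K <- sorted_L[K]
  if (L_K <= 0)
    stop(paste("degenerate training: borderline total distance is zero",
               "(at least K duplicated points)"), call. = FALSE)

  # nominal per-dimension contribution means (squared form, s neighbors)
  cols <- (params$k - params$s + 1L):params$k
  contrib <- matrix(0, N1, d)
  for (n in cols) {
    diff <- parts$x1 - parts$x2[nn$idx[, n], , drop = FALSE]
    contrib <- contrib + diff * diff
  }
  mu <- colMeans(contrib)

  structure(
    list(reference = parts$x2, d = d, N1 = N1, N2 = N2, K = K,
         L_K = L_K, sorted_L = sorted_L, mu = mu,
         center = center, scale = scale, params = params, tree = tree),
    class = "odit_model")
}

#' @export
print.odit_model <- function(x, ...) {
  cat("ODIT nominal model\n")
  cat(sprintf("  d = %d, N1 = %d, N2 = %d, K = %d, L_(K) = %.6g\n",
              x$d, x$N1, x$N2, x$K, x$L_K))
  cat(sprintf("  backend: %s, standardized: %s\n",
              x$params$knn_backend, x$params$standardize))
  invisible(x)
}

#' Anomaly evidence from a total distance
#'
#' `D = d * (log L - log L_(K))`: positive when the observation's total kNN
#' distance exceeds the minimum-volume-set borderline, negative when it
#' falls inside. As the reference set grows (with `k = s = gamma = 1`) this
#' converges to the log-likelihood ratio against a uniform alternative
#' pinned at the density level of the borderline point.
#'
#' @param L Total distance(s), `>= 0` (floored at `1e-12` before the log).
#' @param model A fitted [odit_fit()] model.
#' @return Evidence value(s), same length as `L`.
#' @export
anomaly_evidence <- function(L, model) {
  stopifnot(inherits(model, "odit_model"))
  model$d * (log(pmax(L, LOG_FLOOR)) - log(model$L_K))
}

#' Minimum-volume-set membership
#'
#' One-shot outlier rule: a point is inside the estimated minimum-volume
#' set iff its total kNN distance does not exceed the borderline `L_(K)`.
#' On fresh nominal data the containment fraction approaches `1 - alpha`.
#'
#' @param x A d-vector or an `n x d` matrix of points.
#' @param model A fitted [odit_fit()] model.
#' @return Logical vector.
#' @export
mvs_contains <- function(x, model) {
  stopifnot(inherits(model, "odit_model"))
  ev <- evidence_batch(model, x)
  ev$L <= model$L_K
}

# Shared test-phase computation: standardize, kNN against the reference via
# the configured backend, total distances, evidence, and per-dimension
# contributions (squared form over the s summed neighbors).
evidence_batch <- function(model, stream, contributions = FALSE) {
  if (!is.matrix(stream)) stream <- matrix(as.numeric(stream), nrow = 1L)
  stream <- check_matrix(stream, "stream")
  if (ncol(stream) != model$d)
    stop(sprintf("input-format: stream has %d dimensions, model expects %d",
                 ncol(stream), model$d), call. = FALSE)
  p <- model$params
  y <- sweep(sweep(stream, 2L, model$center), 2L, model$scale, "/")
  nn <- if (p$knn_backend == "approximate")
    tree_query(model$tree, y, k = p$k, B = p$tree_b)
  else
    knn_query(y, model$reference, k = p$k)
  L <- total_distance(nn$dist, p)
  out <- list(L = L, D = anomaly_evidence(L, model))
  if (contributions) {
    cols <- (p$k - p$s + 1L):p$k
    contrib <- matrix(0, nrow(y), model$d)
    for (n in cols) {
      diff <- y - model$reference[nn$idx[, n], , drop = FALSE]
      contrib <- contrib + diff * diff
    }
    out$contrib <- contrib
  }
  out
}
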