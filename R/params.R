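#' Tuning parameters for the online discrepancy test
#'
#' Collects and validates every tuning knob of the detector. The defaults
#' (`k = s = gamma = 1`, `alpha = 0.05`, `n1_frac = 0.3`) are the typical
#' values recommended for the method; only the detection threshold `h`
#' directly trades detection delay against false alarms, the remaining
#' parameters are auxiliary.
#'
#' @param k Number of nearest neighbors used for the total distance
#'   (positive integer).
#' @param s Number of summed neighbors, `1 <= s <= k`. `s = 1` uses only the
#'   k-th neighbor; `s = k` sums all k.
#' @param gamma Distance exponent (> 0). Larger values emphasize large
#'   distances.
#' @param alpha Significance level of the minimum-volume-set estimate,
#'   in (0, 1). The borderline total distance is the `floor(N1 * (1 - alpha))`-th
#'   order statistic of the training total distances.
#' @param h Detection threshold (>= 0). `Inf` disables alarms.
#' @param n1_frac Fraction of the training set assigned to the ranked
#'   partition `X_N1`, in (0, 1). The remainder `X_N2` is the kNN reference.
#' @param partition If `FALSE`, skip the random partition and use the full
#'   training set both as ranked set and reference (small-data mode).
#' @param standardize If `TRUE`, z-score every dimension by training-set
#'   statistics before distance computations. Off by default: Euclidean
#'   distances are scale-sensitive and standardization changes the geometry.
#' @param seed Integer RNG seed controlling the random partition (and the
#'   k-means tree when the approximate backend is used). `NULL` uses the
#'   current RNG state.
#' @param knn_backend `"exact"` (full search over the reference set) or
#'   `"approximate"` (priority-search k-means tree).
#' @param tree_c Branching factor C of the k-means tree (approximate backend).
#' @param tree_b Search budget B: maximum number of candidate reference
#'   points examined per query. Must be `>= k`.
#' @param tree_imax Maximum Lloyd iterations per tree node.
#' @param tree_leaf_size Maximum number of points held in a tree leaf.
#' @param buffer_cap Upper bound on the per-dimension contribution history
#'   retained by a running detector state (ring buffer; oldest entries are
#'   dropped first).
#'
#' @return An object of class `odit_params` (a validated list).
#' @examples
#' p <- odit_params(k = 2, s = 2, alpha = 0.1)
#' p$k
#' @export
odit_params <- function(k = 1L, s = 1L, gamma = 1, alpha = 0.05, h = Inf,
                        n1_frac = 0.3, partition = TRUE, standardize = FALSE,
                        seed = NULL, knn_backend = c("exact", "approximate"),
                        tree_c = 100L, tree_b = 1000L, tree_imax = 10L,
                        tree_leaf_size = 32L, buffer_cap = 10000L) {
  knn_backend <- match.arg(knn_backend)
  k <- as.integer(k); s <- as.integer(s)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("invalid-configuration: 'k' must be a positive integer", call. = FALSE)
  if (length(s) != 1L || is.na(s) || s < 1L || s > k)
    stop("invalid-configuration: 's' must satisfy 1 <= s <= k", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("invalid-configuration: 'gamma' must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("invalid-configuration: 'alpha' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0)
    stop("invalid-configuration: 'h' must be >= 0", call. = FALSE)
  if (!is.numeric(n1_frac) || length(n1_frac) != 1L || is.na(n1_frac) ||
      n1_frac <= 0 || n1_frac >= 1)
    stop("invalid-configuration: 'n1_frac' must lie in (0, 1)", call. = FALSE)
  tree_c <- as.integer(tree_c); tree_b <- as.integer(tree_b)
  tree_imax <- as.integer(tree_imax); tree_leaf_size <- as.integer(tree_leaf_size)
  if (tree_c < 2L)
    stop("invalid-configuration: 'tree_c' must be >= 2", call. = FALSE)
  if (tree_b < k)
    stop("invalid-configuration: 'tree_b' must be >= k", call. = FALSE)
  if (tree_imax < 1L || tree_leaf_size < 1L)
    stop("invalid-configuration: 'tree_imax' and 'tree_leaf_size' must be >= 1",
         call. = FALSE)
  buffer_cap <- as.integer(buffer_cap)
  if (buffer_cap < 2L)
    stop("invalid-configuration: 'buffer_cap' must be >= 2", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)

  structure(
    list(k = k, s = s, gamma = gamma, alpha = alpha, h = h,
         n1_frac = n1_frac, partition = isTRUE(partition),
         standardize = isTRUE(standardize), seed = seed,
         knn_backend = knn_backend, tree_c = tree_c, tree_b = tree_b,
         tree_imax = tree_imax, tree_leaf_size = tree_leaf_size,
         buffer_cap = buffer_cap),
    class = "odit_params")
}

#' @export
print.odit_params <- function(x, ...) {
  cat("ODIT parameters\n")
  cat(sprintf("  k = %d, s = %d, gamma = %g, alpha = %g, h = %g\n",
              x$k, x$s, x$gamma, x$alpha, x$h))
  cat(sprintf("  partition: %s (n1_frac = %g), standardize: %s\n",
              x$partition, x$n1_frac, x$standardize))
  cat(sprintf("  kNN backend: %s", x$knn_backend))
  if (x$knn_backend == "approximate")
    cat(sprintf(" (C = %d, B = %d, Imax = %d, leaf = %d)",
                x$tree_c, x$tree_b, x$tree_imax, x$tree_leaf_size))
  cat("\n")
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# shared input check for observation matrices
check_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("input-format: '%s' must be a numeric matrix", name),
         call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!apply(is.finite(x), 1L, all))[1L]
    stop(sprintf("input-format: '%s' contains non-finite values (first bad row: %d)",
                 name, bad), call. = FALSE)
  }
  x
}
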