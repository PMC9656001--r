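#' Exact k-nearest-neighbor distances
#'
#' Euclidean distances from a query point to its `k` nearest rows of a
#' reference matrix, in nondecreasing order. Ties are broken by reference
#' row index so results are deterministic.
#'
#' @param query Numeric vector of length `d` (or 1 x d matrix).
#' @param reference Numeric `M x d` matrix, `M >= k`.
#' @param k Number of neighbors.
#' @return Numeric vector of length `k`, nondecreasing.
#' @examples
#' knn_distances(0.4, matrix(c(0, 1, 3), ncol = 1), k = 2)  # 0.4 0.6
#' @export
knn_distances <- function(query, reference, k = 1L) {
  res <- knn_query(matrix(as.numeric(query), nrow = 1L), reference, k)
  drop(res$dist)
}

# Batched exact kNN: queries Q (n x d) against reference R (M x d).
# Returns list(dist = n x k, idx = n x k), each row nondecreasing in distance,
# ties broken by the smaller reference index. Blocked so the n x M distance
# matrix never materializes for large n.
knn_query <- function(Q, R, k, block = 256L) {
  Q <- check_matrix(Q, "query"); R <- check_matrix(R, "reference")
  k <- as.integer(k)
  if (ncol(Q) != ncol(R))
    stop("input-format: query and reference dimensionality differ", call. = FALSE)
  M <- nrow(R)
  if (M < k)
    stop("invalid-configuration: reference has fewer rows than k", call. = FALSE)
  n <- nrow(Q)
  dist <- matrix(0, n, k); idx <- matrix(0L, n, k)
  rn <- rowSums(R * R)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    Qb <- Q[rows, , drop = FALSE]
    d2 <- matrix(rowSums(Qb * Qb), length(rows), M) +
      matrix(rn, length(rows), M, byrow = TRUE) - 2 * tcrossprod(Qb, R)
    d2[d2 < 0] <- 0
    if (k == 1L) {
      j <- max.col(-d2, ties.method = "first")
      idx[rows, 1L] <- j
      dist[rows, 1L] <- sqrt(d2[cbind(seq_along(rows), j)])
    } else {
      for (i in seq_along(rows)) {
        v <- d2[i, ]
        kth <- sort(v, partial = k)[k]
        cand <- which(v <= kth)
        cand <- cand[order(v[cand], cand)][seq_len(k)]
        idx[rows[i], ] <- cand
        dist[rows[i], ] <- sqrt(v[cand])
      }
    }
  }
  list(dist = dist, idx = idx)
}

#' Total kNN distance
#'
#' Sums the `s` largest of the first `k` neighbor distances, each raised to
#' the power `gamma`: `L = sum_{n = k-s+1}^{k} g_n^gamma`. With
#' `k = s = gamma = 1` this is simply the nearest-neighbor distance.
#'
#' @param g Nondecreasing numeric vector of `k` neighbor distances (or an
#'   `n x k` matrix of such rows).
#' @param params An [odit_params()] object supplying `k`, `s`, `gamma`.
#' @return Scalar `L >= 0` (or a vector of length `n` for matrix input).
#' @examples
#' total_distance(c(1, 2), odit_params(k = 2, s = 2, gamma = 2))  # 5
#' @export
total_distance <- function(g, params = odit_params()) {
  if (is.matrix(g)) {
    if (ncol(g) != params$k)
      stop("input-format: 'g' must have k columns", call. = FALSE)
    cols <- (params$k - params$s + 1L):params$k
    return(rowSums(g[, cols, drop = FALSE] ^ params$gamma))
  }
  if (length(g) != params$k)
    stop("input-format: 'g' must have length k", call. = FALSE)
  sum(g[(params$k - params$s + 1L):params$k] ^ params$gamma)
}

#' kNN density estimate
#'
#' The classical k-nearest-neighbor density estimate
#' `f(x) = k / (N * v_d * g_k(x)^d)`, where `v_d` is the volume of the unit
#' ball in `d` dimensions and `g_k(x)` the distance from `x` to its k-th
#' nearest reference row. The inverse kNN distance acts as a likelihood
#' surrogate; this estimator is consistent as `k` grows with `N`, while at
#' `k = 1` it carries an irreducible multiplicative noise.
#'
#' @param x Numeric vector (one point) or matrix of points (rows).
#' @param reference Numeric reference matrix (`N x d`).
#' @param k Number of neighbors.
#' @param eps Floor applied to `g_k` to guard against zero distances.
#' @return Density estimate(s) at `x`.
#' @export
knn_density <- function(x, reference, k = 1L, eps = 1e-12) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  reference <- check_matrix(reference, "reference")
  d <- ncol(reference)
  gk <- knn_query(x, reference, k)$dist[, k]
  vd <- pi ^ (d / 2) / gamma(d / 2 + 1)
  k / (nrow(reference) * vd * pmax(gk, eps) ^ d)
}
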