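# Priority-search k-means tree: hierarchical k-means clustering of the
# reference set, searched best-first under a candidate budget B. The search
# examines a subset of the reference, so approximate kNN distances can only
# over-estimate the exact ones, with equality once B >= N.

# squared Euclidean distances between rows of A (n x d) and rows of B (m x d)
sqdist <- function(A, B) {
  d2 <- matrix(rowSums(A * A), nrow(A), nrow(B)) +
    matrix(rowSums(B * B), nrow(A), nrow(B), byrow = TRUE) -
    2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Build a priority-search k-means tree
#'
#' Recursively partitions the reference rows by k-means with branching
#' factor `C`; clusters with at most `leaf_size` points become leaves.
#' Centers are initialized by farthest-point selection (first center drawn
#' at random under `seed`), then refined by at most `imax` Lloyd iterations;
#' an empty cluster retains its previous center. Nodes whose points are all
#' identical (k-means cannot split them) become leaves regardless of size.
#'
#' @param reference Numeric `N x d` matrix indexed by the tree.
#' @param C Branching factor (>= 2).
#' @param imax Maximum Lloyd iterations per node.
#' @param leaf_size Maximum leaf occupancy.
#' @param seed RNG seed; the construction is deterministic given the seed.
#' @return An object of class `odit_kmeans_tree`.
#' @seealso [tree_search()]
#' @export
kmeans_tree <- function(reference, C = 100L, imax = 10L, leaf_size = 32L,
                        seed = NULL) {
  reference <- check_matrix(reference, "reference")
  C <- as.integer(C)
  if (C < 2L) stop("invalid-configuration: 'C' must be >= 2", call. = FALSE)
  root <- with_seed(seed, build_node(reference, seq_len(nrow(reference)),
                                     C, as.integer(imax),
                                     as.integer(leaf_size)))
  structure(list(root = root, reference = reference, C = C,
                 imax = as.integer(imax), leaf_size = as.integer(leaf_size),
                 seed = seed),
            class = "odit_kmeans_tree")
}

build_node <- function(R, idx, C, imax, leaf_size) {
  n <- length(idx)
  if (n <= leaf_size)
    return(list(leaf = TRUE, idx = idx))
  C <- min(C, n)   # a node cannot host more centers than points
  pts <- R[idx, , drop = FALSE]

  # farthest-point initialization
  centers <- matrix(0, C, ncol(R))
  first <- sample.int(n, 1L)
  centers[1L, ] <- pts[first, ]
  mind2 <- sqdist(pts, centers[1L, , drop = FALSE])[, 1L]
  for (j in 2L:C) {
    nxt <- which.max(mind2)
    if (mind2[nxt] == 0)               # all remaining points identical
      return(list(leaf = TRUE, idx = idx))
    centers[j, ] <- pts[nxt, ]
    mind2 <- pmin(mind2, sqdist(pts, centers[j, , drop = FALSE])[, 1L])
  }

  assign <- integer(n)
  for (it in seq_len(imax)) {
    d2 <- sqdist(pts, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(C)) {
      memb <- assign == j
      if (any(memb)) centers[j, ] <- colMeans(pts[memb, , drop = FALSE])
    }
  }

  sizes <- tabulate(assign, nbins = C)
  if (any(sizes == n))                  # no split achieved
    return(list(leaf = TRUE, idx = idx))
  keep <- which(sizes > 0L)
  children <- vector("list", length(keep))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    children[[jj]] <- build_node(R, idx[assign == j], C, imax, leaf_size)
  }
  list(leaf = FALSE, centers = centers[keep, , drop = FALSE],
       children = children)
}

#' @export
print.odit_kmeans_tree <- function(x, ...) {
  count <- function(node) {
    if (node$leaf) return(c(leaves = 1L, depth = 1L))
    sub <- vapply(node$children, count, c(leaves = 0L, depth = 0L))
    c(leaves = sum(sub["leaves", ]), depth = 1L + max(sub["depth", ]))
  }
  info <- count(x$root)
  cat(sprintf("priority-search k-means tree: %d points, C = %d, %d leaves, depth %d\n",
              nrow(x$reference), x$C, info["leaves"], info["depth"]))
  invisible(x)
}

#' Approximate kNN by priority search
#'
#' Best-first descent of a k-means tree: starting from the root, the search
#' repeatedly expands the unexplored branch whose centroid is closest to the
#' query (ties broken by child order), accumulating leaf points as
#' candidates until at least `B` have been examined, then returns the `k`
#' smallest candidate distances. Returned distances are never smaller than
#' the exact ones and coincide with them when `B >= N`.
#'
#' @param tree An [kmeans_tree()] object.
#' @param query Numeric vector of length `d`.
#' @param k Number of neighbors.
#' @param B Candidate budget, `B >= k`. The last leaf expanded may overshoot
#'   the budget by at most the leaf size.
#' @return List with `dist` (nondecreasing length-`k` vector), `idx`
#'   (reference row indices), and `examined` (number of candidates scored).
#' @export
tree_search <- function(tree, query, k = 1L, B = 1000L) {
  k <- as.integer(k); B <- as.integer(B)
  if (B < k) stop("invalid-configuration: 'B' must be >= k", call. = FALSE)
  q <- matrix(as.numeric(query), nrow = 1L)
  if (ncol(q) != ncol(tree$reference))
    stop("input-format: query dimensionality differs from reference", call. = FALSE)

  # simple priority queue; stays small (queue length <= depth * C)
  pq_node <- list(tree$root); pq_dist <- 0
  cand <- integer(0)
  while (length(cand) < B && length(pq_node) > 0L) {
    at <- which.min(pq_dist)            # first minimum: FIFO tie-break
    node <- pq_node[[at]]
    pq_node <- pq_node[-at]; pq_dist <- pq_dist[-at]
    if (node$leaf) {
      cand <- c(cand, node$idx)
    } else {
      d2 <- sqdist(q, node$centers)[1L, ]
      pq_node <- c(pq_node, node$children)
      pq_dist <- c(pq_dist, d2)
    }
  }
  if (length(cand) < k)
    stop("invalid-configuration: fewer than k candidate points reachable",
         call. = FALSE)
  v <- sqdist(q, tree$reference[cand, , drop = FALSE])[1L, ]
  ord <- order(v, cand)[seq_len(k)]
  list(dist = sqrt(v[ord]), idx = cand[ord], examined = length(cand))
}

# batched interface mirroring knn_query()
tree_query <- function(tree, Q, k, B) {
  Q <- check_matrix(Q, "query")
  n <- nrow(Q)
  dist <- matrix(0, n, k); idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    res <- tree_search(tree, Q[i, ], k = k, B = B)
    dist[i, ] <- res$dist
    idx[i, ] <- res$idx
  }
  list(dist = dist, idx = idx)
}
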