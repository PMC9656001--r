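# Delimited-text matrices and the on-disk model archive. Numeric round
# trips use 17 significant digits so detection output is bit-for-bit
# reproducible after save/load with the exact backend.

MODEL_FORMAT_VERSION <- 1L

#' Read an observation matrix from delimited text
#'
#' One row per observation, comma- (or other-) separated, optional single
#' header row. All cells must be finite numbers; offending rows are named
#' in the error.
#'
#' @param path File path.
#' @param header Does the file start with a column-name row?
#' @param sep Field separator.
#' @return Numeric matrix with `dimnames` from the header (if any).
#' @export
read_stream_matrix <- function(path, header = FALSE, sep = ",") {
  if (!file.exists(path))
    stop(sprintf("input-format: file '%s' does not exist", path), call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep,
                      colClasses = "numeric", comment.char = ""),
    error = function(e)
      stop(sprintf("input-format: cannot parse '%s' as a numeric table (%s)",
                   path, conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop(sprintf("input-format: '%s' contains no data rows", path), call. = FALSE)
  x <- as.matrix(df)
  if (!all(is.finite(x))) {
    bad <- which(!apply(is.finite(x), 1L, all))[1L]
    stop(sprintf("input-format: non-finite value in data row %d of '%s'",
                 bad, path), call. = FALSE)
  }
  x
}

#' Write an observation matrix as delimited text
#'
#' Full-precision (17 significant digit) writer so that a write/read round
#' trip reproduces the matrix exactly.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @param col_names Write a header row of column names?
#' @export
write_stream_matrix <- function(x, path, sep = ",", col_names = FALSE) {
  x <- check_matrix(x, "x")
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  if (col_names) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
    lines <- c(paste(nm, collapse = sep), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Save a fitted model to a directory archive
#'
#' The archive holds `metadata.json` (parameters, dimensions, `K`, `L_(K)`,
#' contribution means, standardization statistics, format version), plus the
#' reference set and the sorted training total distances as full-precision
#' delimited text. The k-means tree of the approximate backend is not
#' stored: it is rebuilt deterministically from the reference set and seed
#' on load.
#'
#' @param model A fitted [odit_fit()] model.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "odit_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- unclass(model$params)
  if (!is.finite(p$h)) p$h <- NULL    # JSON has no Inf; absent means "no threshold"
  meta <- list(
    format_version = MODEL_FORMAT_VERSION,
    d = model$d, N1 = model$N1, N2 = model$N2, K = model$K,
    L_K = model$L_K, mu = model$mu,
    center = model$center, scale = model$scale,
    params = p)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_stream_matrix(model$reference, file.path(path, "reference.csv"))
  write_stream_matrix(matrix(model$sorted_L, ncol = 1L),
                      file.path(path, "training_distances.csv"))
  # JSON number formatting is not bitwise-faithful; the numerics that enter
  # the detection path are duplicated here at 17 significant digits
  stats_mat <- rbind(center = model$center, scale = model$scale, mu = model$mu)
  write_stream_matrix(stats_mat, file.path(path, "statistics.csv"))
  invisible(path)
}

#' Load a model archive
#'
#' Validates the format version and the stored invariants (ordered training
#' distances, `K = floor(N1 * (1 - alpha))`, `L_(K)` equal to the K-th order
#' statistic) before returning a model that reproduces detection output
#' bit-for-bit with the exact backend.
#'
#' @param path Archive directory written by [save_model()].
#' @return An `odit_model`.
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop(sprintf("model-format: '%s' is missing metadata.json", path),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != MODEL_FORMAT_VERSION)
    stop("model-format: unsupported or missing format version", call. = FALSE)
  pm <- meta$params
  params <- odit_params(
    k = pm$k, s = pm$s, gamma = pm$gamma, alpha = pm$alpha,
    h = if (is.null(pm$h)) Inf else pm$h,
    n1_frac = pm$n1_frac, partition = pm$partition,
    standardize = pm$standardize,
    seed = if (is.null(pm$seed)) NULL else pm$seed,
    knn_backend = pm$knn_backend, tree_c = pm$tree_c, tree_b = pm$tree_b,
    tree_imax = pm$tree_imax, tree_leaf_size = pm$tree_leaf_size,
    buffer_cap = pm$buffer_cap)
  reference <- read_stream_matrix(file.path(path, "reference.csv"))
  sorted_L <- drop(read_stream_matrix(file.path(path, "training_distances.csv")))
  stats_path <- file.path(path, "statistics.csv")
  if (!file.exists(stats_path))
    stop("model-format: archive is missing statistics.csv", call. = FALSE)
  stats_mat <- read_stream_matrix(stats_path)

  if (is.unsorted(sorted_L))
    stop("model-format: training distances are not nondecreasing", call. = FALSE)
  if (meta$K != floor(meta$N1 * (1 - params$alpha)))
    stop("model-format: K inconsistent with N1 and alpha", call. = FALSE)
  # the JSON copy of L_K is rounded; the 17-digit order statistic is
  # authoritative, but the two must agree to JSON printing precision
  if (meta$K < 1 || meta$K > length(sorted_L) ||
      abs(meta$L_K - sorted_L[meta$K]) > 1e-9 * max(1, abs(meta$L_K)))
    stop("model-format: L_K does not match the stored order statistics",
         call. = FALSE)
  if (ncol(reference) != meta$d || nrow(reference) != meta$N2)
    stop("model-format: reference set shape disagrees with metadata",
         call. = FALSE)
  if (nrow(stats_mat) != 3L || ncol(stats_mat) != meta$d)
    stop("model-format: statistics.csv shape disagrees with metadata",
         call. = FALSE)

  tree <- NULL
  if (params$knn_backend == "approximate")
    tree <- kmeans_tree(reference, C = params$tree_c, imax = params$tree_imax,
                        leaf_size = params$tree_leaf_size, seed = params$seed)

  structure(
    list(reference = reference, d = meta$d, N1 = meta$N1, N2 = meta$N2,
         K = meta$K, L_K = sorted_L[meta$K], sorted_L = sorted_L,
         mu = unname(stats_mat[3L, ]), center = unname(stats_mat[1L, ]),
         scale = unname(stats_mat[2L, ]), params = params, tree = tree),
    class = "odit_model")
}
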