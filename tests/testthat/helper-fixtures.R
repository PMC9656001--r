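# Small fixtures built in code; sizes chosen so the whole suite stays fast.

# standard-Gaussian training matrix
gauss_train <- function(n = 1000, d = 3, seed = 42) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# a fitted model on Gaussian data with default-ish parameters
small_model <- function(n = 1000, d = 3, seed = 42, ...) {
  odit_fit(gauss_train(n, d, seed), odit_params(seed = seed, ...))
}

# stream with a mean shift in `dims` from time tau + 1 on
shifted_stream <- function(model_d, tau, horizon, dims, shift = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(horizon * model_d), horizon, model_d)
  if (length(dims) && tau < horizon)
    x[(tau + 1):horizon, dims] <- x[(tau + 1):horizon, dims] + shift
  x
}

# brute-force kNN oracle: full sort of all pairwise distances
brute_knn <- function(query, reference, k) {
  d2 <- colSums((t(reference) - as.numeric(query))^2)
  sqrt(sort(d2, method = "radix")[seq_len(k)])
}
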