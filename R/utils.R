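# Internal helpers: argument checking, seed derivation, array utilities.

stop_invalid <- function(...) {
  stop(structure(class = c("met2star_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(ok, ...) if (!isTRUE(ok)) stop_invalid(...)

#' @noRd
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

# Derive a stream of child seeds from one parent seed, all < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# mean/SD helpers on matrices laid out time x voxels
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  sqrt(pmax(colSums(m * m) - n * mu * mu, 0) / (n - 1L))
}

# Reflective (symmetric) 1-D Gaussian smoothing matrix of size n for sigma in
# voxel units; rows sum to 1 so constants are preserved exactly.
gaussian_smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  k <- exp(-offs^2 / (2 * sigma^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    # symmetric reflection without edge repetition avoidance: ..3 2 1 | 1 2 3..
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    # repeat once more for very wide kernels
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    for (t in seq_along(offs)) S[i, j[t]] <- S[i, j[t]] + k[t]
  }
  S
}
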