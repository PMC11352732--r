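#' Multi-echo image objects
#'
#' A `multiecho_image` stacks 2D magnitude images acquired at increasing echo
#' times: `data` is a (row, col, echo) array with all values >= 0 and `te_ms`
#' the strictly increasing echo-time list (length >= 2 for fitting).
#'
#' @param data numeric (row, col, echo) array, non-negative.
#' @param te_ms strictly increasing echo times in ms, one per echo plane.
#' @return An object of class `multiecho_image`.
#' @export
multiecho_image <- function(data, te_ms) {
  check_that(is.array(data) && length(dim(data)) == 3L,
             "data must be a (row, col, echo) array")
  check_that(dim(data)[3] == length(te_ms),
             "echo axis length must equal length(te_ms)")
  check_that(all(te_ms > 0), "echo times must be positive")
  check_that(length(te_ms) < 2L || all(diff(te_ms) > 0),
             "echo times must be strictly increasing")
  check_that(all(data >= 0), "magnitude data must be non-negative")
  structure(list(data = data, te_ms = as.numeric(te_ms)),
            class = "multiecho_image")
}

#' @export
print.multiecho_image <- function(x, ...) {
  cat(sprintf("<multiecho_image> %d x %d, TEs [%s] ms\n",
              dim(x$data)[1], dim(x$data)[2],
              paste(x$te_ms, collapse = ", ")))
  invisible(x)
}

#' Noiseless mono-exponential multi-echo forward model
#'
#' Evaluates S(TE) = M0 * exp(-TE / T2*) at each echo time for every voxel
#' inside the tissue mask; background voxels are exactly 0 at all echoes.
#'
#' @param map a [parametric_map()].
#' @param te_ms positive echo times in ms.
#' @return A [multiecho_image()] with one plane per echo.
#' @export
forward_signal <- function(map, te_ms) {
  check_that(inherits(map, "parametric_map"), "map must be a parametric_map")
  check_that(length(te_ms) >= 1L && all(te_ms > 0),
             "te_ms must be nonempty and positive")
  check_that(length(te_ms) < 2L || all(diff(te_ms) > 0),
             "te_ms must be strictly increasing")
  d <- dim(map$m0)
  out <- array(0, c(d, length(te_ms)))
  msk <- map$mask
  r2 <- ifelse(msk, 1 / pmax(map$t2star, .Machine$double.eps), 0)
  for (n in seq_along(te_ms)) {
    plane <- matrix(0, d[1], d[2])
    plane[msk] <- map$m0[msk] * exp(-te_ms[n] * r2[msk])
    out[, , n] <- plane
  }
  multiecho_image(out, te_ms)
}

#' Add Rician noise to a multi-echo magnitude image
#'
#' Each voxel/echo value S is replaced by |(S + g1) + i g2| with g1, g2
#' independent zero-mean Gaussians of standard deviation
#' `sigma_frac * max(first-echo signal)` — the first echo carries the largest
#' amplitude, making `sigma_frac` a stable per-slice SNR knob. Deterministic
#' given `seed`.
#'
#' @param img a [multiecho_image()].
#' @param sigma_frac noise SD as a fraction of the first-echo maximum, in
#'   \[0, 0.10\].
#' @param seed integer seed.
#' @return A [multiecho_image()]; output values are >= 0 by construction.
#' @export
add_rician_noise <- function(img, sigma_frac, seed = 1L) {
  check_that(inherits(img, "multiecho_image"), "img must be a multiecho_image")
  check_that(length(sigma_frac) == 1L && sigma_frac >= 0 && sigma_frac <= 0.10,
             "sigma_frac must lie in [0, 0.10]")
  if (sigma_frac == 0) return(img)
  sigma <- sigma_frac * max(img$data[, , 1])
  if (sigma == 0) return(img)
  withr::with_seed(as.integer(seed), {
    g1 <- array(rnorm(length(img$data), sd = sigma), dim(img$data))
    g2 <- array(rnorm(length(img$data), sd = sigma), dim(img$data))
    multiecho_image(sqrt((img$data + g1)^2 + g2^2), img$te_ms)
  })
}

#' Fit result objects
#'
#' Holds voxelwise estimates of `s0` (arbitrary units), `t2star_ms` (clipped to
#' the configured bounds) and `r2star_per_ms` (= 1/t2star where valid), plus a
#' logical `valid` mask of voxels where the fit was admissible. Invalid voxels
#' carry 0 in `s0` and `r2star_per_ms`.
#'
#' @param s0,t2star_ms,r2star_per_ms numeric arrays of identical dimensions.
#' @param valid logical array of admissible voxels.
#' @param t2_bounds the (min, max) clipping bounds used, ms.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(s0, t2star_ms, r2star_per_ms, valid,
                       t2_bounds = c(1, 500)) {
  structure(list(s0 = s0, t2star_ms = t2star_ms,
                 r2star_per_ms = r2star_per_ms, valid = valid,
                 t2_bounds = t2_bounds),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, %d/%d valid voxels\n",
              paste(dim(x$t2star_ms), collapse = " x "),
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Voxel-wise log-linear fit (LLF) of the multi-echo decay
#'
#' Solves `[log S0, R2*]` per voxel by applying the Moore–Penrose
#' pseudo-inverse of the design matrix with rows `(1, -TE_n)` to the
#' log-signals. The pseudo-inverse is computed once per TE set and reused
#' across voxels. Signals at or below `floor` (default `1e-6 *` the image
#' maximum) are replaced by the floor before the log and the voxel is marked
#' invalid, as is any voxel with non-positive fitted R2* (rising signal),
#' whose T2* clips to the upper bound. T2* is clipped to `t2_bounds`.
#'
#' @param img a [multiecho_image()] with >= 2 echoes at distinct TEs.
#' @param floor signal floor; `NULL` (default) uses `1e-6 * max(img$data)`.
#' @param t2_bounds T2* clipping bounds in ms (default `c(1, 500)`).
#' @return A [fit_result()].
#' @export
loglinear_fit <- function(img, floor = NULL, t2_bounds = c(1, 500)) {
  check_that(inherits(img, "multiecho_image"), "img must be a multiecho_image")
  te <- img$te_ms
  check_that(length(te) >= 2L, "at least 2 echoes are required")
  check_that(!anyDuplicated(te), "duplicate echo times make the design singular")
  d <- dim(img$data)[1:2]
  if (is.null(floor)) floor <- 1e-6 * max(img$data)
  floor <- max(floor, .Machine$double.xmin)

  X <- cbind(1, -te)
  A <- MASS::ginv(X) # 2 x N, reused for every voxel

  sig <- matrix(img$data, prod(d), length(te)) # voxels x echoes
  floored <- sig <= floor
  sig[floored] <- floor
  coef <- A %*% t(log(sig)) # 2 x voxels
  log_s0 <- coef[1, ]
  r2 <- coef[2, ]

  valid <- !matrixStats_rowAnys(floored) & r2 > 0
  t2 <- rep(t2_bounds[2], length(r2))
  pos <- r2 > 0
  t2[pos] <- pmin(pmax(1 / r2[pos], t2_bounds[1]), t2_bounds[2])
  s0 <- exp(log_s0)
  s0[!valid] <- 0
  r2_out <- ifelse(valid, 1 / t2, 0)

  fit_result(matrix(s0, d[1], d[2]), matrix(t2, d[1], d[2]),
             matrix(r2_out, d[1], d[2]), matrix(valid, d[1], d[2]),
             t2_bounds = t2_bounds)
}

# rowAnys without a matrixStats dependency
matrixStats_rowAnys <- function(m) rowSums(m) > 0

#' Echo-combination weight objects
#'
#' Per-voxel weights `w` laid out (row, col, echo); every voxel's weights are
#' non-negative and sum to 1 within 1e-12.
#' @param w numeric (row, col, echo) array.
#' @param te_ms echo times the weights refer to.
#' @return An object of class `echo_weights`.
#' @export
echo_weights <- function(w, te_ms) {
  check_that(is.array(w) && length(dim(w)) == 3L &&
               dim(w)[3] == length(te_ms), "w must be (row, col, echo)")
  structure(list(w = w, te_ms = as.numeric(te_ms)), class = "echo_weights")
}

#' T2*-weighted echo-combination weights
#'
#' Computes the matched-filter combination weight of echo n at each voxel,
#' `w_n = TE_n exp(-TE_n / T2*) / sum_i TE_i exp(-TE_i / T2*)`, from a
#' voxelwise T2* estimate.
#'
#' @param t2star_ms positive 2D matrix of estimated T2* (ms); callers must clip
#'   non-positive estimates first.
#' @param te_ms echo times in ms.
#' @return An [echo_weights()] object.
#' @export
echo_combination_weights <- function(t2star_ms, te_ms) {
  check_that(is.matrix(t2star_ms), "t2star_ms must be a matrix")
  check_that(all(t2star_ms > 0),
             "non-positive T2* encountered; clip the map before weighting")
  check_that(all(te_ms > 0), "echo times must be positive")
  d <- dim(t2star_ms)
  w <- array(0, c(d, length(te_ms)))
  for (n in seq_along(te_ms)) {
    w[, , n] <- te_ms[n] * exp(-te_ms[n] / t2star_ms)
  }
  tot <- apply(w, c(1, 2), sum)
  w <- w / array(rep(tot, length(te_ms)), dim(w))
  echo_weights(w, te_ms)
}

#' Combine echoes with per-voxel weights
#'
#' Voxel-wise linear combination `sum_n w_n * S_n` of the echo planes.
#'
#' @param img a [multiecho_image()].
#' @param weights an [echo_weights()] of conforming shape.
#' @return A 2D matrix.
#' @export
combine_echoes <- function(img, weights) {
  check_that(inherits(img, "multiecho_image"), "img must be a multiecho_image")
  check_that(inherits(weights, "echo_weights"), "weights must be echo_weights")
  check_that(all(dim(img$data) == dim(weights$w)),
             "image and weight shapes do not conform")
  d <- dim(img$data)
  out <- matrix(0, d[1], d[2])
  for (n in seq_len(d[3])) {
    out <- out + matrix(img$data[, , n], d[1], d[2]) *
      matrix(weights$w[, , n], d[1], d[2])
  }
  out
}
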