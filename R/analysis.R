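#' Derived time-series objects
#'
#' A 4D (x, y, slice, time) series derived from a multi-echo acquisition:
#' a T2* time series (fitted by LLF or by the trained estimator), an
#' echo-combined series, or an externally produced MEICA series. `provenance`
#' records how it was made.
#'
#' @param kind one of `"LLF_T2STAR"`, `"SDDL_T2STAR"`, `"EC"`, `"SDDL_EC"`,
#'   `"MEICA"`, `"SDDL_MEICA"`.
#' @param data numeric 4D (x, y, slice, time) array.
#' @param provenance list describing source series, fitter and weights.
#' @param tr_s repetition time (s).
#' @return An object of class `derived_series`.
#' @export
derived_series <- function(kind, data, provenance = list(), tr_s = NA_real_) {
  kinds <- c("LLF_T2STAR", "SDDL_T2STAR", "EC", "SDDL_EC", "MEICA",
             "SDDL_MEICA")
  check_that(kind %in% kinds,
             "kind must be one of ", paste(kinds, collapse = ", "))
  check_that(is.array(data) && length(dim(data)) == 4L,
             "data must be a 4D (x, y, slice, time) array")
  structure(list(kind = kind, data = data, provenance = provenance,
                 tr_s = tr_s),
            class = "derived_series")
}

#' @export
print.derived_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<derived_series %s> %d x %d x %d, %d volumes\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}

as_series_array <- function(x) {
  if (inherits(x, "derived_series")) x$data else x
}

#' Fit a 4D T2* time series from a multi-echo series
#'
#' For `method = "llf"` every volume is fitted voxel-wise by the log-linear
#' fit; for `method = "sddl"` every volume is fitted slice-by-slice with the
#' trained estimator.
#'
#' @param series a [multiecho_series()].
#' @param method `"llf"` or `"sddl"`.
#' @param est trained `sddl_estimator` (required for `"sddl"`).
#' @return A [derived_series()] of kind `LLF_T2STAR` or `SDDL_T2STAR`.
#' @export
fit_t2star_series <- function(series, method = c("llf", "sddl"), est = NULL) {
  check_that(inherits(series, "multiecho_series"),
             "series must be a multiecho_series")
  method <- match.arg(method)
  d <- dim(series$data)
  out <- array(0, d[c(1, 2, 3, 5)])
  if (method == "llf") {
    for (t in seq_len(d[5])) {
      vol <- series$data[, , , , t, drop = FALSE]
      # voxel-wise fit: fold (x, y, slice) into one 2D grid
      img <- multiecho_image(array(vol, c(d[1], d[2] * d[3], d[4])),
                             series$te_ms)
      fr <- loglinear_fit(img)
      out[, , , t] <- array(fr$t2star_ms, d[1:3])
    }
    derived_series("LLF_T2STAR", out, list(fitter = "llf"), series$tr_s)
  } else {
    check_that(inherits(est, "sddl_estimator"),
               "method 'sddl' requires a trained estimator")
    check_that(est$n_echoes_in == d[4],
               "echo count does not match the trained model")
    for (t in seq_len(d[5])) {
      fr <- fit_volume_slicewise(est, array(series$data[, , , , t], d[1:4]),
                                 series$te_ms)
      out[, , , t] <- fr$t2star_ms
    }
    derived_series("SDDL_T2STAR", out, list(fitter = "sddl"), series$tr_s)
  }
}

ec_combine <- function(series, t2star_map, kind, provenance) {
  d <- dim(series$data)
  check_that(all(dim(t2star_map) == d[1:3]),
             "t2star_map must be (x, y, slice)")
  w <- array(0, d[1:4])
  for (z in seq_len(d[3])) {
    w[, , z, ] <- echo_combination_weights(matrix(t2star_map[, , z],
                                                  d[1], d[2]),
                                           series$te_ms)$w
  }
  out <- array(0, d[c(1, 2, 3, 5)])
  for (t in seq_len(d[5])) {
    acc <- array(0, d[1:3])
    for (e in seq_len(d[4])) {
      acc <- acc + array(series$data[, , , e, t], d[1:3]) *
        array(w[, , , e], d[1:3])
    }
    out[, , , t] <- acc
  }
  provenance$weights_t2star <- t2star_map
  derived_series(kind, out, provenance, series$tr_s)
}

#' T2*-weighted echo combination of a series with a supplied T2* map
#'
#' Computes static per-voxel weights from `t2star_map` (for example the LLF
#' fit of the time-averaged series) and applies them to every volume.
#'
#' @param series a [multiecho_series()].
#' @param t2star_map positive (x, y, slice) T2* map in ms.
#' @return A [derived_series()] of kind `EC`.
#' @export
ec_series <- function(series, t2star_map) {
  check_that(inherits(series, "multiecho_series"),
             "series must be a multiecho_series")
  ec_combine(series, t2star_map, "EC", list(weights_source = "supplied"))
}

#' Echo combination with estimator-derived weights
#'
#' Averages the series over time, estimates the 3D T2* map slice-by-slice
#' with the trained estimator, computes the combination weights from that map,
#' and applies the (time-constant) weights to every volume.
#'
#' @param series a [multiecho_series()].
#' @param est a trained `sddl_estimator`.
#' @return A [derived_series()] of kind `SDDL_EC`.
#' @export
sddl_ec_series <- function(series, est) {
  check_that(inherits(series, "multiecho_series"),
             "series must be a multiecho_series")
  d <- dim(series$data)
  tmean <- array(rowMeans(matrix(series$data, prod(d[1:4]), d[5])), d[1:4])
  fr <- fit_volume_slicewise(est, tmean, series$te_ms)
  out <- ec_combine(series, fr$t2star_ms, "SDDL_EC",
                    list(weights_source = "sddl_time_average"))
  out
}

#' Remove polynomial trends from a 4D series
#'
#' Per voxel, subtracts the least-squares fit of a constant plus linear (and,
#' for `orders = 2`, quadratic) time trend and restores the temporal mean, so
#' the output keeps the raw mean but loses the trends.
#'
#' @param series4d 4D (x, y, slice, time) array or [derived_series()].
#' @param orders 1 (linear) or 2 (linear + quadratic; default).
#' @return An object of the same type as the input.
#' @export
detrend_series <- function(series4d, orders = 2L) {
  arr <- as_series_array(series4d)
  check_that(length(dim(arr)) == 4L, "input must be 4D (x, y, slice, time)")
  n_t <- dim(arr)[4]
  check_that(n_t >= 4L, "at least 4 time points are required")
  check_that(orders %in% c(1L, 2L), "orders must be 1 or 2")
  u <- seq(-1, 1, length.out = n_t)
  X <- cbind(1, u, if (orders == 2L) u^2)
  Y <- t(matrix(arr, prod(dim(arr)[1:3]), n_t)) # time x voxels
  beta <- solve(crossprod(X), crossprod(X, Y))
  res <- Y - X %*% beta
  out <- t(res) + rowMeans(matrix(arr, prod(dim(arr)[1:3]), n_t))
  out <- array(out, dim(arr))
  if (inherits(series4d, "derived_series")) {
    series4d$data <- out
    series4d
  } else {
    out
  }
}

#' Spatially smooth a 4D series with a Gaussian kernel
#'
#' Applies separable 3D Gaussian smoothing per volume with
#' `sigma_vox = fwhm_mm / (voxel_mm * sqrt(8 log 2))` per axis, normalised
#' kernel and reflective boundaries (so constants are preserved exactly).
#' `fwhm_mm = 0` is the identity.
#'
#' @param series4d 4D array or [derived_series()].
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_mm voxel size per axis in mm (default 3.5 isotropic).
#' @return An object of the same type as the input.
#' @export
smooth_series <- function(series4d, fwhm_mm, voxel_mm = c(3.5, 3.5, 3.5)) {
  check_that(fwhm_mm >= 0, "fwhm_mm must be >= 0")
  arr <- as_series_array(series4d)
  check_that(length(dim(arr)) == 4L, "input must be 4D (x, y, slice, time)")
  if (fwhm_mm == 0) return(series4d)
  d <- dim(arr)
  sig <- fwhm_mm / (voxel_mm * sqrt(8 * log(2)))
  Sx <- gaussian_smoothing_matrix(d[1], sig[1])
  Sy <- gaussian_smoothing_matrix(d[2], sig[2])
  Sz <- gaussian_smoothing_matrix(d[3], sig[3])
  out <- array(0, d)
  for (t in seq_len(d[4])) {
    v <- array(arr[, , , t], d[1:3])
    m <- matrix(v, d[1], d[2] * d[3])
    v <- array(Sx %*% m, d[1:3])
    v <- aperm(apply(v, c(1, 3), function(col) Sy %*% col), c(2, 1, 3))
    if (d[3] > 1L) {
      m <- matrix(aperm(v, c(3, 1, 2)), d[3], d[1] * d[2])
      v <- aperm(array(Sz %*% m, c(d[3], d[1], d[2])), c(2, 3, 1))
    }
    out[, , , t] <- v
  }
  if (inherits(series4d, "derived_series")) {
    series4d$data <- out
    series4d
  } else {
    out
  }
}

#' First-level GLM with an HRF-convolved block regressor
#'
#' Fits ordinary least squares per voxel with design matrix
#' `[task | nuisance | constant]`, where the task column is the unit-peak
#' HRF-convolved boxcar of `design`. The t statistic for the task contrast is
#' `t = b / sqrt(sigma2 * c' (X'X)^-1 c)`. Perfect (zero-residual) fits are
#' reported with a finite sentinel t of +/- 1e6.
#'
#' @param series4d 4D array or [derived_series()].
#' @param design a [make_block_design()] result.
#' @param nuisance optional (time x k) matrix of nuisance regressors.
#' @param oversample HRF super-sampling factor (default 16).
#' @return An object of class `glm_result` with `betas` (x, y, slice,
#'   regressor), `tmap`, `dof`, `design_matrix` and the scaling factor `sf`.
#' @export
glm_fit <- function(series4d, design, nuisance = NULL, oversample = 16L) {
  arr <- as_series_array(series4d)
  check_that(length(dim(arr)) == 4L, "input must be 4D (x, y, slice, time)")
  n_t <- dim(arr)[4]
  check_that(n_t == design$n_volumes,
             "design length does not match the time axis")
  reg <- task_regressor(design, oversample)
  X <- cbind(task = reg$volume)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    check_that(nrow(nuisance) == n_t, "nuisance must have one row per volume")
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, constant = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop_invalid("rank-deficient design matrix; collinear columns: ",
                 paste(bad, collapse = ", "))
  }
  dof <- n_t - ncol(X)
  check_that(dof > 0, "no residual degrees of freedom")

  Y <- t(matrix(arr, prod(dim(arr)[1:3]), n_t)) # time x voxels
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y) # p x voxels
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / dof
  cvec <- c(1, rep(0, ncol(X) - 1))
  cxxc <- drop(t(cvec) %*% XtXinv %*% cvec)
  se <- sqrt(sigma2 * cxxc)
  b_task <- beta[1, ]
  tval <- numeric(length(b_task))
  perfect <- sigma2 <= 1e-20 * (colMeans(Y^2) + 1e-300)
  ok <- !perfect & se > 0
  tval[ok] <- b_task[ok] / se[ok]
  tval[perfect] <- sign(b_task[perfect]) * 1e6
  tval[abs(tval) > 1e6] <- sign(tval[abs(tval) > 1e6]) * 1e6

  d3 <- dim(arr)[1:3]
  betas <- array(t(beta), c(d3, ncol(X)))
  structure(list(betas = betas, regressors = colnames(X),
                 tmap = array(tval, d3), dof = dof, design_matrix = X,
                 sf = reg$sf),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %s, regressors [%s], dof %d\n",
              paste(dim(x$tmap), collapse = " x "),
              paste(x$regressors, collapse = ", "), x$dof))
  invisible(x)
}

#' Two-sided p-value map of the task contrast
#'
#' @param glm a [glm_fit()] result.
#' @return A 3D array of two-sided p-values.
#' @export
glm_pmap <- function(glm) {
  2 * pt(-abs(glm$tmap), df = glm$dof)
}

#' Temporal signal-to-noise ratio map
#'
#' Fits a constant + linear + quadratic time model per voxel, subtracts the
#' trend components only (the fitted baseline is kept, so a pure added trend
#' — which has no constant component — leaves the result exactly unchanged),
#' and divides the baseline mean by the residual temporal SD. Voxels with
#' zero SD are set to 0 (flagged in the `"flagged"` attribute).
#'
#' @param series4d 4D array or [derived_series()].
#' @return A 3D tSNR map.
#' @export
tsnr <- function(series4d) {
  arr <- as_series_array(series4d)
  check_that(length(dim(arr)) == 4L, "input must be 4D (x, y, slice, time)")
  n_t <- dim(arr)[4]
  check_that(n_t >= 4L, "at least 4 volumes are required")
  u <- (seq_len(n_t) - 1) / (n_t - 1) # 0-based time so trends have no offset
  X <- cbind(1, u, u^2)
  Y <- t(matrix(arr, prod(dim(arr)[1:3]), n_t)) # time x voxels
  beta <- solve(crossprod(X), crossprod(X, Y))
  mu <- beta[1, ] # fitted baseline at time zero's polynomial origin
  res <- Y - X %*% beta
  sdv <- col_sds(res)
  # treat solver round-off on perfectly smooth series as zero variance
  degenerate <- sdv <= 1e-12 * pmax(abs(mu), 1)
  out <- ifelse(degenerate, 0, mu / sdv)
  out <- array(out, dim(arr)[1:3])
  attr(out, "flagged") <- array(degenerate, dim(arr)[1:3])
  out
}

#' Percentage signal change map from GLM betas
#'
#' `PSC = 100 * SF * beta_task / beta_constant`, where SF is the maximum of a
#' single reference trial's HRF-convolved regressor at the super-sampled
#' design resolution. Voxels with zero constant beta are set to 0 and flagged.
#'
#' @param glm a [glm_fit()] result.
#' @param design the [make_block_design()] used for the fit.
#' @param oversample super-sampling factor for SF (default 16).
#' @return A 3D PSC map (percent).
#' @export
psc <- function(glm, design, oversample = 16L) {
  sf <- task_regressor(design, oversample)$sf
  nd <- length(dim(glm$betas))
  b_task <- array(glm$betas, c(prod(dim(glm$tmap)), length(glm$regressors)))
  const_idx <- which(glm$regressors == "constant")
  bc <- b_task[, const_idx]
  bt <- b_task[, 1]
  out <- ifelse(bc != 0, 100 * sf * bt / bc, 0)
  out <- array(out, dim(glm$tmap))
  attr(out, "flagged") <- array(bc == 0, dim(glm$tmap))
  out
}

#' Functional contrast within an ROI
#'
#' Detrends (linear + quadratic), optionally smooths, spatially averages the
#' series within `roi`, and returns mean(ON volumes) - mean(OFF volumes) using
#' the unconvolved condition labels.
#'
#' @param series4d 4D array or [derived_series()].
#' @param design a [make_block_design()] result.
#' @param roi logical 3D ROI (nonempty).
#' @param fwhm_mm smoothing FWHM in mm (default 0 = none).
#' @param voxel_mm voxel size in mm.
#' @return Scalar functional contrast (ON minus OFF).
#' @export
functional_contrast <- function(series4d, design, roi, fwhm_mm = 0,
                                voxel_mm = c(3.5, 3.5, 3.5)) {
  arr <- as_series_array(series4d)
  check_that(length(dim(arr)) == 4L, "input must be 4D (x, y, slice, time)")
  check_that(any(roi), "roi must be nonempty")
  check_that(all(dim(roi) == dim(arr)[1:3]), "roi shape must match the series")
  arr <- detrend_series(arr, orders = 2L)
  arr <- smooth_series(arr, fwhm_mm, voxel_mm)
  m <- matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4])
  ts <- colMeans(m[as.vector(roi), , drop = FALSE])
  mean(ts[design$condition]) - mean(ts[!design$condition])
}

#' Union of family-wise-error-significant voxels across series
#'
#' For each GLM result, selects voxels whose two-sided task-contrast p-value
#' survives the chosen family-wise correction at level `alpha` (Bonferroni
#' over in-mask voxels by default — exactly implementable and conservative),
#' and returns the union across results.
#'
#' @param glm_results list of [glm_fit()] results on the same grid.
#' @param alpha significance level (default 0.001).
#' @param mask optional logical 3D analysis mask (default: whole grid).
#' @param correction `"bonferroni"` (default) or `"none"` (uncorrected p).
#' @return A logical 3D mask.
#' @export
ufwe_mask <- function(glm_results, alpha = 0.001, mask = NULL,
                      correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  check_that(length(glm_results) >= 1L, "at least one GLM result is required")
  dims <- dim(glm_results[[1]]$tmap)
  for (g in glm_results) {
    check_that(all(dim(g$tmap) == dims), "GLM results are on different grids")
  }
  if (is.null(mask)) mask <- array(TRUE, dims)
  n <- sum(mask)
  out <- array(FALSE, dims)
  for (g in glm_results) {
    p <- glm_pmap(g)
    thr <- if (correction == "bonferroni") alpha / n else alpha
    out <- out | (mask & p < thr)
  }
  out
}

#' Paired comparison of per-subject metric values
#'
#' Two-tailed paired t-test on `b - a` plus paired Cohen's d
#' (`mean(diff) / sd(diff)`, sample SD with n - 1).
#'
#' @param values_a,values_b equal-length (>= 3) per-subject values.
#' @return List with `p_value`, `cohens_d`, `t`, `df`, `mean_diff`.
#' @export
compare_series <- function(values_a, values_b) {
  check_that(length(values_a) == length(values_b),
             "paired samples must have equal length")
  check_that(length(values_a) >= 3L, "at least 3 pairs are required")
  d <- values_b - values_a
  sdd <- sd(d)
  check_that(sdd > 0, "degenerate input: zero-variance differences")
  tt <- t.test(values_b, values_a, paired = TRUE)
  list(p_value = unname(tt$p.value), cohens_d = mean(d) / sdd,
       t = unname(tt$statistic), df = unname(tt$parameter),
       mean_diff = mean(d))
}

#' Mean squared error between two maps within a mask
#'
#' @param map_a,map_b numeric arrays of identical shape.
#' @param mask optional logical array (default: everything).
#' @return Mean of squared differences within the mask.
#' @export
mse <- function(map_a, map_b, mask = NULL) {
  check_that(all(dim(map_a) == dim(map_b)), "map shapes must match")
  if (is.null(mask)) mask <- array(TRUE, dim(map_a))
  check_that(all(dim(mask) == dim(map_a)), "mask shape must match the maps")
  check_that(any(mask), "mask must be nonempty")
  mean((map_a[mask] - map_b[mask])^2)
}

#' Evaluate BOLD-sensitivity indicators for one derived series
#'
#' Computes the ROI summaries used throughout the package: mean tSNR, mean
#' PSC, mean task t-value and functional contrast within `roi`.
#'
#' @param series a [derived_series()] (or 4D array).
#' @param design a [make_block_design()] result.
#' @param roi logical 3D ROI.
#' @param fwhm_mm smoothing applied before GLM/FC (default 0).
#' @param voxel_mm voxel size in mm.
#' @param nuisance optional nuisance matrix passed to [glm_fit()].
#' @return One-row data.frame: series_kind, mean_tsnr, mean_psc, mean_tvalue,
#'   fc.
#' @export
evaluate_series <- function(series, design, roi, fwhm_mm = 0,
                            voxel_mm = c(3.5, 3.5, 3.5), nuisance = NULL) {
  kind <- if (inherits(series, "derived_series")) series$kind else "series"
  arr <- as_series_array(series)
  det <- detrend_series(arr, orders = 2L)
  sm <- smooth_series(det, fwhm_mm, voxel_mm)
  glm <- glm_fit(sm, design, nuisance = nuisance)
  ts_map <- tsnr(arr)
  psc_map <- psc(glm, design)
  data.frame(series_kind = kind,
             mean_tsnr = mean(ts_map[roi]),
             mean_psc = mean(psc_map[roi]),
             mean_tvalue = mean(glm$tmap[roi]),
             fc = functional_contrast(arr, design, roi, fwhm_mm, voxel_mm))
}

#' Metrics report across several derived series
#'
#' Stacks [evaluate_series()] rows for each series and, when per-subject
#' values are supplied later, pairs them with [compare_series()].
#'
#' @param series_list named list of [derived_series()].
#' @inheritParams evaluate_series
#' @return data.frame with one row per series.
#' @export
metrics_report <- function(series_list, design, roi, fwhm_mm = 0,
                           voxel_mm = c(3.5, 3.5, 3.5), nuisance = NULL) {
  do.call(rbind, lapply(series_list, evaluate_series, design = design,
                        roi = roi, fwhm_mm = fwhm_mm, voxel_mm = voxel_mm,
                        nuisance = nuisance))
}
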