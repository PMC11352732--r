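# Reduced-scale evaluation experiments: noise-robustness of the fitters and
# BOLD-sensitivity orderings on simulated task data. These are the routines
# the acceptance script and the heavier tests drive.

#' Train an estimator on a freshly synthesized template bank
#'
#' Convenience wrapper: builds a subject-disjoint template bank, synthesizes
#' noisy training pairs at `te_ms`, and trains a U-net estimator under `cfg`.
#' The default scale (6 subjects x 100 slices, 20 epochs) is the package's
#' reduced CPU training condition.
#'
#' @param te_ms echo times in ms.
#' @param n_subjects,per_subject bank composition.
#' @param rows,cols slice size.
#' @param cfg a [training_config()]; `cfg$seed` drives bank synthesis,
#'   pair noise and training.
#' @return A trained `sddl_estimator`.
#' @export
train_synthetic_estimator <- function(te_ms = c(14, 28, 42), n_subjects = 6L,
                                      per_subject = 100L, rows = 64L,
                                      cols = 64L, cfg = training_config()) {
  seeds <- derive_seeds(cfg$seed, 3L)
  bank <- make_template_bank(n_subjects, per_subject, rows, cols, seeds[1])
  pairs <- make_training_pairs(bank, te_ms, cfg)
  est <- build_estimator(length(te_ms), 2L, cfg$base_width,
                         init_seed = seeds[2], te_ms = te_ms)
  train_estimator(est, pairs, cfg)
}

#' Noise-robustness benchmark: estimator vs log-linear fit
#'
#' On held-out synthetic slices (subjects disjoint from any training bank by
#' seed choice), corrupts the noiseless forward signal with Rician noise at
#' each level, fits T2* with both the estimator and the LLF, and records the
#' in-mask T2* mean squared error against the ground-truth template.
#'
#' @param est a trained `sddl_estimator`.
#' @param bank held-out list of [parametric_map()].
#' @param noise_levels Rician noise fractions (default 1–5 percent).
#' @param seed seed for the noise draws.
#' @return data.frame with columns level, slice, mse_llf, mse_sddl.
#' @export
mse_noise_benchmark <- function(est, bank, noise_levels = (1:5) / 100,
                                seed = 1L) {
  te_ms <- est$te_ms
  check_that(!is.null(te_ms), "estimator carries no echo-time list")
  seeds <- derive_seeds(seed, length(bank) * length(noise_levels))
  rows <- vector("list", length(bank) * length(noise_levels))
  k <- 0L
  for (li in seq_along(noise_levels)) {
    for (si in seq_along(bank)) {
      k <- k + 1L
      map <- bank[[si]]
      img <- add_rician_noise(forward_signal(map, te_ms), noise_levels[li],
                              seeds[k])
      fit_dl <- predict_t2star(est, img)
      fit_ll <- loglinear_fit(img)
      rows[[k]] <- data.frame(
        level = noise_levels[li], slice = si,
        mse_llf = mse(fit_ll$t2star_ms, map$t2star, map$mask),
        mse_sddl = mse(fit_dl$t2star_ms, map$t2star, map$mask))
    }
  }
  do.call(rbind, rows)
}

#' Median MSE per noise level
#'
#' @param bench output of [mse_noise_benchmark()].
#' @return data.frame: level, median_mse_llf, median_mse_sddl.
#' @export
summarize_mse_benchmark <- function(bench) {
  lv <- sort(unique(bench$level))
  data.frame(
    level = lv,
    median_mse_llf = vapply(lv, function(l)
      stats::median(bench$mse_llf[bench$level == l]), numeric(1)),
    median_mse_sddl = vapply(lv, function(l)
      stats::median(bench$mse_sddl[bench$level == l]), numeric(1)))
}

# One simulated task subject at the standard acquisition condition:
# 210 volumes, TR 2 s, 10-volume OFF-first blocks, 3 echoes.
simulate_task_subject <- function(seed, delta_t2star_ms = 3,
                                  sigma_frac = 0.02, te_ms = c(14, 28, 42),
                                  n_volumes = 210L, block_len = 10L,
                                  tr_s = 2.0, rows = 64L, cols = 64L) {
  seeds <- derive_seeds(seed, 3L)
  map <- generate_template(rows, cols, seeds[1])
  design <- make_block_design(tr_s, n_volumes, block_len)
  # compact activation blob inside cortical grey matter
  act <- withr::with_seed(seeds[2], {
    gm <- map$mask & map$t2star >= 60 & map$t2star <= 80
    idx <- which(gm, arr.ind = TRUE)
    ctr <- idx[sample.int(nrow(idx), 1), ]
    rr <- outer((seq_len(rows) - ctr[1])^2, (seq_len(cols) - ctr[2])^2, "+")
    gm & rr <= 3.5^2
  })
  series <- simulate_series(map, design, array(act, c(rows, cols, 1)),
                            delta_t2star_ms = delta_t2star_ms,
                            drift = c(0.01, -0.005),
                            sigma_frac = sigma_frac, te_ms = te_ms,
                            seed = seeds[3])
  list(series = series, design = design, map = map,
       act = array(act, c(rows, cols, 1)))
}

#' Task-activation recovery benchmark
#'
#' Simulates block-design task subjects with a known activation blob
#' (ground-truth T2* increase), fits the LLF and estimator T2* time series,
#' runs the GLM, and reports whether the peak-|t| voxel falls inside the true
#' activation mask plus the ROI-mean fitted T2* effect (the task beta, in ms).
#'
#' @param est a trained `sddl_estimator`.
#' @param seeds integer vector of subject seeds.
#' @param delta_t2star_ms simulated T2* increase (default 3 ms).
#' @param sigma_frac Rician noise fraction (default 2 percent).
#' @return data.frame: seed, peak_in_mask_llf, peak_in_mask_sddl,
#'   delta_hat_llf, delta_hat_sddl.
#' @export
task_recovery_benchmark <- function(est, seeds, delta_t2star_ms = 3,
                                    sigma_frac = 0.02) {
  rows <- lapply(seeds, function(sd) {
    sub <- simulate_task_subject(sd, delta_t2star_ms, sigma_frac, est$te_ms)
    s_llf <- fit_t2star_series(sub$series, "llf")
    s_dl <- fit_t2star_series(sub$series, "sddl", est)
    tissue <- array(sub$map$mask, dim(sub$act))
    one <- function(s) {
      # standard first-level pipeline: detrend, smooth, then GLM
      det <- detrend_series(s)
      g_sm <- glm_fit(smooth_series(det, 7), sub$design)
      tm <- g_sm$tmap
      tm[!tissue] <- 0
      peak <- which.max(abs(tm))
      # effect size from the unsmoothed fit so the ms scale is preserved
      g_raw <- glm_fit(det, sub$design)
      list(in_mask = sub$act[peak],
           delta_hat = mean(g_raw$betas[, , , 1][sub$act]))
    }
    a <- one(s_llf); b <- one(s_dl)
    data.frame(seed = sd, peak_in_mask_llf = a$in_mask,
               peak_in_mask_sddl = b$in_mask,
               delta_hat_llf = a$delta_hat, delta_hat_sddl = b$delta_hat)
  })
  do.call(rbind, rows)
}

#' BOLD-sensitivity ordering benchmark
#'
#' Simulates task subjects and compares, per subject, (a) tissue-mean tSNR of
#' the estimator T2* series against the LLF T2* series and (b) activation-ROI
#' mean PSC of the (LLF) T2* series against the echo-combined series. Paired
#' statistics come from [compare_series()].
#'
#' @param est a trained `sddl_estimator`.
#' @param seeds integer vector of subject seeds.
#' @param sigma_frac Rician noise fraction (default 2 percent).
#' @return list with per-subject data.frame `per_subject` and the two paired
#'   comparisons `tsnr_cmp` (LLF vs estimator) and `psc_cmp` (EC vs T2*).
#' @export
sensitivity_benchmark <- function(est, seeds, sigma_frac = 0.02) {
  per <- lapply(seeds, function(sd) {
    sub <- simulate_task_subject(sd, sigma_frac = sigma_frac,
                                 te_ms = est$te_ms)
    tissue <- array(sub$map$mask, dim(sub$act))
    s_llf <- fit_t2star_series(sub$series, "llf")
    s_dl <- fit_t2star_series(sub$series, "sddl", est)
    # EC weights from the LLF fit of the time-averaged series
    d <- dim(sub$series$data)
    tmean <- array(rowMeans(matrix(sub$series$data, prod(d[1:4]), d[5])),
                   d[1:4])
    ll_mean <- loglinear_fit(multiecho_image(
      array(tmean, c(d[1], d[2] * d[3], d[4])), sub$series$te_ms))
    s_ec <- ec_series(sub$series, array(ll_mean$t2star_ms, d[1:3]))
    prep <- function(s) smooth_series(detrend_series(s), 7)
    g_llf <- glm_fit(prep(s_llf), sub$design)
    g_ec <- glm_fit(prep(s_ec), sub$design)
    data.frame(seed = sd,
               tsnr_llf = mean(tsnr(s_llf)[tissue]),
               tsnr_sddl = mean(tsnr(s_dl)[tissue]),
               psc_t2 = mean(psc(g_llf, sub$design)[sub$act]),
               psc_ec = mean(psc(g_ec, sub$design)[sub$act]))
  })
  per <- do.call(rbind, per)
  list(per_subject = per,
       tsnr_cmp = compare_series(per$tsnr_llf, per$tsnr_sddl),
       psc_cmp = compare_series(per$psc_ec, per$psc_t2))
}
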