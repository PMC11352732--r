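#' Block task designs
#'
#' Builds an alternating OFF/ON boxcar design that starts OFF, with blocks of
#' `block_len` volumes, truncated at `n_volumes`.
#'
#' @param tr_s repetition time in seconds.
#' @param n_volumes number of volumes (>= 2 * block_len).
#' @param block_len block length in volumes.
#' @return A `task_design` with a logical `condition` vector (TRUE = ON).
#' @export
make_block_design <- function(tr_s, n_volumes, block_len) {
  check_that(is_count(block_len, 1L), "block_len must be >= 1")
  check_that(is_count(n_volumes, 2L) && n_volumes >= 2L * block_len,
             "n_volumes must be at least 2 * block_len")
  check_that(tr_s > 0, "tr_s must be positive")
  cond <- rep(rep(c(FALSE, TRUE), each = block_len),
              length.out = n_volumes)
  structure(list(tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 block_len_volumes = as.integer(block_len),
                 start_condition = "OFF", condition = cond),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d volumes, TR %.3g s, %d-volume blocks starting OFF\n",
              x$n_volumes, x$tr_s, x$block_len_volumes))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas HRF (response gamma with shape 6,
#' undershoot gamma with shape 16, undershoot ratio 1/6, unit dispersion).
#' Values are later peak-normalised where a unit-peak regressor is needed.
#'
#' @param t_s time in seconds (>= 0).
#' @return HRF values at `t_s`.
#' @export
hrf_canonical <- function(t_s) {
  stats::dgamma(t_s, shape = 6, rate = 1) -
    stats::dgamma(t_s, shape = 16, rate = 1) / 6
}

#' HRF-convolved task regressor and scaling factor
#'
#' Convolves the design's ON/OFF boxcar with the canonical HRF on a grid
#' oversampled by `oversample` relative to TR, normalises the curve to peak 1,
#' and samples it at volume acquisition times. Also returns the scaling factor
#' SF: the maximum of a single reference trial (one ON block) on the same
#' super-sampled grid, in the same unit-peak normalisation.
#'
#' @param design a [make_block_design()] result.
#' @param oversample super-sampling factor relative to TR (default 16).
#' @return A list with `volume` (unit-peak regressor at volume times), `sf`,
#'   and the oversampled curve `fine` with its time step `dt_s`.
#' @export
task_regressor <- function(design, oversample = 16L) {
  dt <- design$tr_s / oversample
  n_fine <- design$n_volumes * oversample
  box <- rep(as.numeric(design$condition), each = oversample)
  hk <- hrf_canonical(seq(0, 32, by = dt))
  conv_full <- function(u) {
    # direct linear convolution, truncated to the input length
    v <- stats::convolve(u, rev(hk), type = "open")[seq_along(u)] * dt
    v
  }
  fine <- conv_full(box)
  peak <- max(fine)
  check_that(peak > 0, "design has no ON volumes")
  fine <- fine / peak

  # one reference trial: a single ON block with generous OFF padding
  trial_box <- c(rep(0, oversample * design$block_len_volumes),
                 rep(1, oversample * design$block_len_volumes),
                 rep(0, oversample * 3L * design$block_len_volumes))
  sf <- max(conv_full(trial_box)) / peak

  list(volume = fine[seq(1, n_fine, by = oversample)],
       sf = sf, fine = fine, dt_s = dt)
}

#' Multi-echo fMRI series objects
#'
#' `data` is a 5D (x, y, slice, echo, time) magnitude array; `truth` is an
#' optional ground-truth record present when the series was simulated.
#'
#' @param data 5D (x, y, slice, echo, time) array, non-negative.
#' @param te_ms echo times (ms).
#' @param tr_s repetition time (s).
#' @param truth optional simulation ground-truth record.
#' @return An object of class `multiecho_series`.
#' @export
multiecho_series <- function(data, te_ms, tr_s, truth = NULL) {
  check_that(is.array(data) && length(dim(data)) == 5L,
             "data must be a 5D (x, y, slice, echo, time) array")
  check_that(dim(data)[4] == length(te_ms),
             "echo axis length must equal length(te_ms)")
  check_that(all(data >= 0), "magnitude data must be non-negative")
  structure(list(data = data, te_ms = as.numeric(te_ms), tr_s = tr_s,
                 truth = truth),
            class = "multiecho_series")
}

#' @export
print.multiecho_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multiecho_series> %d x %d x %d, %d echoes, %d volumes, TR %.3g s%s\n",
              d[1], d[2], d[3], d[4], d[5], x$tr_s,
              if (is.null(x$truth)) "" else " (simulated)"))
  invisible(x)
}

#' Simulate a multi-echo task fMRI series with known ground truth
#'
#' The BOLD effect is injected as a task-locked additive T2* change: inside
#' `activation_mask`, T2*(t) = baseline + `delta_t2star_ms` * h(t), where h is
#' the ON/OFF boxcar convolved with the canonical HRF and normalised to peak 1.
#' Each volume is generated echo-wise through the noiseless forward model,
#' multiplied by a global polynomial drift 1 + a u + b u^2 (u = normalised
#' volume index in \[0, 1\]), and corrupted with per-volume independent Rician
#' noise whose SD is `sigma_frac` times the maximum baseline first-echo
#' amplitude. The full ground truth is stored in the result's `truth` record.
#'
#' @param templates a [parametric_map()] or list of them, one per slice.
#' @param design a [make_block_design()] result.
#' @param activation_mask logical (x, y, slice) array, subset of the tissue
#'   masks.
#' @param delta_t2star_ms task-locked T2* increase in ms (>= 0; default 3).
#' @param drift c(linear, quadratic) relative drift coefficients.
#' @param sigma_frac Rician noise fraction in \[0, 0.10\].
#' @param te_ms echo times (ms).
#' @param seed integer seed.
#' @return A [multiecho_series()] with `truth`.
#' @export
simulate_series <- function(templates, design, activation_mask,
                            delta_t2star_ms = 3, drift = c(0, 0),
                            sigma_frac = 0.02, te_ms = c(14, 28, 42),
                            seed = 1L) {
  if (inherits(templates, "parametric_map")) templates <- list(templates)
  n_sl <- length(templates)
  d2 <- dim(templates[[1]]$m0)
  check_that(is.array(activation_mask) &&
               all(dim(activation_mask) == c(d2, n_sl)),
             "activation_mask shape must match (rows, cols, n_slices)")
  check_that(delta_t2star_ms >= 0, "delta_t2star_ms must be >= 0")
  check_that(sigma_frac >= 0 && sigma_frac <= 0.10,
             "sigma_frac must lie in [0, 0.10]")
  for (z in seq_len(n_sl)) {
    check_that(!any(activation_mask[, , z] & !templates[[z]]$mask),
               "activation_mask must lie inside the tissue mask")
    check_that(max(templates[[z]]$t2star) + delta_t2star_ms <= 500,
               "baseline + delta T2* would exceed 500 ms")
  }

  reg <- task_regressor(design)
  h <- reg$volume
  n_t <- design$n_volumes
  n_e <- length(te_ms)

  base <- array(0, c(d2, n_sl, n_e))
  for (z in seq_len(n_sl)) {
    base[, , z, ] <- forward_signal(templates[[z]], te_ms)$data
  }
  sigma <- sigma_frac * max(base[, , , 1])
  u <- if (n_t > 1) (seq_len(n_t) - 1) / (n_t - 1) else 0

  data <- array(0, c(d2, n_sl, n_e, n_t))
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(n_t)) {
      vol <- base
      if (delta_t2star_ms > 0 && h[t] != 0) {
        for (z in seq_len(n_sl)) {
          act <- activation_mask[, , z]
          if (!any(act)) next
          t2t <- templates[[z]]$t2star[act] + delta_t2star_ms * h[t]
          m0 <- templates[[z]]$m0[act]
          for (e in seq_len(n_e)) {
            plane <- vol[, , z, e]
            plane[act] <- m0 * exp(-te_ms[e] / t2t)
            vol[, , z, e] <- plane
          }
        }
      }
      dr <- 1 + drift[1] * u[t] + drift[2] * u[t]^2
      vol <- vol * dr
      if (sigma > 0) {
        g1 <- array(rnorm(length(vol), sd = sigma), dim(vol))
        g2 <- array(rnorm(length(vol), sd = sigma), dim(vol))
        vol <- sqrt((vol + g1)^2 + g2^2)
      }
      data[, , , , t] <- vol
    }
  })

  truth <- list(templates = templates, activation_mask = activation_mask,
                delta_t2star_ms = delta_t2star_ms, drift = drift,
                sigma_frac = sigma_frac, seed = as.integer(seed),
                design = design, h = h)
  multiecho_series(data, te_ms, design$tr_s, truth = truth)
}
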