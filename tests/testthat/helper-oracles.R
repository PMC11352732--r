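# Independent brute-force oracles and small fixture builders shared by tests.

# single-voxel parametric map with given S0/T2* at (5, 5) on a 16x16 grid
one_voxel_map <- function(s0 = 100, t2 = 28, rows = 16, cols = 16) {
  m0 <- matrix(0, rows, cols)
  t2s <- matrix(0, rows, cols)
  mask <- matrix(FALSE, rows, cols)
  m0[5, 5] <- s0
  t2s[5, 5] <- t2
  mask[5, 5] <- TRUE
  parametric_map(m0, t2s, mask)
}

# per-voxel log-linear fit through lm(), the reference for the LLF path
oracle_loglin <- function(sig, te) {
  fit <- stats::lm(log(sig) ~ te)
  c(s0 = exp(unname(stats::coef(fit)[1])), r2 = -unname(stats::coef(fit)[2]))
}

# loop-based weighted echo combination
oracle_combine <- function(data, w) {
  d <- dim(data)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    for (e in seq_len(d[3])) out[i, j] <- out[i, j] + w[i, j, e] * data[i, j, e]
  }
  out
}

# lm-based polynomial detrend (residuals plus temporal mean), one voxel
oracle_detrend_1d <- function(y, orders = 2) {
  n <- length(y)
  u <- seq(-1, 1, length.out = n)
  X <- if (orders == 2) cbind(u, u^2) else cbind(u)
  stats::resid(stats::lm(y ~ X)) + mean(y)
}

# lm-based GLM betas and task t for one voxel time series
oracle_glm_1d <- function(y, X) {
  fit <- stats::lm(y ~ X - 1)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)),
       t = unname(s$coefficients[1, "t value"]),
       dof = fit$df.residual)
}

# fitted-baseline over residual SD, one voxel (0-based polynomial time)
oracle_tsnr_1d <- function(y) {
  n <- length(y)
  u <- (seq_len(n) - 1) / (n - 1)
  fit <- stats::lm(y ~ u + I(u^2))
  unname(stats::coef(fit)[1]) / stats::sd(stats::resid(fit))
}

# small simulated series fixture (single slice)
tiny_task_sim <- function(seed = 11L, n_volumes = 20L, block_len = 5L,
                          delta = 3, sigma_frac = 0, rows = 16L, cols = 16L) {
  map <- generate_template(rows, cols, seed)
  design <- make_block_design(2.0, n_volumes, block_len)
  gm <- map$mask & map$t2star >= 60 & map$t2star <= 80
  idx <- which(gm, arr.ind = TRUE)
  act <- matrix(FALSE, rows, cols)
  act[idx[seq_len(min(6, nrow(idx))), , drop = FALSE]] <- TRUE
  series <- simulate_series(map, design, array(act, c(rows, cols, 1)),
                            delta_t2star_ms = delta, sigma_frac = sigma_frac,
                            te_ms = c(14, 28, 42), seed = seed + 1L)
  list(series = series, design = design, map = map,
       act = array(act, c(rows, cols, 1)))
}

# quick untrained estimator for mechanical (non-accuracy) contracts
untrained_estimator <- function(base_width = 4L, seed = 3L) {
  build_estimator(3L, 2L, base_width, init_seed = seed, te_ms = c(14, 28, 42))
}
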