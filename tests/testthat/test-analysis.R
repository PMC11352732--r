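test_that("LLF time-series fitting matches a per-voxel lm oracle", {
  sim <- tiny_task_sim(sigma_frac = 0.02)
  s <- fit_t2star_series(sim$series, "llf")
  te <- sim$series$te_ms
  t_pick <- 6
  set.seed(2)
  vox <- which(sim$map$mask)[sample.int(sum(sim$map$mask), 8)]
  vol <- sim$series$data[, , 1, , t_pick]
  fit2d <- s$data[, , 1, t_pick]
  for (v in vox) {
    sig <- vol[cbind(rep(v %% 16, 3), rep(1, 3))] # placeholder, replaced below
  }
  for (v in vox) {
    ij <- arrayInd(v, c(16, 16))
    sig <- vol[ij[1], ij[2], ]
    if (all(sig > 1e-6 * max(vol))) {
      o <- oracle_loglin(sig, te)
      if (o["r2"] > 0 && 1 / o["r2"] >= 1 && 1 / o["r2"] <= 500) {
        expect_equal(fit2d[ij[1], ij[2]], unname(1 / o["r2"]),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("estimator-weighted combination equals the manual pipeline", {
  est <- untrained_estimator()
  sim <- tiny_task_sim(seed = 31, n_volumes = 4, block_len = 2,
                       sigma_frac = 0.01)
  ser <- sim$series
  out <- sddl_ec_series(ser, est)
  expect_equal(out$kind, "SDDL_EC")

  # manual: time-average -> slice-wise estimate -> Eq-style weights -> sum
  d <- dim(ser$data)
  tmean <- array(rowMeans(matrix(ser$data, prod(d[1:4]), d[5])), d[1:4])
  fr <- fit_volume_slicewise(est, tmean, ser$te_ms)
  w <- echo_combination_weights(fr$t2star_ms[, , 1], ser$te_ms)
  for (t in seq_len(d[5])) {
    manual <- combine_echoes(multiecho_image(array(ser$data[, , 1, , t],
                                                   c(d[1], d[2], d[4])),
                                             ser$te_ms), w)
    expect_identical(out$data[, , 1, t], manual)
  }
})

test_that("combination weights are constant over time", {
  sim <- tiny_task_sim(seed = 32, n_volumes = 6, block_len = 3,
                       delta = 0, sigma_frac = 0)
  t2map <- array(sim$map$t2star, c(16, 16, 1))
  t2map[t2map == 0] <- 80 # weights need positive T2* everywhere
  out <- ec_series(sim$series, t2map)
  # static noiseless series: every combined volume is identical
  for (t in 2:6) {
    expect_equal(out$data[, , , t], out$data[, , , 1], tolerance = 1e-12)
  }
  expect_equal(out$provenance$weights_t2star, t2map)
})

test_that("polynomial detrending annihilates trends and keeps the mean", {
  tvec <- seq_len(24)
  y <- 3 + 2 * tvec + tvec^2
  arr <- array(rep(y, each = 4), c(2, 2, 1, 24))
  det <- detrend_series(arr)
  expect_equal(as.vector(det[1, 1, 1, ]), rep(mean(y), 24), tolerance = 1e-8)

  set.seed(9)
  noise <- array(rnorm(2 * 2 * 1 * 30, 50, 2), c(2, 2, 1, 30))
  det2 <- detrend_series(noise)
  expect_equal(apply(det2, 1:3, mean), apply(noise, 1:3, mean),
               tolerance = 1e-10)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(det2[i, j, 1, ], oracle_detrend_1d(noise[i, j, 1, ]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(detrend_series(array(1, c(2, 2, 1, 3))), "4 time points")
})

test_that("Gaussian smoothing preserves constants and has the stated width", {
  set.seed(3)
  arr <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  expect_identical(smooth_series(arr, 0), arr)
  const <- array(7, c(12, 12, 1, 1))
  expect_equal(smooth_series(const, 7), const, tolerance = 1e-12)

  # 7 mm FWHM on 3.5 mm voxels: sigma = 2 / 2.3548 voxels
  imp <- array(0, c(33, 33, 1, 1))
  imp[17, 17, 1, 1] <- 1
  sm <- smooth_series(imp, 7, c(3.5, 3.5, 3.5))
  prof <- sm[, 17, 1, 1] / sum(sm[, 17, 1, 1])
  sigma_hat <- sqrt(sum(prof * (seq_len(33) - 17)^2))
  expect_equal(sigma_hat, 7 / (3.5 * sqrt(8 * log(2))), tolerance = 0.02)
  # kernel mass is preserved
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("the GLM matches a normal-equations oracle and flags perfect fits", {
  design <- make_block_design(2.0, 20, 5)
  reg <- task_regressor(design)$volume

  # perfect fit: series is exactly regressor + constant
  arr <- array(rep(reg + 5, each = 4), c(2, 2, 1, 20))
  g <- glm_fit(arr, design)
  expect_equal(as.vector(g$betas[, , , 1]), rep(1, 4), tolerance = 1e-10)
  expect_true(all(g$tmap == 1e6))

  # noisy toy vs lm oracle, with one nuisance regressor
  set.seed(12)
  nuis <- matrix(rnorm(20), 20, 1)
  y <- array(rnorm(2 * 2 * 1 * 20, 10), c(2, 2, 1, 20))
  g2 <- glm_fit(y, design, nuisance = nuis)
  X <- g2$design_matrix
  for (i in 1:2) for (j in 1:2) {
    o <- oracle_glm_1d(y[i, j, 1, ], X)
    expect_equal(g2$betas[i, j, 1, ], o$beta, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(g2$tmap[i, j, 1], o$t, tolerance = 1e-8)
    expect_equal(g2$dof, o$dof)
  }

  # collinear design is rejected with the offending column named
  expect_error(glm_fit(y, design, nuisance = cbind(dup = reg)),
               "collinear.*constant|collinear.*dup")
})

test_that("GLM null calibration holds on white-noise series", {
  design <- make_block_design(2.0, 60, 10)
  set.seed(77)
  hits <- 0; total <- 0
  for (r in 1:6) {
    y <- array(rnorm(20 * 25 * 1 * 60), c(20, 25, 1, 60))
    g <- glm_fit(y, design)
    p <- glm_pmap(g)
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  expect_equal(hits / total, 0.05, tolerance = 0.25)
})

test_that("tSNR is baseline over trend-residual SD with degenerates flagged", {
  const <- array(3, c(2, 2, 1, 10))
  ts <- tsnr(const)
  expect_true(all(ts == 0))
  expect_true(all(attr(ts, "flagged")))

  set.seed(5)
  y <- array(rnorm(10 * 10 * 1 * 500, mean = 100, sd = 5),
             c(10, 10, 1, 500))
  ts2 <- tsnr(y)
  expect_equal(mean(ts2), 20, tolerance = 0.05)
  for (i in 1:3) {
    expect_equal(ts2[i, 1, 1], oracle_tsnr_1d(y[i, 1, 1, ]),
                 tolerance = 1e-10)
  }

  # invariance to added linear/quadratic trends (time counted from zero)
  tv <- seq_len(500) - 1
  trended <- y + array(rep(0.5 * tv + 0.001 * tv^2, each = 100),
                       c(10, 10, 1, 500))
  expect_equal(as.vector(tsnr(trended)), as.vector(ts2), tolerance = 1e-8)
})

test_that("PSC follows the beta ratio and is scale invariant", {
  design <- make_block_design(2.0, 40, 5)
  reg <- task_regressor(design)
  # null effect (task beta is zero up to solver round-off)
  flat <- array(100, c(2, 2, 1, 40))
  g0 <- glm_fit(flat, design)
  expect_lt(max(abs(psc(g0, design))), 1e-10)

  # beta_task = 1, beta_constant = 100 -> PSC = SF
  y <- array(rep(reg$volume + 100, each = 4), c(2, 2, 1, 40))
  g1 <- glm_fit(y, design)
  expect_equal(as.vector(psc(g1, design)), rep(reg$sf, 4), tolerance = 1e-10)

  set.seed(8)
  yn <- y + array(rnorm(length(y), sd = 0.1), dim(y))
  p1 <- psc(glm_fit(yn, design), design)
  p10 <- psc(glm_fit(yn * 10, design), design)
  expect_equal(p1, p10, tolerance = 1e-8)
})

test_that("functional contrast is ON minus OFF after detrending", {
  design <- make_block_design(2.0, 210, 10)
  roi <- array(TRUE, c(2, 2, 1))
  flat <- array(5, c(2, 2, 1, 210))
  expect_equal(functional_contrast(flat, design, roi), 0, tolerance = 1e-12)

  box <- array(rep(as.numeric(design$condition), each = 4), c(2, 2, 1, 210))
  fc <- functional_contrast(box, design, roi)
  expect_equal(fc, 1, tolerance = 0.05)

  # permuted labels with equal ON/OFF counts average to ~0
  set.seed(14)
  y <- array(rnorm(2 * 2 * 1 * 210), c(2, 2, 1, 210))
  fcs <- vapply(1:40, function(r) {
    d2 <- design
    d2$condition <- sample(design$condition)
    functional_contrast(y, d2, roi)
  }, numeric(1))
  expect_lt(abs(mean(fcs)), 0.05)
  expect_error(functional_contrast(flat, design, array(FALSE, c(2, 2, 1))),
               "nonempty")
})

test_that("the union FWE mask is the union of per-series significant sets", {
  fake_glm <- function(tvals, dims = c(4, 4, 4), dof = 100) {
    tm <- array(0, dims)
    tm[seq_along(tvals)] <- tvals
    structure(list(tmap = tm, dof = dof,
                   betas = array(0, c(dims, 2)),
                   regressors = c("task", "constant"), sf = 1),
              class = "glm_result")
  }
  g1 <- fake_glm(rep(30, 10))
  g2 <- fake_glm(c(rep(0, 10), rep(30, 15)))
  expect_equal(sum(ufwe_mask(list(g1), alpha = 0.001)), 10)
  m <- ufwe_mask(list(g1, g2), alpha = 0.001)
  expect_equal(sum(m), 25)
  expect_error(ufwe_mask(list(g1, fake_glm(1, dims = c(2, 2, 2)))),
               "grid")
})

test_that("paired comparisons reproduce the textbook example", {
  out <- compare_series(c(1, 2, 3), c(2, 4, 6))
  expect_equal(out$cohens_d, 2, tolerance = 1e-12)
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(out$p_value, 0.0742, tolerance = 1e-3)
  swapped <- compare_series(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swapped$cohens_d, -out$cohens_d, tolerance = 1e-12)
  expect_equal(swapped$p_value, out$p_value, tolerance = 1e-12)
  expect_error(compare_series(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(compare_series(c(1, 2), c(3, 4)), "3 pairs")
})

test_that("masked MSE matches its closed forms and a loop oracle", {
  a <- matrix(rnorm(36), 6, 6)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, a + 3), 9, tolerance = 1e-12)
  b <- matrix(rnorm(36), 6, 6)
  mask <- matrix(rep(c(TRUE, FALSE), 18), 6, 6)
  loop <- mean((a[mask] - b[mask])^2)
  expect_equal(mse(a, b, mask), loop, tolerance = 1e-12)
  expect_error(mse(a, b, matrix(FALSE, 6, 6)), "nonempty")
  expect_error(mse(a, matrix(0, 2, 2)), "match")
})

test_that("the metrics report carries one row of indicators per series", {
  sim <- tiny_task_sim(seed = 51, n_volumes = 20, block_len = 5,
                       delta = 3, sigma_frac = 0.01)
  s <- fit_t2star_series(sim$series, "llf")
  rep <- metrics_report(list(s), sim$design, sim$act)
  expect_equal(nrow(rep), 1)
  expect_named(rep, c("series_kind", "mean_tsnr", "mean_psc", "mean_tvalue",
                      "fc"))
  expect_equal(rep$series_kind, "LLF_T2STAR")
  expect_true(all(is.finite(as.numeric(rep[1, -1]))))
  expect_gt(rep$mean_psc, 0) # positive injected effect
})
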