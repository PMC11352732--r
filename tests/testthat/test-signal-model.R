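test_that("forward model evaluates the mono-exponential decay exactly", {
  m <- one_voxel_map(100, 28)
  img <- forward_signal(m, c(14, 28, 42))
  expect_equal(img$data[5, 5, ], 100 * exp(-c(14, 28, 42) / 28),
               tolerance = 1e-12)
  expect_equal(img$data[5, 5, ], c(60.6531, 36.7879, 22.3130),
               tolerance = 1e-4)
  # TE -> 0 limit recovers S0
  expect_equal(forward_signal(m, 1e-9)$data[5, 5, 1], 100, tolerance = 1e-9)
  # background voxels are zero at all echoes
  expect_true(all(img$data[-5, , ] == 0))
  expect_error(forward_signal(m, c(-14, 28)), "positive")
})

test_that("zero-noise injection is the identity and noise is reproducible", {
  m <- generate_template(32, 32, 6)
  img <- forward_signal(m, c(14, 28, 42))
  expect_identical(add_rician_noise(img, 0, 1), img)
  n1 <- add_rician_noise(img, 0.03, 42)
  n2 <- add_rician_noise(img, 0.03, 42)
  expect_identical(n1, n2)
  n3 <- add_rician_noise(img, 0.03, 43)
  expect_false(identical(n1, n3))
  expect_true(min(n1$data) >= 0)
  expect_error(add_rician_noise(img, -0.01, 1), "sigma_frac")
})

test_that("Rician noise on zero signal has the Rayleigh mean", {
  # one bright voxel sets the sigma reference; everything else is zero signal
  d <- array(0, c(320, 320, 1))
  d[1, 1, 1] <- 100
  img <- multiecho_image(d, 10)
  out <- add_rician_noise(img, 0.05, seed = 9)
  zero_vox <- out$data[, , 1][-1]
  sigma <- 0.05 * 100
  expect_equal(mean(zero_vox), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("log-linear fit inverts the noiseless forward model", {
  for (seed in c(3, 31)) {
    m <- generate_template(64, 64, seed)
    fr <- loglinear_fit(forward_signal(m, c(14, 28, 42)))
    rel_t2 <- abs(fr$t2star_ms[m$mask] - m$t2star[m$mask]) / m$t2star[m$mask]
    rel_s0 <- abs(fr$s0[m$mask] - m$m0[m$mask]) / m$m0[m$mask]
    expect_lt(max(rel_t2), 1e-8)
    expect_lt(max(rel_s0), 1e-8)
    expect_true(all(fr$valid[m$mask]))
  }
})

test_that("flat decay clips to the upper bound and is flagged invalid", {
  d <- array(50, c(4, 4, 3))
  fr <- loglinear_fit(multiecho_image(d, c(14, 28, 42)))
  expect_true(all(fr$t2star_ms == 500))
  expect_false(any(fr$valid))
  expect_true(all(fr$r2star_per_ms == 0))
})

test_that("log-linear fit matches a per-voxel least-squares oracle", {
  te <- c(14, 28, 42)
  set.seed(8)
  d <- array(exp(rnorm(5 * 4 * 3, mean = 3, sd = 0.5)), c(5, 4, 3))
  fr <- loglinear_fit(multiecho_image(d, te))
  for (i in 1:5) for (j in 1:4) {
    o <- oracle_loglin(d[i, j, ], te)
    if (fr$valid[i, j]) {
      # the fitter clips T2* to [1, 500] ms after inversion
      t2_ref <- min(max(1 / o[["r2"]], 1), 500)
      expect_equal(fr$t2star_ms[i, j], t2_ref, tolerance = 1e-10)
      expect_equal(fr$s0[i, j], o[["s0"]], tolerance = 1e-10)
    }
  }
  # r2star is the reciprocal of t2star wherever valid
  expect_equal(fr$r2star_per_ms[fr$valid], 1 / fr$t2star_ms[fr$valid],
               tolerance = 1e-12)
})

test_that("duplicate echo times are rejected", {
  expect_error(multiecho_image(array(1, c(2, 2, 2)), c(14, 14)),
               "increasing")
})

test_that("echo-combination weights follow the matched-filter formula", {
  w <- echo_combination_weights(matrix(28, 1, 1), c(14, 28, 42))
  ref <- c(14, 28, 42) * exp(-c(14, 28, 42) / 28)
  expect_equal(w$w[1, 1, ], ref / sum(ref), tolerance = 1e-12)
  expect_equal(w$w[1, 1, ], c(0.3015, 0.3658, 0.3327), tolerance = 1e-3)
  # single echo normalises to 1
  w1 <- echo_combination_weights(matrix(50, 2, 2), 30)
  expect_true(all(w1$w == 1))
  expect_error(echo_combination_weights(matrix(c(28, 0), 1, 2), c(14, 28)),
               "clip")
})

test_that("weights lie on the probability simplex for arbitrary T2* maps", {
  set.seed(21)
  t2 <- matrix(runif(64, 1, 500), 8, 8)
  w <- echo_combination_weights(t2, c(14, 28, 42))
  expect_true(all(w$w >= 0))
  expect_lt(max(abs(apply(w$w, c(1, 2), sum) - 1)), 1e-12)
})

test_that("echo combination is a voxel-wise weighted sum", {
  te <- c(14, 28, 42)
  onehot <- array(0, c(3, 3, 3)); onehot[, , 2] <- 1
  d <- array(seq_len(27), c(3, 3, 3))
  img <- multiecho_image(d, te)
  expect_equal(combine_echoes(img, echo_weights(onehot, te)), d[, , 2])

  uni <- array(1 / 3, c(1, 1, 3))
  img2 <- multiecho_image(array(c(60, 36, 24), c(1, 1, 3)), te)
  expect_equal(combine_echoes(img2, echo_weights(uni, te))[1, 1], 40)

  set.seed(4)
  w <- array(runif(27), c(3, 3, 3))
  expect_equal(combine_echoes(img, echo_weights(w, te)),
               oracle_combine(d, w), tolerance = 1e-12)
  expect_error(combine_echoes(img, echo_weights(array(1, c(2, 2, 3)), te)),
               "conform")
})

test_that("combination is linear in the image argument", {
  te <- c(14, 28, 42)
  set.seed(5)
  w <- echo_weights(array(runif(12), c(2, 2, 3)), te)
  a <- array(runif(12), c(2, 2, 3))
  b <- array(runif(12), c(2, 2, 3))
  lhs <- combine_echoes(multiecho_image(2 * a + 3 * b, te), w)
  rhs <- 2 * combine_echoes(multiecho_image(a, te), w) +
    3 * combine_echoes(multiecho_image(b, te), w)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("LLF T2* error grows with the Rician noise level", {
  m <- generate_template(48, 48, 14)
  img <- forward_signal(m, c(14, 28, 42))
  med <- vapply((1:5) / 100, function(lv) {
    errs <- vapply(1:12, function(r) {
      noisy <- add_rician_noise(img, lv, seed = 1000 + r)
      mse(loglinear_fit(noisy)$t2star_ms, m$t2star, m$mask)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
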