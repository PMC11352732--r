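small_cfg <- function(...) {
  defaults <- list(batch_size = 4L, crop_size = 16L, learning_rate = 3e-3,
                   max_epochs = 4L, noise_range = c(0, 0.02),
                   split_fraction = 1 / 2, seed = 7L, crops_per_slice = 2L,
                   base_width = 4L)
  do.call(training_config, utils::modifyList(defaults, list(...)))
}

small_bank <- function() make_template_bank(2, 6, 16, 16, seed = 41)

test_that("training pairs are subject-disjoint, normalised and reproducible", {
  bank <- small_bank()
  cfg <- small_cfg()
  ds <- make_training_pairs(bank, c(14, 28, 42), cfg)
  tr <- unique(vapply(ds$train, `[[`, integer(1), "subject_id"))
  va <- unique(vapply(ds$val, `[[`, integer(1), "subject_id"))
  expect_length(intersect(tr, va), 0)
  expect_identical(ds, make_training_pairs(bank, c(14, 28, 42), cfg))

  # zero noise: inputs equal the normalised noiseless forward signal
  cfg0 <- small_cfg(noise_range = c(0, 0))
  ds0 <- make_training_pairs(bank, c(14, 28, 42), cfg0)
  p <- ds0$train[[1]]
  expect_true(all(p$x >= 0) && max(p$x[, , 1]) == 1)
  # T2* label channel is the augmented map divided by 200 ms
  expect_true(all(p$y[, , 2] >= 0 & p$y[, , 2] <= 1))

  one_subject <- bank[vapply(bank, `[[`, integer(1), "subject_id") == 0L]
  expect_error(make_training_pairs(one_subject, c(14, 28, 42), cfg),
               "2 subjects")
})

test_that("zero-epoch training is a no-op with empty history", {
  bank <- small_bank()
  cfg <- small_cfg(max_epochs = 0L)
  ds <- make_training_pairs(bank, c(14, 28, 42), cfg)
  est <- build_estimator(3, 2, 4, init_seed = 2)
  out <- train_estimator(est, ds, cfg)
  expect_identical(out$params, est$params)
  expect_equal(nrow(out$history), 0)
})

test_that("training reduces validation loss and returns the best checkpoint", {
  bank <- small_bank()
  cfg <- small_cfg()
  ds <- make_training_pairs(bank, c(14, 28, 42), cfg)
  est <- build_estimator(3, 2, cfg$base_width, init_seed = 2)
  fit <- train_estimator(est, ds, cfg)
  expect_equal(nrow(fit$history), cfg$max_epochs)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_lte(fit$best_val_loss, fit$history$val_loss[1])
  expect_lt(min(fit$history$val_loss), fit$history$val_loss[1])
})

test_that("training is reproducible under a fixed seed", {
  bank <- small_bank()
  cfg <- small_cfg(max_epochs = 2L)
  ds <- make_training_pairs(bank, c(14, 28, 42), cfg)
  est <- build_estimator(3, 2, cfg$base_width, init_seed = 2)
  f1 <- train_estimator(est, ds, cfg)
  f2 <- train_estimator(est, ds, cfg)
  expect_identical(f1$best_val_loss, f2$best_val_loss)
  expect_identical(f1$params, f2$params)
})

test_that("inference is deterministic and validates its inputs", {
  est <- untrained_estimator()
  m <- generate_template(32, 32, 3)
  img <- forward_signal(m, c(14, 28, 42))
  p1 <- predict_t2star(est, img)
  p2 <- predict_t2star(est, img)
  expect_identical(p1, p2)
  expect_true(all(p1$t2star_ms >= 1 & p1$t2star_ms <= 500))
  expect_error(predict_t2star(est, multiecho_image(img$data[, , 1:2],
                                                   c(14, 28))),
               "echo count")
})

test_that("an all-zero slice yields an empty valid mask", {
  est <- untrained_estimator()
  img <- multiecho_image(array(0, c(16, 16, 3)), c(14, 28, 42))
  p <- predict_t2star(est, img)
  expect_false(any(p$valid))
})

test_that("slice-wise volume fitting is per-slice and order-independent", {
  est <- untrained_estimator()
  set.seed(10)
  vol <- array(runif(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  fr <- fit_volume_slicewise(est, vol, c(14, 28, 42))
  for (z in 1:4) {
    single <- predict_t2star(est, multiecho_image(vol[, , z, ], c(14, 28, 42)))
    expect_identical(fr$t2star_ms[, , z], single$t2star_ms)
  }
  perm <- c(3, 1, 4, 2)
  fr_perm <- fit_volume_slicewise(est, vol[, , perm, ], c(14, 28, 42))
  expect_identical(fr_perm$t2star_ms[, , order(perm)], fr$t2star_ms)
})

test_that("a 34-slice volume yields 34 stacked slice fits", {
  est <- untrained_estimator()
  vol <- array(runif(16 * 16 * 34 * 3), c(16, 16, 34, 3))
  fr <- fit_volume_slicewise(est, vol, c(14, 28, 42))
  expect_equal(dim(fr$t2star_ms), c(16, 16, 34))
})
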