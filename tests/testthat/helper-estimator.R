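# A reduced-scale trained estimator shared across the heavier tests.
# Training runs once per session (600 subject-disjoint slices, 20 epochs) and
# is cached; the seed is fixed so every run sees the same model.

.est_cache <- new.env(parent = emptyenv())

reduced_trained_estimator <- function() {
  if (is.null(.est_cache$est)) {
    cfg <- training_config(seed = 101L)
    .est_cache$est <- train_synthetic_estimator(cfg = cfg)
  }
  .est_cache$est
}

# held-out templates from subjects never used for training (different master
# seed, hence different subject geometry seeds)
held_out_bank <- function(n_subjects = 4L, per_subject = 25L) {
  make_template_bank(n_subjects, per_subject, 64L, 64L, seed = 90210L)
}
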