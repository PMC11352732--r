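# met2star

Quantitative T2\* mapping for multi-echo gradient-echo fMRI, with a complete
BOLD-sensitivity evaluation pipeline — built for methods researchers who want
to compare T2\* fitters and echo-combination strategies under controlled,
fully synthetic conditions.

## The problem and the methods

Multi-echo fMRI acquires several magnitude images per excitation at echo
times TE₁ < … < TE_N. Each voxel decays mono-exponentially,

    S(TE) = S0 · exp(−TE / T2*),

and the voxelwise T2\* time series carries the BOLD effect more sensitively
than any single echo. The package implements:

* **Log-linear fitting (LLF).** Per voxel, `[log S0, R2*]` is solved by the
  pseudo-inverse of the design matrix with rows `(1, −TE_n)` applied to the
  log-signals (R2\* = 1/T2\*). Exact on noiseless data; noise-amplifying in
  practice.
* **A synthetic-data-trained estimator.** A compact 4-level U-net (hand-built
  compiled convolution kernels, Adam, random 32×32 crops, batch 16,
  lr 10⁻⁴) maps a multi-echo slice directly to (M0, T2\*) maps. It is
  trained purely on procedurally generated brain-like phantoms pushed
  through the forward model with 0–5 % Rician noise, on subject-disjoint
  train/validation splits, keeping the best-validation-loss checkpoint.
* **T2\*-weighted echo combination.** Matched-filter weights
  `w_n ∝ TE_n · exp(−TE_n / T̂2*)`, normalised per voxel, with T̂2\* supplied
  by either fitter from the time-averaged series.
* **A task-fMRI simulator** (TR 2 s, TEs 14/28/42 ms, 210 volumes,
  10-volume OFF-first blocks) that injects BOLD as a task-locked ΔT2\*
  (boxcar ⊗ canonical HRF, peak-normalised), plus polynomial drift and
  Rician noise, with the full ground truth stored alongside the data.
* **Evaluation indicators.** Polynomial detrending, Gaussian smoothing,
  first-level GLM, temporal SNR, percentage signal change
  `PSC = 100 · SF · β_task / β_constant`, functional contrast (ON − OFF),
  union-FWE masks (Bonferroni, p < 0.001), masked MSE, and paired
  t-tests with Cohen's d.

See `vignettes/met2star-methods.Rmd` for the full model description,
parameter choices and limitations.

## Worked example

```r
library(met2star)

# a synthetic "subject": 64x64 slice, 3 echoes, 210 volumes, 10-volume blocks
map    <- generate_template(64, 64, subject_seed = 7)
design <- make_block_design(tr_s = 2, n_volumes = 210, block_len = 10)
act    <- ...  # small activation blob inside grey matter (see vignette)
series <- simulate_series(map, design, act, delta_t2star_ms = 3,
                          sigma_frac = 0.02, te_ms = c(14, 28, 42), seed = 1)
#> <multiecho_series> 64 x 64 x 1, 3 echoes, 210 volumes, TR 2 s (simulated)

# voxel-wise log-linear T2* time series and its BOLD indicators in the ROI
s_llf  <- fit_t2star_series(series, "llf")
metrics_report(list(s_llf), design, act, fwhm_mm = 7)
#>  series_kind mean_tsnr mean_psc mean_tvalue       fc
#>   LLF_T2STAR  6.448118 2.742293    3.257364 0.454771
```

The ROI-mean PSC of ≈ 2.7 % reflects the injected 3 ms T2\* change on a
grey-matter baseline of ≈ 70 ms (ΔT2\*/T2\* ≈ 4 %, scaled by the reference
trial's SF ≈ 0.66); tSNR ≈ 6.4 is the expected noise level of a log-linear
T2\* series at 2 % Rician noise — the trained estimator roughly quintuples it
(see the acceptance script below). A paired comparison across subjects:

```r
compare_series(c(38.1, 37.9, 38.4), c(38.7, 38.2, 38.9))
#> p_value 0.0339, cohens_d 3.055, t 5.29, df 2, mean_diff 0.467
```

Training a reduced-scale estimator and fitting with it:

```r
est  <- train_synthetic_estimator(cfg = training_config(seed = 101))
s_dl <- fit_t2star_series(series, "sddl", est)
```

A thin command-line front end over the same functions is installed at
`inst/cli/met2star.R` (subcommands `make-templates`, `simulate`, `train`,
`fit`, `combine`, `evaluate`, `report`).

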