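---
title: "T2* mapping for multi-echo fMRI: models, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{T2* mapping for multi-echo fMRI: models, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-echo gradient-echo fMRI acquires several magnitude images per
excitation at increasing echo times TE. Each voxel's signal follows, to a
good approximation, the mono-exponential decay

S(TE) = S0 · exp(−TE / T2*),

where S0 is a proton-density-weighted amplitude and T2* the effective
transverse relaxation time. Because neuronal activity changes local T2*
(the BOLD effect), a voxelwise T2* *time series* is a quantitative carrier of
functional contrast — more sensitive than any single echo or weighted echo
combination, but also noisier, because fitting two parameters from three
echoes amplifies acquisition noise.

`met2star` implements and compares two fitters for this problem:

* **LLF (log-linear fit)** — the standard baseline. Per voxel, regress
  log S on (1, −TE) through the pseudo-inverse of the design matrix; the
  slope is R2* = 1/T2*. Exact on noiseless data, noise-amplifying on real
  data.
* **A synthetic-data-trained convolutional estimator** — a 4-level U-net
  that maps a full multi-echo *slice* to (M0, T2*) maps. It is trained
  exclusively on procedurally generated parametric phantoms pushed through
  the same forward model, with Rician noise injected, so it learns both the
  inverse mapping and a spatial denoising prior. No real data are required
  for training.

Around the fitters sits a complete evaluation pipeline: T2*-weighted echo
combination, a block-design task simulator with known ground truth, and the
BOLD-sensitivity indicators (MSE, tSNR, PSC, mean t-value, functional
contrast, union-FWE masks, paired effect sizes).

## Signal model and noise

`forward_signal()` evaluates the decay model exactly; background voxels are
zero in all channels. `add_rician_noise()` replaces each magnitude value S by
|(S + g1) + i·g2| with g1, g2 ~ N(0, σ²). The literature often quotes noise
as a percentage without a referent; here σ = `sigma_frac` × (maximum
noiseless first-echo amplitude of the slice). The first echo carries the
largest signal, which makes `sigma_frac` a stable per-slice SNR knob; during
training-set synthesis `sigma_frac` is drawn uniformly from 0–5 % per sample.

`loglinear_fit()` details that matter on real (noisy, magnitude) data:

* Signals at or below a floor (10⁻⁶ × image maximum) are replaced by the
  floor before the log and the voxel is marked invalid — noise routinely
  drives background magnitudes to ~0 and the log must stay defined.
* Fitted T2* is clipped to [1, 500] ms. The lower bound guards the 1/R2*
  blow-up; 500 ms leaves headroom above CSF rather than censoring it.
* Negative fitted R2* (rising signal, typical in pure-noise voxels) clips to
  the upper bound and is flagged invalid rather than raising an error.
* The pseudo-inverse is computed once per TE set and reused for every voxel.

`echo_combination_weights()` implements the T2*-weighted (matched-filter)
combination w_n ∝ TE_n · exp(−TE_n/T̂2*), normalised to sum to 1 per voxel.
The practical difference between the two "EC" series in the pipeline is only
where T̂2* comes from: the LLF or the estimator fit of the time-averaged
series; the weights are static over time in both cases.

## The phantom generator

Training needs (M0, T2*) templates with brain-like structure. The generator
draws, per synthetic subject, an elliptical head outline with randomised
geometry containing four nested tissue classes with smooth within-class
variation:

| class | T2* range (ms) | M0 (relative) |
|---|---|---|
| WM-like core | 45–60 | 0.70 |
| GM-like band | 60–80 | 0.85 |
| CSF-like rim + ventricles | 150–250, clipped to 200 | 1.00 |
| vessel-like blobs | 15–35 | 0.55 |

The ranges are standard 3 T literature values. CSF is clipped to 200 ms so
every training target lies within the T2*/200 label normalisation (and the
customary 0–200 ms display range). Background is exactly zero in both
channels so the network can learn masking. What the phantoms deliberately do
**not** model: real anatomy (no atlas registration), 3D structure, B0/B1
inhomogeneity, partial-volume mixtures at interfaces beyond
nearest-neighbour borders. Passing tests therefore demonstrate correct
methodology and noise robustness *under the stated forward model*, not
performance on any particular scanner's data.

"Different subjects" are realised as independent top-level seeds controlling
geometry and tissue layout; augmentations (right-angle rotations, flips, and
occasional small-angle nearest-neighbour rotations, which avoid creating
non-physical interpolated T2* values at tissue borders) inherit the base
map's `subject_id`, so train/validation splits are subject-disjoint by
construction.

## The estimator and its training

`build_estimator()` constructs an encoder–decoder with 4 resolution levels
(3 max-poolings), two 3×3 convolution + ReLU layers per level, skip
connections at every level, and a linear 1×1 output head. "4-level" is read
as 4 resolution scales; channel width doubles per level from `base_width`.
The default `base_width = 8` (≈ 122 k parameters) is deliberately compact:
the slice-to-map problem is mostly voxelwise with a local spatial prior, and
a compact model trains to convergence quickly on one CPU. The convolution
kernels are compiled (im2col + GEMM through RcppArmadillo); everything else,
including the Adam optimiser, is vectorised R.

Fixed training hyperparameters: batch size 16, random 32×32 crops, Adam at
learning rate 10⁻⁴, MSE loss on the two normalised output channels jointly
(MSE because the evaluation metric is MSE; M0 is kept as a second target for
regularisation even though only T2* is consumed downstream). Normalisation:
inputs are divided by the slice's first-echo maximum (self-computable at
inference); T2* labels by 200 ms; M0 labels by their slice maximum. One
epoch draws 8 random crops per training slice — patch oversampling, giving
each epoch twice the pixel coverage of a full pass, which the reduced epoch
budget needs to approach convergence. No scheduler, no weight decay; the
returned weights are the best-validation-loss checkpoint, so a generous
epoch budget cannot hurt.

The reduced study condition used throughout the tests and the acceptance
script is: 6 synthetic subjects × 100 slices (500 train / 100 validation,
subject-disjoint), 20 epochs, noise U(0, 5 %). On one CPU this trains in
about 10 minutes. A full-scale run would use the 5400-sample bank
(6 × 900, split 4500/900) and ~100 epochs; the module scale is configurable
and nothing in the code depends on the reduced sizes.

Inference normalises the input slice, runs the full 64×64 slice through the
network (valid because it is fully convolutional; no cropping at inference),
de-normalises, and clips T2* to [1, 500] ms. The `valid` mask marks tissue
voxels (first-echo signal above 1 % of the slice maximum) whose raw
prediction already lay in bounds. Volumes are fitted slice-by-slice with no
inter-slice coupling.

## The task simulator

`simulate_series()` produces 5D (x, y, slice, echo, time) series with the
acquisition geometry of a typical 3 T multi-echo EPI protocol (TR 2 s,
TEs 14/28/42 ms, 64×64 matrix, 210 volumes, 10-volume OFF-first blocks) and
full ground truth:

* **BOLD as ΔT2*.** Inside the activation mask,
  T2*(t) = baseline + Δ · h(t), where h is the ON/OFF boxcar convolved with
  the canonical double-gamma HRF and normalised to peak 1. The default
  Δ = 3 ms (≈ 4 % of a grey-matter baseline) is a literature-informed
  magnitude for robust task activation, not a measured value. Injecting the
  effect additively in T2* (rather than multiplicatively in R2*) matches how
  the sensitivity analysis frames the effect; at 3 ms the two
  parameterisations differ negligibly.
* **Drift** is a global multiplicative polynomial 1 + a·u + b·u²
  (u = normalised volume index), motivated by the linear-and-quadratic
  detrending step in the analysis; defaults in the benchmarks are
  a = 1 %, b = −0.5 %.
* **Noise** is per-volume independent Rician noise at the slice-referenced σ
  above. Motion and physiological fluctuations are *not* simulated — the
  pipeline consumes realigned data by contract, and the GLM accepts an
  arbitrary nuisance matrix where physiological regressors would enter.

With σ = 0 and no drift the simulator is exactly invertible: the LLF time
series inside the mask equals baseline + Δ·h(t) to numerical precision, and
the GLM recovers the activation mask as the support of the task beta. That
round trip anchors the test suite.

## The analysis pipeline

The first-level chain mirrors standard practice: polynomial detrending
(constant + linear + quadratic, temporal mean restored), optional Gaussian
smoothing (σ_vox = FWHM / (voxel · √(8 ln 2)), normalised separable kernel,
reflective boundaries — constants are preserved exactly), then a voxelwise
OLS GLM with design [HRF-convolved task | nuisance | constant]. Numerical
choices:

* The task regressor is evaluated on a 16× super-sampled grid, normalised to
  peak 1, and sampled at volume onsets; the same curve defines the PSC
  scaling factor SF (maximum of a single reference trial in the same
  normalisation), so a fitted task beta is directly in the units of the
  injected effect.
* Zero-residual fits report a capped sentinel t = ±10⁶ so maps stay finite.
* tSNR = fitted temporal baseline / trend-residual SD. The numerator is the
  constant term of the per-voxel constant+linear+quadratic fit on 0-based
  time (for trend-free data this estimates the temporal mean), so adding a
  pure linear or quadratic trend changes the tSNR by exactly nothing, not
  just approximately. Zero-SD voxels are set to 0 and flagged.
* PSC = 100 · SF · β_task / β_constant; zero constant betas are flagged and
  set to 0.
* Functional contrast uses the *unconvolved* ON/OFF labels (no
  hemodynamic-lag shift of the labels; with 10-volume blocks the lag
  affects 1 of 10 volumes per block edge and partially cancels between ON
  and OFF means — a known approximation, flagged here).
* The union-FWE mask uses Bonferroni correction over in-mask voxels.
  Random-field-theory FWE is the common alternative; Bonferroni was chosen
  because it is exactly implementable, conservative, and easy to audit.
  α defaults to 0.001.
* Paired comparisons: two-tailed paired t-test and Cohen's d =
  mean(diff)/SD(diff) with the n−1 sample SD.

## Design choices that were genuinely open

* **No deep-learning framework is used.** The estimator's compute core is
  ~150 lines of compiled im2col/GEMM convolution plus an R training loop.
  This keeps the package self-contained, deterministic and auditable, at the
  cost of GPU support — acceptable because the model is small by design.
* **Loss and output channels.** The training loss is unweighted MSE over
  both (M0, T2*) channels; evaluation uses only T2*.
* **Epoch budget.** The checkpoint rule makes the epoch count a compute
  budget rather than a tuning parameter; 20 epochs is the reduced CPU
  condition documented above.
* **Rician σ referent** (per-slice first-echo maximum) and the **floor
  policy** for non-positive signals in the LLF are this package's choices;
  neither is standardised in the field.
* **MEICA** denoising is reachable only through an external-command hook
  (`meica_hook()`), which stages echo NIfTIs, runs the tool, and ingests its
  output with full provenance; when the executable is absent the hook
  reports itself disabled and the four internal series carry the analysis.

## Problem sizes used by the tests and the acceptance script

Training: 600 slices / 20 epochs (≈ 10 min, one CPU). Noise benchmark:
100 held-out slices from 4 unseen subjects × 5 noise levels. Task
experiments: 10 simulated subjects × 210 volumes × 64×64 × 3 echoes each for
activation recovery and for the sensitivity orderings. Null calibration:
10–15 white-noise runs of 3 000 voxels × 120 volumes. These sizes are the
package's reduced study conditions; all of them are arguments, not
constants.

## Known limitations

* Trained models are TE-set specific: one model per echo-time list, matching
  the synthesis-for-acquisition workflow; echo count is checked at inference.
* The phantom prior transfers to real data only to the extent that real
  slices resemble smooth nested tissue classes; no claim is made about
  pathology, susceptibility dropout, or field inhomogeneity.
* The estimator's M0 output is de-normalised by the input's first-echo
  maximum, an amplitude convention adequate for weighting and masking but
  not a calibrated proton-density estimate.
* Functional-contrast lag handling and the exact FWE procedure are
  documented conventions (see above), not uniquely determined by the
  field's practice.
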