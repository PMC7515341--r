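---
title: "Multi-band time-frequency spectrum entropy of short-time HRV: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-band time-frequency spectrum entropy of short-time HRV: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfse)
```

## The problem

Obstructive sleep apnea (OSA) perturbs autonomic balance: repetitive airway
obstructions during sleep drive sympathetic surges and vagal withdrawal, and
both leave a signature in heart-rate variability (HRV) — the beat-to-beat
fluctuation of RR intervals. `mtfse` implements a screening feature set that
summarises a single 5-minute RR segment by the *two-dimensional* texture of
its time-frequency power spectrum, rather than by band powers or
one-dimensional entropies alone. The intended use is per-segment screening:
a segment from a patient record that contains at least one apnea-annotated
minute (A-OSA), a non-apneic segment from a patient (A-N), or a segment
from a healthy control (C-N).

## Pipeline and model

1. **Artifact removal.** Automatic beat detection leaves spurious intervals.
   Any RR value deviating from the running median of its 5-beat window by
   more than 20% of that median is replaced by the median (both parameters
   configurable). This is the standard ectopic-beat rejection rule; it
   preserves series length and is idempotent on clean series.

2. **Segmentation and labeling.** Records are tiled into consecutive,
   non-overlapping 5-minute windows aligned to minute boundaries (windows
   are half-open `[300w, 300(w+1))`; minute *m* covers `[60m, 60(m+1))`).
   A patient-record window with ≥ 1 apnea minute is A-OSA, with none A-N;
   control windows with apnea minutes are discarded, the rest are C-N. The
   per-minute annotation granularity is what motivates minute-aligned,
   non-overlapping tiling; overlapping schemes would make the per-group
   segment counts ambiguous.

3. **Resampling.** The RR series is irregularly sampled (one value per
   beat). A cubic spline through (beat time, RR) — each interval attached
   to the beat that ends it, a common tachogram convention — is evaluated
   on a uniform 4 Hz grid, giving 1200 samples per segment. 4 Hz is the
   conventional HRV resampling rate: it is comfortably above twice the
   0.4 Hz band edge.

4. **AR spectrum.** Each sliding window of the tachogram is mean-removed
   and fitted with an autoregressive model
   `x(t) = -Σ a_k x(t-k) + u(t)` by the Burg lattice algorithm, which
   minimises summed forward and backward prediction error directly on the
   samples — the reason it is preferred over autocorrelation-based
   Yule–Walker solutions for short segments. The parametric spectrum is
   `S(f) = δ² / |1 + Σ a_k e^(-i2πfk/fs)|²`. Order 16 is the standard
   choice at 4 Hz and the package default.

5. **Time-frequency spectrum image (TFSI).** Window length 64 s, hop 4 s:
   64 s at 4 Hz gives 256 samples per window, far above the `2p` minimum
   for a stable AR(16) fit, while retaining roughly 0.016 Hz of effective
   VLF resolution; the 4 s hop yields 60 rows of temporal texture for a
   300 s segment. The spectra are evaluated on 256 uniform grid points
   over 0–0.4 Hz. No windowing/overlap convention is canonical for this
   construction, so all three values are explicit configuration with these
   defaults, and they are echoed into every output artifact.

6. **Band split.** The image is cut at 0.04 and 0.15 Hz into VLF
   (0–0.04 Hz), LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) sub-images.
   Membership is half-open with 0.4 Hz assigned to HF, so every frequency
   column belongs to exactly one band and the three sub-images partition
   the total image.

7. **Entropy indices.** Pixel intensities are quantized into K = 256
   equal-width bins spanning the *total* image's range — the range is
   shared by all sub-images so that their entropies are commensurable —
   and the Shannon entropy `-Σ p_k log10 p_k` is taken over each
   (sub-)image's bin-occupancy distribution. Eight indices result:
   `ShEnVLF, ShEnLF, ShEnHF, ShEnTotal`, the ratios
   `ShEnpVLF/pLF/pHF = ShEn_band / ShEnTotal`, and
   `ShEnLFHF = ShEnLF / ShEnHF`. With per-image linear quantization the
   indices are exactly invariant under positive rescaling of the image, so
   the PSD scaling convention cannot affect them.

### Quantizer choice

The discretization underlying the entropy (bin count, range convention,
logarithm base) is genuinely open: published index magnitudes do not pin it
down (their reported totals exceed `log10(256)`, so no (K, base) pair in
this family reproduces them numerically). We fix K = 256 / base 10 /
shared-range linear binning as documented defaults and treat absolute index
values as instrument-specific: all statements the package tests are
*relative* (group orderings, ratios, separability), which are insensitive
to (K, base) over the ranges we examined.

### Degenerate inputs

A constant (sub-)image has entropy exactly 0. If `ShEnTotal` or `ShEnHF`
is 0, the dependent ratios are reported as missing (`NA`) rather than
propagating a division: degenerate segments must be visible. Downstream,
rows with missing indices are excluded from t-tests and classification and
the exclusion count is carried in the report.

## The synthetic generator

`generate_rr()` emulates what the pipeline needs to be exercised end to
end, without claiming physiological fidelity:

- a target tachogram `r(t) = mean_rr + Σ amp·sin(2πft + φ)` with
  components placed in the canonical bands;
- an optional apnea-like cosine amplitude modulation (period 25–60 s —
  the typical apnea cycle length — depth up to 1) whose troughs define the
  apnea-annotated minutes, giving the segmentation rule real work;
- integrate-to-threshold beat emission (the next beat falls one current
  RR interval after the last), so beat times are irregular and the spline
  resampling path is exercised nontrivially;
- white per-beat jitter and ectopic-like doubled intervals at a
  configurable rate, giving the median filter real work.

The study presets are fixed once:

| preset | mean RR | LF (0.095 Hz) | HF (0.24 Hz) | apnea cycle | jitter | artifacts |
|---|---|---|---|---|---|---|
| apnea-like | 800 ms | 50 ms | 15 ms | 45 s, depth 0.3 | 20 ms | 0.5% |
| normal-like | 850 ms | 20 ms | 45 ms | none | 20 ms | 0.2% |

These encode the physiological contrast the indices target: sympathetic
dominance (LF up, HF down, slow cyclic modulation) versus vagal dominance
during normal sleep. The `lf-dominant`/`hf-dominant` presets used for
separability checks put a 50 ms component in one band and a deliberate
weak 12 ms component in the other: a literally pure tone would leave the
suppressed band's sub-image constant at the noise floor, entropy exactly 0,
making the ratio indices undefined — defined-but-extreme contrast is the
useful test condition.

What the generator does **not** emulate: real QRS detection error
structure, respiration-cardiac coupling, non-stationary sleep-stage
transitions, or inter-subject variability. Passing tests on synthetic
cohorts therefore demonstrate that the implementation computes the method
faithfully and that the indices separate the spectral contrast they were
designed for — not that the published clinical accuracies transfer.

## Evaluation protocol

- **Screening statistics:** Welch's unequal-variance two-sided t-test per
  index per group pair (group SDs differ, so the pooled-variance test is
  not safe), with means ± SD and 0.05/0.01/0.001 stars.
- **Classification:** per repetition, `n_per_group` segments are drawn
  from each group without replacement, then stratified 10-fold
  cross-validation is run with the chosen adapter at its ecosystem
  defaults (`class::knn` k = 1; `e1071::svm` C-classification, RBF,
  cost 1; `rpart` defaults), fold confusions pooled, and
  accuracy/sensitivity/specificity computed; means over repetitions are
  reported. Folding is over segments (an optional caveat: segments of one
  subject can appear in train and test; subject-grouped folding is the
  conservative alternative and the reported numbers should be read as
  per-segment performance). Resampling happens outside the fold loop: one
  subsample per repetition, folded once.
- **Multi-group tasks** report per-class one-vs-rest Acc/Sen/Spe, their
  macro mean, and the row-normalised classification-rate table (rows sum
  to 100%).
- **Chance-level control:** permuted-label accuracy is averaged over
  several independent permutations. A single fixed permutation of strongly
  clustered samples retains a few percent of accidental cluster–label
  overlap (SD ≈ 3.5% at 2 × 100 segments), which any cluster-majority
  classifier picks up; that is a property of the permutation draw, not
  information leakage, and averaging removes it.

## Numerical choices

- Burg recursion: the innovation variance is the final forward/backward
  prediction-error power, `E_p = E_0 Π (1 - k_m²)`; coefficients follow
  the `x(t) = -Σ a_k x(t-k) + u(t)` sign convention throughout (so an
  AR(1) process with autoregression 0.5 yields `a₁ ≈ -0.5`).
- Constant windows (zero variance) are rejected as degenerate rather than
  fitted; `build_tfsi` names the offending window.
- Quantization maps a pixel to bin `⌊(v - min)/(max - min)·K⌋ + 1`,
  clamping the range maximum into the top bin; a zero-width range puts all
  pixels in bin 1 (entropy 0).
- Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; cohort members use `seed + 10000·group + index`, so
  any member is individually reproducible.

## Problem sizes

The bundled tests and the acceptance script run on cohorts of up to 100
segments per group with 20 cross-validation repetitions — sizes chosen so
the full suite re-runs in well under a minute of compute per check while
leaving the group-separation statistics overwhelming (Welch p-values below
1e-40 at these effect sizes). The protocol constants for a full-data run
(300 segments per group, 500 repetitions) remain the configuration
defaults in `mtfse_config()`.

## Known limitations

- Absolute entropy magnitudes depend on the quantizer; only relative
  statements are validated.
- The bundled beat detector is a simple amplitude threshold for clean
  traces; clinical ECG needs a validated QRS detector plugged into
  `rr_from_ecg()`.
- Per-segment cross-validation can leak subject identity between folds on
  real multi-segment records.
- The WFDB reader covers header + signal formats 16/212 and the
  minute-wise apnea annotation convention only.
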