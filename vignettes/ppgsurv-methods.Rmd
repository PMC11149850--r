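---
title: "Deep survival modelling of pulse waveforms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep survival modelling of pulse waveforms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ppgsurv)
```

## The problem

Ten-year cardiovascular risk scores in wide use (WHO/ISH-style charts,
Globorisk) need blood-pressure cuffs, scales or laboratory assays. A
photoplethysmography (PPG) pulse waveform, by contrast, can be captured by a
pulse oximeter or a phone camera. `ppgsurv` implements a two-stage method
that turns a single device-summarized pulse — 100 amplitude samples spanning
one beat, plus the pulse rate — into a ten-year risk of major adverse
cardiovascular events (MACE), and the full statistical apparatus needed to
compare such a score against conventional ones.

Because the cohorts such models are built on are access-restricted, the
package ships a synthetic-cohort generator that reproduces the *structure*
of that setting (ages 40–74, ~3% ten-year event rate, site-based geographic
splits, single-beat waveforms whose shape carries vascular information), so
every stage of the pipeline can be exercised, tested and audited end to end
without restricted data.

## The model

**Stage 1 — waveform feature extractor.** The 100-sample pulse is placed
back on a physical time axis (linear interpolation onto an 18.2 ms grid, so
slower pulses give longer series), min–max normalized, and zero-padded into
rectangular batches. A compact one-dimensional residual network (ResNet18
topology: a 7-tap stem, four stages of two residual blocks, stride-2
downsampling between stages, masked global average pooling) maps each
variable-length waveform to an embedding and a scalar risk score. It is
trained by minimizing the negative Cox partial log-likelihood of the risk
score within each minibatch,

$$\ell = -\frac{1}{D}\sum_{i:\,\delta_i=1}\Big[r_i -
\log\!\!\sum_{j:\,t_j \ge t_i}\!\! e^{r_j}\Big],$$

with Breslow handling of tied event times. The checkpoint with the best
tune-split partial likelihood is kept. Train-split embeddings are reduced by
PCA to five features (`ppg1`–`ppg5`).

**Stage 2 — survival model.** A ridge-penalized Cox proportional-hazards
model is fitted over a registry of feature sets: demographic metadata (age,
sex, smoking), office and laboratory refits of the WHO-style predictors,
engineered pulse-morphology features, and the deep score family
(`dls` = metadata + `ppg1..5` + PPG heart rate; `dls_plus` adds BMI;
`dls_plus_plus` adds BMI and systolic blood pressure). Numeric features are
standardized with train-split statistics; the deep-feature models carry
age-interaction terms for every non-age predictor, and hazard ratios for
interacting terms are reported at a stated age (by default the median event
age). The penalty maximizes
$\log PL(\beta) - \tfrac{\lambda}{2}\lVert\beta\rVert^2$ by Newton–Raphson
(convergence when the largest gradient component is below $10^{-7}$), with
$\lambda$ chosen on the tune split. Absolute risk comes from the Breslow
baseline cumulative hazard: $p_{10} = 1 - \exp(-H_0(10\,\text{y})\,e^{lp})$.

**Evaluation.** Harrell's C; a paired permutation test for non-inferiority
(margin 2.5 C percentage points) and superiority; category-free and
threshold NRI with event/nonevent components; sensitivity/specificity with
Clopper–Pearson intervals after excluding subjects censored before ten
years; decile calibration (observed event rate regressed on predicted risk
by ordinary least squares); percentile bootstrap intervals; Kaplan–Meier
curves and the log-rank test; operating points matched to the SBP-140 rule
(systolic pressure strictly above 140 mmHg) or fixed at 10% predicted risk.

**Interpretability.** Integrated gradients of the Cox log partial hazard
with respect to the waveform, along the straight path from an all-zeros
baseline with metadata held fixed; the completeness residual
$\sum_i IG_i - (F(x)-F(0))$ is always reported. Quantile-averaged waveforms
(mean of the 100 waves nearest the 10th/50th/90th percentile of a feature)
and Spearman correlation tables against the engineered morphology features
connect the learned features to pulse landmarks.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| grid step | 18.2 ms | device-equivalent uniform time base |
| sample-spacing divisor | 99 | the 100 samples are taken to include both pulse endpoints (period/99 spacing); the endpoint convention is not documented for the source device, so it is a config switch |
| network width | 8→64 channels | the inputs are 30–120 steps of one channel; this width saturates the synthetic signal and trains in ~3 minutes on one CPU. The conventional 64→512 width is configurable but far past saturation here |
| batch size | 256 | risk sets are formed within minibatches; at a ~3% event rate a batch this size carries ~8 events, enough for a usable gradient |
| epochs / learning rate | 8 / 2e-3 | Adam; the tune-split checkpoint rule makes extra epochs harmless but wasteful |
| augmentation σ | 0.05 | Brownian tape-speed volatility per step; 0 disables |
| ridge grid | 0.01–100 | tune-split likelihood selects; ties break to the larger penalty |
| non-inferiority margin | 2.5 pp | pre-specified comparison margin on the C scale |
| permutations / bootstrap | 500–1000 / 200–1000 | inference resolution vs run time |

## The augmentation

The tape-speed augmentation resamples each training waveform at warped
times: a latent log tape speed follows a Brownian random walk with per-step
standard deviation σ, warped times are the cumulative sum of its
exponential, rescaled to pin both endpoints. The warp is strictly monotone,
so landmark order is preserved, and σ = 0 is the exact identity. The precise
construction used with the original cohort is not public; this definition
is the package's own, kept behind a single `augment` interface so an
alternative can be swapped in. It is applied only during extractor
training, never at embedding time.

## What the synthetic cohort emulates — and what it does not

One latent vascular-stiffness factor $s = 0.05\,(\text{age}-57) +
\varepsilon$, $\varepsilon \sim N(0, 0.75^2)$, drives *both* the waveform
morphology (shorter reflected-wave delay, larger reflection index,
shallower dicrotic notch as $s$ rises) *and* the hazard (log-hazard 0.60
per SD of $s$, alongside 0.55 per SD age, 0.35 male, 0.45 smoking). This is
the minimal structure under which the waveform carries risk information
beyond metadata — the mechanism-level claim the method rests on. The
exponential baseline rate is calibrated numerically so the marginal
ten-year event probability hits 3%; censoring is administrative at 12 years
plus a 30% uniform early-censoring fraction. Fifteen named sites in three
regions give the geographic train/tune/test split (weights 50/22/28;
the default pipeline uses 60/20/20 so a 10,000-subject cohort yields about
6,000/2,000/2,000).

Waveforms are two skewless Gaussian bumps (direct and reflected), a
Gaussian notch dip between them, a small diastolic tail bump, and additive
Gaussian noise, rendered onto the 100-sample device grid. Real PPG has
skewed systolic upstrokes, baseline wander, device filtering and motion
artifacts — none of which are modelled. Passing tests therefore demonstrate
that the pipeline recovers morphology-encoded risk signal under clean
conditions; they say nothing about robustness to real-device noise, and
the reported C-statistics are properties of the simulator, not of any real
cohort. Columns the generator knows to be hidden truth (`_latent_*`) are
physically present for auditing but refused by the model feature resolver,
which prevents accidental leakage in tests.

## Numerical and design choices

- **Endpoint convention.** The 100 device samples are assumed to span
  exactly one period with spacing period/99; configurable (`spacing_divisor`).
- **Notch detection.** The dicrotic notch is the *first* local minimum
  after the systolic peak on a 3-point-smoothed copy of the wave. A
  "deepest minimum" rule is tempting but wrong on decaying pulses: the
  end-diastolic trough is almost always deeper than the notch. A
  positive-curvature fallback handles notchless (stiff-vessel) morphologies
  and flags them lower-confidence; the peak search window (first 60% of the
  pulse) avoids capturing the reflected peak.
- **Masked computation.** Padded positions are exactly zero after every
  network operation and excluded from normalization statistics and pooling,
  which makes embeddings provably invariant to the amount of padding (a
  tested contract, not an aspiration).
- **Ties.** Breslow everywhere (loss, ridge fit, baseline hazard); score
  ties in C count 1/2; tied tune likelihoods break toward the larger ridge
  penalty; threshold matching takes the largest threshold meeting a
  sensitivity target and the smallest meeting a specificity target.
- **Ten-year labels.** Events before the horizon are 1, follow-up past the
  horizon is 0, censoring before the horizon is excluded. The same rule
  feeds sensitivity/specificity, NRI and calibration, one consistent
  censoring treatment throughout.
- **Permutation scheme.** The non-inferiority null exchanges the two
  scores within each subject with probability 1/2; non-inferiority uses the
  shift construction (permuted deltas compared against the observed delta
  plus the margin). Both p-values use the add-one convention, which keeps
  the test exact-level at finite permutation counts.
- **Degenerate inputs.** Flat waveforms are rejected with a logged reason;
  constant design columns are dropped from a fit rather than failing it;
  empty calibration bins merge with their neighbor; degenerate bootstrap
  resamples are redrawn and counted.
- **Determinism.** One run seed fans out to per-stage substreams
  (simulation, extractor, evaluation); all randomness goes through R's RNG,
  so a rerun with the same configuration reproduces every number.

## Problem sizes

The default pipeline simulates 10,000 subjects (≈6,000/2,000/2,000 after
the site split), trains the extractor for 8 epochs at batch 256 (~3 minutes
on one CPU), and evaluates with 500 permutations and 200 bootstrap
iterations; the whole run takes about 4–5 minutes. The test suite uses the
same default run once, plus smaller simulations (500–20,000 subjects) for
the statistical validity checks: permutation and log-rank type-I error over
500–1,000 null replicates, Clopper–Pearson coverage over 2,000 draws, and
parameter recovery at n = 10,000.

## Known limitations

- The extractor is trained on one summarized beat per subject; beat-to-beat
  variability, raw PPG streams and beat segmentation are out of scope.
- The simulator's event model is a single-factor proportional-hazards
  construction; it cannot probe non-proportionality, competing risks, or
  morphology patterns beyond its one latent axis.
- Ridge Cox fits use a dense Newton solver, comfortable to ~10^5 subjects
  and tens of terms, not built for high-dimensional feature sets.
- The permutation and bootstrap schemes assume exchangeable subjects;
  clustered or family data would need block variants.

## Reproducing a run

```{r}
run <- run_pipeline(run_config(seed = 1), verbose = TRUE)
run$metrics$dls$c_statistic
compare_models(run, "dls", "office_refit_who")
leakage_report(run)
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` performs the
same computation from a clean start and writes the headline quantities as
JSON.
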