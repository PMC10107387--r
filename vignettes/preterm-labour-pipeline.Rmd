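---
title: "Threshold-decomposition learning for preterm-labour signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-decomposition learning for preterm-labour signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretermlsdl)
```

## The problem

Active labour produces three physiological time series that plausibly carry
information about whether a delivery will be preterm (32–36 weeks) or term
(38–40 weeks): the electrohysterogram (EHG), whose contraction bursts appear
as amplitude events in an envelope exported at one sample per 2-second
epoch, and the maternal and foetal beat-to-beat RR interval series in
milliseconds. This package implements the full prediction pipeline over
those signals: windowing, an amplitude-band decomposition learner, a
20-feature ensemble, class balancing, supervised model comparison and
unsupervised cluster evaluation. Clinical recordings of this kind are not
publicly deposited, so the package also owns a synthetic-cohort generator
that reproduces the statistical structure the analysis assumes; everything
downstream is exercised against it.

## Pipeline and model

1. **Preprocessing.** `epoch_average()` reduces a raw recording to the mean
   absolute amplitude per non-overlapping 2-s epoch (the export convention
   of the acquisition software; the mean of |x| was chosen over RMS for
   simplicity and is the definition tested). `select_records()` drops
   too-short files. `window_records()` cuts each record into 10 equal
   disjoint windows; the trailing remainder is discarded so windows have
   identical length — equal length is the contract, and tail-drop is the
   simplest rule that satisfies it.
2. **LSDL.** `lsdl_fit()` evaluates eight dyadic amplitude bands (lower
   thresholds A/2, 3A/4, 7A/8, 15A/16; upper thresholds A/2, A/4, A/8,
   A/16, with A the maximum absolute training amplitude) by decomposing
   every window, extracting features and scoring the class separability
   J = ED(p, q)/σ\_m. The dyadic two-region grid gives exactly four
   iterations per region and reproduces the qualitative behaviour expected
   of the method on these signals: envelope cohorts select mid-amplitude
   lower bands, while RR series — whose samples all sit near the mean, far
   above A/2 — only admit upper-region candidates, the lower bands being
   reported as invalid (`n/a`). The decomposition operator sits behind
   `lsdl_decompose()` so an alternative banding scheme can be swapped in.
3. **Features, balancing, models.** `featurize()` produces the 20-feature
   table per window; `smote_balance()` oversamples the minority class to
   parity; `run_model_suite()` compares eight classifiers on raw and
   decomposed arms; `kmeans_partition()`/`gmm_partition()` +
   `evaluate_clusters()` cover the unsupervised exercise;
   `run_experiment()` orchestrates everything from one config and master
   seed.

## Interpretation of the separability cost

σ in the cost is read as the per-feature population SD across the pooled
windows of both classes (divisor N), and σ\_m as the mean of those SDs. The
alternative reading — an SD across the components of one feature vector —
mixes units of incommensurable features and is rejected. Two consequences
are tested as invariants: J is invariant under a common positive rescaling
of all features (so features enter the cost raw, unstandardised), and J = 0
exactly when the class mean vectors coincide. A worked-value caveat: given
class means (0,0) and (3,4), J = 5/σ\_m by definition; a pooled σ\_m of
exactly 1 cannot coexist with that mean separation (the pooled SD contains
the between-class spread), so the suite checks the ratio identity and a
brute-force oracle rather than a fabricated instance.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `epoch_s` | 2 | s | export convention of the envelope |
| `n_windows` | 10 | — | disjoint equal slices per record |
| `eps_threshold` | 1 (EHG), 0 (RR) | µV | amplitude gate for ZC/SSC/NP; a microvolt gate is meaningless for RR series in ms, so it resolves per signal kind |
| `sampen_m`, `sampen_r` | 2, 0.2·SD | — | template length below 1 degenerates the statistic, so the standard m = 2 is used; r scales with the window SD |
| `ar_order`, `ceps_order` | 4, 4 | — | fourth-order autoregression; cepstra follow from the AR coefficients by the standard recursion |
| `max_iterations` | 4 | — | four dyadic iterations per region |
| `min_keep` | 16 | samples | a decomposed window shorter than this cannot support the feature set; the candidate is recorded invalid |
| `k_neighbors` | 5 | — | SMOTE neighbourhood |
| `k_folds` | 10 | — | stratified cross-validation |
| `reg` | 0.1 | — | added to each GMM covariance diagonal at every M-step |
| `restarts` | 5 | — | clustering repetitions; the best is kept |
| `ar1_coeff` | 0.6 | — | lag-1 correlation of synthetic RR series; a moderate value typical of short-range heart-rate correlation |

Spectral features use a raw periodogram of the demeaned, Hann-windowed
window with the DC bin excluded; the estimator is deliberately simple and
is pinned by an O(N²) DFT oracle in the tests. AR coefficients are
estimated by Burg's method (stable on short windows), cross-checked against
an independent hand-written Burg recursion.

## What the generator emulates — and what it does not

`generate_ehg()` builds a non-negative envelope: rectified Gaussian noise
plus Gaussian-windowed contraction bursts with Poisson counts (≥ 4 per
10 min, the active-labour criterion; preterm rate and burst gain larger by
default). `generate_rr()` draws a stationary AR(1) series around the class
mean with the innovation variance scaled so the stationary SD matches the
configured class SD (term 431.2 ± 31.0 ms, preterm 413.2 ± 26.9 ms);
foetal series take their mean from the midpoint of the 110–170 bpm
baseline (60000/bpm ms) and inherit the maternal standardised mean
difference, since no foetal class moments are available to calibrate
against. RR intervals are clipped positive. A raw-scale EHG mode (900 Hz
oscillatory carrier under the same burst envelope) exists solely to
exercise `epoch_average()`; the analysis consumes the exported envelope,
so the generator's default is the envelope scale.

Three presets define the study conditions used throughout the tests:

- `amplitude` (default): class effect in burst rate (4 vs 6 per 10 min) and
  burst peak gain.
- `mid_band`: the class effect lives **only** in mid-amplitude contraction
  bursts (rates 4 vs 7 per 10 min, gains 1 vs 1.5 on a 12 µV base), while
  saturation artefacts — stretches where the envelope rails at a fixed
  60 µV amplifier ceiling, at the same rate of 6 per 10 min in both
  classes — occupy the top of the amplitude range. Saturation was chosen
  deliberately: a railed artefact occupies a single amplitude A disjoint
  from the burst band, so a lower-region rule excises it exactly, whereas
  peaked artefact shapes leak flank samples into every amplitude band and
  make band excision a poor denoiser. This is the scenario in which a
  band-selection method is the *right* tool, and it is the configuration
  under which the decomposition arm demonstrably dominates the raw arm.
- `null`: identical class parameters everywhere — the negative control.

The generator does not attempt biophysical realism: no cell-scale
electrophysiology, no ECG waveform shape (only beat-to-beat intervals), one
channel per record, no electrode drift or baseline wander, and burst shapes
are smooth Gaussians rather than oscillatory bursts with spectral
structure. Passing tests therefore demonstrate the pipeline's mechanics and
its behaviour under controlled class effects — not clinical performance on
real recordings.

## Numerical and protocol choices

- **Excision, not zero-filling:** retained samples are concatenated;
  zero-filling would fabricate amplitude values inside the band. A
  consequence worth knowing: excision shortens windows by a variable
  amount, which perturbs length-sensitive features (counts and sums), so
  band rules that excise little or nothing of the informative signal are
  at an advantage — visible in the `mid_band` experiments.
- **Leakage guards:** the reference amplitude A comes from training windows
  only, and SMOTE runs inside training folds by default
  (`smote_mode = "before_split"` reproduces the global-balancing protocol).
- **Fold granularity:** stratified window-level folds by default (matching
  the apparent original protocol); `group_by_patient = TRUE` keeps each
  patient's correlated windows on one side of the split — both are
  reported in the test suite's negative controls.
- **Metric pooling:** accuracy/sensitivity/specificity come from the
  aggregate confusion matrix over folds and AUC from the pooled scores;
  per-fold metrics are retained in `tidy()`. Pooled metrics equal the
  sample-weighted fold metrics, which is asserted.
- **Tie-breaks:** exact cost ties resolve toward the lower region, then the
  smaller iteration; k-means ties in distance resolve to the first
  centroid. Restart selection for the clustering models follows the
  label-aware "best of five repetitions" rule when labels are supplied
  (the replication convention), with label-free selection (minimum
  within-cluster SS / maximum likelihood) as the alternative.
- **Truncated overall accuracy:** the clustering summary is
  floor((preterm% + term%)/2); truncation rather than rounding is the only
  convention consistent with every reference row it mirrors (e.g. 98/37 →
  67, 53/50 → 51).
- **Degenerate inputs:** constant windows yield the documented identities
  (WL = ZC = SSC = VAR = 0) and a NaN sample entropy, which `featurize()`
  logs and the model layer imputes by the column median; a GMM restart
  with a singular covariance is recorded as a failed restart, and a fully
  failed fit is reported as `n/a` in the clustering table.
- **Hyperparameters:** fixed, documented values (SVM cost 1; quadratic and
  cubic kernels with γ = 1/P, offset 1; fine-Gaussian γ = 16/P,
  corresponding to a kernel scale of √P/4; 1-NN on train-standardised
  features with a nearest-neighbour distance-margin score). Fixed values
  were preferred over opaque automatic tuning for reproducibility;
  overrides are accepted through `hyper =`.

## Problem sizes in the shipped tests

The planted-effect experiments use 12 + 12 records of 30 minutes at the
envelope rate (90-sample windows, 240 windows per cohort) over 10 seeds;
calibration checks use 10,000 RR intervals; oracle checks use 50–100 random
small instances. These sizes were chosen so the full suite demonstrates the
claimed properties with comfortable statistical margins while remaining
quick to run on a single CPU.

## Known limitations

- Window-level cross-validation with multiple windows per patient is
  optimistic about patient-level generalisation; use the patient-grouped
  option for honest per-patient claims.
- The label-aware restart rule for clustering uses the evaluation labels;
  it mirrors the replication protocol but should not be read as an
  unsupervised performance estimate.
- The dyadic band grid cannot isolate an informative band lying strictly
  inside (A/2, 3A/4) boundaries other than at its fixed thresholds; an
  adaptive (hill-climbing) threshold search is a natural extension and the
  operator interface anticipates it.
- Sample entropy is O(N²) per window; fine for the window lengths used
  here, noticeable for very long windows.
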