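# pretermlsdl

Predicting preterm versus term delivery from physiological signals recorded
during active labour. The package is aimed at biomedical-signal researchers
who want a fully reproducible, testable version of this analysis pipeline:
uterine-contraction (EHG) envelopes and maternal/foetal beat-to-beat RR
series go in; threshold-decomposition models, feature tables, supervised
classification reports and unsupervised clustering reports come out.
Because the clinical recordings this kind of study uses are rarely
deposited, the package ships a calibrated synthetic-cohort generator so
every stage can be exercised and tested end to end without any download.

## The method

**Linear Series Decomposition Learner (LSDL).** A signal is decomposed into
dyadic amplitude bands relative to a reference amplitude *A* (the maximum
absolute amplitude over the training windows): the *lower* region at
iteration *i* retains samples with |x| ≤ A·(2^i − 1)/2^i (A/2, 3A/4, 7A/8,
15A/16), the *upper* region retains |x| ≥ A/2^i (A/2, A/4, A/8, A/16).
Retained samples are concatenated in time order (excision). Each of the
eight candidate bands is scored by the normalised Euclidean
class-separability cost

    J = ED(p, q) / σ_m

where *p*, *q* are the class-mean vectors of the 20-dimensional feature
ensemble extracted from every decomposed window, ED is their Euclidean
distance, and σ_m is the mean over features of the population SD on the
pooled windows. The band with maximal J becomes the fitted rule, reusable
on new records.

**Feature ensemble (20 values per window).** MAV, waveform length, zero
crossings, slope-sign changes, RMS, order-4 Burg AR coefficients, sample
entropy (m = 2, r = 0.2·SD, Chebyshev), four AR-derived cepstral
coefficients, maximum fractal length, median/peak frequency of a
Hann-windowed periodogram, peak count, simple squared integral, variance.

**Models.** SMOTE class balancing; eight supervised classifiers (decision
tree, LDA, logistic regression, linear/quadratic/cubic/fine-Gaussian SVM,
1-NN) under stratified 10-fold cross-validation with pooled
accuracy/sensitivity/specificity/AUC (preterm positive); and two-cluster
K-Means and full-covariance regularised GMM evaluated by per-class
accuracies and their truncated macro-average.

## Worked example

```r
library(pretermlsdl)

params  <- cohort_params(n_term = 12, n_preterm = 12, preset = "mid_band",
                         duration = 1800, seed = 1)
cohort  <- generate_cohort(params)
windows <- window_records(epoch_average(cohort))

model <- lsdl_fit(windows)
model
#> LSDL model
#>   best: lower region, iteration 2 (threshold 0.7500 * A), J = 17.5974
#>   reference amplitude A = 63.71
#>   8 candidates evaluated (4 valid)
```

The `mid_band` preset plants the class difference in mid-amplitude
contraction bursts underneath class-independent saturation artefacts, so
the fitted rule correctly picks a lower band (3A/4) and the upper bands are
invalid (too few loud samples per window — reported as `n/a`):

```r
lsdl_table(model)
#>   Region          Iteration 1 Iteration 2 Iteration 3 Iteration 4
#> 1 Upper threshold n/a         n/a         n/a         n/a
#> 2 Lower threshold 16.8983     17.5974     17.0432     16.6406
```

Both preprocessing arms through the supervised suite:

```r
features_raw  <- featurize(windows)
features_lsdl <- featurize(windows, lsdl = model)
suite <- run_model_suite(features_raw, features_lsdl, k_folds = 10, seed = 1)
suite_table(suite)
#>   Model Raw-Acc (%) LSDL-Acc (%) ... Raw-AUC (%) LSDL-AUC (%)
#> 1    DT        61.7         70.8 ...        65.9         71.4
#> 2   LDA        72.1         75.0 ...        76.0         79.8
#> 3    LR        69.2         75.0 ...        75.0         79.2
#> 4  LSVM        70.8         77.5 ...        76.0         80.2
#> 5  QSVM        71.2         77.5 ...        75.2         80.3
#> 6  CSVM        70.8         75.0 ...        74.2         80.2
#> 7 FGSVM        62.5         70.8 ...        66.0         75.5
#> 8   KNN        61.7         69.2 ...        65.0         73.4
```

Decomposition improves every model on this cohort because the band rule
excises the artefact amplitudes while leaving the discriminative
mid-amplitude bursts untouched. Unsupervised partitioning of the same
decomposed features:

```r
cluster_report(features_lsdl, seed = 1)
#>     Model Preterm (%) Term (%) Overall accuracy (%)
#> 1     GMM          88       38                   62
#> 2 K-Means          89       38                   63
```

The overall column is the truncated unweighted mean of the two per-class
accuracies. `run_experiment(experiment_config(...))` chains all of the
above and writes every table to disk reproducibly from one master seed;
`autoplot()` methods cover the fitted model, PCA coordinates and the suite
comparison.

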