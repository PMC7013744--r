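---
title: "Universal texture feature selection across acquisition settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal texture feature selection across acquisition settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniftex)
```

## The problem

Ultrasound scanners expose acquisition parameters — depth, dynamic
range, gain, edge enhancement, gray map, frame averaging — and the same
lesion scanned under two parameter settings produces visibly different
images. A texture-based classifier tuned on one setting can therefore
degrade badly on another. `uniftex` implements a two-stage method for
selecting a single *universal* subset of texture features that
classifies breast-lesion regions of interest (ROIs) well under every
setting simultaneously: a classifier-independent *filter* stage that
scores and prunes features using statistics computed across the
per-setting datasets, followed by a classifier-in-the-loop *wrapper*
stage — a genetic algorithm (GA) whose fitness combines per-setting SVM
cross-validation accuracies with a penalty on their spread.

The unit of analysis is a 23×23 pixel block tiled from a
radiologist-outlined ROI; classes are invasive ductal carcinoma (IDC)
versus the benign breast mouse / fibroadenoma class (BM).

## The feature bank

`extract_features()` computes 126 descriptors per block, numbered
F1–F126 in a fixed order (`feature_names()` maps numbers to names):

* **F1–F7** first-order histogram statistics (energy, entropy in bits,
  kurtosis, mean, skewness, SD, variance) of the raw gray values.
* **F8–F20** thirteen Haralick-style statistics of the gray-level
  co-occurrence matrix, symmetric, distance 1, averaged over the angles
  0°/45°/90°/135°.
* **F21** statistical-feature-matrix dissimilarity (mean absolute
  gray-level difference over the same displacement set).
* **F22–F26** run-length statistics averaged over the four directions.
* **F27–F36** Laws texture energies: mean and variance of the absolute
  valid-region responses to the five 5×5 masks LE, EL, SL, EE, LS built
  as outer products of L5 = (1,4,6,4,1), E5 = (−1,−2,0,2,1),
  S5 = (−1,0,2,0,−1) (first letter = row factor).
* **F37–F41** neighboring gray-level dependence statistics (distance 1,
  tolerance 0, interior pixels only).
* **F42–F46** neighborhood gray-tone difference statistics (3×3
  neighborhood, interior pixels only).
* **F47–F94** the same families recomputed on the LL subband of a
  one-level orthonormal Haar wavelet transform (re-quantized before the
  matrix families), plus the raw subband mean and SD (F73/F74).
* **F95–F126** local Fourier statistics: per interior pixel the 8
  neighbors, clockwise from east, are transformed by an unnormalized
  8-point DFT; means and SDs of the eight magnitudes and phases are
  taken over interior pixels.

All matrix families operate on the block quantized to 32 gray levels by
monotone min–max binning (`quantize_gray()`); 32 levels is standard
texture practice, keeping co-occurrence and run-length matrices well
populated on 23×23 blocks. Histogram, Laws and Fourier features use the
raw gray values.

Numerical conventions, chosen once and mirrored by the brute-force
oracles in the test suite: entropies are base-2; image-domain variances
and SDs are population (divide-by-n) moments; skewness and kurtosis of
a constant block are defined as 0; a co-occurrence correlation with
zero marginal variance is 0; NGTDM denominators that vanish on flat
blocks are guarded by epsilon = 1e−6 (so a constant block has
coarseness 1/epsilon); NGLDM small-number emphasis uses the raw
dependence count k, with k = 0 cells contributing zero mass but
counting in the normalization; Fourier components with magnitude below
1e−8 are treated as exact zeros so the phase at the ±π boundary is well
defined, and a zero coefficient has phase 0. The wavelet-domain Laws
features need an LL subband of at least 5×5, so the extractor requires
blocks of at least 9×9.

## The filter stage

With one dataset per setting, three scores are computed per feature
(`compute_filter_scores()`):

* an **augmented Sorensen–Dice ratio** `dice_score()`: between-setting
  squared deviation of per-setting means about the pooled mean over the
  sum of within-setting sample variances. Note this measures how much a
  feature's *level* shifts between settings relative to its spread; it
  is class-blind, and in synthetic experiments it does not rank
  class-informative features highly — it is kept because it is part of
  the published three-metric battery.
* a **multi-setting t score** `ttest_score()`: per-setting absolute
  Welch statistics between the classes, summed and divided by `s`
  times their sample SD across the `s` settings — large when class
  separation is strong *and* consistent.
* a **paired Pearson consistency score** `pearson_score()`: features of
  the same physical block observed under two settings are correlated
  (pairing via `pair_id`); per-setting mean absolute correlations are
  summed and divided by `s` times their sample SD.

A dispersion denominator can legitimately be zero for a perfectly
consistent feature; denominators below 1e−12 are replaced by 1e−12 and
the feature flagged `degenerate`, so perfect consistency is rewarded
rather than producing infinities. The t statistic uses the standard
absolute-difference numerator by default; a `squared_numerator` form is
available as a config switch for compatibility with a literal reading
of the source formula.

`build_candidate_pool()` ranks features by aggregate (mean) rank across
the three metrics and, separately, by single-feature cross-validated
SVM accuracy, intersects the two top-`top_n` lists (default 40), and
falls back to the rank-ordered union if the intersection is smaller
than a floor (default 5); the fallback is flagged in the result.

## The wrapper stage

Features are first standardized per column (`scale_features()`,
sample-SD z-transform learned on the selection half only and reapplied
to the held-out half; constant columns map to 0 and are flagged). The
GA (`ga_evolve()`) then searches binary chromosomes over the candidate
pool:

* fitness of a chromosome = `sum(acc) − sum of all pairwise squared
  accuracy differences`, where `acc` are stratified 5-fold SVM
  cross-validation accuracies per setting (`ga_fitness()`,
  `evaluate_chromosome()`). For a fixed accuracy total the penalty
  vanishes exactly when all settings agree, which is the formal
  expression of "universal".
* roulette-wheel selection, two-point crossover (probability 0.65),
  independent bit mutation (rate 0.03), elitism of one — the published
  operator set and rates. Full-scale defaults are population 500 and
  500 generations; the examples below use desk-scale parameters.
* an exact-cardinality repair operator keeps chromosomes at exactly
  `k` features (the published selections report k = 5, 10, 15), run as
  separate constrained searches per k.
* duplicate chromosomes are evaluated once (a cache keyed by bit
  pattern), and all randomness flows from one recorded seed, so runs
  are exactly reproducible.

One design choice deserves emphasis. Because the fitness is a sum of
four accuracies, all candidate values crowd into a narrow band
(roughly 3.0–3.9 of a possible 4), and raw fitness-proportional
roulette then selects almost uniformly: in recovery experiments the
search repeatedly stalled on subsets sharing only two of three planted
features. `ga_params(selection_scaling = "window")` (the default)
therefore rebases the population's fitness to its current minimum
before the roulette draw — the classic windowing remedy for vanishing
selection pressure — while `"raw"` retains plain proportional
selection. With windowing, the small-scale recovery study below
succeeds in 19 of 20 runs; without it, 17 of 20.

The SVM is the soft-margin RBF machine of `e1071` (libsvm), with
kernel `exp(−‖x−x′‖²/2σ²)`. The study that motivated this package
specifies the kernel form only; defaults here are C = 1 and the median
heuristic σ² = (median squared pairwise distance)/2, resolved once per
cross-validation call on its input (a label-free statistic). Folds are
stratified, sized within one sample of each other, and fixed by a
recorded `fold_seed` so that all chromosomes face the same folds.

## The synthetic data generators

No public dataset accompanies the method (the originating study's
23-patient scanner data is private), so the package ships two seeded
generators that emulate the statistical structure the method consumes.

`generate_feature_table()` draws paired multi-setting feature tables:
each physical block (`pair_id`) is observed once per setting; a latent
per-pair effect (SD 0.5) makes paired observations correlate across
settings, independent noise tops the within-class SD up to 1, and each
(feature, setting) receives a fixed mean shift (SD 0.25) emulating
systematic setting-to-setting level changes. The default size — 500
pairs per class, i.e. 4000 per-setting observations over four settings
— mirrors the scale of the motivating study's block collection (its
two reported totals, 4038 and 4604, disagree; the generator sides with
the balanced reading of the smaller one). Planted universal
features separate the class means by `effect_size` within-class SDs in
every setting (default 2, a strong but realistic single-feature
effect); setting-specific features do so only in their own setting.

`generate_texture_dataset()` draws two-class 23×23 image blocks:
Gaussian white noise smoothed with a class-specific kernel width
(default SDs 1 vs 3 pixels, so the classes differ in texture scale),
one base field per block shared across settings, and per-setting
monotone intensity maps (gain then power-law compression) followed by
8-bit quantization — an abstract stand-in for gain/dynamic-range
differences between scanner settings. Speckle, attenuation and other
acquisition physics are deliberately not modeled: the selection method
consumes only feature statistics, so passing tests on these data show
that the *pipeline* behaves correctly (recovery of planted structure,
preference for consistency, chance level without signal), not that any
particular clinical accuracy would be reproduced on real ultrasound
data.

## A desk-scale run

```{r pipeline, eval = FALSE}
tab <- generate_feature_table(table_gen_spec(
  n_settings = 4, n_per_class_per_setting = 100, n_features = 30,
  universal_informative = c(3, 11, 19), effect_size = 2, seed = 7
))
cfg <- pipeline_config(
  ga = ga_params(population_size = 30, generations = 20, rng_seed = 1),
  svm = svm_config(fold_seed = 1),
  top_n = 12, cardinalities = 3L, seed = 1
)
report <- run_select(tab, cfg)
print(report)
```

`run_select()` splits pairs 50/50 stratified by class (both halves keep
all settings of a pair together, so nothing leaks across the split),
scales on the selection half, filters, runs the GA per cardinality, and
reports both selection-half cross-validation and held-out accuracies
with their mean and sample SD per setting.

## Problem sizes, verification, and limitations

The test suite verifies every texture family against independently
coded brute-force oracles on 100 random blocks each (sizes 9–23,
relative tolerance 1e−8), reproduces the filter and fitness hand
values to 1e−12, and runs the two behavioral studies at study-scale
sample sizes: subset recovery (4 settings, 3 planted universal among
20 features, effect 2 SD, 200/class/setting, GA at population 30 / 20
generations / k = 3, 20 seeded runs) and fitness consistency
preference (20 seeded runs), plus determinism, leakage and
label-shuffle chance-level guards. These sizes keep a complete run in
minutes on one CPU while leaving the planted-recovery problem genuinely
non-trivial (1140 candidate subsets, ~250 unique evaluations per run).

Known limitations: the setting-shift ratio score is class-blind (see
above); the GA offers only the published operator set (no tournament
selection or island models); the SVM is binary with the RBF kernel
only, without probability calibration; and synthetic images are
abstract texture surrogates, not simulated ultrasound.
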