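---
title: "Chemometric authentication of meat origin from ATR-FTIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric authentication of meat origin from ATR-FTIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirauth)
```

## The problem

Mid-infrared attenuated total reflectance (ATR-FTIR) spectroscopy
fingerprints the bulk biochemical composition of a meat sample — lipids
(C–H stretches near 2850–2955 cm⁻¹), proteins (Amide I/II/III at ~1650,
~1540, ~1240–1450 cm⁻¹), phospholipids (P=O at ~1080 cm⁻¹) and
carbohydrates/collagen (C–O near 970–1030 cm⁻¹). Samples of different
geographical or production origin differ subtly but consistently in the
relative intensities of these bands, so a labeled collection of spectra can
train classifiers that authenticate origin. `ftirauth` implements the full
chemometric workflow for the two-class case: spectral ingestion and region
masking, eleven pre-processing operators, PCA-based outlier rejection,
SIMCA, PCA-LDA and PLS-LDA, PLS1 regression with VIP scores, RBF-kernel
support vector regression with permutation importance, a feed-forward
neural-network classifier with region-of-importance mapping, and three
validation schemes, orchestrated by a factorial experiment driver.

## Data model

A `spectra_set` holds the n × p absorbance matrix `X` (rows are spectra)
on a strictly monotonic wavenumber axis, with per-row sample id, replicate
number, and a binary label (1 = target origin). FTIR instruments commonly
export descending axes; the container always stores ascending and flips on
ingestion. Replicate spectra of one sample (three per sample is the
conventional protocol) are collapsed by `average_replicates()` into the
row-per-sample modeling matrix. Region masking uses closed intervals on
both ends — the fingerprint window is taken as 600–1800 cm⁻¹ and the whole
spectrum as 650–4000 cm⁻¹ with the atmospheric CO₂ (2250–2390 cm⁻¹) and
water-vapor (3200–3400 cm⁻¹) windows excluded. Where a source reports both
600 and 850 cm⁻¹ as the lower fingerprint bound, we default to the wider
600 cm⁻¹ and leave the narrower choice to configuration; no resampling is
ever performed, and mixed grids across files are an error rather than an
interpolation.

## Pre-processing operators

Eleven treatments (plus the raw baseline) are provided as composable
operators. Row-local ones — SNV, detrending, Savitzky–Golay derivatives,
median filtering, ATR correction — act on one spectrum at a time. The
reference-based ones — MSC, quantile normalization, OSC — are *fit* on
training rows and *applied* to any set, so cross-validated pipelines never
leak held-out information into the fitted state
(`fit_recipe()` / `apply_recipe()`).

Numerical choices, with rationale:

* **Savitzky–Golay**: window 11 / polyorder 2 for the first derivative,
  window 15 / polyorder 3 for the second — common practice at a 2 cm⁻¹
  grid, where an 11-point window spans ~22 cm⁻¹, below typical condensed
  -phase band widths. Derivatives are scaled by the grid spacing so units
  are AU·(cm⁻¹)⁻ᵒʳᵈᵉʳ. When region masking leaves gaps in the axis the
  filter runs per contiguous uniform segment and never differentiates
  across a gap.
* **SNV** uses the n−1 standard deviation; a constant row is an error
  naming the row rather than a silent division by zero.
* **MSC** regresses each spectrum on the training-mean reference; slopes
  below 1e-10 in magnitude are a degenerate-fit error.
* **Detrend** projects out an orthonormal polynomial basis; degree 1 when
  used alone (linear drift), degree 2 inside SNV+detrend (the standard
  Barnes formulation).
* **"Deresolve" (derivative with smoothing)** is implemented literally as
  SG smoothing followed by an SG first derivative. The same name sometimes
  denotes resolution *reduction* (band broadening); we follow the
  derivative-with-smoothing reading and note the alternative here rather
  than switching silently.
* **Median filter** width 5 with reflect padding at the edges.
* **Quantile normalization** maps each value to the per-rank mean of the
  sorted training rows; tied ranks average the bracketing reference
  values. It is fit per training split, the leakage-safe reading of an
  otherwise unstated protocol.
* **OSC** is single-pass Wold-style: the leading principal score is
  orthogonalized against the response, a weight vector is refit by least
  squares (minimum-norm via the SVD), and the data are deflated by the
  resulting score/loading product; default one component. Components with
  variance below 1e-12 stop the loop with a warning.
* **ATR correction** rescales column ν by ν/ν_ref (default
  ν_ref = 1000 cm⁻¹), compensating the wavelength-proportional penetration
  depth of the evanescent wave.

## PCA and outlier rejection

`fit_pca()` is mean-centered SVD PCA with a deterministic sign convention
(largest-magnitude loading element positive). Sample diagnostics are
Hotelling's T² = tᵀS_t⁻¹t on the score covariance and the Q residual
‖x − x̂‖², the squared norm of what the model fails to reconstruct.
`flag_outliers()` thresholds both statistics at their empirical
mean + 3·SD over the modeled samples and flags the union — the empirical
rule as commonly practiced, not an F- or χ²-based limit. The outlier
model's component count defaults to the smallest number reaching 95%
cumulative variance, capped at 10; thresholds are computed on the same
samples used to fit. Note that a 3-sigma empirical rule on ~60 samples
will occasionally flag an honest sample along with a gross outlier; the
guarantee we test is that a grossly displaced sample is always caught, not
that it is the only one caught.

## SIMCA

One PCA model per class (components: smallest count reaching 90% class
variance, capped at 10), classification by the smaller residual distance
d_k = √Q_k, ties to class 0 with a warning. Coomans coordinates are the
pair (d₀, d₁) per sample; the per-class critical distance is the type-1
(inverse ECDF) empirical 95th percentile of that class's training
distances, which guarantees at least 95% of training distances fall at or
below it — interpolating quantile definitions do not. Reported metrics
follow the confusion-matrix definitions with class 1 positive: accuracy,
specificity TN/(TN+FP), and selectivity TP/(TP+FN) (selectivity is the
field's synonym for sensitivity/recall). Metrics with an empty denominator
are reported as missing, never as zero.

## PCA-LDA and PLS-LDA

Both hybrids z-score each wavenumber column (training mean and n−1 SD,
floored at 1e-12), reduce to at most 10 components — principal components
or PLS1 latent variables against the 0/1 label — and fit a two-class
pooled-covariance LDA on the scores, with priors from training
frequencies and a 1e-8·trace ridge (with warning) if the pooled covariance
is singular. A two-class LDA has exactly one discriminant axis, so the
canonical score is one-dimensional; plots pair it with the first reducer
score when a second axis is wanted.

## PLS1 regression, LV selection and VIP

`fit_plsr()` is NIPALS PLS1 on mean-centered (not variance-scaled)
spectra against the 0/1 response. For every candidate component count up
to `max_lv` (default 15) the leave-one-out RMSE is computed by refitting
per fold; the minimizing count wins, ties to the smaller. VIP scores use
the standard Wold form with the square root and per-component weight
normalization,

VIP_j = √( p · Σ_a (w_ja/‖w_a‖)² s_a / Σ_a s_a ),

where s_a is the response variance explained by component a; this
normalization makes mean(VIP²) = 1 exactly, which is what gives the
conventional "VIP > 1" threshold its meaning. Classification uses the
coding-consistent rule: a continuous prediction strictly above 0.5 is
assigned the class coded 1. (Descriptions of this rule in the literature
sometimes invert the class names; we keep the rule consistent with the
coding and say so here rather than guessing.)

## SVR and permutation importance

`fit_svr_grid()` searches the 4 × 4 × 2 grid C ∈ {0.1, 1, 10, 100},
ε ∈ {0.01, 0.1, 0.5, 1.0}, γ ∈ {scale, auto} by five-fold CV mean R² on
the 0/1 response treated as continuous, with a seeded fold shuffle. The
γ conventions are 1/(p·var(X)) for "scale" and 1/p for "auto". The solver
is `e1071::svm`; a grid cell whose ε tube swallows all points (zero
support vectors) degrades to the constant mean predictor rather than
erroring. Permutation importance is the mean drop in R² over seeded
repeats when one column is shuffled; negative values are reported as-is.
Because an RBF kernel evaluated on its own training rows uses every
coordinate, a truly uninformative feature shows a small genuinely positive
importance rather than exact zero — negligible in absolute terms and
orders of magnitude below an informative band, which is how the tests
phrase the null check.

## Neural network

The classifier is a feed-forward multilayer perceptron with ReLU hidden
layers, a softmax output, full-batch Adam (β₁ = 0.9, β₂ = 0.999), and
early stopping on the loss of a held-out validation fraction (default
10%, patience 10 improvements of at least 1e-4). It is implemented in the
package itself because the candidate architectures have several hidden
layers. The default candidate grid crosses layouts
{50, 100, 50-20, 100-50, 50-30-10} with iteration caps
{1000, 2000, 3000}; selection is by validation loss, ties to the smaller
network. Features are z-scored with the training scaler. Reported metrics:
accuracy, precision, recall, specificity, F1, misclassification percent,
mean binary cross-entropy (probabilities clipped at 1e-12) and AUC via the
rank-based Mann–Whitney identity.

Region-of-importance (ROI) mapping is sliding-window block permutation:
each window of contiguous wavenumbers (default 11 points, ~22 cm⁻¹) is
shuffled jointly and the mean log-loss increase over repeats is assigned
to the window center; the curve is floored at zero and normalized to max
1 (raw values retained). This model-agnostic choice is ours — attribution
curves of this kind are rarely specified exactly — and is documented as
such rather than claimed canonical.

## Validation schemes

Three schemes are applied uniformly through model factories that refit
*everything* — stateful preprocessing included — inside each fold:

* **Training accuracy**: resubstitution, in percent.
* **Leave-one-out**: one refit per sample.
* **Venetian blinds**: every third sample withheld (0-based offset 2, i.e.
  1-based positions 3, 6, 9, …), exactly one third of the data; the other
  two thirds train.

Replicate averaging precedes splitting, so folds never separate replicates
of one sample. One calibration caveat worth knowing: leave-one-out LDA on
*null* data (identical class distributions) is pessimistically biased —
removing a sample shifts its own class mean away from it — so null LOO
accuracy sits visibly *below* 50% at small n (we measured ~35% at n = 24
and ~46% at n = 60). The meaningful null check is therefore one-sided: no
classifier may score above the chance upper confidence bound. SIMCA's
distance rule is much less affected.

## Synthetic data generator

Because real spectra collections of this kind are typically not publicly
deposited, the package ships a generator that emulates the statistical
structure the analysis assumes. Each sample is a sum of Gaussian bands at
the canonical meat-tissue positions (2955, 2920, 2850, 1650, 1540, 1450,
1400, 1330, 1240, 1080, 1030, 970, 920 cm⁻¹) on a 2 cm⁻¹ grid over
600–4000 cm⁻¹, with a per-sample linear baseline, a lognormal
multiplicative scatter factor, and per-replicate white noise plus a
smooth low-frequency wiggle; three replicates per sample. Class 1
multiplies lipid-associated band amplitudes by the class effect (default
1.15 — strong enough for high accuracy, weak enough that preprocessing
matters) and carbohydrate/collagen bands by its reciprocal; Amide I is
shared. `null_dataset()` forces every class effect to 1 for
type-I-error-style calibration. The generator is deliberately idealized:
Gaussian (not Voigt) line shapes, no instrument line-shape function, no
ATR optics simulation, no batch or temporal structure. Passing tests on
it demonstrate the *mechanics* of the workflow — leakage-safety,
calibration, parameter recovery — not performance on real meat spectra.

## The factorial driver

`run_experiment()` crosses the preprocessing set with the region set,
optionally removes T²/Q outliers per cell (mirroring per-treatment outlier
counts in published tables), and runs the requested model families under
the requested schemes, emitting one tidy data frame per family plus a
per-cell manifest. A failing cell is recorded and skipped, not fatal. One
master seed fans out deterministically to per-cell seeds, so any cell can
be reproduced in isolation; two runs with the same seed serialize to
byte-identical CSVs. `report_summary()` picks each family's best cell by
excluded-set accuracy (lowest excluded RMSE for the regression families),
breaking ties by fewer components and then lexical preprocessing name.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the workflow at sizes
chosen to make the statistical properties sharp while remaining quick on
a single CPU: oracle comparisons at n ≈ 20–60 and p ≈ 6–200; planted
-outlier detection at n = 61, 50 seeds; SIMCA calibration at 60 samples
per class (excluded-set, 50 seeds) and n = 120 (null LOO); VIP and SVR
planted-feature recovery at n = 60–80 over 20 seeds; the neural network at
n = 160 over 10 seeds; and the determinism check on the full
preprocessing × region factorial at 40 samples per class with three
replicates. These sizes are the package's own choices and are stated here
so results can be reproduced exactly.

## Known limitations

* Two classes only; multiclass SIMCA/LDA are out of scope.
* No probabilistic SIMCA membership (F-test style) — the distance rule
  and empirical percentile boundaries only.
* The SVR excluded-set protocol selects hyperparameters once on the
  training partition; nested CV would give less biased generalization
  estimates.
* The generator's idealizations mean quantitative results on it do not
  transfer to real spectra; only qualitative behavior does.
* JCAMP-DX support covers plain AFFN XYDATA/XYPOINTS; compressed dialects
  are rejected explicitly.
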