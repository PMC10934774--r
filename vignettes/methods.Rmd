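---
title: "Chemometric characterisation of street heroin from mid-IR spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric characterisation of street heroin from mid-IR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirpls)
```

## The problem

Street heroin is a complex mixture: 3,6-diacetylmorphine at anywhere from a
fraction of a percent to over half the mass, cut with pharmacologically
active diluents (caffeine, acetaminophen), and carrying opium-alkaloid
impurities (morphine, codeine, papaverine, noscapine) and their acetylation
products (6-monoacetylmorphine, acetylcodeine) from the production process.
ATR-FTIR measures a pseudo-absorbance spectrum, log10(1/R), from a few
milligrams of powder with no sample preparation, which makes it attractive
for harm-reduction drug checking — but the information about individual
compounds is buried in overlapping bands and must be extracted
chemometrically.

`ftirpls` implements the full workflow: fingerprint-region selection,
spectral pre-treatment, Duplex train/test partitioning, exploratory PCA,
PLS regression for heroin purity, PLS-DA presence models for eleven
compounds, confusion-matrix validation and a permutation-based overfitting
test. Because measured street-sample spectra are not publicly available,
the package ships a synthetic mixture-spectrum generator with the same
statistical structure, so every stage is exercised end to end by code
alone.

## Data model and pre-treatments

Spectra live in a `spectra_set`: samples x wavenumbers, axis stored in
descending wavenumber order (instrument convention; ascending input is
re-sorted on ingest). Analysis restricts to the fingerprint region,
650–2000 cm⁻¹ read as a closed interval — the region is stated in the
chemometric literature without an endpoint convention, and including the
boundary grid points is the conservative reading. On a 4 cm⁻¹ grid that is
338 variables.

Four pre-treatments are supported, applied mutually exclusively (the
workflow evaluates them competitively rather than chaining them):

* **mean centering** — subtract the per-wavenumber training mean;
* **autoscaling** — additionally divide by the per-wavenumber training
  standard deviation (sample sd, n−1 denominator, everywhere in the
  package);
* **SNV** — per spectrum, subtract the row mean and divide by the row sd;
  removes multiplicative scatter and path-length variation and needs no
  fitted state;
* **Savitzky–Golay second derivative** — local quadratic least squares
  over a 17-point window per spectrum; removes baseline and sharpens band
  structure.

Two choices in the derivative deserve a note. The derivative is taken with
respect to the point index; on the uniform 4 cm⁻¹ grid this is proportional
to the derivative per cm⁻¹ (`scale_delta` applies the 1/Δν² factor when the
physical scale matters), and index units match common chemometrics toolbox
behaviour. At the first and last eight points the window is truncated at
the boundary and the quadratic refitted on the one-sided window, so no
variables are discarded; a line is annihilated and a pure quadratic
recovered exactly even at the edges.

Column statistics are always fitted on the training partition only and
applied frozen to held-out data. SNV and the derivative are per-spectrum
operations with no fitted state, so for them the distinction is moot — a
fact the cross-validation code exploits to transform once instead of per
fold.

## Duplex partitioning

The external test set (~20%, 25 of 125 by default) is selected
deterministically by the Duplex algorithm on the raw fingerprint spectra:
rounds alternate between training and test set, each round assigning the
pair of still-unassigned samples with the largest Euclidean distance, until
the test set is full; remaining samples join the training set. One split is
shared by all eleven presence models and the purity regression — the
per-compound class ratios in the shared test set are then verified against
the full-set ratios (default tolerance 0.15 absolute difference in positive
fraction) and the purity range coverage is checked for the regression.
Details the algorithm statement leaves open were fixed as follows: exact
distance ties break towards the lexicographically smallest id pair; an odd
test size takes, in the final round, the pair member farther (larger mean
distance) from the remaining samples. Both rules keep the split a
deterministic function of the data.

## PCA overlays

Exploration uses SVD-based PCA of the pre-treated spectra, with an explicit
column centering after pre-treatment (uncentered PCA conflates the mean
spectrum with variance; for mean centering and autoscaling the step is a
no-op). Sign convention: the largest-magnitude loading element of each
component is positive. "Visible clustering" of a compound's positives and
negatives in PC1–3 space is made quantitative as the mean silhouette width
of the binary grouping (via `cluster::silhouette`), and
`loading_correspondence()` relates a component's loading pattern to a
reference spectrum (absolute Pearson correlation plus band matching within
±8 cm⁻¹, two grid steps). The package reports silhouettes under all four
pre-treatments and lets the user rank, rather than hard-coding a "best"
pre-treatment per compound.

## PLS and PLS-DA

The core is NIPALS PLS1 with X- and y-deflation, chosen for transparency
over SIMPLS-style variants (an independent-implementation cross-check
against `mixOmics` at equal factor counts is part of the test suite).
The pre-treated training matrix is column mean-centered
(`center_x = TRUE`; PLS on uncentered data is unusual, but the flag is
exposed because toolbox behaviour after SNV/derivative is not universal)
and the response centered by its training mean, which predictions add
back. With as many factors as the rank bound, PLS reproduces the
least-squares fit — one of the oracle equivalences in the tests.

Purity is modelled as a mass fraction in [0, 1] (percent m/m divided by
100): this is the only scale on which root-mean-squared errors of a few
hundredths are coherent with purities up to ~0.57. Presence models use 0/1
class coding with a fixed decision threshold of 0.5; the threshold is a
model field, so alternative strategies can be plugged in.

Factor selection uses 10-fold cross-validation in which the pre-treatment
and model are re-fitted per fold (no leakage; folds stratified by class in
discriminant mode so every training part keeps both classes). The selection
rule is mode-dependent: regression takes the smallest factor count within
2% relative of the RMSECV minimum (parsimony tie-break); discriminant
models take the highest cross-validated correct classification rate with
RMSECV as tie-break — the literature reports both calibration and CV ccr
without stating the criterion, so the rule is explicit and the alternative
selectable. `A_max` defaults to 15, the largest factor count the reference
workflow ever selected (codeine). The grid search is exhaustive over
(pre-treatment, factor count).

## Validation metrics

`classification_metrics()` computes exact integer confusion counts and
ccr, sensitivity, specificity and precision as percentages at full
precision; reports round to two decimals only at serialisation. A rate
with a zero denominator is `NA` ("undefined"), never 0 or 100.
`regression_report()` returns RMSEC/RMSECV/RMSEP and the three
determination coefficients on the purity-fraction scale, plus the
true-vs-predicted pairs for correlation plots.

The packaged audit `reported_model_check()` re-derives the published
per-compound percentages from the stated class sizes and
misclassification counts. Several printed entries are internally
inconsistent — a test sensitivity consistent with a 22/3 split printed
beside a 21/4 ratio, a specificity pair impossible under the stated two
false positives among six test negatives, cross-validation rates implying
99 rather than 100 training samples — and the audit lists these
discrepancies rather than resolving them.

## The permutation test

The overfitting test re-fits the selected configuration on randomly
shuffled responses and asks whether the real model beats the shuffled ones.
Each model's absolute residuals — self-prediction and 10-fold
cross-validated, with folds re-drawn per shuffle from a derived seed — are
measured against the response it was trained on, which makes the original
model exchangeable with the shuffles under the null hypothesis. Three
paired statistics compare the original's residuals with each shuffle's:
Wilcoxon signed-rank, sign, and the paired t statistic (used only
directionally, never through the parametric t distribution).

Aggregation across shuffles was the least constrained design point, and
two options are implemented:

* **per-permutation (default)** — count the shuffles whose paired
  statistic fails to favour the original and report
  `(1 + #not beaten) / (n_permutations + 1)`. This is exactly valid under
  exchangeability; its price is a discrete p-value grid whose floor is
  `1/(n_permutations + 1)` (0.032 at 30 shuffles), and a conservative
  sign-test stream, since rejecting requires the original to win every
  single pairwise comparison.
* **pooled** — average each sample's residual over all shuffled models and
  run one paired test of the original against that average (with a
  sign-flip randomization null for the t statistic). More powerful, but
  only approximately calibrated: the pooled differences all share the
  original model's fit, and simulation shows inflation of the type-I error
  to roughly 15–25% at a nominal 5% — which is why it is not the default.

The SSQY-vs-correlation diagnostic records, per shuffle, the sum of squared
residuals against the correlation between shuffled and original response;
the unpermuted reference point sits at correlation 1 with the smallest
SSQY when the data are informative, and shuffles that happen to correlate
with the truth drift towards it.

The test-suite calibrations use sizes chosen once: the null simulation
draws a continuous response independent of 120 x 60 noise spectra (2
factors, 30 shuffles, 200 replicates) and checks the rejection rate pooled
over the six p-value streams; the power simulation uses the strongly
informative generator scenario below (100 samples, 7-factor SNV model, 30
shuffles, 20 replicates) and requires all six p-values below 0.05.

## The synthetic generator

Spectra are Beer–Lambert linear mixtures: per-compound band signatures
(Gaussian/Lorentzian bands inside 650–2000 cm⁻¹; synthetic stand-ins, not
measured reference spectra) weighted by mass fractions, multiplied by a
per-spectrum log-normal scatter factor, plus a random low-order polynomial
baseline and i.i.d. Gaussian noise — exactly the artefact classes SNV and
the derivative are designed to remove. The default composition mirrors the
structure of the bundled 124-sample assay panel: a 5.6% heroin-negative
rate, of which roughly two in seven are "confusable" negatives containing
caffeine and acetaminophen; log-normal purity with median 0.11 truncated to
[0.002, 0.60]; opium alkaloids and their acetylated forms present with
probability 0.95–0.99 given heroin; codeine sparse (0.23) and, with
morphine, confined to 0.2–1% mass fractions (most of both is acetylated
during production, which is precisely why they resist modelling);
methacetin rare (0.08) and low-dosed. A compound is flagged present when
its fraction exceeds a 5·10⁻⁴ detection floor; the remainder of each
sample's mass is a generic cutting-agent signature. Adulterant
concentration distributions are declared assumptions — only presence, not
concentration, is known for the real panel.

Two deliberate departures from the defaults appear in tests and are part of
the scenario design, not tuning: the SNV-superiority property uses scatter
sdlog 0.25, because below ~0.2 the scatter-induced error of mean centering
(≈ purity × sdlog) stays under SNV's own floor from ratio nonlinearity and
the two pre-treatments tie; and the permutation-power scenario concentrates
purity in 0.22–0.48 with plain negatives at rate 0.15, because with the
full 0.002–0.57 purity range the class indicator is a step function of a
wildly varying amplitude, bulk residuals stay near 0.05–0.1 even for a
good model, and no paired sign comparison can sweep thirty shuffles. What
passing these tests shows is that the machinery behaves correctly under
the stated conditions; it does not show that real street-sample spectra —
with instrument drift, ATR penetration-depth effects, nonlinear detector
response and compounds outside the library — would yield the same numbers.

## The pipeline

`run_characterisation()` drives the whole analysis from one configuration:
simulate or load spectra, select the fingerprint region, draw the single
Duplex split, grid-search every presence target (trained on all training
samples) and the purity regression (trained on heroin-positive training
samples only), and emit a per-target report. A presence target whose best
cross-validated ccr fails to beat the majority-class rate by more than one
percentage point is reported as "no significant model" — the observed
methacetin behaviour, for which the reference workflow states only the
outcome, not a rule. The permutation test is post-hoc validation: it never
changes model selection, and `n_permutations` defaults to 0 in the
pipeline, with the dedicated analysis script running it for the selected
heroin model (50 shuffles).

The numbered scripts under `analysis/` narrate the workflow at study scale
(125 samples, seed 7): simulate, explore by PCA, split, characterise,
permutation-test, and audit the published arithmetic; each writes its
tables under `results/`.

## Known limitations

* Band signatures are spectroscopically plausible but synthetic; loading
  interpretations transfer to real data only qualitatively.
* The linear mixing model omits ATR penetration-depth wavelength
  dependence, band shifts from molecular interactions, and detector
  nonlinearity.
* With very few negative samples (the real panel has seven), specificity
  estimates rest on a handful of observations, and the
  majority-class-plus-one-point significance rule becomes strict — a
  borderline dataset can flip a compound between "model" and "no
  significant model".
* The per-permutation sign statistic is conservative; a decisive sign
  verdict needs either many samples or the pooled aggregation with its
  documented anticonservatism.
* JCAMP-DX support is a minimal single-spectrum `(X++(Y..Y))` reader;
  vendor binary formats are out of scope.
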