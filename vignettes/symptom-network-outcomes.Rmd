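---
title: "Paired HoNOS outcomes: individual scores and symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired HoNOS outcomes: individual scores and symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honosnet)
```

## The analysis problem

Community mental-health services routinely rate patients on the Health of
the Nation Outcome Scales (HoNOS): 12 clinician-rated items, each scored on
a five-point severity scale 0–4, covering psychiatric symptoms (agitation,
self-harm, substance use, cognition, physical health, psychosis, depressed
mood, other symptoms) and social functioning (relationships, activities of
daily living, living conditions, occupation).  With one rating at entry to
the service and one roughly a year later, two complementary questions arise:

1. **Individual scores** — did each item improve, and who reached
   *treatment response* (an end-point profile with no item rated 3 or
   above)?
2. **Symptom networks** — did the *interplay* between symptoms change?
   Here each occasion's scores are modelled as a Gaussian graphical model:
   nodes are items, and an edge is a nonzero partial correlation between
   two items controlling for the other ten.

`honosnet` implements both arms as a reproducible pipeline over a
`HonosCohort` object (a `SummarizedExperiment` with paired
`baseline`/`endpoint` score matrices and per-patient age, gender and
between-rating delay), plus a simulator with known ground-truth networks so
that every stage can be verified against a recoverable truth.

## Severity, response, and the individual-scores arm

A profile is *severe* iff any item is rated 3 or above; analysis cohorts
are restricted to patients severe at baseline (`filterBaselineSevere()`),
mirroring service-evaluation practice: patients already below the severity
threshold at entry cannot show a meaningful response.

Per item, baseline and end point are compared with the paired Wilcoxon
signed-rank test (`pairedWilcoxon()`).  Zero differences are dropped,
absolute differences receive midranks under ties, and `V` is the rank sum
of positive differences.  For up to 25 non-zero pairs the two-sided p-value
comes from the exact distribution of `V` (a generating-function convolution
over sign assignments, valid under ties — unlike the usual exact routine,
which refuses tied data); beyond that, the normal approximation with tie
and continuity corrections is used.  The cut-off 25 is where enumeration
stops being necessary: the approximation error is negligible there, and the
exact distribution stays cheap below it.  Raw p-values are reported per
item, as is conventional for HoNOS tables; `itemSummaryTable(adjust=)`
offers Holm/Bonferroni adjustment but it is off by default.

Treatment response (`responseStatus()`) is reaching non-severity at end
point.  `fitResponseLogistic()` regresses response on the 12 baseline
items, age (years, untransformed — there is no substantive reason to bend
it) and a single male/female indicator; unknown-gender rows are dropped
with a warning.  Separation is flagged when any coefficient passes 15 on
the log-odds scale, beyond which Wald statistics are meaningless.

## The network arm

### Delay residualization

Real follow-up ratings are not taken exactly at one year.  Variation in the
between-rating delay both adds noise and, because scores improve with time,
compresses end-point variance.  Before network estimation, each item is
therefore replaced by its residual from an ordinary least-squares
regression on the delay, separately per occasion and per item (24 simple
regressions; `residualizeOnDelay()`).  Scores are regressed *on* delay —
the only direction that yields residual score matrices usable downstream.
The OLS residual property makes every residual column mean exactly zero,
so paired t statistics between baseline and end-point residuals vanish by
construction; the pipeline checks this identity rather than treating it as
an empirical finding.  When all delays are equal the slope is undefined and
the fallback is plain centering.  The baseline matrix is residualized too
by default (`residualizeBaseline = TRUE`); setting it to `FALSE` merely
centers baseline scores, for users who prefer to adjust only the occasion
that actually varies with delay.

### SKEPTIC correlations

Ordinal five-point scores are far from normal, so Pearson correlations of
residuals would be biased.  The nonparanormal SKEPTIC estimator replaces
them with `r = sin(pi/2 * tau)`, where `tau` is Kendall's tau-b
(tie-corrected, computed by an O(n log n) merge-sort algorithm).  Under a
latent Gaussian copula this is a consistent estimator of the latent
correlation without assuming normal margins.  The tau form is used rather
than the Spearman form because it is the canonical SKEPTIC choice and its
tie correction handles ordinal data naturally.  An entrywise sine transform
need not produce a positive semi-definite matrix; when it does not, the
matrix is repaired by clipping eigenvalues at 1e-4 and rescaling to unit
diagonal, and the repair is flagged (`psdRepaired`).

### Graphical lasso and EBIC

The sparse precision matrix is estimated by the graphical lasso: maximise
`log det K - tr(SK) - lambda * sum_{i!=j} |K_ij|`, penalising off-diagonal
entries only.  The solver is the standard block coordinate-descent
algorithm, compiled (RcppArmadillo) because it sits inside permutation and
bootstrap loops, and it certifies each solution by the duality gap
(`< 1e-6`).  A log-spaced path of 100 penalties runs from `lambda_max`
(the largest absolute off-diagonal correlation, where the graph is empty)
down to `0.01 * lambda_max` — the conventional EBICglasso path; the model
is selected by the extended Bayesian information criterion

`EBIC = -2 L + E log n + 4 E gamma log p`,

with `E` the number of nonzero off-diagonal entries (tolerance 1e-10) and
ties resolved toward the sparser model.  The pipeline preset is
`gamma = 0` — ordinary BIC — because at cohort sizes around 100–150 any
larger value prunes the network down to a handful of edges or none.  The
library default for standalone use of `ebic()` follows the common
conservative choice 0.5; the pipeline sets 0 explicitly.  Selected
precisions are converted to partial correlations
(`w_ij = -K_ij / sqrt(K_ii K_jj)`), giving the `WeightedNetwork`.

### Comparing occasions and interpreting nodes

Overall connectivity is *global strength*, the sum of absolute edge
weights.  The two occasions are compared by a permutation network
comparison test (`nctGlobalStrength()`): pool all rows, regroup them
randomly into two groups of the original sizes, re-run the *entire*
estimation (SKEPTIC + EBIC-glasso) on each regrouped sample, and compare
the observed absolute difference against the permutation distribution,
with the add-one p-value convention so p is never exactly zero.  The free
regrouping of pooled individuals is used even though the samples are
paired, matching standard NCT practice; a `paired = TRUE` variant
(within-patient occasion swapping) is available as a methodological
alternative.  Residualization happens once, before the test — permutations
regroup residual rows rather than re-running the delay regressions, which
keeps the null hypothesis about network structure rather than about delay
composition.

Node importance uses *node strength* (row sums of absolute weights, also
z-standardised).  Closeness and betweenness are implemented
(`closenessBetweenness()`, edge length `1/|w|`, the conventional mapping)
but excluded from default reports: at these sample sizes they essentially
never satisfy the stability criteria.  Stability itself is assessed by
case-drop bootstrapping (`casedropStability()`): drop 10%–70% of cases,
re-estimate, and correlate subsample with full-sample centrality.  The
CS-coefficient is the largest drop fraction at which that correlation stays
at or above 0.7 in at least 95% of subsamples; a measure is interpreted
only when CS ≥ 0.25.  All three constants are exposed in the API.

## The synthetic-data generator

`makeTrueNetwork()` draws a random graph of the requested density, gives
each edge a uniform weight with random sign, and builds the precision
matrix with unit diagonal; if indefinite, weights are shrunk by a fixed
factor (0.9) until positive definite, so the stored partials always match
the implied `sigma`.  `sampleOrdinalCohort()` then draws each patient's
latent 12-vector from the baseline `sigma`; the end-point latent reuses the
same standard-normal noise with weight `rho` (the cross-occasion
correlation, default 0.3 — moderate within-patient trait stability) plus
fresh noise, mapped through the end-point structure.  Scores are obtained
by thresholding each latent against per-item cutpoints.

Cutpoints are equally spaced (0.8 latent SD apart) and shifted per item so
the implied ordinal mean matches a reference profile typical of a severe
community cohort at entry; improvement is a per-item *latent mean shift*
calibrated the same way against the end-point profile, so the network
structure — not the thresholds — carries the occasion difference.  Delays
are normal (defaults: mean 462.1, SD 170.3 days) truncated at one day.
Age and gender are drawn independently of everything, which makes them
genuine null predictors for the logistic arm.  The default study-like
cohort (`simulateDefaultCohort()`) uses a sparse baseline truth (density
0.08, about 5 of 66 possible edges) and a denser end-point truth (0.30,
about 20 edges) with absolute weights 0.2–0.35 — the qualitative regime of
a symptom network that tightens over treatment, with the baseline network
"scarce" at a handful of edges.  One R RNG stream is seeded per generator
call; the same seed always reproduces the same cohort, which is the
reproducibility regression tests rely on.

### What the generator does and does not emulate

It emulates: paired five-point ordinal items with realistic skewed
marginals, a latent sparse partial-correlation structure, within-patient
dependence across occasions, item-wise improvement, and dispersed
follow-up delays.  It does **not** emulate diagnosis mixtures, rater
effects, informative dropout, floor effects beyond what thresholding
produces, or any true dependence of scores on delay (delays are drawn
independently).  Passing recovery tests therefore show that the estimation
machinery works when the data-generating assumptions hold; they do not
certify behaviour under clinical messiness.

Two quantitative caveats discovered with this generator are worth stating
because they are properties of the *method*, not of the code:

* **Discretization bias.**  SKEPTIC is consistent for continuous
  nonparanormal data, but 5-category scores are not a monotone transform
  of the latent variable.  The resulting small systematic distortion of
  the correlation matrix is invisible at n ≈ 137 but detectable by BIC at
  n = 1000, where it adds spurious weak edges: with continuous latent data
  the false-positive edge rate in our recovery setting is ≈ 0.15, with
  ordinal data ≈ 0.2–0.3.  Polychoric/latent-threshold correlations would
  remove this bias but are outside this pipeline's scope.
* **Residualizing ordinal scores on a shared covariate.**  OLS residuals
  of a discrete score on a continuous delay break score ties *in the same
  order for every item* (the order induced by delay).  A rank-based
  correlation then converts formerly neutral tied pairs into systematically
  concordant or discordant ones, inflating tau between all item pairs.
  Recovery of generative structure is therefore evaluated on the score
  matrices themselves; in the pipeline proper, residualization is applied
  to both occasions identically, so the between-occasion *comparison*
  (the NCT) remains calibrated — which the test suite checks directly.

## Numerical and design choices

* Glasso convergence: duality gap below 1e-6, coordinate-descent sweeps
  capped at 1000; non-convergence is an error, not a warning.
* Edge-count monotonicity along the path is checked per run; the rare
  glasso non-monotonicities are logged as messages, not fatal.
* Constant columns: correlations set to 0 with a warning; constant-item
  residuals are all zero.
* Degenerate all-zero networks: node-strength z-scores are `NA` with a
  warning; closeness/betweenness return zeros; stability correlations for
  degenerate subsamples are recorded as 0 (maximally pessimistic).
* The Wilcoxon exact/approximate switch is at 25 effective pairs;
  `exactLimit` is an argument, so the choice is auditable.
* The severity filter requires at least 13 analysable patients — the
  minimum for the widest (70%) case-drop to remain estimable.

## Problem sizes used in the shipped checks

The package's own validation uses reduced but fixed simulation sizes,
chosen so the full suite runs comfortably on a laptop core: NCT type-I
calibration with 200 replicates of n = 100 per group and 200 permutations
(nominal 5% level, accepted band 2–10%); Wilcoxon type-I calibration with
2000 replicates at n = 137 (band 3–7%); edge recovery at n = 1000 over 20
seeds; NCT power against a dense alternative (density 0.4, weights ≥ 0.3,
n = 300) over 50 replicates; and the sparse-baseline/dense-endpoint
contrast at n = 137 over 20 seeds with 200 permutations.  The
`scripts/acceptance.R` entry point runs the full pipeline once at the
study scale (248 screened patients, 1000 NCT permutations, 250 bootstrap
subsamples per drop proportion).

## Known limitations

* Ordinal items are treated as opaque 0–4 variables; no HoNOS glossary
  semantics, no item-level missingness imputation (complete-case only).
* Only the global-strength NCT is provided, not the fuller family of
  edge-wise or invariance permutation tests.
* No temporal or directed network models; the two occasions are two
  cross-sections.
* The logistic arm offers no ordinal/proportional-odds alternative.
* The generator's end-point marginal targets are applied through latent
  shifts before residualization; the post-residualization marginals are
  therefore approximate, which is intrinsic to encoding improvement on the
  latent scale.
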