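# honosnet

Paired HoNOS outcome analysis for mental-health services: individual item
scores and symptom networks.

## The problem

Community mental-health teams rate patients on the **Health of the Nation
Outcome Scales (HoNOS)** — 12 clinician-rated items (agitation, self-harm,
substance use, cognition, physical health, psychosis, depressed mood, other
symptoms, relationships, daily living, living conditions, occupation), each
scored 0–4.  Given one rating at entry and one about a year later,
`honosnet` answers two questions:

1. **Individual scores** — did each item improve (paired Wilcoxon
   signed-rank tests), how many patients reached *treatment response*
   (an end-point profile with no item ≥ 3), and does anything at baseline
   predict response (logistic regression on baseline items, age, gender)?
2. **Symptom networks** — did the interplay between symptoms change?  Each
   occasion is modelled as a Gaussian graphical model whose edges are
   partial correlations: scores are residualized on the between-rating
   delay, correlations estimated by the nonparanormal SKEPTIC transform
   `r = sin(pi/2 * tau_b)`, a sparse precision matrix fit by the graphical
   lasso along a 100-point penalty path, and the model selected by the
   extended Bayesian information criterion
   `EBIC = -2L + E log n + 4 E gamma log p` (pipeline preset `gamma = 0`,
   i.e. ordinary BIC).  Occasions are compared by a permutation **network
   comparison test** on global strength (the sum of absolute edge
   weights), and node-strength centrality is vetted by case-drop bootstrap
   stability (CS-coefficient, interpretable when ≥ 0.25).

A latent Gaussian copula simulator with known ground-truth networks
(`makeTrueNetwork()`, `sampleOrdinalCohort()`) makes every stage testable
without clinical data.

## Worked example

```r
library(honosnet)

sim  <- simulateDefaultCohort(n = 137, seed = 7)   # sparse baseline truth,
cohort <- filterBaselineSevere(sim$cohort)$cohort  # denser endpoint truth
cohort
#> HonosCohort: 101 patients x 12 items (paired baseline/endpoint)
#>   delay_days: mean 484.0, sd 166.8
#>   severe at baseline: 101/101

responseProportion(cohort)$proportion
#> [1] 0.5445545

d  <- delayDays(cohort)
rb <- residualizeOnDelay(baselineScores(cohort), d)
re <- residualizeOnDelay(endpointScores(cohort), d)
estimateNetwork(rb)$network
#> WeightedNetwork: 12 nodes, 4 edges, global strength 0.279
estimateNetwork(re)$network
#> WeightedNetwork: 12 nodes, 45 edges, global strength 6.420

nctGlobalStrength(rb, re, nPermutations = 1000, seed = 7)
#> NCT (global strength): observed |diff| = 6.1405, p = 0.0010 (1000 permutations)

casedropStability(re, nBoots = 250, seed = 7)
#> Case-drop stability (strength): CS = 0.10 (threshold 0.25) -> NOT interpretable
```

Read as: after restricting to patients severe at baseline, 54% responded;
the baseline network is scarce (4 edges) while the end-point network is
much more strongly connected (global strength 6.42 vs 0.28), and the
permutation test calls that difference significant (p = 0.001).  At this
cohort size the end-point strength ordering is not yet stable (CS = 0.10,
below the 0.25 interpretability bar), so individual node rankings from a
single run of this size should be read with caution.

`runFullAnalysis(analysisConfig(...))` chains all stages (severity filter →
individual scores → residualization → per-occasion networks → NCT →
centrality + stability) and writes `report.json` plus per-stage CSVs; a
thin CLI with `simulate`/`scores`/`network`/`compare`/`centrality`/
`stability`/`run` subcommands lives in `inst/scripts/honosnet-cli.R`.

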