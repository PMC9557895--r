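---
title: "Distribution-matched negative controls for GRS-by-environment interaction"
author: "grsInteract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-matched negative controls for GRS-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsInteract)
```

## The problem

A recurring claim in obesity epidemiology is that depression *accentuates*
genetic susceptibility to high BMI: a weighted BMI genetic risk score (GRS)
appears to have a steeper slope in depression cases than in controls, i.e. a
positive GRS-by-depression interaction. The difficulty is that depression
cases also have a higher BMI **mean and standard deviation** than controls.
Whenever the outcome's conditional variance grows with its mean — which it
does for BMI, a right-skewed trait plausibly generated on a multiplicative
scale — any selection of a group with a larger outcome SD mechanically
inflates the within-group regression slope of every predictor of the
outcome. An "interaction" estimated by comparing slopes across such groups
may therefore be a scale artefact, not effect modification.

grsInteract implements the analysis pipeline around a *negative-control
experiment* that separates the two explanations: repeatedly select pairs of
disjoint pseudo-exposure groups from the full sample, **matched to the real
groups' outcome mean and SD but random with respect to everything else**,
refit the identical interaction model with pseudo-group membership as the
exposure, and ask where the observed interaction P-value falls in this
replicate distribution. If the artefact alone drives the result, random
moment-matched groups reproduce it; if the interaction is real, they do not.

## Models

The interaction model is ordinary least squares on the pooled sample,

$$ y_i = \beta_0 + \beta_G G_i + \beta_E E_i + \beta_{GE}\, G_i E_i +
   \boldsymbol{\gamma}^\top \mathbf{c}_i + \varepsilon_i, $$

with \(y\) the (by default inverse-normalized) BMI, \(G\) the allele-count
scale GRS, \(E\) a binary exposure and \(\mathbf{c}\) covariates.
`fitInteractionModel()` reports \(\hat\beta_{GE}\), its SE and two-sided P
(normal approximation; the exact t distribution when the residual df fall
below 200), along with per-stratum per-allele slopes and, optionally, the
exposure contrast in raw kg/m² within the bottom and top GRS decile. The
Keller sensitivity variant (`keller = TRUE`) adds every covariate-by-exposure
and covariate-by-genetic product, so confounded interactions cannot
masquerade as the G×E term. Decile contrasts are reported on the raw BMI
scale (kg/m², the interpretable scale) while interaction P-values use the
transformed outcome; both scales are explicit in the result metadata, and a
flag disables covariate adjustment of the contrasts since either convention
is defensible.

The GRS follows the standard weighted construction: after recoding every
variant to its trait-increasing allele (negative weight ⇒ negate the weight,
replace dosage by \(2-d\), swap allele labels), the weighted score
\(\sum_j \beta_j d_{ij}\) is rescaled by \(M/\sum_j\beta_j\) so that the
score reads as a number of trait-increasing alleles (range \(0\) to \(2M\)).
The printed definition of this rescale in the source literature is ambiguous
between dividing by \(\sum\beta\) and multiplying by \(M/\sum\beta\); the two
differ by the constant \(M\) and cannot change any regression P-value, so we
default to the allele-count scale (which makes "per 10 alleles" statements
meaningful) and expose `rescale = "sumBeta"` for the alternative. Missing
dosages are mean-imputed at \(2\times\)EAF with a per-variant missingness
report — the standard GRS practice that keeps the analysis N constant —
and individuals missing every dosage are flagged NA.

### Inverse normal transformation

`inverseNormalTransform()` maps ranks through
\(\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)\) (Blom offset). The offset is
configurable but 3/8 is the GWAS-standard choice; ties take the average rank
so the transform is deterministic, and the transform is applied once to the
assembled analysis sample rather than per stratum — it models a single
pre-analysis transformation step. For \(n \ge 200\) distinct values the
output has mean \(\approx 0\) and SD within \([0.95, 1.05]\).

## The negative-control engine

`selectMatchedGroup()` finds an \(n\)-subset of the pool whose sample mean
and SD are each within a tolerance (default 0.05, operationalizing matching
"to one decimal place") of the targets, by random-restart swap descent on
the loss \((\bar x - \mu^\ast)^2 + (s - \sigma^\ast)^2\): start from a
random subset, propose random member/non-member swaps, accept improvements,
stop at tolerance. Only the achieved moments matter to the downstream
statistics, so the simplest reproducible optimizer is preferred; swaps
update the running sums in \(O(1)\) and the search is implemented in C++.
Infeasible targets (e.g. a mean outside the pool range, or group sizes so
large the pool cannot be reshaped) raise a typed error carrying the
best-achieved moments — the same failure mode a large cohort's control group
produces in practice, which is reported rather than papered over.

`runNegativeExperiments()` draws group 1 (size and targets of the real
exposed group) from the **full** analysis pool, then group 2 from the
remainder, fits the same interaction model with pseudo-exposure membership,
and repeats R times (1000 in the original design; scaled-down runs are
configurable). Notable conventions, each of which the engine exposes as a
flag because the original description is silent:

* failed selections are redrawn so exactly R converged replicates are
  reported (`strictR = TRUE`); with `strictR = FALSE` they are logged and
  excluded. More than 50% failures aborts with an infeasibility summary.
* replicate models reuse the full covariate set of the observed model
  (`replicateCovariates = FALSE` drops them).
* the empirical P is the plain proportion of replicates with interaction P
  **strictly below** the observed one — `empiricalP(67, 1000) = 0.067` — with
  no \((k+1)/(R+1)\) correction, because published count/proportion pairs
  imply the plain ratio.
* the reported "median analysis" is the replicate holding the middle order
  statistic of the replicate P-values; for an even count the lower of the
  two middle replicates (a deterministic tie rule).

When the group sizes exhaust the pool (\(n_1 + n_2 = N\), the usual
whole-cohort setting), group 2 is the forced complement of group 1; its
moments then match automatically up to a factor \(n_1/n_2\) of group 1's
matching error, because total sums and sums of squares are fixed. The
one-group selector API is retained because sub-sampled pools
(\(n_1 + n_2 < N\)) are also supported.

`simulateGroupsFromSummary()` covers the case where only published group
sizes and moments are available: replicate outcomes are drawn from the two
normal distributions, genotypes independently of group, giving both a
type-I calibration of the interaction test and an empirical reference
distribution for a published P-value.

## The synthetic cohort generator

Real individual-level data for this design are access-restricted, so
`simulateCohort()` generates cohorts with the statistical structure the
analysis assumes, and the defaults are the study conditions used throughout
the package's tests:

| parameter | default | meaning |
|---|---|---|
| `n_individuals`, `n_variants` | 10000, 73 | cohort and panel size |
| `allele_freq_range` | (0.05, 0.95) | effect-allele frequencies, HWE dosages |
| `weight_scale` | 0.03 | mean per-allele effect (SD units); gives the GRS a realistic ~2–3% of outcome variance |
| `bmi_mean`, `bmi_sd` | 27, 4.5 kg/m² | marginal BMI moments |
| `noise_model` | additive_normal | or multiplicative_lognormal (mean–variance coupling) |
| `exposure_prevalence` | 0.24 | case fraction |
| `exposure_bmi_shift` | 0.6 kg/m² | target case − control mean BMI |
| `exposure_bmi_scale` | 1.16 | target case/control BMI SD ratio |
| `true_interaction` | 0 | per-allele × exposure effect, inverse-normal scale |
| `severity_max`, `treated_fraction_in_cases` | 8, 0.5 | severity score range; treatment prevalence in cases |

The exposure defaults mirror the moment structure reported for major
depression in a large population cohort (cases ≈ 27.2 (5.1) vs controls
≈ 26.6 (4.4) kg/m²). Case status is sampled **conditional on BMI** — the
direction real ascertainment works — via a logistic-quadratic selection
function \(P(E=1\mid b) = \mathrm{logit}^{-1}(a + cz + dz^2)\), the exact
posterior form of a two-component normal mixture. The component moments are
solved from (prevalence, shift, scale) and the marginal moments, and the
three coefficients are then polished numerically against the empirical BMI
sample (Nelder–Mead on the squared moment deviations), because the marginal
is not literally that mixture; at \(n = 10^5\) the realized shift is within
±0.1 of target. Severity (cases only) is binomial with a BMI-increasing
success probability, so the severity median split shows the expected BMI
gradient; covariates (age, sex, centre, TDI, 5 PCs, array) are independent
of genotype and exposure unless the explicit confounding switches are set.
A planted interaction is added after exposure assignment as
\(\text{bmi} \mathrel{+}= \text{bmi\_sd}\cdot\gamma\cdot E\cdot(G - E[G])\)
on the same allele-count genetic scale the model tests (exposure-first
generation is impossible when case status is outcome-conditional).

What the generator deliberately does **not** emulate: linkage
disequilibrium between variants, imputation uncertainty, population
stratification, non-normal covariate structure, and longitudinal drift
between phenotype and exposure measurement. Passing tests therefore show
the statistical machinery behaves correctly under the assumed generative
structure, not that any particular real-data finding is right.

## Numerical choices and problem sizes

* All fits run through one QR-based least-squares engine with a rank check
  that names aliased columns; P-values switch from the normal approximation
  to the exact t below 200 residual df. Equivalence to an explicit
  normal-equations oracle is tested to 1e-8 relative error.
* Deciles use stable ranks with ties broken by input (id) order; decile 1 is
  the lowest risk tenth.
* One integer master seed per simulated cohort; sub-streams (variants, BMI,
  exposures, covariates) derive from it by fixed offsets, and
  negative-control replicate r seeds as `seed + attempt`, so reruns are
  byte-identical and replicate-level parallelism could not reorder results.
* Simulation-based checks use desk-scale sizes chosen for statistical
  power rather than realism: type-I calibration at n = 5000 over 1000
  cohorts; planted-effect recovery (γ = 0.05) at n = 20000 over 200
  cohorts; artefact reproduction at n = 10000 over 500 cohorts (at this size
  the naive raw-scale test rejects ≈ 18% of the time at α = 0.05, so the
  above-nominal property is tested with essentially full power; the
  original cohort is another order of magnitude larger); negative-control
  de-inflation/preservation at n = 4000 with R = 200 replicates over 50
  pipeline repetitions — those properties concern the rank of the observed
  P among moment-matched replicates and are insensitive to scale. The
  planted-interaction preservation scenario uses γ = 0.08 at n = 4000,
  sized by power arithmetic (interaction t ≈ γ·sd(G)·√(nπ(1−π)) ≈ 6) so a
  real signal is unambiguous at simulation scale.

## A worked run

```{r example, eval = FALSE}
cfg <- simConfig(n_individuals = 4000, n_variants = 20, seed = 7,
                 noise_model = "multiplicative_lognormal",
                 exposure_bmi_shift = 0.7, exposure_bmi_scale = 1.15)
cohort <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
fit <- fitInteractionModel(cohort, outcome = "bmi_raw",
                           decileContrasts = TRUE)
neg <- runNegativeExperiments(cohort, outcome = "bmi_raw",
                              R = 200, seed = 7, observedP = fit@pInt)
fit
neg
hist <- negControlHistogram(neg)   # -log10 P bins for the standard figure
```

Here the cohort has **no** generative interaction; any small observed
interaction P comes from the mean–variance artefact, and `neg@empiricalP`
is typically far above 0.05 — the negative control correctly attributes the
signal to the BMI distributions. Rerun with `true_interaction = 0.08` and
`outcome = "bmi_int"` and the empirical P collapses toward 0: real signal
survives matching.

## Limitations

* The matching loss targets mean and SD only, as in the original design;
  higher moments of the outcome distribution are uncontrolled
  (`Non-goal`: no full-shape or covariate matching).
* Swap descent is a heuristic: convergence failure proves nothing about
  strict infeasibility, although the returned best-achieved moments make
  the failure interpretable.
* The empirical P has resolution 1/R and, as a plain proportion, can be
  exactly 0; users comparing empirical Ps across exposures should use equal
  R.
* OLS with homoscedastic SEs is the deliberate match to the published
  analysis; robust/sandwich variants would partially absorb the very
  artefact the negative controls are designed to expose, so they are out of
  scope here.
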