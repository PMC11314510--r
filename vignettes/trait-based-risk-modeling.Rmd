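---
title: "Trait-based extinction-risk modeling and Data Deficient triage for mosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based extinction-risk modeling and Data Deficient triage for mosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossrisk)
```

## The problem

Only a few hundred of the world's roughly 13,000 moss species have a global
IUCN Red List assessment, and many of the assessed ones are Data Deficient
(DD). Functional traits — characteristics of reproduction and
ecophysiology that are routinely recorded in taxonomic descriptions — carry
information about a species' capacity to disperse and persist, and can
therefore stand in as predictors of threat status where a full assessment
is missing. mossrisk implements a complete trait-to-verdict pipeline:

1. a species × trait matrix with IUCN status binarization,
   empty-cell-as-absence imputation for binary traits and z-scaling of
   continuous traits (`trait_matrix`, `read_trait_matrix`, `zscale`);
2. univariate logistic screening of each trait against binary threat
   status, plus trait–trait association checks (`screen_traits`,
   `screen_trait_pairs`);
3. construction of two maximal models and reduction to minimum adequate
   models (MAMs) by forward stepwise AIC (`build_maximal_models`,
   `stepwise_forward_aic`);
4. ROC-based classification cutoffs chosen with the Index of Union
   criterion under a sensitivity-priority override (`roc_curve`,
   `index_of_union`, `select_cutoff`);
5. risk scoring and triage of DD species into Threatened / Possibly
   Threatened / Non-threatened verdicts (`score_mam1`, `score_mam2`,
   `triage_dd`).

A synthetic-cohort generator (`generate_cohort`) provides matrices with
known risk structure so every stage is testable without any download.

## The model

Threat status is binarized: EX, CR, EN and VU count as threatened (1); NT
and LC as non-threatened (0); DD species are held out as the prediction
set. Each model is a binary logistic GLM,

$$\operatorname{logit} \Pr(\text{threatened}) = \beta_0 + \sum_j \beta_j x_j,$$

with continuous predictors entered as z-scores so coefficients are
per-SD effects. Two models are kept because sporophyte morphology
(capsule, seta and spore traits) can only be recorded for
sporophyte-bearing specimens:

* **MAM1** uses traits observable for every species — plant sex,
  sporophyte presence and substrate breadth (the count of distinct
  substrate types occupied, equally weighted).
* **MAM2** uses sporophyte morphology — seta length — together with
  substrate breadth, and applies only to species with recorded
  sporophyte traits.

Complete cases are recomputed per model, which is why the two models fit
on different n from the same matrix. The published parameter sets shipped
with the package (`mam_published_params()`) are

| model | intercept | coefficients | scaling | cutoff |
|---|---|---|---|---|
| MAM1 | −0.79 | monoicous +0.54; sporophyte present −1.18; breadth −0.83/SD | breadth (1.69, 0.94) | 0.21 |
| MAM2 | −1.65 | seta −0.61/SD; breadth −0.90/SD | seta (14, 13.32) mm; breadth (1.8, 0.98) | 0.18 |

Evaluated at the scaling means, MAM1 gives a 31% risk for a dioicous
species without sporophytes, 44% for a monoicous one, and 12% / 19% with
sporophytes present; one SD more substrate breadth divides the risk by
1.9. MAM2's baseline evaluates to 0.161 from these (2-decimal) printed
coefficients, falling by 1.7-fold per seta-length SD and 2.2-fold per
breadth SD. These same numbers come out of `score_mam1()` /
`score_mam2()` and are asserted by the test suite.

## Cutoffs: Index of Union with a sensitivity override

The fitted risk is continuous; a cutoff turns it into a binary call with
the rule risk ≥ cutoff ⇒ threatened (boundary inclusive). Candidate
cutoffs are the observed score values (plus 0 and 1), which keeps the
ranking finite and makes "the third-best cutoff" well defined. The Index
of Union criterion ranks cutoffs by

$$IU(c) = |Se(c) - AUC| + |Sp(c) - AUC|,$$

ties broken by smaller \|Se − Sp\|, then by lower threshold. Because the
models exist to *find* threatened species, sensitivity takes priority
over specificity: `select_cutoff()` walks down the IU ranking and
returns the first cutoff with sensitivity ≥ 0.70 (the default
`min_sensitivity`). When the IU optimum already qualifies it is kept
unchanged; when nothing qualifies, the optimum is returned with a
warning.

## The verdict rule

Each DD species is scored by MAM1 and, when sporophyte traits are
recorded, also by MAM2. Verdicts combine the per-model classes: both
threatened → **Threatened**; both non-threatened → **Non-threatened**;
disagreement → **Possibly Threatened**; a single available model decides
alone. On the packaged 44-species DD reference table this reproduces 24 /
13 / 7:

```{r triage}
report <- triage_dd()
report
```

## The synthetic cohort

`generate_cohort()` draws matrices from the structure the analysis
assumes, with defaults chosen to emulate the study cohort:

* 723 species, threatened prevalence ≈ 22% (baseline logit −0.79 plus
  the published MAM coefficients as the generating truth);
* plant sex Bernoulli (monoicy 0.40); vegetative reproduction and
  sporophyte presence drawn conditionally on sex via closed-form 2×2
  solutions for a given marginal and odds ratio (defaults: dioicous
  species reproduce vegetatively more often, odds ratio 0.5; monoicous
  species bear sporophytes more often, odds ratio 2.0);
* lengths log-normal with the stated raw-scale moments (seta 14 ± 13.32
  mm implies strong right skew, which log-normality respects); substrate
  breadth 1 + Poisson with mean 1.8 (SD ≈ 0.89, close to the published
  0.94–0.98);
* seta shape logistic on log seta length (default: odds of a curved seta
  double per unit log-length, the direction a seta bending under its
  capsule suggests);
* sporophyte morphology structurally missing for sporophyte-lacking
  species, plus a 4% random masking block, and 3.2% missing substrate
  data — reproducing ~700 species usable for MAM1 and ~540 for MAM2 out
  of 723.

Marginal frequencies of monoicy and vegetative reproduction are not
published for the study cohort; the defaults above are the package's own
choices of realistic values, fixed once. The generator uses one seeded
stream with a fixed, documented draw order (sex, vegetative, sporophyte,
lengths, breadth, shape traits, threat, masking), which gives bit-identical
matrices per seed; the caller's RNG state is restored afterwards.

The generator deliberately omits phylogenetic structure: related species
share trait values in real data, so real-data errors are correlated in a
way the simulation does not reproduce. Passing parameter-recovery and
calibration tests on these cohorts therefore validates the machinery, not
the field accuracy of any particular fitted model.

## Numerical choices

* Logistic fits are maximum likelihood via iteratively reweighted least
  squares, convergence at relative log-likelihood change < 10⁻⁸, max 100
  iterations. Complete separation surfaces as a typed error
  (`mossrisk_separation`) rather than divergent estimates; during
  stepwise selection a separating candidate is skipped with a warning.
* Confidence intervals are Wald (symmetric estimate ± z·SE), matching the
  ± half-width reporting convention of the published tables.
* z-scaling uses the sample SD (n − 1); DD records never contribute to
  estimated scaling parameters, since they are the prediction set.
* Range-valued continuous cells ("4–8") are stored as the midpoint — the
  only parameter-free reading of a printed range.
* Pearson's χ² is computed without continuity correction.
* Forward stepwise selection adds a candidate on any strict AIC
  improvement (no ΔAIC threshold), with ties broken by registry order for
  determinism. Forward-only search is the default and only mode; an
  exhaustive-subset search exists in the test suite as an oracle, not as
  a selection path. Note a known property of forward-AIC: a null
  candidate is admitted with probability P(χ²₁ > 2) ≈ 0.16, so selected
  sets may carry an occasional noise predictor; the tests assert
  containment of true predictors and the greedy bound, not exact-set
  recovery.
* AUC is the trapezoid over (1 − Sp, Se) anchored at (0,0) and (1,1),
  which equals pairwise concordance with ties counted ½ (asserted to
  10⁻¹² in the tests).
* Substrate breadth is required by both models; species without it are
  unscoreable and land in the triage exclusion list, never at risk 0.

## Problem sizes used in the tests

The simulation-backed properties run at sizes chosen to give stable
Monte-Carlo answers while keeping the default suite quick: CI coverage
over 200 cohorts of n = 2,000; χ² power over 200 cohorts of n = 2,000;
AUC/concordance identity over 100 random score sets; the greedy AIC bound
over 100 cohorts of n = 120 with 5 candidates; screening calibration over
60 cohorts of n = 300. Fixture metadata: the source cohort is described
as 723 species with 162 threatened and 567 non-threatened (which sum to
729; both printed numbers are recorded here without reconciliation).

## Known limitations

* The two published categorical contrast sets beyond plant sex (capsule
  shape, spore shape/ornamentation groupings) are not published in the
  available material; the registry ships plausible two-level groupings,
  which matters only for simulated categorical traits, none of which
  enter the published MAMs.
* Verdicts are a triage signal, not an assessment: with cutoff
  sensitivities near 0.75 and specificities near 0.5–0.6, false positives
  are accepted by design so that few truly threatened species are missed.
* MAM2's published baseline is stated as 17% in prose but evaluates to
  16.1% from the printed 2-decimal coefficients; the package evaluates
  the equation and does not force the prose value.
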