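---
title: "Couple-level IPV classification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Couple-level IPV classification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipvdyad)
```

## The measurement model

`ipvdyad` scores dyadic survey records from a two-informant partner
maltreatment instrument into a couple-level IPV taxonomy. The instrument
has two sections.

**Physical section.** Each respondent answers act-frequency items twice —
once for acts they committed ("perpetration") and once for acts committed
against them ("victimization") — on the ordinal scale *never / once /
twice / 3–5 times / 6 times or more*. The default registry holds 13 acts
(12 named plus a human-coded write-in "other"); any act reported above
*never* triggers injury follow-ups over six impact kinds (fear for own
safety, pain lasting at least 4 hours, graze or wound, bruise or welt,
sprain or fracture, fainting).

**Psychological section (victimization only).** Screener items ask about
significant depression, stress, or fear caused by the partner's behavior;
nine coercive or denigrating acts are rated on the same frequency scale;
respondents who endorse acts are asked whether those acts caused or
contributed to the screened impacts, and two further impact lists cover
safety fears and fear-driven interference with five major life areas.

The registries are arguments everywhere (`fm_physical_acts()`,
`fm_psych_acts()`), so instrument dialects with additional items — some
deployments describe 15 physical and 10 psychological acts — can extend
them without code changes; the defaults are the items the analysis
actually tabulates.

## Couple-level scoring

Three rules turn two individual reports into one couple record:

1. **Union rule.** In a given direction (woman→partner or
   partner→woman) an act occurs if either the perpetrator's self-report
   or the victim's report endorses it; the couple-level frequency is the
   maximum of the two ordinal categories. This deliberately counts a
   concordantly reported act once and accepts the empirical finding that
   individual informants under-report: the union is an upper envelope of
   the two single-informant views.
2. **Severity.** Per direction, physical IPV is clinically significant
   (CS) if any injury impact is reported for an occurring act, if an
   occurring act is inherently dangerous, or if the victim reports fear
   for their own safety. Acts without any such impact are low impact
   (LI). Psychological CS status is evaluated per victim, solely from the
   victim's own report: at least one endorsed act *and* at least one
   impact clause (attribution to screened impacts, safety fears, or life
   interference).
3. **Taxonomy.** Each couple with at least one report receives exactly
   one of six mutually exclusive labels: `NO_IPV`, `LI_PHY_ONLY`,
   `CS_PHY_ONLY`, `CS_PSY_ONLY`, `CS_PSY_AND_LI_PHY`,
   `CS_PSY_AND_CS_PHY`. The definitions are exhaustive and mutually
   exclusive by construction, so "most severe applicable category" needs
   no extra precedence rule. Overlap rollups (any IPV, any physical, CS
   physical, CS psychological) are sums of category counts.

### Direction, repetition and the fear clause

One-way direction labels are named by the perpetrator:
`WOMAN_TO_PARTNER` means the partner is the victim. A type is
bidirectional iff both directions are positive at the relevant severity.
Direction denominators follow the taxonomy: the LI direction table is
computed over couples whose category involves LI physical IPV (the
LI-only and CS-psych-with-LI categories), the CS-physical table over the
two CS-physical categories, and the psychological table over the three
CS-psychological categories. This is what makes the direction-table
denominators equal the corresponding rollup counts.

Two impact-attribution choices were genuinely open and are resolved as
follows. The *fear-for-own-safety* impact counts toward physical CS only
when the victim reports it — fear is the victim's experience, and
accepting a perpetrator's claim that the victim was afraid would let one
informant assert the other's mental state. All other injury impacts
follow the union rule and count from either informant, including a
perpetrator's self-reported infliction of injury when the victim's report
is missing; this mirrors the occurrence union and keeps single-report
couples scorable.

*Repetition* ("more than one act per partner in the year") is computed
from the couple-level union: a couple is repeated for a type if some
perpetrator's total act count is at least 2, where each frequency
category contributes its minimum count (0, 1, 2, 3, 6). Using category
minima is conservative — a "3–5 times" answer counts as 3 — and makes the
repeated flag a lower bound; no midpoint convention is assumed.
Psychological repetition is only defined for CS-positive victims, because
the instrument only collects behavioral frequency after an impact is
endorsed.

## Aggregation choices

* **Rounding.** All percentages are `100·n/denominator` rounded half away
  from zero to one decimal (`round_half_up()`), not banker's rounding.
* **Chi-squared comparisons.** Victimization rates are compared with a
  Pearson chi-squared on the 2×2 of two independent counts over the type
  denominator, without continuity correction by default (a Yates flag is
  exposed); α = 0.05, two-sided. A degenerate table with identical
  proportions short-circuits to p = 1 rather than relying on the test's
  behavior at zero expected discrepancy.
* **Masking.** Rendered tables suppress small cells: 0 prints as `-`,
  counts below the threshold (default 3) as `<3`. Masking is purely a
  rendering layer; every unmasked count remains available in the result
  objects, so conservation invariants stay checkable.
* **Missingness.** Couples with no non-missing report cannot be
  classified; they are excluded from the analysis denominator but
  counted, and `missingness_bound()` computes worst-case prevalence under
  the extreme assumption that some or all unobserved couples are
  positive. The bound is a plain ratio over a caller-chosen denominator
  because more than one worst-case formulation is defensible (all
  both-missing couples positive; additionally all one-report couples
  positive); the function supports any of them and blesses none.
* **Concordance** is computed among dual-report couples only, as percent
  agreement of the two informants' any-occurrence indicators per
  direction. Kappa is deliberately not reported: with prevalence around
  15% the marginal-chance correction is unstable and percent agreement is
  the quantity of record here.

## The synthetic generator

`generator_config()` defaults encode the reference study conditions:
1,781 enrolled couples; latent category probabilities equal to the
observed category frequencies over 1,726 reporting couples; direction
mixtures per type at the observed splits; both-missing probability
55/1781 and one-missing 110/1781 (85:25 partner-missing to
woman-missing); perfect reporters unless degraded. Where the underlying
distributions are not observable from published marginals — true act
frequencies, act identities, impact composition — the defaults are a
single realistic choice, made once: one act per positive direction,
frequency uniform over the four non-never categories, injury impacts
weighted toward bruises/grazes/pain as in observed impact tables.

Truth is generated couple-first (category, then direction, then realized
acts and impacts), which guarantees classifier consistency: with
sensitivity and specificity 1 and no missingness, `classify_couples()`
recovers every couple's latent category, direction labels and repetition
flags exactly. `degrade_records()` then models reporting error at the
item level: true items survive with probability *sensitivity* per
informant, never-items flip on with probability *1 − specificity*, and
impact reports are only ever degraded off, never invented. Silencing an
act clears its injury follow-up and an attribution flag cannot outlive
its last act, so degraded records always re-validate. Under this model
the couple-level union detects a true one-way act with probability
1 − (1 − s)², the closed form the property tests check.

`exact_count_records()` is the deterministic companion: a quota-built
cohort whose classification marginals equal the reference cohort's
printed counts exactly (categories, direction splits, repetition rates,
missingness pattern, one-report-subsample prevalence). Its act-level
composition is intentionally minimal — physical IPV realized as
pushing/shoving, CS impacts as bruises, psychological CS as insults
attributed to screened stress — because the fixture pins couple-level
marginals, not per-act rows.

**What passing tests do and do not show.** The generator emulates
marginal structure, reporter error and missingness; it does not model
demographic covariates, within-couple correlation of reporting error,
longitudinal dynamics, or the selection processes that shape who enrolls
and who responds. Tests passing on synthetic data therefore validate the
scoring and aggregation logic, not the instrument's validity or the
transportability of any prevalence estimate to other populations.

## Numerical and degenerate-input conventions

* Frequency ties under the union resolve to the maximum by the ordinal
  coding; the reduction is written to return *never* on an empty set so
  zero-group edge cases are well-defined.
* Empty direction tables (no type-positive couples) render as headers
  with no division by zero; concordance over zero dual-report couples
  returns `NA` agreement.
* Validation (`validate_fm()`) returns violations as data rather than
  raising, so a pipeline can log and continue (`strict = FALSE`);
  `run_ipv_pipeline()` defaults to failing fast.
* All randomness flows through a single seed; identical configuration
  and seed give byte-identical pipeline outputs.

## Problem sizes used by the test suite

The packaged checks run the exact-count cohort (1,781 couples), a closed
enumeration of ~450 single-couple configurations against a brute-force
evaluator of the six definitions, partition/conservation invariants on a
10,000-couple random draw, mixture recovery on a noiseless
100,000-couple draw (within 3 binomial standard errors), and
misclassification simulations of a few thousand couples — sizes chosen so
the full suite completes in well under a minute while keeping Monte Carlo
error far below the tolerances being asserted.

## Known limitations

Sexual IPV is not part of the instrument section this package scores.
Psychological perpetration self-reports are collected by some instrument
dialects but never scored (victim-report-only by design). No
multiple-testing correction is applied to the per-act chi-squared
comparisons, matching the descriptive intent of the tables; users making
confirmatory claims should adjust. Prevalence adjustment beyond
worst-case bounds (e.g. capture–recapture on the two informants) is out
of scope.
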