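---
title: "Methods: scoring and evaluating a brief cognitive screen for HAND"
author: "handscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and evaluating a brief cognitive screen for HAND}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handscreen)
```

## The problem

Mild forms of HIV-associated neurocognitive disorder (HAND) — asymptomatic
neurocognitive impairment (ANI) and mild neurocognitive disorder (MND) —
are common in treated, virally suppressed HIV-infected adults, yet they are
poorly detected both by dementia-oriented screens and by patients' own
reports: self-perceived cognition is miscalibrated in this population, and
a majority of patients with objective impairment do not complain. A
practical response is a brief, nurse-administered battery of standardized
tests plus a complaint questionnaire, validated against a full
neuropsychological examination. This package implements such a battery's
scoring rules and its diagnostic-accuracy evaluation end to end.

## The scoring model

**Tests and norms.** Seven brief tests are administered: Trail Making A and
B (seconds), Digit Symbol (correct items), a 10-item wordlist with learning
and delayed recall (correct items), and Grooved Pegboard with the dominant
and non-dominant hand (seconds). Raw scores are converted to standard
scores against age-banded normative means and SDs:

$$z = \begin{cases} (\mu - x)/\sigma & \text{timed tests} \\
(x - \mu)/\sigma & \text{count tests} \end{cases}$$

The orientation is normalized at scoring so that negative `z` always means
worse performance; every downstream rule then uses the single convention
"pathological below $z = -1$". Norms are external configuration
(`read_norms()`): normative tables are licensed site assets and are not
redistributable, so the package ships an illustrative table
(`demo_norms()`) whose Trail Making A band for ages 40–49 (mean 31 s,
SD 9 s) places the raw cutoff at 40 seconds — the worked example used for
the nurse-facing lookup table (`nurse_lookup()`). Norms are stratified by
age only; an education column is accepted but not used by default, since
education-adjusted stratification is a site decision.

**Cutoff convention.** "Below $-1.0$" is read strictly: $z = -1.0$ exactly
is *not* pathological. This matches the phrasing of the raw-score rule
("more than 40 seconds") at the implied boundary. The same strictness is
applied to count-based tests; the boundary behaviour for those is a
documented policy choice rather than an attested fact, and the cutoff is a
parameter (`screen_config(cutoff = )`) should a site prefer otherwise.

**Domains and the screen rule.** The tests map onto four domains —
cognitive speed {TMT-A, TMT-B, DST}, memory {wordlist learning, recall},
executive function {TMT-B}, motor speed {DST, both pegboards, TMT-A,
TMT-B} — with several tests deliberately serving multiple domains. A
domain is pathological if *any* of its tests is; the screen is positive
with pathological findings in *two or more* domains (`min_domains = 2`,
configurable). A domain none of whose tests was administered is
*unevaluable*: it is never counted as pathological, and the run carries a
warning annotation. This is the conservative choice — a missing test
cannot create a case — and it keeps every decision auditable.

**Questionnaire.** Five complaint items are answered on
never/rarely/sometimes/often/always. The positivity rule for "complainer"
status is not fixed by the battery's description; the package's default —
*memory loss* or *attention* endorsed at "often" or worse — mirrors the
phrase "complaining of memory loss or difficulties to concentrate" while
leaving both the item set and threshold configurable. The two robustness
items (prospective memory, informant remarks) are recorded and reported
but excluded from the default rule, since their intended use was never
operationalized. Two PHQ-2-style depression items are scored as a separate
descriptive flag (either item at "more than half the days" or worse); the
depression flag never enters the screen decision. The *combined criterion*
is the logical OR of screen and complaint.

## Accuracy evaluation

Screen decisions are tabulated against the reference-standard diagnosis
(HAND = ANI ∪ MND ∪ HAD) in a 2×2 table, and sensitivity, specificity,
PPV and NPV are computed with exact Clopper–Pearson intervals on each
metric's own numerator and denominator:

$$\mathrm{CI}(k, n) = \left[ B_{\alpha/2}(k,\, n-k+1),\;
B_{1-\alpha/2}(k+1,\, n-k) \right]$$

with the boundary cases pinned to 0 and 1. The exact interval was chosen
over Wilson or Wald because the strata here are tiny (down to $n = 2$) and
the exact interval's coverage guarantee is unconditional; the package's
tests verify it against a direct inversion of the binomial CDF for every
$k \le n \le 30$ and verify exact coverage $\ge 95\%$ by summing binomial
probabilities. A metric with a zero denominator is reported as *undefined*
(`NA`), never as 0 — with pilot-scale strata this occurs routinely and a
silent zero would corrupt summaries.

Point estimates are formatted as integer percentages rounded half away
from zero (`pct()`: 16/17 → 94, 4/13 → 31). CI bounds are compared with a
±1-point tolerance wherever published values are involved, because
published integer bounds follow no single consistent rounding rule.

The descriptive comparison of screen-positive versus screen-negative
patients (`compare_groups()`) uses the two-sided Mann–Whitney test for
continuous variables — in the uncorrected normal-approximation convention,
so that identical groups give exactly $p = 1$ — and Fisher's exact test
for 2×2 categorical rows whenever any expected cell is below 5, chi-square
otherwise (the customary switching rule, adopted because the source
analysis lists both tests without stating one).

## The synthetic cohort simulator

`simulate_cohort()` generates cohorts with the statistical structure the
evaluation assumes:

* latent diagnosis from prevalence 25/30 and severity mix 16:8:1
  (ANI:MND:HAD) — the composition of the pilot cohort the package models;
* seven test z-scores from an equicorrelated Gaussian (single shared
  factor, correlation 0.3 by default), with per-domain mean decrements
  under HAND. A test inherits the largest decrement among the domains it
  serves; decrements scale with severity (×1 ANI, ×1.5 MND, ×2.5 HAD).
  The default decrements (0.6–0.8 SD at ANI severity) are moderate
  subclinical deficits — the regime in which a 2-of-4-domain rule is
  genuinely informative rather than saturated;
* raw scores back-transformed through the norms at the patient's age, at
  full precision (deliberately unrounded, so that large-sample
  Monte-Carlo estimates are comparable to the closed form below without a
  discretization bias), clamped at the physiologic floor of zero;
* complaint status as a diagnosis-conditional Bernoulli: 9/25 among
  impaired and 3/5 among unimpaired patients by default — the key
  miscalibration (most impaired patients do **not** complain) that
  motivates objective screening. This is a deliberate simplification;
  complaint severity does not depend on depth of impairment, and
  depression-mediated over-reporting is not modelled;
* ages around a median of 52.5 years (IQR ≈ 47–64), education, and an
  antiretroviral-regimen annotation column, for descriptive tables.

For uncorrelated tests, `analytic_operating_characteristics()` computes
the screen's exact sensitivity and specificity by enumerating all $2^7$
test-pathology patterns with per-test flag probabilities
$\Phi(\text{cutoff} + \text{shift})$ and mapping each pattern through the
domain rule; sensitivity averages over the severity mix. This closed form
is the simulator's independent oracle: the test suite checks Monte-Carlo
runs of the full pipeline at $n = 10^5$ against it within three standard
errors, across several parameterizations. Correlated parameterizations
have no closed form here and are explicitly refused.

What the simulator does *not* emulate: practice effects, item-level
response processes, missing-data mechanisms, comorbidity structure, or any
dependence of complaints on deficit severity. Passing simulator-based
tests therefore demonstrates the *internal* consistency of rules,
enumeration and pipeline — not clinical performance on real patients.

## The reconstructed 30-patient cohort

`reference_cohort()` rebuilds, deterministically and with no randomness, a
cohort whose joint (diagnosis × complaint × screen) cross-classification
is the unique one forced by published margins: 25/30 HAND (16 ANI, 8 MND,
1 HAD); 9 HAND complainers and 3 normal complainers; a 16/1/9/4 accuracy
table; 4 of 9 complainer-HAND and 12 of 16 non-complainer-HAND
screen-positive; the lone false positive a complainer (forced by 100%
specificity among non-complaining normals). Row-level details the margins
do not fix — which severity sits in which cell, ages, raw scores — are
fixed arbitrarily but consistently; any consistent completion reproduces
the same published metrics. Raw scores are *synthesized* (rounded to 0.1)
so that the shipped demo norms and default rules route every row to its
required flags: screen-positives carry two-or-more-domain deficit
patterns, false negatives carry single-domain (memory or motor) deficits
the rule cannot see, and the HAD row is globally impaired. The fixture is
thus an end-to-end test of the whole pipeline, not a table of
pre-computed flags, and it ships both as code and as a committed CSV
(`synthetic_reference_cohort.csv`) whose equality with the generator is
itself under test.

```{r fixture}
fit <- run_pipeline(reference_cohort())
fit
```

## Numerical and design notes

* **Problem sizes.** Unit and property tests run at desk scale (exhaustive
  $2^7$ patterns; all binomial counts to $n = 30$; Fisher enumeration over
  all small tables). Simulator validation uses $n = 10^5$ patients, where
  three Monte-Carlo standard errors are ≈ 0.5 percentage points.
* **Determinism.** `simulate_cohort()` is byte-reproducible given
  (seed, params); the fixture and the whole evaluation pipeline are fully
  deterministic.
* **Degenerate inputs.** Empty norms, overlapping age bands, unknown
  ordinal tokens and misaligned vectors fail fast with messages naming the
  offending test, band, row or column; empty strata and zero denominators
  degrade to explicitly marked non-results rather than numbers.
* **Known limitations.** The demo norms are illustrative, not normative;
  the complainer rule is a documented convention, not an attested one; the
  reconstructed cohort pins unpublished row-level details arbitrarily; and
  reusing tests across domains (TMT-B serves three) makes the domain count
  sensitive to single tests by design — a property of the battery itself,
  inherited faithfully.
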