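# handscreen

Scoring and diagnostic-accuracy evaluation of a brief, nurse-administered
screening battery for HIV-associated neurocognitive disorders (HAND).

## The problem

Treated, virally suppressed HIV-infected adults carry a high burden of
mild neurocognitive disorders — asymptomatic neurocognitive impairment
(ANI), mild neurocognitive disorder (MND), and, rarely, HIV-associated
dementia (HAD). Dementia screens miss the mild forms, and self-report is
unreliable: most patients with objective impairment do not complain. A
practical compromise is a ~25-minute battery of seven standardized tests
plus a short complaint questionnaire, administered by trained nurses and
validated against a full neuropsychological examination. This package
implements that battery's scoring rules and evaluates its accuracy,
for clinical researchers validating screening instruments.

## The model

Raw scores are converted to age-normed standard scores, oriented so
negative is always worse:

    z = (mu - x) / sigma   (timed tests: TMT-A/B, Grooved Pegboard)
    z = (x - mu) / sigma   (count tests: Digit Symbol, wordlist)

A single test result is pathological when `z < -1.0` (strict). The seven
tests map onto four domains (cognitive speed, memory, executive function,
motor speed; some tests serve several); a domain is pathological if any
of its tests is, and the **screen is positive with deficits in ≥ 2 of the
4 domains**. A patient is a **complainer** when the memory-loss or
attention item is endorsed at "often" or worse; the **combined criterion**
is screen OR complaint. Accuracy against the reference diagnosis
(HAND = ANI ∪ MND ∪ HAD) is reported as sensitivity, specificity, PPV and
NPV with exact Clopper–Pearson 95% CIs,

    CI(k, n) = [ qbeta(alpha/2; k, n-k+1), qbeta(1-alpha/2; k+1, n-k) ],

with zero-denominator metrics reported as undefined. A synthetic-cohort
simulator (latent diagnosis, equicorrelated test z-scores with per-domain
severity-scaled decrements, diagnosis-conditional Bernoulli complaints)
and an exact 2^7-enumeration closed form for its operating
characteristics make the whole pipeline testable without patient data.

## Worked example

The package ships a deterministic 30-patient synthetic cohort
reconstructed from published marginal counts (`reference_cohort()`; also at
`inst/extdata/synthetic_reference_cohort.csv`). Running the default
pipeline on it:

```r
library(handscreen)
fit <- run_pipeline(reference_cohort())
fit
#> Screening battery evaluation: 30 patients, 25 (83%) HAND, 17 (57%) screen-positive
#> Screen result x reference standard
#>          HAND normal total
#> positive   16      1    17
#> negative    9      4    13
#> total      25      5    30
#> Diagnostic accuracy (95% exact CIs)
#>   sensitivity  64% (16/25, CI 43-82%)
#>   specificity  80% (4/5, CI 28-99%)
#>   ppv          94% (16/17, CI 71-100%)
#>   npv          31% (4/13, CI 9-61%)
```

Of 25 HAND patients the screen detects 16 (sensitivity 64%); almost every
screen-positive patient truly has HAND (PPV 94%), but a negative screen
rules little out (NPV 31%) at this 83% prevalence. `summary(fit)` adds
the complaint-stratified analyses (sensitivity rises to 75% with
specificity 100% among non-complainers), the combined criterion
(sensitivity 84%), complaint-only validity (36%/40% — complaints alone do
not separate impaired from unimpaired), and the descriptive comparison of
screen-positive versus screen-negative patients.

The nurse-facing raw-cutoff table comes straight from the norms:

```r
nurse_lookup(demo_norms())[7, ]
#>    test age_min age_max direction raw_cutoff
#> 7 TMT_B      40      49 more_than         86
```

i.e. a Trail Making B time of more than 86 seconds is pathological for a
patient aged 40–49 under the shipped demonstration norms.

Other entry points: `read_cohort()`/`write_cohort()` (CSV),
`simulate_cohort()`/`sim_params()` (synthetic cohorts),
`analytic_operating_characteristics()` (closed-form oracle),
`screen_report()` (per-patient JSON audit trail), and a thin command-line
front end at `inst/cli/handscreen` with subcommands
`score | screen | evaluate | simulate | fixture | lookup`.

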