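---
title: "Modelling the natural history of DCIS under mammography screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the natural history of DCIS under mammography screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcissim)
```

## The model

Ductal carcinoma in situ (DCIS) is a stage-zero breast cancer whose natural
history is essentially unobservable: almost every detected lesion is treated
immediately, so progression and regression cannot be followed directly.
`dcissim` implements a yearly micro-simulation Markov model of that natural
history in a population-based mammography screening setting.  Each simulated
woman is followed from birth, one year at a time, through the states

* **healthy**,
* **DCIS of grade 1, 2 or 3** (grade fixed at onset; at most one lesion at a
  time), and
* four absorbing exits that remove her from the model: **death from other
  causes**, **invasive breast cancer (IBC)** reached by progression from
  DCIS, **screen-detection**, and **clinical detection** (any detection
  outside the organised programme).

Six annual probabilities drive the transitions, all used exactly as given,
never converted to rates or renormalised:

| parameter | meaning | base value (Dutch setting) |
|---|---|---|
| death | all-cause death, age-dependent, identical in healthy and DCIS state | per-year life table, 0.324&times;10^-2^ at age 0 rising to 1 at age 100 |
| onset | DCIS onset per grade, age-dependent | banded table, e.g. (0.2095, 0.3105, 0.3250)&times;10^-3^/yr at ages 49–54 |
| regression | spontaneous return of DCIS to healthy | 0.0488/yr, all grades |
| progression | DCIS &rarr; IBC, age- and grade-dependent | 0.087–0.159/yr (ages 20–54), 0.073–0.134/yr (55+) |
| screening sensitivity | detection of a present DCIS at an attended round | 0.86 |
| clinical detection | detection of a present DCIS outside the programme | 0.05/yr |

plus the screening policy: rounds every 2 years at ages 50–74 with
participation 0.76 drawn independently per round.  Death while in DCIS state
uses the healthy-state probability (death *from* DCIS is negligible); direct
healthy&rarr;IBC transitions and everything after IBC are outside the model's
scope — IBC is an exit, not a modelled disease course.  A woman whose lesion
regresses returns to the healthy state and remains at risk of a new onset,
which then counts as a new episode.

Within one DCIS-year a woman faces competing risks: one multinomial draw
among regression, progression, clinical detection, and remaining in place
with the residual mass.  Parameter sets for which regression + progression +
clinical detection exceed 1 at any age and grade are rejected at load time.

## Within-year event ordering

The yearly update has three parts — the screening round, the death draw, and
the onset/competing-transition draw — and their order within the year is a
genuine modelling choice, so it is configurable (`event_order`) and
centralised in one kernel used by both the engine and the expectation
oracle.  The default, `"screen_last"`, applies death, then transitions, then
the screening round, which makes a lesion with onset earlier in the same
year already detectable at that year's round.  We prefer it on calibration
grounds: propagating the Dutch base parameters through the deterministic
oracle, screen-last reproduces the registry detection-rate pattern
(total 1.38 per 1,000 examinations; age strata 1.61, 1.10, 1.19, 1.27, 1.61)
while screen-first yields a visibly flatter prevalence peak (total 1.32;
50–54 stratum 1.42) — the first rounds of a woman's screening career catch a
prevalent pool that screen-first systematically under-detects.  The
alternative `"screen_first"` ordering remains available and fully tested.
Clinical detection may occur in the same year as a (missed or unattended)
screening round; participation carries no between-round persistence, matching
the single participation rate the programme reports.

## The expectation oracle

`dcis_expect()` propagates exact probability mass through the *same* ordered
kernel: screening moves participation&times;sensitivity of each DCIS mass
into the screen-detected absorber, death and the competing transitions act
multiplicatively on the remaining masses, and onset mass is accumulated per
grade.  Competing transitions always act on the start-of-step DCIS mass, so
freshly arisen mass is not transitioned in the same year — mirroring the
single draw per woman per year in the engine.  The oracle serves three
purposes: an analytic cross-check of the engine (every aggregate must agree
within Monte-Carlo error), a noise-free driver for sensitivity analyses, and
a fast estimator (about a millisecond per scenario).  Mass conservation is
asserted at every age with an absolute tolerance of 1e-12; a leak is an
internal error, never silently repaired.  On short horizons the oracle is
itself verified against brute-force enumeration of *all* individual event
paths, branch probability by branch probability.

## Reporting conventions

* **Detection rates** are screen-detected DCIS per 1,000 screening
  examinations; one examination per attended round per woman still in the
  model.  Age strata use age at the screening round (registries report age
  at detection), grade strata use the lesion grade with all examinations as
  denominator, so grade rates are additive to the total.
* **Uncertainty** across iterations is summarised by 2.5/97.5 percentile
  bounds — the registry comparison construction is not published, so the
  plain percentile interval was chosen — together with the standard error of
  the mean.  Percentile bounds estimate the spread of a single-cohort
  outcome and do not narrow as iterations are added; the standard error
  does.
* **Episode fates** partition all DCIS onsets into regression, progression
  to IBC, screen-detection, clinical detection, death from other causes
  while the lesion is present, and censoring at the model horizon; the six
  fractions sum to one.

## Scenarios as the data-generating process

A `dcis_scenario` is the package's synthetic-data generator: its defaults
*are* the study conditions (Dutch base scenario: Table-style banded inputs,
biennial 50–74, participation 0.76, sensitivity 0.86, 10 iterations of
100,000 women).  What the generator emulates is the population screening
process: age-structured mortality, age/grade-structured onset and
progression, imperfect attendance and test sensitivity.  What it does *not*
emulate: high-risk subpopulations, grade progression within an episode,
calendar-time trends in incidence or screening practice, per-woman
attendance habits, and anything after an exit (IBC course, treatment,
breast-cancer death).  Passing validation therefore shows that the
transition parameters reproduce registry *detection* patterns, not that
every unobservable natural-history quantity is identified.

The per-year mortality between published band endpoints is log-linearly
interpolated (mortality grows roughly exponentially in age), with the
printed endpoint values pinned to the band's first and last age; an exact
per-year table can be supplied instead via the `age,value` file format.  The
UK scenario ships with a clearly labelled *synthetic* life table
(`uk_life_synthetic.csv`) approximating UK female mortality magnitudes,
replaceable by the authoritative table; at screening ages mortality is
0.3–1.3% per year, so its influence on detection rates is second-order.

## Sensitivity analyses

Univariate analysis (`dcis_usa()`) re-evaluates the scenario with one
parameter at a bound, all else at base.  Table-valued inputs (onset,
progression, mortality) vary through a single multiplicative factor that
preserves the age/grade shape; scalar inputs vary directly.  With the
simulation engine the low/high/base runs share seeds (common random
numbers); with the oracle the tornado is exact.  The probabilistic analysis
(`dcis_psa()`, default 100 scenarios) samples parameter vectors uniformly
and independently within the intervals — the sampling law behind the
published analysis is not printed, and uniform is the conventional agnostic
choice; the sampler is a small, replaceable function.  Published 95%
confidence intervals per parameter are likewise unavailable, so
`intervals_example.csv` carries illustrative &plusmn;10% bounds and users
substitute their own.

## Numerical and degenerate-input choices

* Probabilities are validated to [0, 1] with full age coverage; onset may
  sum to at most 1 across grades per year.
* The life table is not forced to end in certain death: death-free toy
  configurations are legitimate, and any woman still in the model past
  `max_age` is censored (her open episode takes the `censored` fate).  The
  shipped scenarios end in probability 1 at age 100, so censoring is
  structurally zero there.
* Strata with zero examinations are reported as absent rather than as 0/0.
* Child seeds for iteration *i* are derived from the master seed by a fixed
  integer recurrence, so a `(scenario, seed)` pair is bit-reproducible and
  iterations are independent streams.
* Within a transition year, one uniform draw decides a woman's outcome
  against the cumulative probabilities in a fixed order (regression,
  progression, clinical detection, remain; onset grades 1, 2, 3) — ties are
  impossible with continuous uniforms, and the order only matters for
  reproducibility.

## Problem sizes

The validation runs use the full study size, 10 iterations of 100,000 women
(about 6 seconds on one core); unit and property tests use cohorts of
1,000–30,000 women, and the one-year multinomial check uses 10^6 women for
three model years.  The brute-force path enumeration is restricted to
horizons of five years, where the full path tree is still small.

## Known limitations

Onset probabilities are derived from *detected* incidence, so truly occult
disease that never surfaces is outside the identified range; estimates
condition on the detection intensity of the era the data come from.  The
model carries no covariates beyond age and grade, a single lesion per woman,
and no calendar time.  External validation of the UK setting currently rests
on a synthetic mortality stand-in (see above).  Overdiagnosis estimation —
the model's natural downstream use — is deliberately not implemented here;
it requires comparing matched screened and unscreened scenarios, which the
scenario machinery supports but the package does not yet wrap.
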