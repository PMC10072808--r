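---
title: "Methods: from contact diaries to reciprocity-adjusted mixing matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from contact diaries to reciprocity-adjusted mixing matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactweave)
```

## The problem

Age-structured transmission models need an estimate of how often people of
different ages meet. Diary-based contact surveys provide this: each
participant records, for one 24-hour period, every person they had a
two-way conversation with in physical presence, or touched, together with
the contactee's (estimated) age, the setting, duration, physicality,
frequency and distance from home of the encounter. Because diaries
under-capture busy days, participants may additionally report *supplementary*
contacts — a bare count of contacts they recall omitting, recorded only in
four coarse age bands (0–4, 5–15, 16–64, 65+) split by physical versus
non-physical. Supplementary counts enter degree summaries and regressions
but never the mixing matrices, whose cells need precise contactee ages and
settings.

`contactweave` implements the full analysis pipeline for surveys of this
design — validation, sampling weights, mixing matrices, descriptive and
regression summaries — together with a synthetic-survey generator whose
ground truth makes every stage testable without field data.

## Age band schemes

Three partitions of age recur and are available via `standard_scheme()`:
the recruitment quota bands (0–5, 6–12, 13–19, 20–29, 30–39, 40–59, 60+),
the 14 five-year matrix bands (0–4, …, 60–64, 65+), and the regression /
weighting bands (0–4, 5–14, …, 55–64, 65+). Bands are half-open intervals
on integer age, `[lower, next_lower)`, with the last band open-ended;
printed recruitment labels such as "0–5" are inclusive of both endpoints,
so the next lower bound is 6. A contactee age reported as a range is
resolved to `floor((min + max) / 2)` before banding (a seedable
uniform-draw alternative exists via `resolve_contact_age(mode =
"uniform")`); the field convention here is not standardised, and the
midpoint is deterministic and unbiased for symmetric ranges. Contacts with
no usable contactee age are excluded from matrices and the count of
exclusions is carried on the result — redistribution would fabricate
information where exclusion is merely conservative and visible.

## Sampling weights by raking

Quota samples are balanced by design variables, not by the population, so
analyses are weighted. `rake_weights()` computes per-participant weights by
iterative proportional fitting over four margins: urban/rural residence,
age band (regression scheme), weekday/weekend diary day, and employment
status (non-working-age / employed / unemployed, derivable from occupation
and age through a documented, overridable mapping). Each pass multiplies
the weights of every level of every margin by `target share / weighted
sample share`, until the largest relative margin deviation falls below
`tol`.

Controls and their defaults: `tol = 1e-8` relative margin error,
`max_iter = 1000` full passes; weights are normalised to mean 1. Trimming
is off by default; when enabled, weights are clamped to multiples of the
mean weight (default `[0.2, 5]`) with up to 5 clamp/re-rake cycles. Since
IPF has a unique fixed point, re-raking alone can never keep weights inside
the bounds: the final clamp wins, the bounds are guaranteed, and the
resulting (possibly non-zero) margin error is reported honestly through
`max_margin_error` and `converged`. Trimming trades a small bias for a
smaller design effect; the default is off because the reference design
rarely produces extreme weights.

Margin targets are always user-supplied (`margin_spec()`, or
`population_margins()` to derive residence and age margins from population
tables): day-type and employment shares are facts about the population
that no age pyramid contains.

## Mean contact matrices and the reciprocity correction

The raw matrix cell is the weighted mean number of diary contacts a
participant in age band $i$ reports with contactees in band $j$ per diary
day:

$$c_{ij} = \frac{\sum_{p \in i} w_p\, n_{pj}}{\sum_{p \in i} w_p}.$$

Bands with no participants give missing rows, never zeros. At the
population level, the total number of contacts band $i$ makes with band
$j$ must equal the total band $j$ makes with band $i$; sample estimates
violate this, so each pair of cells is replaced by the
population-size-weighted average

$$c'_{ij} = \frac{1}{2 N_i}\left(c_{ij} N_i + c_{ji} N_j\right),$$

after which $c'_{ij} N_i = c'_{ji} N_j$ holds exactly, the total number of
contact events is conserved, and the operation is idempotent. When
$c_{ij}$ is missing but $c_{ji}$ is observed, the cell is filled from the
transposed term alone; cells missing in both directions stay missing.
Urban and rural matrices are adjusted against their own stratum's
population table, the combined matrices against the summed table — using
one shared table would force the wrong balance inside each stratum.

Matrices are stratified into five settings: home with household members,
home with non-household members, work, school/college, and a merged
transport/leisure/other category (transport and leisure contacts are too
rare to stand alone). A contact reporting several settings contributes
once to **each** reported setting matrix by default, while the
all-settings matrix counts it exactly once; the alternative
`attribution = "exclusive_multiple"` pools multi-setting contacts into
their own matrix instead. The choice is genuinely open — descriptive
displays conventionally use an exclusive "multiple" category, matrix
construction is rarely specified — so both are implemented and the default
favours not discarding setting information from matrices. High-intensity
companions use `contact_filter(high_intensity = TRUE)`: physical **or** at
least 15 minutes long, the 15-minute cut mapping exactly onto the duration
categories at and above `15to59min`.

## Descriptive conventions

* **Duration midpoints** (minutes): `lt5min` 2.5, `5to14min` 9.5,
  `15to59min` 37, `1to4h` 150, and `gt4h` right-truncated at 240 — the
  open-ended top category would otherwise dominate total hours.
* **Weighted quantiles** use the left-continuous inverse of the weighted
  ECDF (the weighted analogue of type-1 quantiles): with equal weights
  they reduce to ordinary type-1 quantiles, and with integer weights they
  agree with quantiles of the expanded sample.
* **Setting proportions** use the exclusive display: multi-setting
  contacts form a `multiple` category and transport/leisure merge into
  `other`, mirroring how such figures are conventionally drawn; this
  deliberately differs from the matrix attribution rule above.
* **Chi-squared machinery**: `chi2_independence()` is plain Pearson
  (no continuity correction — the reference analyses report uncorrected
  statistics at large n), `chi2_trend()` is Cochran–Armitage with integer
  scores 1..k (configurable; the statistic is invariant to affine score
  changes, including reversal).
* **Reporting-method comparison** coarsens diary contactee ages onto the
  four supplementary bands and contrasts the two methods' age distributions
  (df 3) and physical shares (df 1).
* Missing distance categories are tabulated as their own `missing` level,
  never dropped.

## Negative binomial regression

`fit_nb_model()` fits log-link negative binomial models of total degree
(diary + supplementary) or total contact hours (diary only) on residence,
day type, sex, household size (per unit), number of rooms, age band and
occupation, with the dispersion estimated by maximum likelihood jointly
with the coefficients (`MASS::glm.nb`). Reference levels are the first
canonical level of each factor (urban, weekday, male, one room, youngest
band, child at home). Three open choices and their resolutions:

* The hours response is continuous; it enters as total minutes rounded to
  integers, keeping a count likelihood while preserving resolution (2.5
  minutes is the smallest midpoint). Relative rates are unchanged by the
  unit choice.
* Sampling weights enter as analytic (frequency-style) weights in the
  likelihood; point estimates then target the population-weighted model.
* Per-term ANOVA is a likelihood-ratio test against the model with the
  term removed, dispersion re-estimated in the reduced fit, `df = levels -
  1` (1 for continuous terms); a reduced fit that fails to converge flags
  the term with `NA` rather than fabricating a statistic.

## The synthetic-survey generator

`generate_survey()` emulates the reference study conditions so that every
downstream stage has a recoverable target:

* **Design**: 2016 participants, recruited to an exact quota of 72 per
  age-band × sex × residence stratum (7 × 2 × 2). Quota satisfaction is a
  hard constraint of the generator, not an expectation.
* **Population**: one million people, 25% urban, with a geometric age
  pyramid (`pyramid_shape = 0.12` per five-year band) giving the young
  structure typical of a high-fertility, majority-rural country.
* **Mixing kernel**: an age-assortative Gaussian ridge (bandwidth 7.5
  years) plus intergenerational side-bands offset by ±27 years (amplitude
  0.5, for parent–child and grandparent–grandchild mixing) over a uniform
  background (0.15), symmetrised against the population so the truth
  satisfies the reciprocity identity by construction, then scaled to a
  population-mean total degree of 30 contacts/day.
* **Degrees**: negative binomial with mean `rowsum of the kernel ×
  exp(covariate effects)` and dispersion 1.5; default effects are
  rural × 1.23, weekend × 0.81, sex × 1 — multiplicative effects of the
  size reported for comparable surveys.
* **Settings**: per-contact probabilities over the seven setting tokens,
  shaped by eligibility (school only when both parties are aged 3–24;
  work only for employed participants and working-age contactees) and by a
  household-affinity factor that concentrates home-household contacts on
  same-age and one-generation-apart pairs. About 3% of contacts report a
  second setting.
* **Intensity**: per-setting duration distributions (home-household and
  school skew long); the probability a contact is physical rises
  logistically with the duration category, so duration and physicality
  agree as intensity measures.
* **Supplementary relegation**: each contact moves from the diary to
  coarse-band supplementary reporting with probability 0.30 if physical
  and 0.55 if not — roughly half of contacts relegated, biased so diary
  contacts are markedly more physical than supplementary ones. Setting and
  duration are erased on relegation, exact age is coarsened. Setting both
  probabilities to 0 disables relegation (used by recovery tests).
* **Reproducibility**: one master seed feeds a fixed sub-seed per
  sub-model; identical configs give byte-identical surveys.

What the generator does **not** emulate, and tests therefore cannot show:
age- or degree-dependent diary fatigue (relegation is independent of the
participant's age and degree, so the diary-vs-supplementary age comparison
is null in synthetic data), an explicit household/contact network (the
same person met twice is two diary lines), day-to-day temporal structure,
spatial geography behind the distance categories, and any claim that its
default parameters equal the field values. Passing recovery tests
demonstrate the estimators are correct on data with this structure, not
that field data have this structure.

## Numerical choices and test scale

Raking tolerance 1e-8 (tests compare against a brute-force IPF oracle at
1e-10–1e-13); reciprocity identity and conservation asserted to 1e-9
relative; weighted-ECDF quantile comparisons exact against sample
expansion. The test suite exercises the matrix estimator against a
brute-force per-contact tally on surveys of up to 20 participants, raking
against the contingency-table IPF oracle on up to 3 variables × 5 levels,
ground-truth matrix recovery at 10,024 participants (the nearest
quota-feasible size above 10,000) with relegation off — every adjusted
cell within 3 Monte-Carlo standard errors of the kernel — and NB coverage
with 100 replicates of n = 2000 (95% CI for a true rate ratio of 1.25
covering in at least 93). The `analysis/` scripts run the full pipeline at
the design scale of 2016 participants.

## Known limitations

Cells of sparse band pairs (e.g. oldest bands) rest on few participants
and inherit their noise; no smoothing or bootstrap intervals are provided.
The reciprocity correction assumes the population tables match the survey
frame. Weighted NB fits use analytic weights rather than a
design-consistent sandwich variance, so CIs are model-based. Multi-day
diaries, geocoding and date arithmetic beyond weekday/weekend are out of
scope.
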