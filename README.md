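# contactweave

Analysis of diary-based social contact surveys for infectious-disease
modelling: from the conventional two-table participants/contacts layout to
raking-weighted, reciprocity-corrected, setting- and residence-stratified
age mixing matrices, plus the descriptive and regression summaries that
typically accompany them. A synthetic-survey generator with known ground
truth makes every stage verifiable, so the package is usable (and fully
tested) without access to any field dataset.

It is aimed at epidemiologists and modellers working with POLYMOD-style
surveys — in particular designs that also collect *supplementary* contacts
(counts of contacts the participant recalls omitting from the diary,
reported only in four coarse age bands split by physical/non-physical) and
that distinguish home contacts with household members from those with
visitors.

## The statistics at the core

**Raking (iterative proportional fitting).** Quota samples are balanced by
design, not by the population, so per-participant weights \(w_p\) are
raked to population margins (urban/rural, age band, weekday/weekend,
employment status) until every weighted sample share matches its target
within tolerance.

**Mean contact matrices and reciprocity.** The raw cell is the weighted
mean number of diary contacts a participant in age band \(i\) makes with
band \(j\) per day:

\[ c_{ij} = \frac{\sum_{p \in i} w_p n_{pj}}{\sum_{p \in i} w_p}. \]

Population-level consistency requires total contacts of \(i\) with \(j\)
to equal those of \(j\) with \(i\), so cells are symmetrised as

\[ c'_{ij} = \frac{1}{2N_i}\,(c_{ij} N_i + c_{ji} N_j),
   \qquad c'_{ij} N_i = c'_{ji} N_j, \]

where \(N_i\) is the population size of band \(i\). The adjustment
conserves total contact events and is idempotent. Matrices come in five
setting strata (home/household, home/non-household, work, school,
transport–leisure–other) by urban/rural residence, on 14 five-year age
bands, with an optional high-intensity filter (physical or ≥ 15 min).

**Negative binomial regression.** Log-link NB models of a participant's
total degree (diary + supplementary) and total contact hours (diary-only,
via duration-category midpoints right-truncated at 4 h) on the standard
covariate set, with ML dispersion and per-term likelihood-ratio ANOVA.

## Worked example

```r
library(contactweave)

cfg <- generator_config(n_participants = 560, seed = 7)
gen <- generate_survey(cfg)
gen$survey
#> <contact_survey> 560 participants, 10378 diary contacts, 7530 supplementary contacts

w <- rake_weights(gen$survey, gen$ground_truth$weights_target_margins)
w
#> <weight_vector> n = 560, converged = TRUE, max margin error = 9.85e-09, range = [0.123, 3.1]

adj <- reciprocity_adjust(mean_contact_matrix(gen$survey, w),
                          gen$ground_truth$populations$all)
round(adj$values[1:4, 1:4], 2)
#>            contactee
#> participant  0-4  5-9 10-14 15-19
#>       0-4   2.75 1.86  1.38  0.94
#>       5-9   2.09 2.37  2.64  1.21
#>       10-14 1.76 2.97  3.94  3.05
#>       15-19 1.34 1.53  3.44  4.09

ps <- participant_summaries(gen$survey)
weighted_quantile(ps$degree_total, w$weights, c(0.25, 0.5, 0.75))
#> [1] 13 25 47

fit <- fit_nb_model(gen$survey, w, response = "degree_total",
                    covariates = c("residence", "day_type", "sex"))
subset(fit$relative_rates, term != "(Intercept)")
#>                            term  estimate  conf_low conf_high
#> residencerural   residencerural 1.2280209 1.0432223  1.445555
#> day_typeweekend day_typeweekend 0.9852431 0.8078179  1.201637
#> sexfemale             sexfemale 1.0860074 0.9436581  1.249830
```

Reading the output: the raked weights hit all four margins to within
1e-8; the adjusted matrix shows the assortative diagonal (e.g. 3.94 mean
daily contacts between 10–14-year-olds) and satisfies
\(c'_{ij}N_i = c'_{ji}N_j\) exactly; the weighted median participant
reports 25 contacts/day (IQR 13–47); and the regression recovers the
generator's true rural effect of 1.23 as 1.23 (95% CI 1.04–1.45).

## The analysis workflow

Numbered driver scripts under `analysis/` run the full pipeline at the
reference design scale (2016 participants, 72 per quota stratum) and
write tidy tables to `results/`:

1. `01_simulate.R` — generate the reference synthetic survey + ground truth
2. `02_weights.R` — raking weights
3. `03_matrices.R` — setting/residence-stratified adjusted matrices
4. `04_descriptives.R` — degree/duration, settings, intensity, reporting
   comparison, distance/mobility
5. `05_regression.R` — NB models of degree and contact hours

`run_pipeline()` performs the same stages from one config (YAML or list),
with a content-hashed manifest; runs are bit-reproducible under a fixed
seed.

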