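#!/usr/bin/env Rscript
# Stage 5: negative binomial regression of contact degree and hours.
#
# Multivariable NB models of (a) total degree (diary + supplementary) and
# (b) total contact hours (diary only, via duration midpoints) on
# residence, day type, sex, household size, rooms, age band and
# occupation, with per-term likelihood-ratio ANOVA. Emits the standard
# survey-report table per response.

library(contactweave)

dat <- "results/data"
survey <- load_survey(file.path(dat, "participants.csv"),
                      file.path(dat, "contacts.csv"),
                      file.path(dat, "supplementary.csv"))
wt <- read.csv("results/weights.csv")
weights <- setNames(wt$weight, wt$participant_id)

for (resp in c("degree_total", "contact_hours")) {
  fit <- fit_nb_model(survey, weights, response = resp)
  tab <- nb_summary_table(fit)
  write.csv(tab, sprintf("results/regression_%s.csv", resp),
            row.names = FALSE)
  rr <- fit$relative_rates
  rural <- rr[rr$term == "residencerural", ]
  cat(sprintf(
    "%s: dispersion %.2f; rural vs urban relative rate %.2f (%.2f-%.2f).\n",
    resp, fit$dispersion, rural$estimate, rural$conf_low, rural$conf_high))
  an <- term_anova(fit)
  sig <- an$term[!is.na(an$p) & an$p < 0.001]
  cat("  ANOVA p < 0.001 for:", paste(sig, collapse = ", "), "\n")
}
cat("True rural degree effect in the generator: 1.23.\n")
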