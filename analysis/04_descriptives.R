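#!/usr/bin/env Rscript
# Stage 4: descriptive summaries.
#
# Weighted degree and contact-hours summaries, setting proportions by
# participant group, intensity (physical-by-duration) trend, the
# diary-vs-supplementary reporting comparison, and distance/mobility
# tables.

library(contactweave)

dat <- "results/data"
survey <- load_survey(file.path(dat, "participants.csv"),
                      file.path(dat, "contacts.csv"),
                      file.path(dat, "supplementary.csv"))
wt <- read.csv("results/weights.csv")
weights <- setNames(wt$weight, wt$participant_id)

ps <- participant_summaries(survey)
write.csv(ps, "results/participant_summaries.csv", row.names = FALSE)

qs <- function(x) weighted_quantile(x, weights, c(0.25, 0.5, 0.75))
tot <- qs(ps$degree_total); dia <- qs(ps$degree_diary)
sup <- qs(ps$degree_supplementary)
cat(sprintf("Weighted median degree: %d (IQR %d-%d) total; %d (%d-%d)
diary; %d (%d-%d) supplementary.\n",
            tot[2], tot[1], tot[3], dia[2], dia[1], dia[3],
            sup[2], sup[1], sup[3]))

for (g in c("age_band", "residence", "sex", "day_type", "occupation")) {
  tab <- setting_proportions(survey, weights, groupby = g)
  write.csv(tab$proportions,
            sprintf("results/setting_proportions_%s.csv", g))
  test <- chi2_independence(round(tab$counts[rowSums(tab$counts) > 0, ]))
  cat(sprintf("Setting x %s: X2 = %.1f, df = %d, p %s.\n", g,
              test$statistic, test$df,
              format.pval(test$p, eps = 0.001)))
}
overall <- setting_proportions(survey, weights)
write.csv(overall$proportions, "results/setting_proportions.csv")
cat(sprintf("Share of contacts at home with non-household members: %.1f%%.\n",
            100 * overall$proportions[1, "home_nonhousehold"]))

# intensity: physical share should rise with duration category
ct <- survey$contacts
dur <- factor(ct$duration_cat,
              c("lt5min", "5to14min", "15to59min", "1to4h", "gt4h"))
s <- tapply(ct$physical, dur, sum); n <- tapply(!is.na(dur), dur, sum)
tr <- chi2_trend(as.numeric(s), as.numeric(n))
cat(sprintf("Physical-by-duration trend: X2 = %.1f, df = 1, p %s.\n",
            tr$statistic, format.pval(tr$p, eps = 0.001)))

rc <- reporting_method_comparison(survey)
write.csv(data.frame(
  comparison = c("age_distribution", "physical_proportion"),
  statistic = c(rc$age_test$statistic, rc$physical_test$statistic),
  df = c(rc$age_test$df, rc$physical_test$df),
  p = c(rc$age_test$p, rc$physical_test$p)),
  "results/reporting_comparison.csv", row.names = FALSE)
cat(sprintf("Reporting methods: age distribution X2 = %.1f (df 3);
physical proportion X2 = %.1f (df 1).\n",
            rc$age_test$statistic, rc$physical_test$statistic))

dm <- distance_mobility_tables(survey, weights)
write.csv(dm$distance, "results/distance.csv", row.names = FALSE)
write.csv(dm$mobility, "results/mobility.csv", row.names = FALSE)
cat(sprintf("Contacts within 1 km of home: %.1f%%; beyond 9 km: %.1f%%.\n",
            100 * dm$distance$share[dm$distance$distance == "lt1km"],
            100 * dm$distance$share[dm$distance$distance == "gt9km"]))
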