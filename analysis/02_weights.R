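#!/usr/bin/env Rscript
# Stage 2: raking weights.
#
# Rakes per-participant sampling weights to the four population margins
# (urban/rural, age band, weekday/weekend, employment status) by iterative
# proportional fitting and writes a participant_id -> weight table.

library(contactweave)
library(yaml)

dat <- "results/data"
survey <- load_survey(file.path(dat, "participants.csv"),
                      file.path(dat, "contacts.csv"),
                      file.path(dat, "supplementary.csv"))

mg <- read_yaml(file.path(dat, "margins.yaml"))
margins <- lapply(names(mg), function(v) margin_spec(v, unlist(mg[[v]])))

w <- rake_weights(survey, margins)
stopifnot(w$converged)

write.csv(data.frame(participant_id = names(w$weights),
                     weight = unname(w$weights)),
          "results/weights.csv", row.names = FALSE)

cat(sprintf("Raking converged in %d passes; max margin error %.2e.\n",
            w$iterations_used, w$max_margin_error))
cat(sprintf("Weight range [%.2f, %.2f] around mean 1 (no trimming needed).\n",
            min(w$weights), max(w$weights)))
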