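#!/usr/bin/env Rscript
# Stage 1: simulate the study panel.
#
# Generates a synthetic municipality panel at the scale of the real study
# (1,601 municipalities in 47 prefectures, two census periods, two sexes,
# four causes of death) and writes every table as delimited text under
# results/data/. Downstream stages read these files, so the whole workflow
# exercises the same text interfaces a user with real data would.

suppressPackageStartupMessages(library(phnsmr))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- default_config(seed = 20260920L)
d <- generate_panel(cfg)

write_tsv <- function(x, name) {
  utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
write_tsv(d$panel, "panel")
write_tsv(d$resources, "resources")
write_tsv(d$adjacency, "adjacency")
write_tsv(d$rates, "reference_rates")
write_tsv(d$truth$theta, "truth_theta")

truth <- d$truth
truth$theta <- NULL
truth$config <- unclass(truth$config)
jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

r1 <- d$resources[d$resources$period == "2010", ]
small <- r1$population_base < 10000
cat(sprintf("simulated %d municipalities (%d below 10,000 inhabitants)\n",
            nrow(r1), sum(small)))
cat(sprintf("population: mean %.0f, sd %.0f (study: 44,299 / 57,712)\n",
            mean(r1$population_base), sd(r1$population_base)))
cat(sprintf("PHNs per 100k: %.1f overall, %.1f in small municipalities\n",
            mean(r1$phn_all_per100k), mean(r1$phn_all_per100k[small])))
cat("wrote", out_dir, "\n")
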