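#!/usr/bin/env Rscript
# Stage 5: collate the report.
#
# Gathers the stage outputs into results/report/ and prints the study-style
# summary: descriptive contrasts by municipality size, the adjusted
# first-difference coefficients with q-values, and the BYM posterior
# estimates. Every number here is read back from the delimited tables the
# earlier stages wrote, so the report is regenerable from the manifest.

files <- c(descriptive = "results/descriptive.tsv",
           changes = "results/changes.tsv",
           bivariate = "results/bivariate.tsv",
           adjusted = "results/adjusted.tsv",
           vif = "results/vif.tsv",
           stratified = "results/stratified.tsv",
           bym = "results/bym.tsv")
missing <- files[!file.exists(files)]
if (length(missing) > 0) {
  stop("missing stage outputs: ", paste(missing, collapse = ", "),
       "; run stages 01-04 first")
}

dir.create("results/report", showWarnings = FALSE, recursive = TRUE)
tabs <- lapply(files, utils::read.delim)
for (nm in names(tabs)) {
  file.copy(files[[nm]], file.path("results/report", basename(files[[nm]])),
            overwrite = TRUE)
}

manifest <- data.frame(
  key = c("generator_seed", "n_municipalities", "stages"),
  value = c("20260920", as.character(max(tabs$adjusted$n)),
            paste(basename(files), collapse = ",")))
utils::write.table(manifest, "results/report/manifest.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("== descriptive contrasts (baseline, small vs large municipalities) ==\n")
d <- tabs$descriptive
for (v in c("phn_all_per100k", "physicians_per100k", "population")) {
  r <- d[d$variable == v, ]
  cat(sprintf("  %-22s mean %10.1f | small %10.1f large %10.1f | d = %5.2f\n",
              v, r$mean_all, r$mean_small, r$mean_large, r$cohens_d))
}

cat("\n== adjusted first-difference model: d ln(PHN per 100k) ==\n")
a <- tabs$adjusted
phn <- a[a$model == "all_phn" & a$term == "d_ln_phn", ]
for (i in seq_len(nrow(phn))) {
  cat(sprintf("  %-6s %-24s %7.2f  p = %.3f  q = %.3f\n", phn$sex[i],
              phn$cause[i], phn$estimate[i], phn$p[i], phn$q[i]))
}

cat("\n== BYM posterior (reported scale) ==\n")
b <- tabs$bym
pr <- b[b$parameter %in% c("ln_phn", "ln_phn_baseline", "ln_phn_change"), ]
for (i in seq_len(nrow(pr))) {
  cat(sprintf("  %-6s %-6s %-15s %8.2f (%8.2f, %8.2f)\n", pr$sex[i],
              pr$variant[i], pr$parameter[i], pr$mean_reported[i],
              pr$q2.5_reported[i], pr$q97.5_reported[i]))
}
cat("\nreport tables copied to results/report/\n")
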