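#!/usr/bin/env Rscript

# Stratified sex-ratio analysis of the 44 sexed individuals.
# Computes SR = males / females overall and by tomb, phase, method and age
# group, under both counting policies, and tests departure from parity.

suppressPackageStartupMessages(library(paleosex))

dir.create("results", showWarnings = FALSE)

ind <- read_individuals(
  system.file("extdata", "panoria_individuals.tsv", package = "paleosex",
              mustWork = TRUE))

tables <- list()
for (by in c("none", "tomb", "phase", "method", "age_class")) {
  for (policy in c("include_probable", "definite_only")) {
    tbl <- stratify_sex_ratio(ind, by = by, policy = policy)
    tbl$stratification <- by
    tbl$policy <- policy
    tables[[paste(by, policy)]] <- tbl
  }
}
all_sr <- dplyr::bind_rows(tables)
print(as.data.frame(all_sr[, c("stratification", "stratum", "policy",
                               "pm", "pf", "sr_display", "range_class")]))

counts <- sex_count(ind, policy = "definite_only")
cat(sprintf("\nBinomial departure from parity (definite calls, %d M / %d F): p = %.4f\n",
            counts$pm, counts$pf, binomial_departure_test(counts)))

write_result_table(all_sr, "results/sex_ratios_stratified.tsv")
cat("wrote results/sex_ratios_stratified.tsv\n")
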