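#!/usr/bin/env Rscript

# Amelogenin peptide sexing of the seven enamel digests.
# Classifies each tooth from its five peak areas and writes the call table.

suppressPackageStartupMessages(library(paleosex))

dir.create("results", showWarnings = FALSE)

areas <- read_peak_areas(
  system.file("extdata", "panoria_peak_areas.tsv", package = "paleosex",
              mustWork = TRUE))
res <- classify_peptide_batch(areas)

print(res$calls)
cat("\nSummary: ", paste(names(res$summary), res$summary, collapse = ", "),
    "\n", sep = "")

write_result_table(res$calls, "results/peptide_calls.tsv")
cat("wrote results/peptide_calls.tsv\n")
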