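#!/usr/bin/env Rscript

# End-to-end pipeline run: peptide stage, individual merge via the explicit
# id mapping, and the complete stratified sex-ratio report written to results/.

suppressPackageStartupMessages(library(paleosex))

fixture <- function(name) {
  system.file("extdata", name, package = "paleosex", mustWork = TRUE)
}

cfg <- run_config(
  peak_areas = fixture("panoria_peak_areas.tsv"),
  individuals = read_individuals(fixture("panoria_individuals.tsv")),
  id_mapping = fixture("panoria_id_mapping_synthetic.tsv"),
  display = "round1",
  seed = 1,
  output_dir = "results/full_report")

report <- run_all(cfg)
print(report)
cat("\nreport files written to results/full_report/\n")
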