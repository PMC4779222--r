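#!/usr/bin/env Rscript
# Call tissue-enriched genes per species from the bundle written by
# 01_simulate.R, check library comparability, and score the calls against
# the planted truth.

library(gutdiverge)

dir <- file.path("results", "bundle")
tab_A <- read_expression_table(file.path(dir, "expression_A.tsv"))
tab_B <- read_expression_table(file.path(dir, "expression_B.tsv"))

for (tab in list(tab_A, tab_B)) {
  qc <- correlation_qc(tab)
  message(sprintf("%s tissue/whole log-FPKM correlation r = %.3f (%s)",
                  tab$species_label, qc$correlation,
                  if (qc$comparable) "comparable" else "NOT comparable"))
}

calls_A <- call_tissue_enriched(tab_A)
calls_B <- call_tissue_enriched(tab_B)
print(calls_A); print(calls_B)
write_tsv_report(calls_A$calls, file.path("results", "calls_A.tsv"))
write_tsv_report(calls_B$calls, file.path("results", "calls_B.tsv"))

truth_A <- readLines(file.path(dir, "truth", "enriched_A.txt"))
truth_B <- readLines(file.path(dir, "truth", "enriched_B.txt"))
score <- function(calls, truth) {
  called <- enriched_genes(calls)
  message(sprintf(
    "%s: %d called, %d/%d planted recovered, %d false calls",
    calls$species_label, length(called), sum(truth %in% called),
    length(truth), sum(!called %in% truth)))
}
score(calls_A, truth_A)
score(calls_B, truth_B)
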