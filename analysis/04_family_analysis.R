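#!/usr/bin/env Rscript
# Gene-family level comparison: cumulative expression shares, the
# abundant-family display filter, per-species family enrichment among the
# tissue-enriched genes, and the families shared between species.

library(gutdiverge)

dir <- file.path("results", "bundle")
tab_A <- read_expression_table(file.path(dir, "expression_A.tsv"))
tab_B <- read_expression_table(file.path(dir, "expression_B.tsv"))
dom_A <- read_domain_annotation(file.path(dir, "domains_A.tsv"))
dom_B <- read_domain_annotation(file.path(dir, "domains_B.tsv"))
calls_A <- call_tissue_enriched(tab_A)
calls_B <- call_tissue_enriched(tab_B)

for (x in list(list(tab = tab_A, dom = dom_A, calls = calls_A, tag = "A"),
               list(tab = tab_B, dom = dom_B, calls = calls_B, tag = "B"))) {
  sh <- cumulative_family_share(x$tab, x$dom)
  ab <- abundant_families(sh)
  message(sprintf(
    "%s: %d families, %d above 1%% tissue share and tissue-skewed; top: %s (%.1f%%)",
    x$tab$species_label, nrow(sh), nrow(ab), ab$family_id[1],
    100 * ab$share_tissue[1]))
  write_tsv_report(sh, file.path("results",
                                 paste0("family_shares_", x$tag, ".tsv")))
  fe <- family_enrichment(x$calls, x$dom)
  message(sprintf("%s: %d families significantly enriched (p < 0.01)",
                  x$tab$species_label, sum(fe$significant)))
  write_tsv_report(fe, file.path("results",
                                 paste0("family_enrichment_", x$tag,
                                        ".tsv")))
  assign(paste0("fe_", x$tag), fe)
}

shared <- shared_enriched_families(fe_A, fe_B)
planted <- readLines(file.path(dir, "truth", "planted_families.txt"))
message("families enriched in BOTH species: ",
        paste(shared, collapse = ", "))
message("planted shared families:          ",
        paste(planted, collapse = ", "))
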