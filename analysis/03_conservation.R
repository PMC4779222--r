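#!/usr/bin/env Rscript
# Single-gene conservation through one-to-one orthologs: the conserved
# enrichment overlap, expression-category distributions, depletion of
# lowly expressed genes, and the cross-species low-expression fractions.

library(gutdiverge)

dir <- file.path("results", "bundle")
tab_A <- read_expression_table(file.path(dir, "expression_A.tsv"))
tab_B <- read_expression_table(file.path(dir, "expression_B.tsv"))
om <- read_ortholog_map(file.path(dir, "orthologs.tsv"))
calls_A <- call_tissue_enriched(tab_A)
calls_B <- call_tissue_enriched(tab_B)

rep <- conserved_overlap_test(calls_A, calls_B, om)
print(rep)
write_tsv_report(conserved_gene_report(rep),
                 file.path("results", "table1_conserved_genes.tsv"))

for (x in list(list(calls = calls_A, tab = tab_A, side = "A"),
               list(calls = calls_B, tab = tab_B, side = "B"))) {
  core <- if (x$side == "A") om$gene_id_A else om$gene_id_B
  enr_core <- restrict_to_core(enriched_genes(x$calls), om, x$side)
  depl <- low_expression_depletion_test(enr_core, x$tab, background = core)
  message(sprintf(
    "%s: enriched core genes depleted of FPKM<1 (k=%d/%d below, p=%.3g)",
    x$tab$species_label, depl$k, depl$K, depl$p_value))
  d <- expression_category_distribution(enr_core, x$tab)
  message("  FPKM bins ", paste(d$bin_labels, collapse = " "), ": ",
          paste(sprintf("%.2f", d$fractions), collapse = " "))
}

xa <- cross_species_expression_check(enriched_genes(calls_A), om, tab_B)
swapped <- data.frame(gene_id_A = om$gene_id_B, gene_id_B = om$gene_id_A)
xb <- cross_species_expression_check(enriched_genes(calls_B), swapped,
                                     tab_A)
message(sprintf(
  "%.0f%% of %s-enriched orthologs show FPKM<1 in the %s intestine",
  100 * xa$fraction_below, tab_A$species_label, tab_B$species_label))
message(sprintf(
  "%.0f%% of %s-enriched orthologs show FPKM<1 in the %s intestine",
  100 * xb$fraction_below, tab_B$species_label, tab_A$species_label))
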