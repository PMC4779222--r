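#!/usr/bin/env Rscript
# Gene-set level comparisons: the cross-study percentage-overlap matrix,
# agreement of enriched annotation terms across studies, and the
# pathogen-response overlap tables for both species.

library(gutdiverge)

dir <- file.path("results", "bundle")
tab_A <- read_expression_table(file.path(dir, "expression_A.tsv"))
tab_B <- read_expression_table(file.path(dir, "expression_B.tsv"))
terms_A <- read_term_annotation(file.path(dir, "terms_A.tsv"))
studies <- read_gene_sets(file.path(dir, "studies.gmt"))
resp_A <- read_gene_sets(file.path(dir, "response_A.gmt"))
resp_B <- read_gene_sets(file.path(dir, "response_B.gmt"))
calls_A <- call_tissue_enriched(tab_A)
calls_B <- call_tissue_enriched(tab_B)

sets <- c(list(this_study = enriched_genes(calls_A)), studies$sets)
coll <- gene_set_collection(sets, tab_A$species_label)
m <- pairwise_overlap_matrix(coll)
message("cross-study overlap matrix (% of row set found in column set):")
print(round(m, 1))
write_tsv_report(data.frame(set_name = rownames(m), as.data.frame(m),
                            check.names = FALSE),
                 file.path("results", "cross_study_matrix.tsv"))

enr_terms <- lapply(coll$sets, function(s)
  with(term_enrichment(s, terms_A, tab_A$data$gene_id),
       term_id[significant]))
ag <- term_agreement(enr_terms)
message(sprintf("%d terms enriched in at least one study; %d in all %d",
                nrow(ag), sum(ag$n_datasets_enriched == length(coll$sets)),
                length(coll$sets)))
write_tsv_report(ag, file.path("results", "term_agreement.tsv"))

tab2 <- rbind(response_overlap_table(calls_A, resp_A),
              response_overlap_table(calls_B, resp_B))
print(tab2[, c("species_label", "response_name", "k", "fold", "display_p")])
message(sprintf(
  "significant (p<0.01) response overlaps: %d/8 for %s, %d/8 for %s",
  sum(tab2$p_value[tab2$species_label == tab_A$species_label] < 0.01),
  tab_A$species_label,
  sum(tab2$p_value[tab2$species_label == tab_B$species_label] < 0.01),
  tab_B$species_label))
write_tsv_report(tab2, file.path("results", "table2_response_overlap.tsv"))
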