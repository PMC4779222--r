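# ---------------------------------------------------------------------------
# End-to-end orchestration: reads every artifact from files, runs all
# stages, writes the figure/table-shaped TSV reports plus a JSON summary
# carrying every overlap statistic produced anywhere in the run.  No hidden
# state between stages; reruns are bit-for-bit identical.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Collects all input paths and stage thresholds.  `bundle_dir` fills the
#' standard paths of a [write_bundle()] directory; individual paths can be
#' overridden.
#'
#' @param bundle_dir directory laid out by [write_bundle()]; optional when
#'   every path is given explicitly.
#' @param out_dir output directory for the reports.
#' @param expr_A,expr_B expression table TSVs.
#' @param orthologs one-to-one ortholog map TSV.
#' @param domains_A,domains_B domain annotation TSVs.
#' @param terms_A,terms_B term annotation TSVs.
#' @param response_A,response_B response-set GMTs.
#' @param studies GMT of replicate study sets (species A).
#' @param alpha_de FDR level of the enrichment caller (default 0.05).
#' @param alpha_family raw-p level of the family screen (default 0.01).
#' @param alpha_term corrected level of the term screen (default 0.05).
#' @param min_share cumulative-share display floor (default 0.01).
#' @param fpkm_low "lowly expressed" FPKM cutoff (default 1).
#' @param ns_threshold display threshold for "n.s." (default 0.05).
#' @param correction correction mode of the term screen (`"BH"` or
#'   `"none"`).
#' @param pseudocount,min_log2fc forwarded to [call_tissue_enriched()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir = NULL, out_dir,
                            expr_A = NULL, expr_B = NULL,
                            orthologs = NULL,
                            domains_A = NULL, domains_B = NULL,
                            terms_A = NULL, terms_B = NULL,
                            response_A = NULL, response_B = NULL,
                            studies = NULL,
                            alpha_de = 0.05, alpha_family = 0.01,
                            alpha_term = 0.05, min_share = 0.01,
                            fpkm_low = 1.0, ns_threshold = 0.05,
                            correction = "BH",
                            pseudocount = 1.0, min_log2fc = 0.0) {
  std <- function(given, name)
    if (!is.null(given)) given
    else if (!is.null(bundle_dir)) file.path(bundle_dir, name)
    else stop("path for '", name, "' missing and no bundle_dir given")
  cfg <- list(out_dir = out_dir,
              expr_A = std(expr_A, "expression_A.tsv"),
              expr_B = std(expr_B, "expression_B.tsv"),
              orthologs = std(orthologs, "orthologs.tsv"),
              domains_A = std(domains_A, "domains_A.tsv"),
              domains_B = std(domains_B, "domains_B.tsv"),
              terms_A = std(terms_A, "terms_A.tsv"),
              terms_B = std(terms_B, "terms_B.tsv"),
              response_A = std(response_A, "response_A.gmt"),
              response_B = std(response_B, "response_B.gmt"),
              studies = std(studies, "studies.gmt"),
              alpha_de = alpha_de, alpha_family = alpha_family,
              alpha_term = alpha_term, min_share = min_share,
              fpkm_low = fpkm_low, ns_threshold = ns_threshold,
              correction = correction, pseudocount = pseudocount,
              min_log2fc = min_log2fc)
  for (thr in c("alpha_de", "alpha_family", "alpha_term", "min_share",
                "ns_threshold"))
    if (cfg[[thr]] <= 0 || cfg[[thr]] >= 1)
      stop(thr, " must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

# stage wrapper: abort with the stage name on any failure
.stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  out
}

.stats_record <- function(stats, stage, input) {
  c(list(stage = stage, input = input),
    as.list(as.data.frame(stats)))
}

#' Run the full two-species comparison pipeline
#'
#' Reads all inputs from files, then: per-species correlation QC and
#' tissue-enrichment calling; the cross-study percentage-overlap matrix and
#' term-agreement table; the conserved-ortholog overlap test and conserved
#' gene report; FPKM category distributions and low-expression depletion
#' tests; cumulative family shares and family enrichment with the
#' cross-species shared list; and the pathogen-response overlap tables.
#'
#' Writes `fig1c_matrix.tsv`, `fig1d_agreement.tsv`,
#' `fig2a_conservation.tsv`, `fig2bc_distributions.tsv`,
#' `fig3ab_shares.tsv`, `fig3cd_family_enrichment.tsv`,
#' `table1_conserved_genes.tsv`, `table2_response_overlap.tsv` and
#' `summary.json` (plus the per-species call tables) into
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stats <- list()
  note <- function(stats, stage, input)
    all_stats[[length(all_stats) + 1L]] <<- .stats_record(stats, stage, input)

  inp <- .stage("read_inputs", {
    list(expr_A = read_expression_table(config$expr_A),
         expr_B = read_expression_table(config$expr_B),
         orthomap = read_ortholog_map(config$orthologs),
         domains_A = read_domain_annotation(config$domains_A),
         domains_B = read_domain_annotation(config$domains_B),
         terms_A = read_term_annotation(config$terms_A),
         terms_B = read_term_annotation(config$terms_B),
         response_A = read_gene_sets(config$response_A, "gmt"),
         response_B = read_gene_sets(config$response_B, "gmt"),
         studies = read_gene_sets(config$studies, "gmt"))
  })
  labA <- inp$expr_A$species_label
  labB <- inp$expr_B$species_label

  qc <- .stage("correlation_qc", {
    list(A = correlation_qc(inp$expr_A), B = correlation_qc(inp$expr_B))
  })

  calls <- .stage("call_enrichment", {
    out <- list(
      A = call_tissue_enriched(inp$expr_A, alpha = config$alpha_de,
                               pseudocount = config$pseudocount,
                               min_log2fc = config$min_log2fc),
      B = call_tissue_enriched(inp$expr_B, alpha = config$alpha_de,
                               pseudocount = config$pseudocount,
                               min_log2fc = config$min_log2fc))
    write_tsv_report(out$A$calls, file.path(config$out_dir, "calls_A.tsv"))
    write_tsv_report(out$B$calls, file.path(config$out_dir, "calls_B.tsv"))
    out
  })

  cross_study <- .stage("cross_study_matrix", {
    sets <- inp$studies$sets
    sets <- c(list(this_study = enriched_genes(calls$A)), sets)
    coll <- gene_set_collection(sets, labA)
    m <- pairwise_overlap_matrix(coll)
    df <- data.frame(set_name = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_report(df, file.path(config$out_dir, "fig1c_matrix.tsv"))
    list(matrix = m, collection = coll)
  })

  agreement <- .stage("term_agreement", {
    uni <- inp$expr_A$data$gene_id
    enr_terms <- lapply(cross_study$collection$sets, function(s) {
      te <- term_enrichment(s, inp$terms_A, uni,
                            alpha = config$alpha_term,
                            correction = config$correction)
      te$term_id[te$significant]
    })
    agree <- term_agreement(enr_terms)
    write_tsv_report(agree, file.path(config$out_dir,
                                      "fig1d_agreement.tsv"))
    agree
  })

  conserve <- .stage("conservation", {
    if (nrow(inp$orthomap) == 0L)
      stop("the ortholog map is empty")
    rep <- conserved_overlap_test(calls$A, calls$B, inp$orthomap)
    note(rep$stats, "conservation", "enriched_A vs enriched_B in core")
    df <- data.frame(n_orthologs = rep$n_orthologs,
                     enriched_A_in_core = rep$enriched_A_in_core,
                     enriched_B_in_core = rep$enriched_B_in_core,
                     shared = rep$shared, fold = rep$stats$fold,
                     p_value = rep$stats$p_value)
    write_tsv_report(df, file.path(config$out_dir,
                                   "fig2a_conservation.tsv"))
    write_tsv_report(conserved_gene_report(rep),
                     file.path(config$out_dir,
                               "table1_conserved_genes.tsv"))
    rep
  })

  distributions <- .stage("expression_distributions", {
    coreA <- inp$orthomap$gene_id_A
    coreB <- inp$orthomap$gene_id_B
    enrA <- enriched_genes(calls$A)
    enrB <- enriched_genes(calls$B)
    enrB_in_A <- coreA[match(restrict_to_core(enrB, inp$orthomap, "B"),
                             coreB)]
    enrA_in_B <- coreB[match(restrict_to_core(enrA, inp$orthomap, "A"),
                             coreA)]
    spec <- list(
      list(lab = labA, tab = inp$expr_A, set = enrA,
           name = "enriched_own"),
      list(lab = labA, tab = inp$expr_A, set = enrB_in_A,
           name = "orthologs_of_other_enriched"),
      list(lab = labA, tab = inp$expr_A, set = coreA,
           name = "all_one_to_one"),
      list(lab = labB, tab = inp$expr_B, set = enrB,
           name = "enriched_own"),
      list(lab = labB, tab = inp$expr_B, set = enrA_in_B,
           name = "orthologs_of_other_enriched"),
      list(lab = labB, tab = inp$expr_B, set = coreB,
           name = "all_one_to_one"))
    rows <- lapply(spec, function(s) {
      if (length(s$set) == 0L) return(NULL)
      d <- expression_category_distribution(s$set, s$tab,
                                            set_name = s$name)
      data.frame(species = s$lab, set_name = s$name, bin = d$bin_labels,
                 fraction = d$fractions, n_genes = d$n_genes,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    write_tsv_report(df, file.path(config$out_dir,
                                   "fig2bc_distributions.tsv"))
    # depletion of lowly expressed genes, against the one-to-one core
    depl_A <- low_expression_depletion_test(
      restrict_to_core(enrA, inp$orthomap, "A"), inp$expr_A,
      threshold = config$fpkm_low, background = coreA)
    depl_B <- low_expression_depletion_test(
      restrict_to_core(enrB, inp$orthomap, "B"), inp$expr_B,
      threshold = config$fpkm_low, background = coreB)
    note(depl_A, "low_expression_depletion", labA)
    note(depl_B, "low_expression_depletion", labB)
    list(table = df, depletion = list(A = depl_A, B = depl_B))
  })

  families <- .stage("family_analysis", {
    sh_A <- cumulative_family_share(inp$expr_A, inp$domains_A)
    sh_B <- cumulative_family_share(inp$expr_B, inp$domains_B)
    ab_A <- abundant_families(sh_A, config$min_share)
    ab_B <- abundant_families(sh_B, config$min_share)
    shares <- rbind(cbind(species = labA, sh_A, abundant =
                            sh_A$family_id %in% ab_A$family_id),
                    cbind(species = labB, sh_B, abundant =
                            sh_B$family_id %in% ab_B$family_id))
    write_tsv_report(shares, file.path(config$out_dir,
                                       "fig3ab_shares.tsv"))
    fe_A <- suppressMessages(
      family_enrichment(calls$A, inp$domains_A,
                        alpha = config$alpha_family))
    fe_B <- suppressMessages(
      family_enrichment(calls$B, inp$domains_B,
                        alpha = config$alpha_family))
    shared <- shared_enriched_families(fe_A, fe_B)
    fam <- rbind(cbind(species = labA, fe_A,
                       shared = fe_A$family_id %in% shared),
                 cbind(species = labB, fe_B,
                       shared = fe_B$family_id %in% shared))
    write_tsv_report(fam, file.path(config$out_dir,
                                    "fig3cd_family_enrichment.tsv"))
    list(shares_A = sh_A, shares_B = sh_B, enrichment_A = fe_A,
         enrichment_B = fe_B, shared = shared)
  })

  responses <- .stage("pathogen_overlap", {
    tab_A <- response_overlap_table(calls$A, inp$response_A,
                                    ns_threshold = config$ns_threshold)
    tab_B <- response_overlap_table(calls$B, inp$response_B,
                                    ns_threshold = config$ns_threshold)
    both <- rbind(tab_A, tab_B)
    for (i in seq_len(nrow(both)))
      all_stats[[length(all_stats) + 1L]] <- c(
        list(stage = "pathogen_overlap",
             input = paste(both$species_label[i], both$response_name[i])),
        as.list(both[i, c("k", "K", "n", "N", "expected", "fold",
                          "p_value")]))
    write_tsv_report(both, file.path(config$out_dir,
                                     "table2_response_overlap.tsv"))
    list(A = tab_A, B = tab_B)
  })

  .stage("summary", {
    run <- list(
      thresholds = config[c("alpha_de", "alpha_family", "alpha_term",
                            "min_share", "fpkm_low", "ns_threshold",
                            "correction", "pseudocount", "min_log2fc")],
      species = list(A = labA, B = labB),
      correlation_qc = qc,
      n_enriched = list(A = sum(calls$A$calls$enriched),
                        B = sum(calls$B$calls$enriched)),
      conservation = list(n_orthologs = conserve$n_orthologs,
                          shared = conserve$shared,
                          fold = conserve$stats$fold,
                          p_value = conserve$stats$p_value),
      shared_enriched_families = families$shared,
      overlap_stats = all_stats)
    write_json_summary(run, file.path(config$out_dir, "summary.json"))
    run
  })

  invisible(list(qc = qc, calls = calls, cross_study = cross_study,
                 agreement = agreement, conservation = conserve,
                 distributions = distributions, families = families,
                 responses = responses))
}
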