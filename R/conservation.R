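# ---------------------------------------------------------------------------
# Single-gene-level cross-species comparison through one-to-one orthologs:
# the conserved-enrichment overlap test (the Venn of the two enriched sets
# inside the orthologous core), FPKM category distributions, and
# low-expression depletion tests.
# ---------------------------------------------------------------------------

# accept either an enrichment_result or a bare character vector of gene ids
.as_enriched_set <- function(x) {
  if (inherits(x, "enrichment_result")) return(enriched_genes(x))
  if (is.character(x)) return(unique(x))
  stop("expected an enrichment_result or a character vector of gene ids")
}

#' Restrict a gene set to the one-to-one orthologous core
#'
#' @param gene_set character vector of gene ids.
#' @param orthomap ortholog map data frame (`gene_id_A`, `gene_id_B`).
#' @param side `"A"` or `"B"`: which species' identifiers `gene_set` uses.
#' @return The subset of `gene_set` with a one-to-one ortholog.
#' @export
restrict_to_core <- function(gene_set, orthomap, side = c("A", "B")) {
  side <- match.arg(side)
  col <- if (side == "A") "gene_id_A" else "gene_id_B"
  intersect(unique(as.character(gene_set)), orthomap[[col]])
}

#' Conserved-enrichment overlap test across the one-to-one core
#'
#' The universe is the set of one-to-one ortholog pairs (N = map size).
#' K and n are the two species' enriched sets restricted to the core, k the
#' number of pairs enriched on both sides.  Significance of k is assessed
#' with the one-sided (enrichment) hypergeometric test.
#'
#' @param enrA,enrB per-species enrichment: either `enrichment_result`
#'   objects or character vectors of enriched gene ids.
#' @param orthomap one-to-one ortholog map (`gene_id_A`, `gene_id_B`);
#'   must be non-empty.
#' @return An object of class `conservation_report`: list with
#'   `n_orthologs`, `enriched_A_in_core`, `enriched_B_in_core`, `shared`,
#'   `stats` (an [overlap_test()] result) and `shared_pairs` (data frame of
#'   the doubly enriched pairs).
#' @export
conserved_overlap_test <- function(enrA, enrB, orthomap) {
  orthomap <- validate_ortholog_map(orthomap)
  if (nrow(orthomap) == 0L)
    stop("no one-to-one core: the ortholog map is empty")
  setA <- .as_enriched_set(enrA)
  setB <- .as_enriched_set(enrB)
  coreA <- restrict_to_core(setA, orthomap, "A")
  coreB_asA <- orthomap$gene_id_A[orthomap$gene_id_B %in% setB]
  stats <- suppressMessages(
    overlap_test(coreA, coreB_asA, orthomap$gene_id_A))
  shared_A <- sort(intersect(coreA, coreB_asA))
  shared_pairs <- orthomap[match(shared_A, orthomap$gene_id_A), , drop = FALSE]
  rownames(shared_pairs) <- NULL
  structure(
    list(n_orthologs = nrow(orthomap),
         enriched_A_in_core = stats$K,
         enriched_B_in_core = stats$n,
         shared = stats$k,
         stats = stats,
         shared_pairs = shared_pairs),
    class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf(
    "conservation_report: %d / %d vs %d enriched core genes shared (N = %d)\n",
    x$shared, x$enriched_A_in_core, x$enriched_B_in_core, x$n_orthologs))
  cat(sprintf("  fold = %.3g, p = %.4g\n", x$stats$fold, x$stats$p_value))
  invisible(x)
}

#' Distribution of a gene set over FPKM expression categories
#'
#' Fraction of the set's genes falling into each FPKM bin of the chosen
#' library.  Default bins `[0,1) [1,10) [10,100) [100,Inf)`; only the
#' FPKM < 1 ("lowly expressed") boundary carries analytical weight, the
#' others are display conventions.
#'
#' @param gene_set character vector of gene ids (non-empty after
#'   intersection with the table).
#' @param table an [expression_table()].
#' @param which `"tissue"` or `"whole"`: which library's FPKM to bin.
#' @param bin_edges increasing upper edges of the bins; the last should be
#'   `Inf`.
#' @param set_name label carried into reports.
#' @return List with `set_name`, `bin_edges`, `bin_labels`, `fractions`
#'   (summing to 1) and `n_genes`.
#' @export
expression_category_distribution <- function(gene_set, table,
                                             which = c("tissue", "whole"),
                                             bin_edges = c(1, 10, 100, Inf),
                                             set_name = "gene_set") {
  which <- match.arg(which)
  stopifnot(inherits(table, "expression_table"))
  if (length(gene_set) == 0L) stop("gene set is empty")
  table <- .ensure_fpkm(table)
  d <- table$data
  idx <- match(unique(as.character(gene_set)), d$gene_id)
  if (all(is.na(idx))) stop("no gene of the set occurs in the table")
  if (anyNA(idx))
    message("expression_category_distribution: ", sum(is.na(idx)),
            " gene(s) not in the table dropped")
  idx <- idx[!is.na(idx)]
  fpkm <- if (which == "tissue") d$fpkm_tissue[idx] else d$fpkm_whole[idx]
  edges <- c(0, bin_edges)
  bins <- cut(fpkm, breaks = edges, right = FALSE, include.lowest = TRUE)
  labels <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1L])
  fr <- as.numeric(table(bins)) / length(fpkm)
  list(set_name = set_name, bin_edges = bin_edges, bin_labels = labels,
       fractions = fr, n_genes = length(fpkm))
}

#' Depletion of lowly expressed genes within a gene set
#'
#' Exact one-sided (lower-tail) test that the proportion of genes below the
#' FPKM threshold inside `gene_set` is smaller than among the background.
#' Tissue-enriched sets are expected to be significantly depleted of
#' FPKM < 1 genes.
#'
#' @param gene_set character vector of gene ids.
#' @param table an [expression_table()].
#' @param threshold FPKM cutoff defining "lowly expressed" (default 1).
#' @param which which library's FPKM to threshold (default `"tissue"`).
#' @param background optional character vector restricting the universe
#'   (e.g. the one-to-one core); default: all genes in the table.
#' @return An [overlap_test()] result with `alternative = "less"`, where
#'   `k` counts below-threshold members of the set.
#' @export
low_expression_depletion_test <- function(gene_set, table, threshold = 1,
                                          which = c("tissue", "whole"),
                                          background = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(table, "expression_table"))
  table <- .ensure_fpkm(table)
  d <- table$data
  universe <- if (is.null(background)) d$gene_id
              else intersect(unique(as.character(background)), d$gene_id)
  if (length(universe) == 0L) stop("empty background universe")
  fpkm <- if (which == "tissue") d$fpkm_tissue else d$fpkm_whole
  low <- d$gene_id[fpkm < threshold]
  overlap_test(gene_set, low, universe, alternative = "less")
}

#' Cross-species expression of a tissue-enriched set
#'
#' Maps `gene_set_A` through the one-to-one orthologs and reports which
#' fraction of the mapped genes falls below the FPKM threshold in the other
#' species' tissue library (the paper-style "very low expression in the
#' other species" fraction).  Genes without a one-to-one ortholog are
#' reported separately as unmappable.
#'
#' @param gene_set_A character vector of species-A gene ids.
#' @param orthomap one-to-one ortholog map.
#' @param table_B the other species' [expression_table()].
#' @param threshold FPKM cutoff (default 1).
#' @param which which library of species B to inspect (default tissue).
#' @return List with `fraction_below` (NA when nothing maps), `n_mapped`,
#'   `n_below`, `unmappable` (count) and `mapped_ids` (species-B ids).
#' @export
cross_species_expression_check <- function(gene_set_A, orthomap, table_B,
                                           threshold = 1,
                                           which = c("tissue", "whole")) {
  which <- match.arg(which)
  orthomap <- validate_ortholog_map(orthomap)
  stopifnot(inherits(table_B, "expression_table"))
  table_B <- .ensure_fpkm(table_B)
  gene_set_A <- unique(as.character(gene_set_A))
  hit <- match(gene_set_A, orthomap$gene_id_A)
  unmappable <- sum(is.na(hit))
  ids_B <- orthomap$gene_id_B[hit[!is.na(hit)]]
  idx <- match(ids_B, table_B$data$gene_id)
  ids_B <- ids_B[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  fpkm <- if (which == "tissue") table_B$data$fpkm_tissue[idx]
          else table_B$data$fpkm_whole[idx]
  n_below <- sum(fpkm < threshold)
  list(fraction_below = if (length(idx) > 0) n_below / length(idx)
                        else NA_real_,
       n_mapped = length(idx), n_below = n_below,
       unmappable = unmappable, mapped_ids = ids_B)
}

#' Tabulate the genes with conserved tissue-enriched expression
#'
#' One row per ortholog pair enriched in both species, sorted by the
#' species-A identifier, with optional gene symbols and descriptions.
#'
#' @param report a `conservation_report` from [conserved_overlap_test()].
#' @param symbols optional named character vector mapping species-A gene ids
#'   to gene symbols.
#' @param descriptions optional named character vector mapping species-A
#'   gene ids to free-text descriptions.
#' @return Data frame with columns `gene_id_A`, `symbol`, `gene_id_B`,
#'   `description` (always present, possibly empty).
#' @export
conserved_gene_report <- function(report, symbols = NULL,
                                  descriptions = NULL) {
  stopifnot(inherits(report, "conservation_report"))
  pairs <- report$shared_pairs
  if (nrow(pairs) == 0L)
    return(data.frame(gene_id_A = character(0), symbol = character(0),
                      gene_id_B = character(0),
                      description = character(0), stringsAsFactors = FALSE))
  out <- data.frame(
    gene_id_A = pairs$gene_id_A,
    symbol = if (is.null(symbols)) NA_character_
             else unname(symbols[pairs$gene_id_A]),
    gene_id_B = pairs$gene_id_B,
    description = if (is.null(descriptions)) NA_character_
                  else unname(descriptions[pairs$gene_id_A]),
    stringsAsFactors = FALSE)
  out[order(out$gene_id_A), , drop = FALSE]
}
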