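# ---------------------------------------------------------------------------
# Gene-family (protein-domain) level statistics.  A family is the set of
# genes carrying a given domain; a multi-domain gene contributes fully to
# each of its families, so cumulative shares are not a partition and may
# sum above one.
# ---------------------------------------------------------------------------

#' Cumulative expression share of each gene family
#'
#' For each family, the sum of its member genes' FPKM divided by the sum of
#' FPKM over ALL genes in the table (annotated or not), computed separately
#' for the tissue and the whole-organism library.  A gene annotated to
#' several families contributes its full FPKM to each of them.
#'
#' @param table an [expression_table()].
#' @param domains domain annotation data frame (`gene_id`, `family_id`).
#' @return Data frame with columns `family_id`, `n_genes`, `share_tissue`,
#'   `share_whole`, sorted by descending `share_tissue`.
#' @export
cumulative_family_share <- function(table, domains) {
  stopifnot(inherits(table, "expression_table"))
  table <- .ensure_fpkm(table)
  d <- table$data
  total_t <- sum(d$fpkm_tissue)
  total_w <- sum(d$fpkm_whole)
  if (total_t <= 0 || total_w <= 0)
    stop("total FPKM is zero in at least one library")
  dom <- domains[domains$gene_id %in% d$gene_id, , drop = FALSE]
  dom <- dom[!duplicated(dom[, c("gene_id", "family_id")]), , drop = FALSE]
  idx <- match(dom$gene_id, d$gene_id)
  st <- tapply(d$fpkm_tissue[idx], dom$family_id, sum)
  sw <- tapply(d$fpkm_whole[idx], dom$family_id, sum)
  ng <- tapply(dom$gene_id, dom$family_id, length)
  fam <- names(st)
  out <- data.frame(family_id = fam,
                    n_genes = as.integer(ng[fam]),
                    share_tissue = as.numeric(st[fam]) / total_t,
                    share_whole = as.numeric(sw[fam]) / total_w,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share_tissue, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter for abundantly and preferentially tissue-expressed families
#'
#' Keeps families whose tissue share exceeds `min_share` AND whose tissue
#' share exceeds their whole-organism share (the display rule for the
#' cumulative-expression comparison), sorted by descending tissue share.
#'
#' @param shares output of [cumulative_family_share()].
#' @param min_share minimum tissue cumulative share (default 0.01, i.e. 1
#'   percent of the tissue transcriptome).
#' @return Filtered, sorted data frame of the same shape.
#' @export
abundant_families <- function(shares, min_share = 0.01) {
  keep <- shares$share_tissue > min_share &
    shares$share_tissue > shares$share_whole
  out <- shares[keep, , drop = FALSE]
  out <- out[order(-out$share_tissue, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-family enrichment among tissue-enriched genes
#'
#' For each family with at least two members in the universe (all genes of
#' the calls table, or only annotated genes when `annotated_only`), tests
#' whether the family's members are over-represented among the
#' tissue-enriched genes (one-sided hypergeometric).  Significance defaults
#' to unadjusted `p < alpha` (the family-screen convention); BH-adjusted
#' mode is available.
#'
#' @param calls an `enrichment_result` from [call_tissue_enriched()], or a
#'   list with elements `universe` (character) and `enriched` (character).
#' @param domains domain annotation data frame (`gene_id`, `family_id`).
#' @param alpha significance level (default 0.01).
#' @param adjust if `TRUE`, apply BH across families and test `q < alpha`
#'   instead of raw p.
#' @return Data frame with one row per tested family: `family_id`, `k`
#'   (enriched members), `K` (family size in universe), `n` (enriched-set
#'   size), `N`, `expected`, `fold`, `p_value`, `q_value`, `significant`;
#'   sorted by ascending p.
#' @export
family_enrichment <- function(calls, domains, alpha = 0.01,
                              adjust = FALSE) {
  if (inherits(calls, "enrichment_result")) {
    universe <- calls$calls$gene_id
    enriched <- enriched_genes(calls)
  } else {
    universe <- unique(as.character(calls$universe))
    enriched <- unique(as.character(calls$enriched))
  }
  dom <- domains[domains$gene_id %in% universe, , drop = FALSE]
  dom <- dom[!duplicated(dom[, c("gene_id", "family_id")]), , drop = FALSE]
  fam_sizes <- table(dom$family_id)
  small <- names(fam_sizes)[fam_sizes < 2]
  if (length(small) > 0)
    message("family_enrichment: skipping ", length(small),
            " family(ies) with < 2 members in the universe")
  fams <- sort(names(fam_sizes)[fam_sizes >= 2])
  if (length(fams) == 0L)
    return(data.frame(family_id = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      expected = numeric(0), fold = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  members <- split(dom$gene_id, dom$family_id)
  rows <- lapply(fams, function(f) {
    st <- suppressMessages(overlap_test(members[[f]], enriched, universe))
    data.frame(family_id = f, k = st$k, K = st$K, n = st$n, N = st$N,
               expected = st$expected, fold = st$fold,
               p_value = st$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- if (adjust) out$q_value < alpha else out$p_value < alpha
  out <- out[order(out$p_value, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Families significantly tissue-enriched in both species
#'
#' @param resA,resB per-species [family_enrichment()] tables.
#' @return Sorted character vector of family ids significant on both sides.
#' @export
shared_enriched_families <- function(resA, resB) {
  sort(intersect(resA$family_id[resA$significant],
                 resB$family_id[resB$significant]))
}
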