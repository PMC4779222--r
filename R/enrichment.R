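# ---------------------------------------------------------------------------
# Tissue-enrichment calling from one tissue library vs one whole-organism
# library.  With a single library per condition there is no replicate
# dispersion to estimate, so the defensible test is the per-gene one-sided
# 2x2 exact test on raw counts against library totals, BH-corrected across
# genes.  FPKM and the pseudocounted log2 fold change are display values
# only; the test sees raw counts.
# ---------------------------------------------------------------------------

#' Fragments per kilobase per million mapped reads
#'
#' `count * 1e9 / (length_bp * library_size)`; vectorised.
#'
#' @param count non-negative read count(s).
#' @param length_bp gene length(s) in base pairs (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return FPKM value(s).
#' @examples
#' compute_fpkm(100, 1000, 1e6)  # 100
#' @export
compute_fpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count * 1e9 / (length_bp * library_size)
}

# fill fpkm columns from counts when absent
.ensure_fpkm <- function(table) {
  d <- table$data
  if (is.null(d$fpkm_tissue))
    d$fpkm_tissue <- compute_fpkm(d$count_tissue, d$length_bp,
                                  table$library_size_tissue)
  if (is.null(d$fpkm_whole))
    d$fpkm_whole <- compute_fpkm(d$count_whole, d$length_bp,
                                 table$library_size_whole)
  table$data <- d
  table
}

#' Call tissue-enriched genes from paired tissue / whole-organism libraries
#'
#' Per gene, tests one-sidedly whether the gene's read proportion in the
#' tissue library exceeds its proportion in the whole-organism library:
#' the hypergeometric upper tail on the 2x2 table `(count_tissue,
#' library_size_tissue - count_tissue; count_whole, library_size_whole -
#' count_whole)`.  P-values are BH-adjusted across all genes; a gene is
#' flagged `enriched` when `q <= alpha`, its tissue FPKM exceeds its
#' whole-organism FPKM, and its pseudocounted log2 fold change reaches
#' `min_log2fc`.
#'
#' @param table an [expression_table()].
#' @param alpha FDR level for the enriched flag (default 0.05).
#' @param pseudocount FPKM pseudocount for the displayed log2 fold change
#'   (default 1; the test itself uses raw counts).
#' @param min_log2fc minimum displayed log2 fold change required for the
#'   enriched flag (default 0).
#' @return An object of class `enrichment_result`: list with
#'   `species_label`, a `calls` data frame (`gene_id`, `fpkm_tissue`,
#'   `fpkm_whole`, `log2fc`, `p_value`, `q_value`, `enriched`) and the
#'   `thresholds` used.
#' @export
call_tissue_enriched <- function(table, alpha = 0.05, pseudocount = 1.0,
                                 min_log2fc = 0.0) {
  stopifnot(inherits(table, "expression_table"))
  if (table$library_size_tissue <= 0 || table$library_size_whole <= 0)
    stop("library sizes must be positive")
  table <- .ensure_fpkm(table)
  d <- table$data
  lt <- table$library_size_tissue
  lw <- table$library_size_whole
  if (any(d$count_tissue > lt) || any(d$count_whole > lw))
    stop("a per-gene count exceeds its library size")
  N <- lt + lw
  p <- vapply(seq_len(nrow(d)), function(i) {
    K <- d$count_tissue[i] + d$count_whole[i]
    if (K == 0) return(1)
    hypergeom_upper_tail(d$count_tissue[i], K, lt, N)
  }, numeric(1))
  q <- bh_adjust(p)
  log2fc <- log2((d$fpkm_tissue + pseudocount) /
                 (d$fpkm_whole + pseudocount))
  enriched <- q <= alpha & d$fpkm_tissue > d$fpkm_whole & log2fc >= min_log2fc
  structure(
    list(species_label = table$species_label,
         calls = data.frame(gene_id = d$gene_id,
                            fpkm_tissue = d$fpkm_tissue,
                            fpkm_whole = d$fpkm_whole,
                            log2fc = log2fc,
                            p_value = p, q_value = q,
                            enriched = enriched,
                            stringsAsFactors = FALSE),
         thresholds = list(alpha = alpha, pseudocount = pseudocount,
                           min_log2fc = min_log2fc)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %s, %d genes, %d enriched (q <= %g)\n",
              x$species_label, nrow(x$calls), sum(x$calls$enriched),
              x$thresholds$alpha))
  invisible(x)
}

#' Gene identifiers flagged as tissue-enriched
#' @param result an `enrichment_result`.
#' @return Character vector of enriched gene ids.
#' @export
enriched_genes <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  result$calls$gene_id[result$calls$enriched]
}

#' Library comparability check via tissue/whole expression correlation
#'
#' Computes [log_correlation()] of tissue vs whole-organism FPKM across all
#' genes.  High correlation indicates that relative (library-total)
#' normalisation is valid and the two libraries are comparable.
#'
#' @param table an [expression_table()].
#' @param method correlation method, see [log_correlation()].
#' @param floor flag threshold: `comparable` is `TRUE` when the coefficient
#'   reaches this value (default 0.6).
#' @return List with `correlation`, `comparable`, `method`, `floor`.
#' @export
correlation_qc <- function(table, method = "pearson", floor = 0.6) {
  stopifnot(inherits(table, "expression_table"))
  table <- .ensure_fpkm(table)
  r <- log_correlation(table$data$fpkm_tissue, table$data$fpkm_whole,
                       method = method)
  list(correlation = r, comparable = !is.na(r) && r >= floor,
       method = method, floor = floor)
}
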