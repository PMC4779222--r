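# ---------------------------------------------------------------------------
# Gene-set-level comparisons: the cross-study percentage-overlap matrix,
# GO-term enrichment and cross-dataset term agreement, and the
# pathogen-response overlap table.
# ---------------------------------------------------------------------------

#' Pairwise percentage-overlap matrix between gene sets
#'
#' `value[i, j]` is the percentage of row set `i`'s genes also found in
#' column set `j`; the matrix is row-normalised and therefore NOT symmetric
#' in general.  Diagonal entries are 100 by construction.
#'
#' @param sets a [gene_set_collection()] with at least two sets.
#' @return A square numeric matrix (percentages) with set names as
#'   dimnames.
#' @export
pairwise_overlap_matrix <- function(sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  nms <- names(sets$sets)
  if (length(nms) < 2L) stop("need at least two gene sets")
  m <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in nms) for (j in nms)
    m[i, j] <- 100 * length(intersect(sets$sets[[i]], sets$sets[[j]])) /
      length(sets$sets[[i]])
  m
}

#' Term (GO) over-representation within a gene set
#'
#' For every annotation term with at least two annotated genes in the
#' universe, tests over-representation of the term's genes within
#' `gene_set` (one-sided hypergeometric), then applies the requested
#' multiple-testing correction.  Annotations are used flat, as given.
#'
#' @param gene_set character vector of gene ids.
#' @param terms term annotation data frame (`gene_id`, `term_id`, optional
#'   `term_label`).
#' @param universe character vector of gene ids forming the universe.
#' @param alpha significance level after correction (default 0.05).
#' @param correction `"BH"` (default) or `"none"`.
#' @return Data frame with one row per tested term: `term_id`,
#'   `term_label`, `k`, `K`, `n`, `N`, `expected`, `fold`, `p_value`,
#'   `q_value`, `significant`; sorted by ascending p.
#' @export
term_enrichment <- function(gene_set, terms, universe, alpha = 0.05,
                            correction = c("BH", "none")) {
  correction <- match.arg(correction)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  ann <- terms[terms$gene_id %in% universe, , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("gene_id", "term_id")]), , drop = FALSE]
  sizes <- table(ann$term_id)
  keep <- sort(names(sizes)[sizes >= 2])
  labels <- if ("term_label" %in% names(ann)) {
    tl <- ann$term_label[match(keep, ann$term_id)]
    ifelse(is.na(tl), keep, tl)
  } else keep
  if (length(keep) == 0L)
    return(data.frame(term_id = character(0), term_label = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), expected = numeric(0),
                      fold = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  members <- split(ann$gene_id, ann$term_id)
  rows <- lapply(seq_along(keep), function(i) {
    st <- suppressMessages(
      overlap_test(members[[keep[i]]], gene_set, universe))
    data.frame(term_id = keep[i], term_label = labels[i],
               k = st$k, K = st$K, n = st$n, N = st$N,
               expected = st$expected, fold = st$fold,
               p_value = st$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- if (correction == "BH") out$q_value <= alpha
                     else out$p_value <= alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agreement of enriched terms across datasets
#'
#' Counts, for every term enriched in at least one dataset, in how many
#' datasets it was enriched.
#'
#' @param per_dataset_enriched_terms named list of character vectors of
#'   enriched term ids, one per dataset.
#' @return Data frame with `term_id`, `n_datasets_enriched` and one logical
#'   flag column per dataset, sorted by descending agreement count.
#' @export
term_agreement <- function(per_dataset_enriched_terms) {
  if (is.null(names(per_dataset_enriched_terms)))
    names(per_dataset_enriched_terms) <-
      paste0("dataset_", seq_along(per_dataset_enriched_terms))
  all_terms <- sort(unique(unlist(per_dataset_enriched_terms)))
  if (length(all_terms) == 0L) {
    out <- data.frame(term_id = character(0),
                      n_datasets_enriched = integer(0),
                      stringsAsFactors = FALSE)
    for (nm in names(per_dataset_enriched_terms)) out[[nm]] <- logical(0)
    return(out)
  }
  flags <- vapply(per_dataset_enriched_terms,
                  function(s) all_terms %in% s,
                  logical(length(all_terms)))
  flags <- matrix(flags, nrow = length(all_terms),
                  dimnames = list(NULL, names(per_dataset_enriched_terms)))
  out <- data.frame(term_id = all_terms,
                    n_datasets_enriched = as.integer(rowSums(flags)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  out <- out[order(-out$n_datasets_enriched, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of tissue-enriched genes with pathogen-response gene sets
#'
#' One row per response set (named `"<pathogen>/<up|down>"`): the common
#' gene count with the species' tissue-enriched set, the enrichment fold,
#' the exact upper-tail p-value, and a display rendering of the p-value
#' (`"n.s."` at or above `ns_threshold`, numbers between 0.01 and the
#' threshold, power-of-ten ceilings below 0.01).
#'
#' @param calls an `enrichment_result` for the species.
#' @param response_sets a [gene_set_collection()] whose `species_label`s
#'   must match `calls$species_label` (where not `NA`).
#' @param universe character vector of gene ids; default: all genes with
#'   expression records in the species (the calls table).
#' @param ns_threshold p-value at or above which the display reads
#'   `"n.s."` (default 0.05).
#' @return Data frame with `response_name`, `species_label`, `k`, `K`, `n`,
#'   `N`, `expected`, `fold`, `p_value`, `display_p`.
#' @export
response_overlap_table <- function(calls, response_sets, universe = NULL,
                                   ns_threshold = 0.05) {
  stopifnot(inherits(calls, "enrichment_result"),
            inherits(response_sets, "gene_set_collection"))
  if (is.null(universe)) universe <- calls$calls$gene_id
  universe <- unique(as.character(universe))
  enr <- enriched_genes(calls)
  labs <- response_sets$species_label
  wrong <- names(response_sets$sets)[!is.na(labs) &
                                       labs != calls$species_label]
  if (length(wrong) > 0)
    stop("response set(s) from the wrong species (",
         paste(wrong, collapse = ", "), "); calls are for ",
         calls$species_label)
  rows <- lapply(names(response_sets$sets), function(nm) {
    rs <- response_sets$sets[[nm]]
    if (length(intersect(rs, universe)) == 0L)
      stop("response set '", nm, "' is disjoint from the universe")
    st <- suppressMessages(overlap_test(enr, rs, universe))
    data.frame(response_name = nm, species_label = calls$species_label,
               k = st$k, K = st$K, n = st$n, N = st$N,
               expected = st$expected, fold = st$fold,
               p_value = st$p_value,
               display_p = format_p_display(st$p_value, ns_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
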