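# ---------------------------------------------------------------------------
# Readers and writers for every tabular artifact the pipeline touches.
# Canonical dialect: tab-separated UTF-8 with '#' comment lines; gene sets
# additionally as GMT.  Base R connections decompress .gz transparently, so
# all paths may be gzipped.
# ---------------------------------------------------------------------------

#' Construct an expression table
#'
#' Per-gene expression records for one species: a tissue library and a
#' whole-organism library sequenced in parallel.  Library sizes (total
#' mapped reads) are explicit because multi-mapping makes column sums
#' unreliable as totals.
#'
#' @param species_label species name for reports.
#' @param data data frame with columns `gene_id`, `length_bp`,
#'   `count_tissue`, `count_whole` and optionally `fpkm_tissue`,
#'   `fpkm_whole`.
#' @param library_size_tissue,library_size_whole positive integer totals of
#'   mapped reads per library.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(species_label, data,
                             library_size_tissue, library_size_whole) {
  required <- c("gene_id", "length_bp", "count_tissue", "count_whole")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("expression table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  data$gene_id <- as.character(data$gene_id)
  dup <- data$gene_id[duplicated(data$gene_id)]
  if (length(dup) > 0)
    stop("duplicated gene_id in expression table: ",
         paste(unique(dup), collapse = ", "))
  for (col in c("count_tissue", "count_whole")) {
    bad <- which(is.na(data[[col]]) | data[[col]] < 0)
    if (length(bad) > 0)
      stop("negative or missing ", col, " at row ", bad[1L])
  }
  bad_len <- which(is.na(data$length_bp) | data$length_bp <= 0)
  if (length(bad_len) > 0)
    stop("non-positive gene length at row ", bad_len[1L])
  if (length(library_size_tissue) != 1L || is.na(library_size_tissue) ||
      library_size_tissue <= 0 ||
      length(library_size_whole) != 1L || is.na(library_size_whole) ||
      library_size_whole <= 0)
    stop("library sizes must be single positive numbers")
  structure(
    list(species_label = as.character(species_label),
         data = as.data.frame(data, stringsAsFactors = FALSE),
         library_size_tissue = as.numeric(library_size_tissue),
         library_size_whole = as.numeric(library_size_whole)),
    class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %s, %d genes (libraries %g / %g reads)\n",
              x$species_label, nrow(x$data),
              x$library_size_tissue, x$library_size_whole))
  invisible(x)
}

# parse "#key=value" comment lines at the top of a TSV
.parse_header_comments <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  out <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    kv <- sub("^#\\s*", "", line)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      out[[trimws(key)]] <- trimws(val)
    }
  }
  out
}

#' Read an expression table from TSV
#'
#' Expects a header `gene_id  length_bp  count_tissue  count_whole`
#' (optionally plus `fpkm_tissue`, `fpkm_whole`).  Library sizes come either
#' from `#library_size_tissue=` / `#library_size_whole=` comment lines or
#' from the function arguments (arguments win).
#'
#' @param path TSV file (may be gzipped).
#' @param species_label species name; defaults to the file stem.
#' @param library_size_tissue,library_size_whole optional overrides for the
#'   header-comment library sizes.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, species_label = NULL,
                                  library_size_tissue = NULL,
                                  library_size_whole = NULL) {
  hdr <- .parse_header_comments(path)
  if (is.null(species_label))
    species_label <- if (!is.null(hdr[["species"]])) hdr[["species"]]
                     else sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  if (is.null(library_size_tissue))
    library_size_tissue <- as.numeric(hdr[["library_size_tissue"]])
  if (is.null(library_size_whole))
    library_size_whole <- as.numeric(hdr[["library_size_whole"]])
  if (length(library_size_tissue) == 0L || length(library_size_whole) == 0L)
    stop("library sizes not found in header comments nor supplied as arguments")
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  expression_table(species_label, d, library_size_tissue, library_size_whole)
}

#' Write an expression table to TSV (round-trips with the reader)
#'
#' @param table an [expression_table()].
#' @param path output path (`.gz` to compress).
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("#species=%s", table$species_label),
    sprintf("#library_size_tissue=%.0f", table$library_size_tissue),
    sprintf("#library_size_whole=%.0f", table$library_size_whole)), con)
  d <- table$data[order(table$data$gene_id), , drop = FALSE]
  num <- vapply(d, is.numeric, logical(1)) & !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], signif, digits = 6)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' Two-column TSV (`gene_id_A`, `gene_id_B`); a header line is detected and
#' kept when it matches those names, otherwise the first row is data.  Each
#' identifier may appear at most once on its side.  An empty file yields an
#' empty (valid) map.
#'
#' @param path TSV file (may be gzipped).
#' @return A data frame with columns `gene_id_A`, `gene_id_B`.
#' @export
read_ortholog_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(gene_id_A = character(0), gene_id_B = character(0),
                      stringsAsFactors = FALSE))
  if (grepl("^gene_id_A\\tgene_id_B", lines[1L])) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("ortholog map rows must have two tab-separated columns")
  m <- data.frame(gene_id_A = trimws(vapply(parts, `[[`, "", 1L)),
                  gene_id_B = trimws(vapply(parts, `[[`, "", 2L)),
                  stringsAsFactors = FALSE)
  validate_ortholog_map(m)
}

#' Validate a one-to-one ortholog map
#' @param m data frame with columns `gene_id_A`, `gene_id_B`.
#' @return The validated map, invisibly usable downstream.
#' @export
validate_ortholog_map <- function(m) {
  if (any(!nzchar(m$gene_id_A)) || any(!nzchar(m$gene_id_B)))
    stop("ortholog map contains empty gene identifiers")
  for (side in c("gene_id_A", "gene_id_B")) {
    dup <- unique(m[[side]][duplicated(m[[side]])])
    if (length(dup) > 0)
      stop("ortholog map is not one-to-one; repeated on ", side, ": ",
           paste(dup, collapse = ", "))
  }
  m
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique, non-empty).
#' @param species_label single species label, or a named vector giving one
#'   label per set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, species_label = NA_character_) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (any(duplicated(names(sets)))) stop("duplicate gene set name")
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty) > 0)
    stop("empty gene set after parsing: ", paste(empty, collapse = ", "))
  if (length(species_label) == 1L)
    species_label <- stats::setNames(rep(species_label, length(sets)), names(sets))
  structure(list(sets = sets, species_label = species_label),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x$sets)))
  for (nm in names(x$sets))
    cat(sprintf("  %s (%s): %d genes\n", nm,
                x$species_label[[nm]], length(x$sets[[nm]])))
  invisible(x)
}

#' Read gene sets from plain or GMT files
#'
#' Plain format: one identifier per line, the set named after the file stem.
#' GMT: standard tab-separated lines `name  description  id1  id2 ...`.
#' Identifiers are whitespace-trimmed and de-duplicated; an empty set or a
#' duplicated GMT set name is an error.
#'
#' @param path input file (may be gzipped).
#' @param format `"plain"` or `"gmt"`; guessed from the extension when
#'   missing.
#' @param species_label species label attached to every set.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path, format = c("auto", "plain", "gmt"),
                           species_label = NA_character_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt(\\.gz)?$", path)) "gmt" else "plain"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "plain") {
    nm <- sub("\\.(txt|tsv|genes)(\\.gz)?$", "", basename(path))
    sets <- stats::setNames(list(lines), nm)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L))
      stop("GMT lines need at least a name, a description and one gene")
    nms <- vapply(parts, `[[`, "", 1L)
    if (any(duplicated(nms)))
      stop("duplicate gene set name in GMT: ",
           paste(unique(nms[duplicated(nms)]), collapse = ", "))
    sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), nms)
    desc <- vapply(parts, `[[`, "", 2L)
    if (all(is.na(species_label)) && any(grepl("^species=", desc))) {
      species_label <- stats::setNames(
        ifelse(grepl("^species=", desc), sub("^species=", "", desc),
               NA_character_), nms)
    }
  }
  gene_set_collection(sets, species_label)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nms <- sort(names(collection$sets))
  lines <- vapply(nms, function(nm) {
    paste(c(nm, paste0("species=", collection$species_label[[nm]]),
            sort(collection$sets[[nm]])), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# shared reader for many-to-many annotation tables
.read_annotation <- function(path, key_col, expected) {
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(expected, names(d))
  if (length(missing_cols) > 0)
    stop("annotation file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(d), c(expected, "term_label"))
  if (length(extra) > 0) {
    warning("ignoring unknown annotation column(s): ",
            paste(extra, collapse = ", "))
    d <- d[, setdiff(names(d), extra), drop = FALSE]
  }
  d$gene_id <- as.character(d$gene_id)
  d[[key_col]] <- as.character(d[[key_col]])
  d[!duplicated(d[, c("gene_id", key_col)]), , drop = FALSE]
}

#' Read a gene-to-protein-domain annotation (many-to-many)
#'
#' TSV with columns `gene_id`, `family_id` (e.g. PFAM accessions).  A gene
#' may carry several families; duplicate rows are collapsed silently;
#' unknown extra columns are dropped with a warning.
#'
#' @param path TSV file (may be gzipped).
#' @return Data frame with columns `gene_id`, `family_id`.
#' @export
read_domain_annotation <- function(path) {
  d <- .read_annotation(path, "family_id", c("gene_id", "family_id"))
  d[, c("gene_id", "family_id")]
}

#' Read a gene-to-GO-term annotation (many-to-many)
#'
#' TSV with columns `gene_id`, `term_id` and optionally `term_label`.
#'
#' @param path TSV file (may be gzipped).
#' @return Data frame with columns `gene_id`, `term_id`, `term_label`.
#' @export
read_term_annotation <- function(path) {
  d <- .read_annotation(path, "term_id", c("gene_id", "term_id"))
  if (is.null(d$term_label)) d$term_label <- NA_character_
  d[, c("gene_id", "term_id", "term_label")]
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted by the first (primary-key) column, floating point values
#' are rounded to six significant digits, so output is byte-stable across
#' runs and independent of input row order.
#'
#' @param report a data frame.
#' @param path output path (`.gz` to compress).
#' @export
write_tsv_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  if (nrow(report) > 0 && ncol(report) > 0)
    report <- report[order(report[[1L]]), , drop = FALSE]
  num <- vapply(report, is.numeric, logical(1)) &
    !vapply(report, is.integer, logical(1))
  report[num] <- lapply(report[num], signif, digits = 6)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a TSV report written by [write_tsv_report()]
#' @param path TSV file.
#' @return A data frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a JSON run summary
#'
#' Serialises a (possibly nested) list of results; used by the pipeline to
#' store every overlap statistic it produced together with the thresholds in
#' force.
#'
#' @param run a list; the pipeline guarantees a `thresholds` block.
#' @param path output path.
#' @export
write_json_summary <- function(run, path) {
  jsonlite::write_json(run, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
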