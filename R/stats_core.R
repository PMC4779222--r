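#' gutdiverge: cross-species comparison of nematode intestinal transcriptomes
#'
#' Tools to call tissue-enriched genes from paired tissue/whole-animal RNA-seq
#' libraries in two species and to quantify conservation of the resulting
#' transcriptomes at the single-gene (one-to-one ortholog), gene-family
#' (protein domain) and functional (gene set / GO term) levels.  A synthetic
#' two-species generator with planted ground truth supports calibration and
#' parameter-recovery testing of every stage.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Hypergeometric machinery.
#
# All overlap statistics in the package reduce to tail probabilities of
# X ~ Hypergeometric(N, K, n): draw n items from an urn of N containing K
# marked ones, X = number of marked items drawn.  The pmf is evaluated over
# its whole support in log space via the ratio recurrence
#
#   pmf(k+1)/pmf(k) = (K-k)(n-k) / ((k+1)(N-K-n+k+1))
#
# which stays finite at genome scale (N ~ 10^7) where factorials overflow.
# ---------------------------------------------------------------------------

.check_hyper_args <- function(K, n, N) {
  if (length(K) != 1L || length(n) != 1L || length(N) != 1L)
    stop("K, n and N must be single numbers")
  for (v in list(K = K, n = n, N = N)) {
    if (is.na(v) || v < 0 || v != round(v)) stop("K, n and N must be non-negative integers")
  }
  if (N <= 0) stop("universe size N must be > 0")
  if (K > N || n > N) stop("K and n cannot exceed the universe size N")
  invisible(NULL)
}

# log pmf over the full support max(0, K+n-N) .. min(K, n)
.hyper_logpmf_support <- function(K, n, N) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  lp0 <- lchoose(K, lo) + lchoose(N - K, n - lo) - lchoose(N, n)
  if (hi > lo) {
    j <- lo:(hi - 1)
    step <- log(K - j) + log(n - j) - log(j + 1) - log(N - K - n + j + 1)
    lp <- c(lp0, lp0 + cumsum(step))
  } else {
    lp <- lp0
  }
  list(k = lo:hi, logp = lp)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric probability mass function over the full support
#'
#' Exposed mainly so that tests can assert that the mass function the tail
#' probabilities are built from sums to one and matches enumeration.
#'
#' @param K number of marked items in the universe.
#' @param n number of items drawn.
#' @param N universe size.
#' @return A data frame with columns `k` (the support) and `prob`.
#' @examples
#' hypergeom_pmf(3, 3, 6)
#' @export
hypergeom_pmf <- function(K, n, N) {
  .check_hyper_args(K, n, N)
  s <- .hyper_logpmf_support(K, n, N)
  data.frame(k = s$k, prob = exp(s$logp))
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' The enrichment-direction one-sided Fisher exact test used throughout the
#' package: the probability that a random overlap between a size-`K` and a
#' size-`n` subset of an `N`-gene universe is at least as large as the one
#' observed.  Computed in log space over the exact support, so it is accurate
#' far into the tail (p-values below 1e-300 are representable down to the
#' double minimum).
#'
#' @param k observed overlap count(s); may be a vector.
#' @param K size of set one within the universe.
#' @param n size of set two within the universe.
#' @param N universe size (> 0).
#' @return Numeric vector of tail probabilities, one per `k`.
#' @examples
#' hypergeom_upper_tail(15, 124, 107, 5985)   # conserved-ortholog overlap
#' hypergeom_upper_tail(2, 3, 3, 6)           # = 0.5
#' @seealso [hypergeom_lower_tail()], [overlap_test()]
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  .check_hyper_args(K, n, N)
  if (length(k) < 1L) stop("k must be non-empty")
  if (any(is.na(k)) || any(k < 0) || any(k != round(k)))
    stop("k must contain non-negative integers")
  if (any(k > min(K, n)))
    stop("k cannot exceed min(K, n) = ", min(K, n))
  s <- .hyper_logpmf_support(K, n, N)
  lo <- s$k[1L]
  vapply(k, function(ki) {
    if (ki <= lo) return(1)
    idx <- which(s$k >= ki)
    min(1, exp(.logsumexp(s$logp[idx])))
  }, numeric(1))
}

#' Lower-tail hypergeometric probability P(X <= k)
#'
#' The depletion-direction one-sided exact test (used e.g. to show that
#' tissue-enriched gene sets are depleted of lowly expressed genes).
#'
#' @inheritParams hypergeom_upper_tail
#' @return Numeric vector of tail probabilities, one per `k`.
#' @export
hypergeom_lower_tail <- function(k, K, n, N) {
  .check_hyper_args(K, n, N)
  if (any(is.na(k)) || any(k < 0) || any(k != round(k)))
    stop("k must contain non-negative integers")
  if (any(k > min(K, n)))
    stop("k cannot exceed min(K, n) = ", min(K, n))
  s <- .hyper_logpmf_support(K, n, N)
  hi <- s$k[length(s$k)]
  vapply(k, function(ki) {
    if (ki >= hi) return(1)
    idx <- which(s$k <= ki)
    if (length(idx) == 0L) return(0)
    min(1, exp(.logsumexp(s$logp[idx])))
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Overlap statistics
# ---------------------------------------------------------------------------

#' Exact overlap test between two gene sets in a common universe
#'
#' Counts the overlap `k` between `set1` (size `K`) and `set2` (size `n`)
#' inside `universe` (size `N`), reports the expected overlap under
#' independence `K*n/N`, the enrichment fold `k / expected`, and the exact
#' hypergeometric p-value in the requested direction.  Members of either set
#' that are not part of the universe are dropped before counting (published
#' gene sets routinely carry retired identifiers); a message reports how many
#' were dropped.
#'
#' @param set1,set2 character vectors of gene identifiers.
#' @param universe character vector: the gene universe.
#' @param alternative `"greater"` (enrichment, default), `"less"`
#'   (depletion), or `"two.sided"` (sum of point masses no larger than the
#'   observed one, the `fisher.test` convention).
#' @return An object of class `overlap_stats`: a list with elements `k`, `K`,
#'   `n`, `N`, `expected`, `fold` (0 when `k = 0`, `NA` when the expectation
#'   is 0), `p_value`, `q_value` (`NA` until filled by a multiple-testing
#'   step) and `alternative`.
#' @examples
#' u <- sprintf("g%04d", 1:5985)
#' overlap_test(u[1:124], u[c(1:15, 200:291)], u)
#' @export
overlap_test <- function(set1, set2, universe,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  s1 <- unique(as.character(set1))
  s2 <- unique(as.character(set2))
  d1 <- sum(!s1 %in% universe)
  d2 <- sum(!s2 %in% universe)
  if (d1 + d2 > 0)
    message("overlap_test: dropped ", d1 + d2,
            " set member(s) outside the universe")
  s1 <- s1[s1 %in% universe]
  s2 <- s2[s2 %in% universe]
  K <- length(s1)
  n <- length(s2)
  N <- length(universe)
  k <- length(intersect(s1, s2))
  expected <- K * n / N
  fold <- if (expected > 0) k / expected else NA_real_
  if (k == 0 && expected > 0) fold <- 0
  p <- switch(alternative,
    greater = hypergeom_upper_tail(k, K, n, N),
    less    = hypergeom_lower_tail(k, K, n, N),
    two.sided = {
      s <- .hyper_logpmf_support(K, n, N)
      obs <- s$logp[match(k, s$k)]
      idx <- which(s$logp <= obs + 1e-7)
      min(1, exp(.logsumexp(s$logp[idx])))
    })
  structure(
    list(k = k, K = K, n = n, N = N, expected = expected, fold = fold,
         p_value = p, q_value = NA_real_, alternative = alternative),
    class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "overlap: k = %d of K = %d x n = %d in N = %d (expected %.3g)\n",
    x$k, x$K, x$n, x$N, x$expected))
  cat(sprintf("  fold = %s, p (%s) = %.4g\n",
              ifelse(is.na(x$fold), "undefined", sprintf("%.3g", x$fold)),
              x$alternative, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.overlap_stats <- function(x, ...) {
  data.frame(k = x$k, K = x$K, n = x$n, N = x$N, expected = x$expected,
             fold = x$fold, p_value = x$p_value, q_value = x$q_value,
             alternative = x$alternative, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`,
#' the false-discovery-rate control applied across every p-value screen in
#' the pipeline (the enrichment caller, term enrichment, and optionally the
#' family screen).
#'
#' @param p_values numeric vector of p-values, all in \[0, 1\].
#' @return Numeric vector of q-values of the same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # -> 0.03 0.03 0.03
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Correlation between paired expression vectors
#'
#' Pearson correlation is computed on `log10(x + 1)`-transformed values (the
#' usual scale for FPKM comparisons between libraries); Spearman is rank
#' based and applied to the raw values.  Pairs where both values are zero
#' are retained.
#'
#' @param x,y non-negative numeric vectors of equal length (>= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A correlation coefficient in \[-1, 1\].
#' @export
log_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  if (method == "pearson") {
    stats::cor(log10(x + 1), log10(y + 1), method = "pearson")
  } else {
    stats::cor(x, y, method = "spearman")
  }
}

#' Format a p-value the way comparison tables print it
#'
#' Values at or above `ns_threshold` print as `"n.s."`; values between 0.01
#' and the threshold print as rounded numbers; smaller values print as a
#' power-of-ten ceiling such as `"<10^-12"` (the largest power of ten still
#' above the p-value).
#'
#' @param p a p-value.
#' @param ns_threshold the non-significance cut (default 0.05).
#' @return A character scalar.
#' @export
format_p_display <- function(p, ns_threshold = 0.05) {
  if (is.na(p)) return("n.s.")
  if (p >= ns_threshold) return("n.s.")
  if (p >= 0.01) return(sprintf("%.2f", p))
  if (p == 0) return("<10^-308")
  e <- floor(-log10(p))
  if (p >= 10^(-e)) e <- e - 1  # exact powers of ten: keep the claim strict
  sprintf("<10^-%d", e)
}
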