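# Shared in-code fixtures: all test data is built programmatically.

# a minimal well-formed expression table
toy_expression_table <- function(species = "toy",
                                 gene_id = c("g1", "g2", "g3"),
                                 length_bp = c(1000, 2000, 500),
                                 count_tissue = c(100, 50, 10),
                                 count_whole = c(80, 60, 10),
                                 lib_t = 1e6, lib_w = 1e6,
                                 fpkm = TRUE) {
  d <- data.frame(gene_id = gene_id, length_bp = length_bp,
                  count_tissue = count_tissue, count_whole = count_whole,
                  stringsAsFactors = FALSE)
  if (fpkm) {
    d$fpkm_tissue <- compute_fpkm(count_tissue, length_bp, lib_t)
    d$fpkm_whole <- compute_fpkm(count_whole, length_bp, lib_w)
  }
  expression_table(species, d, lib_t, lib_w)
}

# expression table with prescribed FPKM values (counts consistent)
fpkm_expression_table <- function(fpkm_tissue, fpkm_whole = fpkm_tissue,
                                  species = "toy", lib = 1e6,
                                  length_bp = 1000) {
  n <- length(fpkm_tissue)
  ids <- sprintf("g%03d", seq_len(n))
  len <- rep(length_bp, n)
  ct <- round(fpkm_tissue * len * lib / 1e9)
  cw <- round(fpkm_whole * len * lib / 1e9)
  d <- data.frame(gene_id = ids, length_bp = len, count_tissue = ct,
                  count_whole = cw, fpkm_tissue = fpkm_tissue,
                  fpkm_whole = fpkm_whole, stringsAsFactors = FALSE)
  expression_table(species, d, lib, lib)
}

toy_orthomap <- function(n = 5, prefix_a = "ce", prefix_b = "pp") {
  data.frame(gene_id_A = paste0(prefix_a, seq_len(n)),
             gene_id_B = paste0(prefix_b, seq_len(n)),
             stringsAsFactors = FALSE)
}

# independent oracle: textbook Pearson correlation formula
pearson_formula <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# independent oracle: hypergeometric upper tail by direct summation of
# binomial-coefficient ratios (no shared code with the package internals)
brute_upper_tail <- function(k, K, n, N) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  ks <- lo:hi
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}
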