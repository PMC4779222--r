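# Cross-species conservation through one-to-one orthologs.

test_that("restrict_to_core intersects with the right map side", {
  m <- toy_orthomap(5)
  expect_identical(restrict_to_core(c("x", "y"), m, "A"), character(0))
  expect_setequal(restrict_to_core(m$gene_id_A, m, "A"), m$gene_id_A)
  expect_setequal(restrict_to_core(c("ce1", "ce3", "zz", "pp2"), m, "A"),
                  c("ce1", "ce3"))
  expect_setequal(restrict_to_core(c("pp2", "pp5", "ce1"), m, "B"),
                  c("pp2", "pp5"))
})

test_that("conserved overlap reproduces the planted Venn margins", {
  m <- toy_orthomap(5985)
  enrA <- m$gene_id_A[1:124]
  enrB <- m$gene_id_B[c(1:15, 2000:2091)]  # 15 shared, 107 total
  rep <- conserved_overlap_test(enrA, enrB, m)
  expect_identical(rep$n_orthologs, 5985L)
  expect_identical(rep$enriched_A_in_core, 124L)
  expect_identical(rep$enriched_B_in_core, 107L)
  expect_identical(rep$shared, 15L)
  expect_equal(rep$stats$fold, 6.77, tolerance = 0.001)
  expect_lt(rep$stats$p_value, 1e-8)
  expect_identical(nrow(rep$shared_pairs), 15L)
})

test_that("conserved overlap is species-symmetric", {
  set.seed(17)
  m <- toy_orthomap(500)
  enrA <- sample(m$gene_id_A, 60)
  enrB <- sample(m$gene_id_B, 45)
  fwd <- conserved_overlap_test(enrA, enrB, m)
  swapped <- data.frame(gene_id_A = m$gene_id_B, gene_id_B = m$gene_id_A,
                        stringsAsFactors = FALSE)
  rev <- conserved_overlap_test(enrB, enrA, swapped)
  expect_identical(fwd$shared, rev$shared)
  expect_equal(fwd$stats$fold, rev$stats$fold)
  expect_equal(fwd$stats$p_value, rev$stats$p_value)
})

test_that("empty enrichment and empty maps are handled per contract", {
  m <- toy_orthomap(50)
  rep <- conserved_overlap_test(character(0), m$gene_id_B[1:10], m)
  expect_identical(rep$shared, 0L)
  expect_equal(rep$stats$p_value, 1)
  empty <- m[0, ]
  expect_error(conserved_overlap_test("ce1", "pp1", empty), "one-to-one core")
})

test_that("independent enrichment gives calibrated conserved-overlap p-values", {
  set.seed(23)
  m <- toy_orthomap(800)
  p <- replicate(300, {
    enrA <- sample(m$gene_id_A, 40)
    enrB <- sample(m$gene_id_B, 40)
    conserved_overlap_test(enrA, enrB, m)$stats$p_value
  })
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("expression categories bin FPKM with the <1 boundary", {
  tab <- fpkm_expression_table(c(0.5, 2, 20, 200))
  d <- expression_category_distribution(tab$data$gene_id, tab)
  expect_equal(d$fractions, rep(0.25, 4))
  expect_equal(sum(d$fractions), 1, tolerance = 1e-9)
  zero <- fpkm_expression_table(rep(0, 4))
  d0 <- expression_category_distribution(zero$data$gene_id, zero)
  expect_equal(d0$fractions[1], 1)
  expect_error(expression_category_distribution(character(0), tab), "empty")
})

test_that("low-expression depletion matches an exact 2x2 oracle on a toy table", {
  tab <- fpkm_expression_table(c(0.1, 0.2, 0.5, 3, 5, 8, 20, 40))
  set <- c("g004", "g005", "g006", "g007")  # all above threshold
  st <- low_expression_depletion_test(set, tab)
  # oracle: lower tail of Fisher on (in-set x below-threshold)
  oracle <- fisher.test(matrix(c(0, 4, 3, 1), 2),
                        alternative = "less")$p.value
  expect_equal(st$p_value, oracle, tolerance = 1e-9)
  # the most extreme attainable set: exactly the above-threshold genes
  top <- low_expression_depletion_test(c("g004", "g005", "g006", "g007",
                                         "g008"), tab)
  top_oracle <- fisher.test(matrix(c(0, 5, 3, 0), 2),
                            alternative = "less")$p.value
  expect_equal(top$p_value, top_oracle, tolerance = 1e-9)
})

test_that("random sets show no systematic depletion", {
  set.seed(31)
  tab <- fpkm_expression_table(10^rnorm(400, 0, 1))
  p <- replicate(100, {
    s <- sample(tab$data$gene_id, 60)
    low_expression_depletion_test(s, tab)$p_value
  })
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("planted enriched sets are depleted of lowly expressed genes", {
  b <- simulate_bundle(sim_config(seed = 12))
  core <- b$orthomap$gene_id_A
  st <- low_expression_depletion_test(
    restrict_to_core(b$truth$enriched_A, b$orthomap, "A"),
    b$table_A, background = core)
  expect_lt(st$p_value, 0.01)
})

test_that("cross-species expression check counts mapped and unmappable genes", {
  m <- toy_orthomap(4)
  tab_B <- fpkm_expression_table(c(0.2, 5, 0.8, 30), species = "B")
  tab_B$data$gene_id <- paste0("pp", 1:4)
  res <- cross_species_expression_check(c("ce1", "ce2", "ce3", "orphan"),
                                        m, tab_B)
  expect_identical(res$unmappable, 1L)
  expect_identical(res$n_mapped, 3L)
  expect_equal(res$fraction_below, 2 / 3)  # pp1 at 0.2, pp3 at 0.8
  none <- cross_species_expression_check(c("x", "y"), m, tab_B)
  expect_true(is.na(none$fraction_below))
  expect_identical(none$unmappable, 2L)
})

test_that("conserved gene report has one sorted row per shared pair", {
  m <- toy_orthomap(100)
  enrA <- m$gene_id_A[c(20, 3, 15)]
  enrB <- m$gene_id_B[c(3, 15, 20, 50)]
  rep <- conserved_overlap_test(enrA, enrB, m)
  tbl <- conserved_gene_report(
    rep, symbols = c(ce3 = "dpy-2"), descriptions = c(ce3 = "Collagen"))
  expect_identical(nrow(tbl), 3L)
  expect_identical(tbl$gene_id_A, sort(tbl$gene_id_A))
  expect_identical(tbl$symbol[tbl$gene_id_A == "ce3"], "dpy-2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_report(tbl, path)
  expect_identical(nrow(read_tsv_report(path)), 3L)
  empty <- conserved_overlap_test(m$gene_id_A[1], m$gene_id_B[2], m)
  expect_identical(nrow(conserved_gene_report(empty)), 0L)
})

test_that("estimated conservation fold is monotone in the planted probability", {
  folds <- vapply(c(0.05, 0.3), function(rho) {
    f <- vapply(1:8, function(i) {
      cfg <- sim_config(n_genes_A = 1200, n_genes_B = 1200, n_core = 1200,
                        frac_enriched_A = 60 / 1200,
                        frac_enriched_B = 60 / 1200,
                        conservation_prob = rho, n_shared_families = 0,
                        seed = 100L + i)
      b <- simulate_bundle(cfg)
      conserved_overlap_test(b$truth$enriched_A, b$truth$enriched_B,
                             b$orthomap)$stats$fold
    }, numeric(1))
    mean(f)
  }, numeric(1))
  expect_lt(folds[1], folds[2])
})
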