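# The synthetic two-species generator and its planted ground truth.

test_that("identical configs give identical bundles; different seeds differ", {
  cfg <- sim_config(n_genes_A = 400, n_genes_B = 500, n_core = 200,
                    seed = 5L)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$table_A$data, b2$table_A$data)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$response_A$sets, b2$response_A$sets)
  b3 <- simulate_bundle(sim_config(n_genes_A = 400, n_genes_B = 500,
                                   n_core = 200, seed = 6L))
  expect_false(identical(b1$table_A$data$count_tissue,
                         b3$table_A$data$count_tissue))
  expect_false(identical(b1$truth$enriched_A, b3$truth$enriched_A))
})

test_that("the catalog honors core size, family truncation and coverage", {
  cfg <- sim_config(n_genes_A = 600, n_genes_B = 700, n_core = 150,
                    seed = 2L)
  cat <- simulate_catalog(cfg)
  expect_identical(nrow(cat$orthomap), 150L)
  expect_identical(anyDuplicated(cat$orthomap$gene_id_A), 0L)
  expect_identical(anyDuplicated(cat$orthomap$gene_id_B), 0L)
  # every gene carries 1-3 families; sizes within the truncation
  per_gene <- table(cat$domains_A$gene_id)
  expect_setequal(names(per_gene), cat$genes_A)
  expect_true(all(per_gene >= 1 & per_gene <= 3))
  expect_lte(max(table(cat$domains_A$family_id)), cfg$max_family_size)
  expect_lte(max(table(cat$domains_B$family_id)), cfg$max_family_size)
  # orthologs inherit their partner's domains
  g <- cat$orthomap$gene_id_A[1]
  p <- cat$orthomap$gene_id_B[1]
  expect_setequal(cat$domains_B$family_id[cat$domains_B$gene_id == p],
                  cat$domains_A$family_id[cat$domains_A$gene_id == g])
  # zero core is a valid configuration
  cat0 <- simulate_catalog(sim_config(n_genes_A = 100, n_genes_B = 100,
                                      n_core = 0, seed = 2L))
  expect_identical(nrow(cat0$orthomap), 0L)
})

test_that("generated counts have the prescribed Poisson expectation", {
  cfg <- sim_config(n_genes_A = 3000, n_genes_B = 200, n_core = 100,
                    frac_enriched_A = 0, frac_enriched_B = 0,
                    n_shared_families = 0, seed = 9L)
  cat <- simulate_catalog(cfg)
  expr <- simulate_expression_and_counts(cfg, cat)
  d <- expr$table_A$data
  lam <- 10^expr$truth$baseline_A[d$gene_id] * d$length_bp *
    cfg$library_size / 1e9
  # pooled ratio of realised to expected counts is 1 within MC error
  expect_equal(sum(d$count_whole) / sum(lam), 1, tolerance = 0.02)
  expect_equal(sum(d$count_tissue) / sum(lam), 1, tolerance = 0.02)
})

test_that("a zero planted effect leaves recovery at the false positive level", {
  cfg <- sim_config(n_genes_A = 1500, n_genes_B = 200, n_core = 100,
                    frac_enriched_A = 50 / 1500, enrichment_log2_effect = 0,
                    enriched_baseline_shift = 0, seed = 13L)
  b <- simulate_bundle(cfg)
  res <- call_tissue_enriched(b$table_A)
  expect_lte(length(enriched_genes(res)), 5)
})

test_that("planted conserved overlap matches its analytic expectation", {
  rho <- 0.3
  ks <- vapply(1:30, function(i) {
    cfg <- sim_config(n_genes_A = 1000, n_genes_B = 1000, n_core = 1000,
                      frac_enriched_A = 0.05, frac_enriched_B = 0.05,
                      conservation_prob = rho, n_shared_families = 0,
                      seed = 300L + i)
    b <- simulate_bundle(cfg)
    nrow(b$truth$conserved_pairs)
  }, numeric(1))
  expected <- expected_conserved_overlap(rho, 50, 50, 1000)
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - expected), 4 * se + 0.5)
})

test_that("response-set coupling spans the contract extremes", {
  cfg1 <- sim_config(n_genes_A = 800, n_genes_B = 800, n_core = 400,
                     frac_enriched_A = 0.2,  # pool larger than the sets
                     coupling_A = 1, response_set_size = 30, seed = 21L)
  b1 <- simulate_bundle(cfg1)
  for (s in b1$response_A$sets)
    expect_true(all(s %in% b1$truth$enriched_A))
  # coupling 0: overlap fold ~ 1 in expectation across sets
  cfg0 <- sim_config(n_genes_A = 800, n_genes_B = 800, n_core = 400,
                     coupling_A = 0, response_set_size = 100, seed = 22L)
  b0 <- simulate_bundle(cfg0)
  folds <- vapply(b0$response_A$sets, function(s) {
    suppressMessages(overlap_test(b0$truth$enriched_A, s,
                                  b0$genes_A))$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.6)
})

test_that("study noise degrades cross-study overlap monotonically", {
  overlaps <- vapply(c(0, 0.3, 0.8), function(noise) {
    cfg <- sim_config(n_genes_A = 1000, n_genes_B = 300, n_core = 200,
                      frac_enriched_A = 0.1, study_noise = noise,
                      seed = 25L)
    b <- simulate_bundle(cfg)
    m <- pairwise_overlap_matrix(b$studies)
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_equal(overlaps[1], 100)
  expect_true(all(diff(overlaps) < 0))
})

test_that("bundles round-trip through a written directory", {
  b <- simulate_bundle(sim_config(n_genes_A = 300, n_genes_B = 350,
                                  n_core = 150, response_set_size = 30,
                                  seed = 33L))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back_A <- read_expression_table(file.path(dir, "expression_A.tsv"))
  expect_identical(back_A$species_label, b$config$species_A)
  expect_setequal(back_A$data$gene_id, b$genes_A)
  om <- read_ortholog_map(file.path(dir, "orthologs.tsv"))
  expect_identical(nrow(om), 150L)
  resp <- read_gene_sets(file.path(dir, "response_A.gmt"))
  expect_setequal(names(resp$sets), names(b$response_A$sets))
  truth_A <- readLines(file.path(dir, "truth", "enriched_A.txt"))
  expect_setequal(truth_A, b$truth$enriched_A)
  # rewriting the same bundle is byte-identical
  dir2 <- withr::local_tempdir()
  write_bundle(b, dir2)
  expect_identical(readLines(file.path(dir, "expression_A.tsv")),
                   readLines(file.path(dir2, "expression_A.tsv")))
})
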