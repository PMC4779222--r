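# Gene-family cumulative shares and family enrichment.

test_that("cumulative shares follow the summed-FPKM definition", {
  tab <- fpkm_expression_table(c(10, 5, 5))
  dom <- data.frame(gene_id = c("g001", "g002", "g003"),
                    family_id = c("famA", "famA", "famB"))
  sh <- cumulative_family_share(tab, dom)
  expect_equal(sh$share_tissue[sh$family_id == "famA"], 0.75)
  expect_equal(sh$share_tissue[sh$family_id == "famB"], 0.25)
  one <- cumulative_family_share(
    tab, data.frame(gene_id = c("g001", "g002", "g003"),
                    family_id = "famX"))
  expect_equal(one$share_tissue, 1)
})

test_that("multi-domain genes count fully in every family; shares exceed 1", {
  tab <- fpkm_expression_table(c(10, 10))
  dom <- data.frame(gene_id = c("g001", "g001", "g002"),
                    family_id = c("famA", "famB", "famA"))
  sh <- cumulative_family_share(tab, dom)
  expect_equal(sh$share_tissue[sh$family_id == "famA"], 1)
  expect_equal(sh$share_tissue[sh$family_id == "famB"], 0.5)
  expect_gt(sum(sh$share_tissue), 1)
})

test_that("the unannotated denominator covers ALL genes", {
  tab <- fpkm_expression_table(c(10, 10, 20))  # g003 unannotated
  dom <- data.frame(gene_id = c("g001", "g002"), family_id = "famA")
  sh <- cumulative_family_share(tab, dom)
  expect_equal(sh$share_tissue, 0.5)
  zero <- fpkm_expression_table(c(0, 0))
  expect_error(cumulative_family_share(zero, dom), "zero")
})

test_that("single-family-per-gene shares partition to one", {
  set.seed(41)
  tab <- fpkm_expression_table(10^rnorm(100, 1, 1))
  dom <- data.frame(gene_id = tab$data$gene_id,
                    family_id = sample(sprintf("fam%02d", 1:10), 100, TRUE))
  sh <- cumulative_family_share(tab, dom)
  expect_equal(sum(sh$share_tissue), 1, tolerance = 1e-9)
  expect_equal(sum(sh$share_whole), 1, tolerance = 1e-9)
})

test_that("abundant family filter applies both display rules", {
  sh <- data.frame(
    family_id = c("peptidase", "tiny", "whole_dominant"),
    n_genes = c(5, 2, 3),
    share_tissue = c(0.13, 0.009, 0.05),
    share_whole = c(0.04, 0.001, 0.06))
  ab <- abundant_families(sh)
  expect_identical(ab$family_id, "peptidase")
  # ties broken deterministically, sorted by descending tissue share
  sh2 <- rbind(sh, data.frame(family_id = "second", n_genes = 1,
                              share_tissue = 0.02, share_whole = 0.01))
  ab2 <- abundant_families(sh2)
  expect_identical(ab2$family_id, c("peptidase", "second"))
})

test_that("family enrichment p-values match the exact oracle", {
  universe <- sprintf("u%04d", 1:1000)
  enriched <- universe[1:100]
  fam <- universe[c(1:8, 900, 901)]       # 8 of 10 enriched
  dom <- rbind(data.frame(gene_id = fam, family_id = "famHot"),
               data.frame(gene_id = universe[300:320], family_id = "famCold"))
  fe <- suppressMessages(family_enrichment(
    list(universe = universe, enriched = enriched), dom))
  hot <- fe[fe$family_id == "famHot", ]
  oracle <- sum(dhyper(8:10, 10, 990, 100))
  expect_equal(hot$p_value, oracle, tolerance = 1e-12)
  expect_true(hot$significant)
  cold <- fe[fe$family_id == "famCold", ]
  expect_identical(cold$k, 0L)
  expect_identical(cold$fold, 0)
  expect_false(cold$significant)
})

test_that("a family equal to the whole universe is never significant", {
  universe <- sprintf("u%03d", 1:200)
  dom <- data.frame(gene_id = universe, family_id = "all")
  fe <- family_enrichment(list(universe = universe,
                               enriched = universe[1:20]), dom)
  expect_equal(fe$fold, 1)
  expect_equal(fe$p_value, 1)
  expect_false(fe$significant)
})

test_that("families below two members in the universe are skipped", {
  universe <- sprintf("u%03d", 1:50)
  dom <- data.frame(gene_id = c(universe[1], universe[2], universe[3]),
                    family_id = c("big", "big", "lonely"))
  expect_message(
    fe <- family_enrichment(list(universe = universe,
                                 enriched = universe[1:5]), dom),
    "skipping")
  expect_identical(fe$family_id, "big")
})

test_that("fold and p are invariant to relabeling of ids", {
  set.seed(43)
  universe <- sprintf("u%03d", 1:300)
  enriched <- sample(universe, 40)
  dom <- data.frame(gene_id = sample(universe, 120, replace = TRUE),
                    family_id = sample(c("f1", "f2", "f3"), 120, TRUE))
  dom <- dom[!duplicated(dom), ]
  fe1 <- suppressMessages(family_enrichment(
    list(universe = universe, enriched = enriched), dom))
  relab <- setNames(sprintf("X%03d", seq_along(universe)), universe)
  dom2 <- data.frame(gene_id = unname(relab[dom$gene_id]),
                     family_id = paste0("fam_", dom$family_id))
  fe2 <- suppressMessages(family_enrichment(
    list(universe = unname(relab[universe]),
         enriched = unname(relab[enriched])), dom2))
  expect_equal(fe1$p_value, fe2$p_value)
  expect_equal(fe1$fold, fe2$fold)
})

test_that("random enrichment calls rarely produce significant families", {
  set.seed(47)
  universe <- sprintf("u%04d", 1:4000)
  enriched <- sample(universe, 200)
  dom <- data.frame(gene_id = sample(universe, 6000, replace = TRUE),
                    family_id = sample(sprintf("fam%03d", 1:600), 6000, TRUE))
  dom <- dom[!duplicated(dom), ]
  fe <- suppressMessages(family_enrichment(
    list(universe = universe, enriched = enriched), dom))
  expect_gte(nrow(fe), 500)
  expect_lte(mean(fe$significant), 0.02)
})

test_that("shared enriched families recover exactly the planted signal", {
  b <- simulate_bundle(sim_config(seed = 7))
  fa <- suppressMessages(family_enrichment(
    list(universe = b$genes_A, enriched = b$truth$enriched_A),
    b$domains_A))
  fb <- suppressMessages(family_enrichment(
    list(universe = b$genes_B, enriched = b$truth$enriched_B),
    b$domains_B))
  expect_identical(shared_enriched_families(fa, fb),
                   b$truth$planted_families)
  # one side without significant families leaves nothing shared
  none <- fb
  none$significant <- FALSE
  expect_identical(shared_enriched_families(fa, none), character(0))
})
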