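# ---------------------------------------------------------------------------
# Synthetic two-species dataset generator with planted ground truth.
#
# The generator emulates the statistical structure of a paired
# tissue/whole-animal RNA-seq comparison between two related nematode
# species: a shared one-to-one orthologous core inside larger, partly
# lineage-specific gene catalogs; protein-domain families with truncated
# power-law sizes; log-normal baseline expression shared across orthologs;
# a planted tissue-enrichment effect whose cross-species conservation is a
# tunable probability; pathogen-response gene sets with species-specific
# coupling to the tissue-enriched pool; and noisy replicate "studies" of
# the species-A enriched set.  Counts are Poisson (one library per
# condition, so no replicate dispersion exists to estimate).
#
# Determinism: every stage derives its RNG stream from `config$seed` plus a
# fixed small offset, so identical configs give byte-identical bundles.
# ---------------------------------------------------------------------------

#' Configuration for the synthetic two-species generator
#'
#' Defaults instantiate the magnitudes of a two-nematode intestinal
#' comparison (20000 / 24000 genes, a 5985-pair orthologous core, 724 / 464
#' tissue-enriched genes, 4 pathogens x up/down response sets, five noisy
#' replicate studies), scaled by `size_factor` (default 0.25, the desk
#' scale at which the whole pipeline runs in seconds).
#'
#' @param size_factor global scale applied to gene, core, family and term
#'   counts (default 0.25; use 1 for full scale).
#' @param n_genes_A,n_genes_B catalog sizes (defaults 20000 / 24000 times
#'   `size_factor`).
#' @param n_core number of one-to-one ortholog pairs (default 5985 times
#'   `size_factor`); must not exceed either catalog.
#' @param frac_enriched_A,frac_enriched_B fractions of genes planted as
#'   tissue-enriched (defaults 724/20000 and 464/24000).
#' @param conservation_prob probability that the ortholog partner of an
#'   A-enriched core gene is also enriched in B (default 0.10, the
#'   magnitude implied by a 15-of-124 shared overlap).
#' @param n_families size of the shared protein-domain family pool.
#' @param family_size_exponent exponent of the truncated power law family
#'   sizes are drawn from (P(s) proportional to s^-exponent).
#' @param max_family_size truncation of the family-size law.
#' @param n_terms size of the annotation-term pool; each gene carries 0-5
#'   terms.
#' @param baseline_log10_fpkm_mean,baseline_log10_fpkm_sd log-normal
#'   baseline expression (log10 FPKM scale).
#' @param ortholog_jitter_sd species jitter added to the shared ortholog
#'   baseline (log10).
#' @param library_noise_sd per-library technical noise (log10).  Default 0:
#'   in the reference model a null gene has identical expected proportions
#'   in both libraries and only Poisson count noise, which is the null the
#'   single-library exact test assumes.  Positive values inject per-library
#'   expression shifts for robustness experiments (they violate that null,
#'   so expect over-calling).
#' @param enriched_baseline_shift log10-FPKM baseline shift of planted
#'   enriched genes (tissue-enriched genes are robustly expressed; their
#'   sets are depleted of FPKM < 1 members).
#' @param enrichment_log2_effect planted tissue effect in log2 units
#'   (default 3, i.e. 8-fold).
#' @param library_size total mapped reads per library (default 2e6).
#' @param mean_gene_length log-normal median gene length in bp.
#' @param coupling_A,coupling_B probability that a pathogen-response gene
#'   is drawn from the planted tissue-enriched pool (defaults 0.35 / 0).
#' @param n_response_sets,response_set_size response-set structure
#'   (default 8 sets of 100: four pathogens, up and down).
#' @param n_studies,study_noise replicate-study model: each study is the
#'   planted species-A enriched set with this fraction of members swapped
#'   for random genes.
#' @param n_shared_families,family_signal_prob number of families planted
#'   as tissue-enriched in BOTH species, and the probability with which a
#'   member of such a family is planted enriched.
#' @param species_A,species_B species labels.
#' @param seed integer RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(size_factor = 0.25,
                       n_genes_A = NULL, n_genes_B = NULL, n_core = NULL,
                       frac_enriched_A = 724 / 20000,
                       frac_enriched_B = 464 / 24000,
                       conservation_prob = 0.10,
                       n_families = NULL, family_size_exponent = 1.0,
                       max_family_size = NULL, n_terms = NULL,
                       baseline_log10_fpkm_mean = 1.0,
                       baseline_log10_fpkm_sd = 0.8,
                       ortholog_jitter_sd = 0.2,
                       library_noise_sd = 0,
                       enriched_baseline_shift = 0.4,
                       enrichment_log2_effect = 3,
                       library_size = 2e6,
                       mean_gene_length = 1500,
                       coupling_A = 0.35, coupling_B = 0,
                       n_response_sets = 8, response_set_size = 100,
                       n_studies = 5, study_noise = 0.3,
                       n_shared_families = 5, family_signal_prob = 0.8,
                       species_A = "Cel", species_B = "Ppa",
                       seed = 1L) {
  if (is.null(n_genes_A)) n_genes_A <- round(20000 * size_factor)
  if (is.null(n_genes_B)) n_genes_B <- round(24000 * size_factor)
  if (is.null(n_core)) n_core <- round(5985 * size_factor)
  if (is.null(n_families)) n_families <- max(20, round(2400 * size_factor))
  if (is.null(max_family_size)) max_family_size <- max(20, round(200 * size_factor))
  if (is.null(n_terms)) n_terms <- max(20, round(800 * size_factor))
  cfg <- list(size_factor = size_factor,
              n_genes_A = n_genes_A, n_genes_B = n_genes_B, n_core = n_core,
              frac_enriched_A = frac_enriched_A,
              frac_enriched_B = frac_enriched_B,
              conservation_prob = conservation_prob,
              n_families = n_families,
              family_size_exponent = family_size_exponent,
              max_family_size = max_family_size, n_terms = n_terms,
              baseline_log10_fpkm_mean = baseline_log10_fpkm_mean,
              baseline_log10_fpkm_sd = baseline_log10_fpkm_sd,
              ortholog_jitter_sd = ortholog_jitter_sd,
              library_noise_sd = library_noise_sd,
              enriched_baseline_shift = enriched_baseline_shift,
              enrichment_log2_effect = enrichment_log2_effect,
              library_size = library_size,
              mean_gene_length = mean_gene_length,
              coupling_A = coupling_A, coupling_B = coupling_B,
              n_response_sets = n_response_sets,
              response_set_size = response_set_size,
              n_studies = n_studies, study_noise = study_noise,
              n_shared_families = n_shared_families,
              family_signal_prob = family_signal_prob,
              species_A = species_A, species_B = species_B,
              seed = as.integer(seed))
  probs <- c("frac_enriched_A", "frac_enriched_B", "conservation_prob",
             "coupling_A", "coupling_B", "study_noise",
             "family_signal_prob")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$n_core > min(cfg$n_genes_A, cfg$n_genes_B))
    stop("n_core cannot exceed either catalog size")
  if (cfg$library_size <= 0) stop("library_size must be positive")
  structure(cfg, class = "sim_config")
}

# draw family sizes from a truncated power law, then allocate against a
# 3-slots-per-gene capacity pool; finally route unannotated genes to
# below-capacity families so every gene carries 1-3 families.
.assign_families <- function(gene_ids, n_families, exponent, max_size,
                             existing_counts = NULL) {
  if (length(gene_ids) == 0L)
    return(data.frame(gene_id = character(0), family_id = character(0),
                      stringsAsFactors = FALSE))
  n_genes <- length(gene_ids)
  sizes_support <- 1:max_size
  size_prob <- sizes_support^(-exponent)
  size_prob <- size_prob / sum(size_prob)
  fam_ids <- sprintf("FAM%04d", seq_len(n_families))
  cap <- rep(max_size, n_families)
  names(cap) <- fam_ids
  if (!is.null(existing_counts)) {
    hit <- intersect(names(existing_counts), fam_ids)
    cap[hit] <- pmax(0L, max_size - as.integer(existing_counts[hit]))
  }
  sizes <- pmin(sample(sizes_support, n_families, TRUE, size_prob),
                cap)
  total <- sum(sizes)
  pool_cap <- 3L * n_genes
  if (total > pool_cap) {  # rescale to respect per-gene capacity
    sizes <- floor(sizes * pool_cap / total)
    total <- sum(sizes)
  }
  pool <- sample(rep(gene_ids, 3L))
  slots <- pool[seq_len(total)]
  assign <- data.frame(gene_id = slots,
                       family_id = rep(fam_ids, times = sizes),
                       stringsAsFactors = FALSE)
  assign <- assign[!duplicated(assign), , drop = FALSE]
  counts <- table(assign$family_id)
  used <- rep(0L, n_families); names(used) <- fam_ids
  used[names(counts)] <- as.integer(counts)
  left <- setdiff(gene_ids, assign$gene_id)
  if (length(left) > 0) {
    open <- fam_ids[used < cap]
    if (length(open) == 0L) open <- fam_ids
    extra <- data.frame(gene_id = left,
                        family_id = sample(open, length(left), TRUE),
                        stringsAsFactors = FALSE)
    assign <- rbind(assign, extra)
    assign <- assign[!duplicated(assign), , drop = FALSE]
  }
  assign[order(assign$gene_id, assign$family_id), , drop = FALSE]
}

.assign_terms <- function(gene_ids, n_terms) {
  if (length(gene_ids) == 0L)
    return(data.frame(gene_id = character(0), term_id = character(0),
                      term_label = character(0), stringsAsFactors = FALSE))
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  counts <- sample(0:5, length(gene_ids), TRUE)
  gene <- rep(gene_ids, times = counts)
  term <- as.character(unlist(lapply(counts[counts > 0],
                                     function(k) sample(term_ids, k))))
  d <- data.frame(gene_id = gene, term_id = term,
                  term_label = NA_character_, stringsAsFactors = FALSE)
  d <- d[!duplicated(d[, c("gene_id", "term_id")]), , drop = FALSE]
  d[order(d$gene_id, d$term_id), , drop = FALSE]
}

#' Simulate the two-species gene catalog
#'
#' Gene identifiers, the one-to-one ortholog map (exactly `n_core` pairs;
#' remaining genes are lineage-specific), protein-domain annotations
#' (orthologs inherit their partner's domains) and flat term annotations.
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `genes_A`, `genes_B`, `orthomap`, `domains_A`,
#'   `domains_B`, `terms_A`, `terms_B`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes_A <- sprintf("%s_g%05d", config$species_A,
                     seq_len(config$n_genes_A))
  genes_B <- sprintf("%s_g%05d", config$species_B,
                     seq_len(config$n_genes_B))
  core_idx <- seq_len(config$n_core)
  orthomap <- data.frame(gene_id_A = genes_A[core_idx],
                         gene_id_B = genes_B[core_idx],
                         stringsAsFactors = FALSE)
  domains_A <- .assign_families(genes_A, config$n_families,
                                config$family_size_exponent,
                                config$max_family_size)
  # B core genes inherit the A partner's domains (orthologs share domains)
  core_dom <- domains_A[domains_A$gene_id %in% orthomap$gene_id_A, ,
                        drop = FALSE]
  core_dom$gene_id <- orthomap$gene_id_B[match(core_dom$gene_id,
                                               orthomap$gene_id_A)]
  inherited <- table(core_dom$family_id)
  spec_B <- setdiff(genes_B, orthomap$gene_id_B)
  dom_spec_B <- .assign_families(spec_B, config$n_families,
                                 config$family_size_exponent,
                                 config$max_family_size,
                                 existing_counts = inherited)
  domains_B <- rbind(core_dom, dom_spec_B)
  domains_B <- domains_B[order(domains_B$gene_id, domains_B$family_id), ,
                         drop = FALSE]
  rownames(domains_A) <- rownames(domains_B) <- NULL
  terms_A <- .assign_terms(genes_A, config$n_terms)
  core_terms <- terms_A[terms_A$gene_id %in% orthomap$gene_id_A, ,
                        drop = FALSE]
  core_terms$gene_id <- orthomap$gene_id_B[match(core_terms$gene_id,
                                                 orthomap$gene_id_A)]
  terms_spec_B <- .assign_terms(spec_B, config$n_terms)
  terms_B <- rbind(core_terms, terms_spec_B)
  terms_B <- terms_B[order(terms_B$gene_id, terms_B$term_id), ,
                     drop = FALSE]
  rownames(terms_A) <- rownames(terms_B) <- NULL
  list(genes_A = genes_A, genes_B = genes_B, orthomap = orthomap,
       domains_A = domains_A, domains_B = domains_B,
       terms_A = terms_A, terms_B = terms_B)
}

# pick the shared-signal families: present with >= 3 members in both
# species and not degenerately large
.pick_planted_families <- function(config, catalog) {
  if (config$n_shared_families == 0L) return(character(0))
  szA <- table(catalog$domains_A$family_id)
  szB <- table(catalog$domains_B$family_id)
  cand <- intersect(names(szA)[szA >= 3 & szA <= 40],
                    names(szB)[szB >= 3 & szB <= 40])
  if (length(cand) < config$n_shared_families)
    stop("not enough candidate families for the planted shared signal")
  sort(sample(cand, config$n_shared_families))
}

# plant an enriched set of size `quota`: seed members of the planted
# families (each w.p. signal_prob), then fill uniformly from the rest
.plant_set <- function(quota, seed_candidates, all_genes, forced = character(0)) {
  base <- unique(c(forced, seed_candidates))
  if (length(base) >= quota) return(sort(sample(base, quota)))
  fill <- sample(setdiff(all_genes, base), quota - length(base))
  sort(c(base, fill))
}

#' Simulate expression, planted enrichment and Poisson read counts
#'
#' Baseline log10 FPKM is normal, shared across orthologs up to species
#' jitter.  A fraction of genes per species is planted tissue-enriched:
#' their tissue FPKM is multiplied by `2^enrichment_log2_effect` and their
#' baseline shifted up by `enriched_baseline_shift`.  Enrichment of a core
#' gene in species B is conditioned on its A partner through
#' `conservation_prob`; the remaining B quota is drawn uniformly, so at
#' `conservation_prob = 0` the two planted sets are independent.  Members
#' of the planted shared families seed both species' enriched sets.
#' Counts are `Poisson(FPKM * length * library_size / 1e9)` per library;
#' the recorded FPKM is recomputed from the realised counts, as a real
#' pipeline would.
#'
#' @param config a [sim_config()].
#' @param catalog output of [simulate_catalog()].
#' @return List with `table_A`, `table_B` ([expression_table()]s) and
#'   `truth` (planted enriched sets, conserved pairs, planted families,
#'   baselines and lengths).
#' @export
simulate_expression_and_counts <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nA <- config$n_genes_A; nB <- config$n_genes_B
  genes_A <- catalog$genes_A; genes_B <- catalog$genes_B
  om <- catalog$orthomap

  base_A <- stats::rnorm(nA, config$baseline_log10_fpkm_mean,
                         config$baseline_log10_fpkm_sd)
  names(base_A) <- genes_A
  base_B <- stats::rnorm(nB, config$baseline_log10_fpkm_mean,
                         config$baseline_log10_fpkm_sd)
  names(base_B) <- genes_B
  core_B_idx <- match(om$gene_id_B, genes_B)
  base_B[core_B_idx] <- base_A[match(om$gene_id_A, genes_A)] +
    stats::rnorm(nrow(om), 0, config$ortholog_jitter_sd)

  planted_families <- .pick_planted_families(config, catalog)
  fam_members_A <- catalog$domains_A$gene_id[
    catalog$domains_A$family_id %in% planted_families]
  fam_members_B <- catalog$domains_B$gene_id[
    catalog$domains_B$family_id %in% planted_families]
  seed_A <- unique(fam_members_A)
  seed_A <- seed_A[stats::runif(length(seed_A)) < config$family_signal_prob]
  quota_A <- round(config$frac_enriched_A * nA)
  enr_A <- .plant_set(quota_A, seed_A, genes_A)

  # cross-species conservation: partner of an A-enriched core gene
  enr_A_core <- intersect(enr_A, om$gene_id_A)
  partners <- om$gene_id_B[match(enr_A_core, om$gene_id_A)]
  conserved <- partners[stats::runif(length(partners)) <
                          config$conservation_prob]
  seed_B <- unique(fam_members_B)
  seed_B <- seed_B[stats::runif(length(seed_B)) < config$family_signal_prob]
  quota_B <- round(config$frac_enriched_B * nB)
  enr_B <- .plant_set(quota_B, seed_B, genes_B, forced = conserved)

  shift <- config$enriched_baseline_shift
  base_A[enr_A] <- base_A[enr_A] + shift
  base_B[enr_B] <- base_B[enr_B] + shift
  eff <- config$enrichment_log2_effect * log10(2)

  make_table <- function(genes, base, enr, species) {
    n <- length(genes)
    len <- pmax(200, round(stats::rlnorm(n, log(config$mean_gene_length),
                                         0.5)))
    lg_t <- base + eff * (genes %in% enr) +
      stats::rnorm(n, 0, config$library_noise_sd)
    lg_w <- base + stats::rnorm(n, 0, config$library_noise_sd)
    lam_t <- 10^lg_t * len * config$library_size / 1e9
    lam_w <- 10^lg_w * len * config$library_size / 1e9
    ct <- stats::rpois(n, lam_t)
    cw <- stats::rpois(n, lam_w)
    d <- data.frame(gene_id = genes, length_bp = len,
                    count_tissue = ct, count_whole = cw,
                    stringsAsFactors = FALSE)
    d$fpkm_tissue <- compute_fpkm(ct, len, config$library_size)
    d$fpkm_whole <- compute_fpkm(cw, len, config$library_size)
    expression_table(species, d, config$library_size, config$library_size)
  }
  table_A <- make_table(genes_A, base_A, enr_A, config$species_A)
  table_B <- make_table(genes_B, base_B, enr_B, config$species_B)

  both <- om$gene_id_A %in% enr_A & om$gene_id_B %in% enr_B
  truth <- list(enriched_A = enr_A, enriched_B = enr_B,
                conserved_pairs = om[both, , drop = FALSE],
                planted_families = planted_families,
                baseline_A = base_A, baseline_B = base_B)
  list(table_A = table_A, table_B = table_B, truth = truth)
}

#' Simulate pathogen-response gene sets with tunable coupling
#'
#' Each set (named `"<pathogen>/<up|down>"`) draws each member from the
#' planted tissue-enriched pool with probability `coupling_X`, otherwise
#' uniformly from the remaining genes of the species.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of
#'   [simulate_expression_and_counts()].
#' @param catalog output of [simulate_catalog()].
#' @return List with one [gene_set_collection()] per species (`A`, `B`).
#' @export
simulate_response_sets <- function(config, truth, catalog) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  pathogens <- c("B.thuringiensis", "S.aureus", "S.marcescens",
                 "X.nematophila")
  n_sets <- config$n_response_sets
  nm <- paste0(rep(pathogens, each = 2, length.out = n_sets), "/",
               rep(c("up", "down"), length.out = n_sets))
  nm <- make.unique(nm, sep = "_")
  draw <- function(genes, pool, coupling, species) {
    sets <- lapply(seq_len(n_sets), function(i) {
      n_pool <- stats::rbinom(1L, config$response_set_size, coupling)
      n_pool <- min(n_pool, length(pool))
      from_pool <- if (n_pool > 0) sample(pool, n_pool) else character(0)
      rest <- sample(setdiff(genes, from_pool),
                     config$response_set_size - n_pool)
      sort(c(from_pool, rest))
    })
    names(sets) <- nm
    gene_set_collection(sets, species)
  }
  list(A = draw(catalog$genes_A, truth$enriched_A, config$coupling_A,
                config$species_A),
       B = draw(catalog$genes_B, truth$enriched_B, config$coupling_B,
                config$species_B))
}

#' Simulate noisy replicate studies of the species-A enriched set
#'
#' Each study set equals the planted species-A enriched set with a fraction
#' `study_noise` of members swapped for random non-member genes, emulating
#' partially concordant published gene sets.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of
#'   [simulate_expression_and_counts()].
#' @param catalog output of [simulate_catalog()].
#' @return A [gene_set_collection()] with `n_studies` sets
#'   (`study_1`, ...).
#' @export
simulate_study_variants <- function(config, truth, catalog) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  base <- truth$enriched_A
  n_swap <- round(config$study_noise * length(base))
  sets <- lapply(seq_len(config$n_studies), function(i) {
    keep <- sample(base, length(base) - n_swap)
    add <- sample(setdiff(catalog$genes_A, base), n_swap)
    sort(c(keep, add))
  })
  names(sets) <- paste0("study_", seq_len(config$n_studies))
  gene_set_collection(sets, config$species_A)
}

#' Generate a complete synthetic two-species bundle
#'
#' Composes [simulate_catalog()], [simulate_expression_and_counts()],
#' [simulate_response_sets()] and [simulate_study_variants()].  Fully
#' deterministic: identical configs give identical bundles.
#'
#' @param config a [sim_config()] (default: `sim_config()`).
#' @return An object of class `sim_bundle`: list with `config`, the catalog
#'   fields, `table_A`, `table_B`, `response_A`, `response_B`, `studies`
#'   and `truth`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  catalog <- simulate_catalog(config)
  expr <- simulate_expression_and_counts(config, catalog)
  resp <- simulate_response_sets(config, expr$truth, catalog)
  studies <- simulate_study_variants(config, expr$truth, catalog)
  structure(
    c(list(config = config), catalog,
      list(table_A = expr$table_A, table_B = expr$table_B,
           response_A = resp$A, response_B = resp$B,
           studies = studies, truth = expr$truth)),
    class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "sim_bundle: %d + %d genes, %d ortholog pairs, %d + %d planted enriched\n",
    x$config$n_genes_A, x$config$n_genes_B, nrow(x$orthomap),
    length(x$truth$enriched_A), length(x$truth$enriched_B)))
  invisible(x)
}

#' Write a synthetic bundle as a ready-to-run directory of files
#'
#' Emits every artifact in its canonical on-disk format (expression TSVs
#' with library-size header comments, two-column ortholog TSV, annotation
#' TSVs, GMT response and study sets) plus the planted truth under
#' `truth/`, so the full pipeline can be run from files alone.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_expression_table(bundle$table_A,
                         file.path(dir, "expression_A.tsv"))
  write_expression_table(bundle$table_B,
                         file.path(dir, "expression_B.tsv"))
  utils::write.table(bundle$orthomap, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_report(bundle$domains_A, file.path(dir, "domains_A.tsv"))
  write_tsv_report(bundle$domains_B, file.path(dir, "domains_B.tsv"))
  write_tsv_report(bundle$terms_A, file.path(dir, "terms_A.tsv"))
  write_tsv_report(bundle$terms_B, file.path(dir, "terms_B.tsv"))
  write_gene_sets(bundle$response_A, file.path(dir, "response_A.gmt"))
  write_gene_sets(bundle$response_B, file.path(dir, "response_B.gmt"))
  write_gene_sets(bundle$studies, file.path(dir, "studies.gmt"))
  writeLines(sort(bundle$truth$enriched_A),
             file.path(dir, "truth", "enriched_A.txt"))
  writeLines(sort(bundle$truth$enriched_B),
             file.path(dir, "truth", "enriched_B.txt"))
  utils::write.table(bundle$truth$conserved_pairs,
                     file.path(dir, "truth", "conserved_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$truth$planted_families,
             file.path(dir, "truth", "planted_families.txt"))
  invisible(dir)
}

#' Analytic expected conserved overlap of the generator
#'
#' Under the planting scheme, `E[k] = rho*K + (1 - rho)*K*(n - rho*K) /
#' (N - rho*K)`: conserved partners contribute `rho*K`, and each of the
#' remaining `(1 - rho)*K` partners can still be picked by the uniform fill
#' of the B quota.  Used as the reference in parameter-recovery tests.
#'
#' @param rho planted conservation probability.
#' @param K enriched core genes in species A.
#' @param n planted enriched quota in species B.
#' @param N size of the pool the B fill draws from (the species-B catalog;
#'   equal to the core size when every gene has a one-to-one ortholog).
#' @return The expected shared count.
#' @export
expected_conserved_overlap <- function(rho, K, n, N) {
  rho * K + (1 - rho) * K * (n - rho * K) / (N - rho * K)
}
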