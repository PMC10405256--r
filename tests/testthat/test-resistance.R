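two_group_fixture <- function(values, labels, genes = "G1") {
  n <- length(values) / length(genes)
  ceres <- matrix(values, nrow = n, dimnames = list(sprintf("L%02d", seq_len(n)), genes))
  calls <- data.frame(cell_line = rownames(ceres), lineage = "lin",
                      avg_ceres = 0, label = labels, stringsAsFactors = FALSE)
  list(ceres = ceres, calls = calls)
}

test_that("resistance calls sit exactly on the printed cutoff", {
  ceres <- matrix(c(-0.44, -0.46), 2, 1,
                  dimnames = list(c("L1", "L2"), "T1"))
  sets <- structure(list(lin = list(lineage = "lin", tfs = "T1")),
                    class = "lineage_dependency_sets")
  ann <- data.frame(cell_line = c("L1", "L2"), lineage = "lin")
  calls <- classify_cell_lines(ceres, sets, ann)
  expect_equal(calls$label[calls$cell_line == "L1"], "resistant")
  expect_equal(calls$label[calls$cell_line == "L2"], "sensitive")
})

test_that("planted resistant lines are recovered exactly under separation", {
  p <- dependency_sim_params(resistant_fraction = 0.3, ld_tfs_per_lineage = 3,
                             n_acquired_per_lineage = 0,
                             n_mutation_genes_per_lineage = 0)
  sim <- generate_dependency_bundle(n_lineages = 4, lines_per_lineage = 20,
                                    n_genes = 60, n_tfs = 30, params = p, seed = 31)
  sets <- structure(lapply(names(sim$truth$planted_ld), function(l)
    list(lineage = l, tfs = sim$truth$planted_ld[[l]]$tf)),
    .Names = names(sim$truth$planted_ld), class = "lineage_dependency_sets")
  calls <- classify_cell_lines(sim$bundle$ceres, sets, sim$bundle$annotations)
  truth_res <- unlist(sim$truth$resistant_lines)
  expect_setequal(calls$cell_line[calls$label == "resistant"], truth_res)
})

test_that("a melanoma-shaped cohort splits 30 sensitive / 19 resistant", {
  p <- dependency_sim_params(resistant_fraction = 19 / 49, ld_tfs_per_lineage = 3,
                             n_acquired_per_lineage = 1,
                             n_mutation_genes_per_lineage = 1)
  sim <- generate_dependency_bundle(n_lineages = 1, lines_per_lineage = 49,
                                    n_genes = 40, n_tfs = 20, params = p, seed = 19)
  lin <- names(sim$truth$planted_ld)[1]
  sets <- structure(list(list(lineage = lin, tfs = sim$truth$planted_ld[[lin]]$tf)),
                    .Names = lin, class = "lineage_dependency_sets")
  calls <- classify_cell_lines(sim$bundle$ceres, sets, sim$bundle$annotations)
  expect_equal(sum(calls$label == "sensitive"), 30L)
  expect_equal(sum(calls$label == "resistant"), 19L)
})

test_that("Cohen's D matches direct arithmetic and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(2, 4); b <- c(0, 2)
  expect_equal(cohens_d(a, b), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d(a, b), oracle_cohens_d(a, b), tolerance = 1e-12)
  set.seed(3)
  x <- rnorm(8); y <- rnorm(5)
  expect_equal(cohens_d(x, y), -cohens_d(y, x), tolerance = 1e-12)
  expect_equal(cohens_d(x, y), oracle_cohens_d(x, y), tolerance = 1e-12)
  # zero pooled SD
  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
  expect_equal(cohens_d(c(2, 2), c(1, 1)), Inf)
})

test_that("FDR and q equal exhaustive enumeration on a tiny cohort", {
  fx <- two_group_fixture(c(-1.2, -0.9, 0.1, 0.2,   # gene 1 separates groups
                            0.3, -0.2, 0.1, -0.1),  # gene 2 is noise
                          labels = c("resistant", "resistant", "sensitive", "sensitive"),
                          genes = c("G1", "G2"))
  assignments <- enumerate_assignments(4, 2)
  res <- permutation_fdr(fx$ceres, fx$calls, permutations = assignments)
  oracle <- oracle_perm_fdr(fx$ceres, fx$calls$label == "resistant", assignments)
  expect_equal(res$d_obs, oracle$d_obs, tolerance = 1e-12)
  expect_equal(res$fdr_hat, oracle$fdr, tolerance = 1e-12)
  expect_equal(res$q_value, oracle$q, tolerance = 1e-12)
})

test_that("a gene dominating every permutation gets FDR and q of zero", {
  set.seed(5)
  n <- 16
  ceres <- cbind(G1 = c(rep(-3, 8), rep(3, 8)) + rnorm(n, 0, 0.01),
                 G2 = rnorm(n, 0, 0.05))
  rownames(ceres) <- sprintf("L%02d", seq_len(n))
  calls <- data.frame(cell_line = rownames(ceres), lineage = "lin", avg_ceres = 0,
                      label = rep(c("resistant", "sensitive"), each = 8))
  res <- permutation_fdr(ceres, calls, n_permutations = 200, seed = 2)
  g1 <- res[res$gene == "G1", ]
  expect_equal(g1$fdr_hat, 0)
  expect_equal(g1$q_value, 0)
  expect_true(g1$significant)
})

test_that("permutation results are invariant to gene and row order", {
  set.seed(9)
  ceres <- matrix(rnorm(12 * 5), 12, 5,
                  dimnames = list(sprintf("L%02d", 1:12), paste0("G", 1:5)))
  calls <- data.frame(cell_line = rownames(ceres), lineage = "lin", avg_ceres = 0,
                      label = rep(c("resistant", "sensitive"), 6))
  a <- permutation_fdr(ceres, calls, n_permutations = 50, seed = 3)
  b <- permutation_fdr(ceres[, 5:1], calls, genes = paste0("G", 1:5),
                       n_permutations = 50, seed = 3)
  expect_equal(a, b)
  c <- permutation_fdr(ceres, calls[sample(12), ], n_permutations = 50, seed = 3)
  expect_equal(a, c)
})

test_that("q-values are a non-increasing step function of |d|", {
  set.seed(23)
  ceres <- matrix(rnorm(20 * 40), 20, 40,
                  dimnames = list(sprintf("L%02d", 1:20), sprintf("G%02d", 1:40)))
  ceres[1:10, 1] <- ceres[1:10, 1] - 1        # one real effect
  calls <- data.frame(cell_line = rownames(ceres), lineage = "lin", avg_ceres = 0,
                      label = rep(c("resistant", "sensitive"), each = 10))
  res <- permutation_fdr(ceres, calls, n_permutations = 100, seed = 7)
  ord <- order(abs(res$d_obs))
  expect_true(all(diff(res$q_value[ord]) <= 1e-12))
  expect_true(all(res$fdr_hat >= 0 & res$fdr_hat <= 1))
})

test_that("mutation enrichment matches exact tail enumeration", {
  # 2x2 shaped like a 47% vs 28% mutation contrast
  calls <- data.frame(
    cell_line = sprintf("L%02d", 1:49), lineage = "lin", avg_ceres = 0,
    label = rep(c("resistant", "sensitive"), c(19, 30)))
  mut_lines <- c(sprintf("L%02d", 1:9), sprintf("L%02d", 20:27))  # 9 vs 8
  mutations <- data.frame(cell_line = mut_lines, gene = "TP53",
                          variant_classification = "damaging",
                          is_deleterious = TRUE, is_tcga_hotspot = FALSE,
                          is_cosmic_hotspot = FALSE)
  res <- mutation_enrichment(mutations, calls, "TP53")
  expect_equal(unname(res$table[, "mutant"]), c(9, 8))
  # two-sided Fisher p: sum of hypergeometric point masses <= observed
  k_obs <- 9; K <- 17; n1 <- 19; N <- 49
  ks <- max(0, n1 - (N - K)):min(K, n1)
  pmass <- exp(lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1))
  p_exact <- sum(pmass[pmass <= pmass[ks == k_obs] * (1 + 1e-7)])
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
})

test_that("degenerate contingency tables are handled", {
  calls <- data.frame(cell_line = c("a", "b", "c", "d"), lineage = "lin",
                      avg_ceres = 0, label = c("resistant", "resistant",
                                               "sensitive", "sensitive"))
  none <- data.frame(cell_line = character(0), gene = character(0),
                     variant_classification = character(0),
                     is_deleterious = logical(0), is_tcga_hotspot = logical(0),
                     is_cosmic_hotspot = logical(0))
  expect_equal(mutation_enrichment(none, calls, "TP53")$p_value, 1)
  sym <- data.frame(cell_line = c("a", "c"), gene = "TP53",
                    variant_classification = "damaging", is_deleterious = TRUE,
                    is_tcga_hotspot = FALSE, is_cosmic_hotspot = FALSE)
  res <- mutation_enrichment(sym, calls, "TP53")
  expect_equal(res$odds_ratio, 1, tolerance = 1e-8)
})

test_that("CCLE mutation rules flag ccRCC and functional mutations", {
  ceres <- matrix(c(-0.2, -0.8, -0.1), 3, 1,
                  dimnames = list(c("L1", "L2", "L3"), "VHL"))
  mut <- data.frame(
    cell_line = c("L1", "L2", "L3", "L1", "L3"),
    gene = c("VHL", "VHL", "SMARCB1", "ARID1A", "ARID1A"),
    variant_classification = c("damaging", "damaging", "silent",
                               "other non-conserving", "missense"),
    is_deleterious = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    is_tcga_hotspot = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    is_cosmic_hotspot = FALSE)
  fl <- classify_ccle_mutants(mut, ceres)
  expect_true(fl$is_ccRCC[fl$cell_line == "L1"])     # damaging VHL, CERES -0.2
  expect_false(fl$is_ccRCC[fl$cell_line == "L2"])    # VHL still essential (-0.8)
  expect_false(fl$smarcb1_functional[fl$cell_line == "L3"])  # silent hotspot
  expect_true(fl$arid1a_functional[fl$cell_line == "L1"])    # non-conserving
  expect_true(fl$arid1a_functional[fl$cell_line == "L3"])    # missense hotspot
})

test_that("CCLE flags survive a write/read round trip of the cohort", {
  sim <- generate_dependency_bundle(n_lineages = 3, lines_per_lineage = 12,
                                    n_genes = 40, n_tfs = 20, seed = 27)
  dir <- withr::local_tempdir()
  write_dependency_bundle(sim, dir)
  ceres <- read_dependency_csv(file.path(dir, "ceres.csv"))
  mut <- read_mutation_table(file.path(dir, "mutations.csv"))
  fl <- classify_ccle_mutants(mut, ceres)
  # independent rule application straight from the in-memory tables
  m <- sim$bundle$mutations
  for (ln in rownames(ceres)) {
    rows <- m[m$cell_line == ln & m$gene == "VHL", ]
    expected <- any(rows$variant_classification %in%
                      c("damaging", "other non-conserving")) &&
      sim$bundle$ceres[ln, "VHL"] > -0.5
    expect_equal(fl$is_ccRCC[fl$cell_line == ln], expected)
  }
})
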