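block_profiles <- function(sizes, n_specific = 20, n_backbone = 10, eps = 0,
                           seed = 1) {
  n_samples <- sum(sizes)
  samples <- sprintf("s%03d", seq_len(n_samples))
  cluster_of <- rep(seq_along(sizes), sizes)
  nr <- n_backbone + length(sizes) * n_specific + 20
  values <- matrix(0L, nr, n_samples, dimnames = list(NULL, samples))
  values[seq_len(n_backbone), ] <- 1L
  spec <- lapply(seq_along(sizes), function(k)
    n_backbone + (k - 1L) * n_specific + seq_len(n_specific))
  for (k in seq_along(sizes)) values[spec[[k]], cluster_of == k] <- 1L
  if (eps > 0) {
    set.seed(seed)
    flip <- matrix(runif(length(values)) < eps, nr, n_samples)
    values[flip] <- 1L - values[flip]
  }
  regions <- data.frame(chrom = "chr1", start = 1000L * seq_len(nr),
                        end = 1000L * seq_len(nr) + 500L)
  list(profiles = profile_matrix(regions, values),
       truth = lapply(seq_along(sizes), function(k) samples[cluster_of == k]),
       specific = spec)
}

test_that("variance ranking puts half-open regions first and constants last", {
  values <- rbind(rep(1L, 10),                      # constant open
                  rep(c(0L, 1L), 5),                # half open: max variance
                  c(rep(0L, 9), 1L))
  colnames(values) <- sprintf("s%02d", 1:10)
  regions <- data.frame(chrom = "chr1", start = c(100L, 200L, 300L),
                        end = c(150L, 250L, 350L))
  pm <- profile_matrix(regions, values)
  idx <- select_variable_regions(pm, 3)
  expect_equal(idx[1], 2L)
  expect_equal(idx[3], 1L)
  # agrees with a direct variance computation
  v <- apply(values, 1, var)
  expect_equal(v[idx[1]], max(v))
})

test_that("sample correlations match the textbook formula", {
  set.seed(71)
  values <- matrix(rbinom(200, 1, 0.5), 40, 5, dimnames = list(NULL, paste0("s", 1:5)))
  regions <- data.frame(chrom = "chr1", start = 100L * 1:40, end = 100L * 1:40 + 50L)
  pm <- profile_matrix(regions, values)
  pcc <- sample_correlation(pm)
  manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(pcc[i, j], manual(values[, i], values[, j]), tolerance = 1e-12)
  expect_true(all(diag(pcc) == 1))
})

test_that("identical and complementary profiles hit the correlation bounds", {
  v <- c(rep(0L, 5), rep(1L, 5))
  values <- cbind(a = v, b = v, c = 1L - v)
  regions <- data.frame(chrom = "chr1", start = 100L * 1:10, end = 100L * 1:10 + 50L)
  pcc <- sample_correlation(profile_matrix(regions, values))
  expect_equal(pcc["a", "b"], 1)
  expect_equal(pcc["a", "c"], -1)
})

test_that("constant samples get zero correlation and a flag", {
  values <- cbind(a = rep(1L, 6), b = rep(c(0L, 1L), 3))
  regions <- data.frame(chrom = "chr1", start = 100L * 1:6, end = 100L * 1:6 + 50L)
  pcc <- sample_correlation(profile_matrix(regions, values))
  expect_equal(pcc["a", "b"], 0)
  expect_equal(attr(pcc, "constant_samples"), "a")
})

test_that("perfect blocks are recovered exactly by the greedy pass", {
  bp <- block_profiles(c(8, 6, 5))
  pcc <- sample_correlation(bp$profiles)
  cl <- greedy_cluster(pcc)
  expect_length(cl$clusters, 3)
  expect_length(cl$unassigned, 0)
  recovered <- lapply(cl$clusters, sort)
  expect_setequal(recovered, lapply(bp$truth, sort))
  expect_true(all(lengths(cl$clusters) >= 5))
})

test_that("sub-threshold correlation or undersized blocks yield no clusters", {
  pcc <- diag(8); dimnames(pcc) <- list(paste0("s", 1:8), paste0("s", 1:8))
  cl <- greedy_cluster(pcc, pcc_threshold = 0.6, min_cluster_size = 5)
  expect_length(cl$clusters, 0)
  expect_length(cl$unassigned, 8)

  bp <- block_profiles(c(4, 4))
  cl2 <- greedy_cluster(sample_correlation(bp$profiles), min_cluster_size = 5)
  expect_length(cl2$clusters, 0)
})

test_that("the stop rule halts at the first undersized cluster", {
  # one big block and one small one: the small block must not be emitted
  bp <- block_profiles(c(9, 3))
  cl <- greedy_cluster(sample_correlation(bp$profiles))
  expect_length(cl$clusters, 1)
  expect_setequal(cl$clusters[[1]], bp$truth[[1]])
  expect_setequal(cl$unassigned, bp$truth[[2]])
})

test_that("clustering is invariant to sample order", {
  bp <- block_profiles(c(7, 6, 5), eps = 0.03, seed = 4)
  pcc <- sample_correlation(bp$profiles)
  cl1 <- greedy_cluster(pcc)
  perm <- sample(nrow(pcc))
  cl2 <- greedy_cluster(pcc[perm, perm])
  m1 <- membership_of(cl1, rownames(pcc))
  m2 <- membership_of(cl2, rownames(pcc))
  expect_equal(adjusted_rand(m1, m2), 1)
})

test_that("cluster-specific regions follow the sharing rule", {
  # 4 clusters of 5; one region present in all four, one private to cluster 1,
  # one shared by exactly three
  sizes <- c(5, 5, 5, 5)
  samples <- sprintf("s%03d", seq_len(sum(sizes)))
  cluster_of <- rep(1:4, each = 5)
  values <- matrix(0L, 3, 20, dimnames = list(NULL, samples))
  values[1, ] <- 1L                          # in 4 clusters: 3 additional > 2
  values[2, cluster_of == 1] <- 1L           # private
  values[3, cluster_of %in% 1:3] <- 1L       # 2 additional: still specific
  regions <- data.frame(chrom = "chr1", start = c(100L, 200L, 300L),
                        end = c(150L, 250L, 350L))
  pm <- profile_matrix(regions, values)
  cl <- lapply(split(samples, cluster_of), identity)
  names(cl) <- paste0("cluster_", 1:4)
  spec <- cluster_specific_regions(pm, cl)
  expect_false(any(vapply(spec, function(s) 1L %in% s, logical(1))))
  expect_equal(spec$cluster_1, c(2L, 3L))
  expect_equal(spec$cluster_2, 3L)
  expect_equal(spec$cluster_4, integer(0))
})

test_that("planted specific regions are recovered exactly without noise", {
  # four blocks: the shared backbone sits in three additional clusters and is
  # correctly excluded from every specific set
  bp <- block_profiles(c(6, 6, 6, 5), n_specific = 15)
  cl <- greedy_cluster(sample_correlation(bp$profiles))
  spec <- cluster_specific_regions(bp$profiles, cl)
  # match recovered clusters to truth by membership
  for (id in names(cl$clusters)) {
    k <- which(vapply(bp$truth, function(tr) setequal(tr, cl$clusters[[id]]),
                      logical(1)))
    expect_setequal(spec[[id]], bp$specific[[k]])
  }
})

test_that("summit-window containment is strict for overlap enrichment", {
  cons <- data.frame(chrom = "chr1", start = c(975, 1975), end = c(1476, 2476),
                     name = c("pk1", "pk2"), score = 0, strand = ".",
                     signal = 1, pvalue = 1, qvalue = c(30, 20),
                     summit = c(1225, 2225))
  da <- cons[1, ]
  exact <- list(c1 = data.frame(chrom = "chr1", start = 1200, end = 1251))
  res <- overlap_enrichment(exact, da, cons)
  expect_equal(res$n_da_hits, 1L)            # 51 bp window exactly contained
  overhang <- list(c1 = data.frame(chrom = "chr1", start = 1201, end = 1251))
  res2 <- overlap_enrichment(overhang, da, cons)
  expect_equal(res2$n_da_hits, 0L)           # one base short of full containment
})

test_that("overlap enrichment p-values equal the combinatorial tail", {
  set.seed(91)
  cons <- data.frame(chrom = "chr1", start = 0, end = 1,
                     name = sprintf("pk%03d", 1:40), score = 0, strand = ".",
                     signal = 1, pvalue = 1, qvalue = 1,
                     summit = sort(sample(seq(1000, 200000, by = 100), 40)))
  cons$start <- cons$summit - 250L; cons$end <- cons$summit + 251L
  da <- cons[sample(40, 12), ]
  hit_idx <- sample(40, 15)
  regions <- list(cl = data.frame(chrom = "chr1",
                                  start = cons$summit[hit_idx] - 30L,
                                  end = cons$summit[hit_idx] + 31L))
  res <- overlap_enrichment(regions, da, cons)
  k <- sum(da$name %in% cons$name[hit_idx])
  expect_equal(res$n_da_hits, k)
  expect_equal(res$n_consensus_hits, 15L)
  expect_equal(res$p_value, oracle_hyper_upper(k, 15, 40, 12), tolerance = 1e-12)
})
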