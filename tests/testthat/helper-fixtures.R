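# Shared fixture builders.

# background-only CERES matrix at the simulator's noise scale
with_seed_matrix <- function(seed, n_lines, n_genes, sigma = 0.15) {
  set.seed(seed)
  matrix(rnorm(n_lines * n_genes, 0, sigma), n_lines, n_genes,
         dimnames = list(sprintf("L%03d", seq_len(n_lines)),
                         sprintf("G%04d", seq_len(n_genes))))
}

# one region whose window captures exactly n of N expressed genes, k of the
# K differentially expressed ones
hyper_gene_fixture <- function(k, K, N, n, h = 2000L, center = 10000L) {
  k <- as.integer(k); K <- as.integer(K); N <- as.integer(N); n <- as.integer(n)
  stopifnot(k <= K, k <= n, n <= N, K <= N, n - k <= N - K)
  near <- center - h + 10L * seq_len(n)          # inside [center-h, center+h)
  far <- 10L * (N - n) + 50L * seq_len(N - n) + 500000L
  tss <- c(near, far)
  status <- c(rep("down", k), rep("unchanged", n - k),
              rep("down", K - k), rep("unchanged", (N - n) - (K - k)))
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(N)), chrom = "chr1",
                      tss = tss, strand = "+", de_status = status,
                      log2fc = ifelse(status == "down", -1, 0), padj = 0.5,
                      stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chr1", start = center - 250L,
                        end = center + 251L, summit = center)
  list(genes = genes, regions = regions, h = h)
}
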