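# Independent brute-force oracles. These recompute expected values by the
# most direct route available (quadratic scans, explicit enumeration,
# closed-form combinatorics) and stay independent of the package internals.

# O(n^2) consensus builder: same rule, pairwise overlap checks only.
oracle_consensus <- function(peaks, width = 501L) {
  w <- (width - 1L) %/% 2L
  cand <- peaks
  cand$start <- cand$summit - w
  cand$end <- cand$summit + w + 1L
  cand <- cand[cand$start >= 0, , drop = FALSE]
  cand <- cand[order(-cand$qvalue, cand$chrom, cand$summit), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (cand$chrom[i] == cand$chrom[j] &&
          cand$start[i] < cand$end[j] && cand$end[i] > cand$start[j]) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Upper-tail hypergeometric P(X >= k) by direct combinatorial summation.
oracle_hyper_upper <- function(k, n_success, n_total, n_draw) {
  j <- seq(max(0, k), min(n_success, n_draw))
  if (length(j) == 0) return(0)
  sum(exp(lchoose(n_success, j) + lchoose(n_total - n_success, n_draw - j) -
          lchoose(n_total, n_draw)))
}

# Textbook pooled-SD Cohen's D.
oracle_cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

# All distinct resistant/sensitive label assignments preserving group sizes.
enumerate_assignments <- function(n_lines, n_resistant) {
  combos <- utils::combn(n_lines, n_resistant)
  t(apply(combos, 2, function(idx) seq_len(n_lines) %in% idx))
}

# Full-enumeration permutation FDR/q for a tiny matrix: loops only.
oracle_perm_fdr <- function(X, res_lab, assignments) {
  d_of <- function(lab) {
    vapply(seq_len(ncol(X)), function(g)
      oracle_cohens_d(X[lab, g], X[!lab, g]), numeric(1))
  }
  d_obs <- d_of(res_lab)
  d_perm <- t(apply(assignments, 1, d_of))
  fdr <- q <- numeric(ncol(X))
  for (i in seq_len(ncol(X))) {
    numer <- mean(apply(d_perm, 1, function(dp) sum(abs(dp) >= abs(d_obs[i]))))
    denom <- sum(abs(d_obs) >= abs(d_obs[i]))
    fdr[i] <- min(1, numer / denom)
  }
  for (i in seq_len(ncol(X)))
    q[i] <- min(fdr[abs(d_obs) <= abs(d_obs[i])])
  list(d_obs = d_obs, fdr = fdr, q = q)
}

# Quadratic all-pairs TSS capture scan.
oracle_capture <- function(regions, genes, h) {
  center <- if ("summit" %in% names(regions)) regions$summit
            else regions$start + (regions$end - regions$start) %/% 2
  hit <- vapply(seq_len(nrow(genes)), function(gi) {
    any(genes$chrom[gi] == regions$chrom &
        genes$tss[gi] >= center - h & genes$tss[gi] < center + h)
  }, logical(1))
  unique(genes$gene_id[hit])
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# membership vector (sample -> cluster id, unassigned = "none") from a
# cluster_result or a named list of sample vectors
membership_of <- function(clusters, samples) {
  cl <- if (inherits(clusters, "cluster_result")) clusters$clusters else clusters
  m <- rep("none", length(samples)); names(m) <- samples
  for (id in names(cl)) m[cl[[id]]] <- id
  m
}
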