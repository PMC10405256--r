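#' Classify cell lines as lineage-factor sensitive or resistant
#'
#' Each line of a lineage with a dependency set gets the mean CERES score
#' over that lineage's LD TFs (missing values excluded); lines whose average
#' exceeds `resistance_cutoff` are called resistant (lineage-factor
#' independent), the rest sensitive. Lines in lineages without an LD set are
#' skipped; a line with no non-missing value over the set is skipped with a
#' warning.
#'
#' @param ceres CERES matrix, cell lines x genes.
#' @param ld_sets result of [filter_lineage_dependencies()].
#' @param annotations `data.frame` with columns `cell_line`, `lineage`.
#' @param resistance_cutoff average CERES above which a line is resistant.
#'   Default -0.45.
#' @return A `data.frame` with columns `cell_line`, `lineage`, `avg_ceres`,
#'   `label` (`"sensitive"` or `"resistant"`).
#' @export
classify_cell_lines <- function(ceres, ld_sets, annotations,
                                resistance_cutoff = -0.45) {
  if (length(ld_sets) == 0) stop("no lineage has a dependency set")
  res <- list()
  for (lin in names(ld_sets)) {
    tfs <- ld_sets[[lin]]$tfs
    if (length(tfs) == 0) stop("empty TF set for lineage ", lin)
    lines_in <- intersect(annotations$cell_line[annotations$lineage == lin],
                          rownames(ceres))
    if (length(lines_in) == 0) next
    avg <- rowMeans(ceres[lines_in, tfs, drop = FALSE], na.rm = TRUE)
    dropped <- is.nan(avg)
    if (any(dropped)) {
      warning(sprintf("skipped %d line(s) in %s with no CERES value over the LD set",
                      sum(dropped), lin))
      avg <- avg[!dropped]; lines_in <- lines_in[!dropped]
    }
    res[[lin]] <- data.frame(
      cell_line = lines_in, lineage = lin, avg_ceres = unname(avg),
      label = ifelse(avg > resistance_cutoff, "resistant", "sensitive"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cohen's D effect size (pooled-SD variant)
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)`, sample
#' variances with `n-1` denominators. Missing values are dropped. When the
#' pooled SD is zero: `d = 0` if the means agree, otherwise signed infinity.
#'
#' @param group_a,group_b numeric vectors with at least two non-missing
#'   values each.
#' @return Scalar effect size (a minus b).
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("cohens_d needs >= 2 non-missing values in each group")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / sqrt(sp2)
}

#' Permutation-based FDR for acquired dependencies
#'
#' For each gene the observed effect size is Cohen's D of resistant versus
#' sensitive lines. Group labels are then shuffled `n_permutations` times
#' (within each lineage by default), preserving group sizes, and effect
#' sizes recomputed for all genes. The estimated FDR for gene i is the mean
#' (over permutations) count of permuted effect sizes at least as extreme as
#' gene i's observed one, divided by the count of observed effect sizes at
#' least as extreme (the gene always counts itself), capped at 1. The
#' q-value is the running minimum of the FDR over all genes at least as
#' extreme, so significance calls are monotone in `|d|`.
#'
#' @param ceres CERES matrix, cell lines x genes.
#' @param calls resistance calls from [classify_cell_lines()]; both labels
#'   must be present.
#' @param genes genes to scan; subset of `colnames(ceres)`. Default: all.
#' @param n_permutations number of label shuffles. Default 1000.
#' @param q_threshold significance cutoff on the q-value. Default 0.1.
#' @param seed integer seed for the permutation stream.
#' @param shuffle_within_lineage permute labels within each lineage
#'   (default) rather than pooled across the cohort.
#' @param permutations optional logical/0-1 matrix (permutations x lines,
#'   columns ordered by `sort(calls$cell_line)`), each row an explicit
#'   resistant-indicator assignment to use instead of random shuffles; lets
#'   tiny cohorts be scored by exhaustive enumeration. Overrides
#'   `n_permutations` and `seed`.
#' @return A `data.frame` with columns `gene`, `d_obs`, `fdr_hat`,
#'   `q_value`, `significant`.
#' @export
permutation_fdr <- function(ceres, calls, genes = colnames(ceres),
                            n_permutations = 1000L, q_threshold = 0.1,
                            seed = 1L, shuffle_within_lineage = TRUE,
                            permutations = NULL) {
  if (!is.null(permutations)) n_permutations <- nrow(permutations)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (!all(genes %in% colnames(ceres))) stop("genes absent from the CERES matrix")
  calls <- calls[order(calls$cell_line), , drop = FALSE]  # order-invariance
  res_lab <- calls$label == "resistant"
  if (sum(res_lab) < 2 || sum(!res_lab) < 2)
    stop("both groups need at least two cell lines")

  X <- ceres[calls$cell_line, genes, drop = FALSE]
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0
  X0sq <- X0^2

  d_from_indicator <- function(L) {
    # L: permutations x lines indicator of "resistant"; returns perms x genes
    # d. Both groups go through their own explicit products (not totals
    # minus group A) so that swapping the groups negates d exactly in
    # floating point.
    Lc <- 1 - L
    nA <- L %*% obs; sA <- L %*% X0; qA <- L %*% X0sq
    nB <- Lc %*% obs; sB <- Lc %*% X0; qB <- Lc %*% X0sq
    mA <- sA / nA; mB <- sB / nB
    vA <- (qA - nA * mA^2) / (nA - 1)
    vB <- (qB - nB * mB^2) / (nB - 1)
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    sp2[sp2 < 0] <- 0                       # numerical guard
    diff <- mA - mB
    d <- diff / sqrt(sp2)
    zero_sp <- sp2 == 0
    d[zero_sp & diff == 0] <- 0
    d[zero_sp & diff != 0] <- sign(diff[zero_sp & diff != 0]) * Inf
    d[nA < 2 | nB < 2] <- NA_real_
    d
  }

  if (is.null(permutations)) {
    strata <- if (shuffle_within_lineage) calls$lineage else rep("all", nrow(calls))
    L <- matrix(0, n_permutations, nrow(calls))
    with_sub_seed(seed, "permutation_fdr", {
      for (p in seq_len(n_permutations)) {
        lab <- res_lab
        for (s in unique(strata)) {
          idx <- which(strata == s)
          lab[idx] <- res_lab[idx][sample.int(length(idx))]
        }
        L[p, ] <- as.numeric(lab)
      }
    })
  } else {
    if (ncol(permutations) != nrow(calls))
      stop("permutations must have one column per cell line")
    if (!all(rowSums(permutations != 0) == sum(res_lab)))
      stop("each permutation must preserve the resistant group size")
    L <- matrix(as.numeric(permutations != 0), nrow(permutations))
  }
  # observed row first, through the same matrix products as the permuted
  # rows, so exact symmetry ties (e.g. the identity assignment) survive
  # floating point
  d_all <- d_from_indicator(rbind(as.numeric(res_lab), L))
  d_obs <- d_all[1, ]
  d_perm <- d_all[-1, , drop = FALSE]

  abs_obs <- abs(d_obs)
  pooled <- sort(abs(as.vector(d_perm)))     # NAs dropped by sort
  m <- length(pooled)
  # count of pooled values >= t  (findInterval with left.open counts < t)
  cnt_ge <- m - findInterval(abs_obs, pooled, left.open = TRUE)
  numer <- cnt_ge / n_permutations
  denom <- length(abs_obs) - rank(abs_obs, ties.method = "min") + 1
  fdr <- pmin(1, numer / denom)

  # q-value: min estimated FDR over all thresholds that still call gene i
  # significant, i.e. over genes with |d| <= |d_i| (running min along
  # ascending |d|); q is therefore non-increasing in |d_obs|
  ord <- order(abs_obs)
  q <- numeric(length(fdr)); q[ord] <- cummin(fdr[ord])
  # equal |d| must share the q of the whole tie group
  q <- stats::ave(q, abs_obs, FUN = min)

  data.frame(gene = genes, d_obs = d_obs, fdr_hat = fdr, q_value = q,
             significant = q < q_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutation enrichment between resistant and sensitive lines
#'
#' Two-sided Fisher's exact test on the 2x2 table of
#' {resistant, sensitive} x {mutant, wild-type} for one gene. A line is
#' mutant if the mutation table has any record for it in that gene.
#'
#' @param mutations mutation table (see [read_mutation_table()]).
#' @param calls resistance calls from [classify_cell_lines()].
#' @param gene gene symbol to test.
#' @return List with `odds_ratio` (conditional MLE; `NA` when a table margin
#'   is zero), `p_value`, and `table` (the 2x2 contingency matrix).
#' @export
mutation_enrichment <- function(mutations, calls, gene) {
  mut_lines <- unique(mutations$cell_line[mutations$gene == gene])
  is_mut <- calls$cell_line %in% mut_lines
  is_res <- calls$label == "resistant"
  tab <- matrix(c(sum(is_res & is_mut), sum(is_res & !is_mut),
                  sum(!is_res & is_mut), sum(!is_res & !is_mut)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("resistant", "sensitive"),
                                c("mutant", "wild_type")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Functional-mutation flags in the CCLE dialect
#'
#' Applies the study's mutation-filter rules per cell line:
#' \itemize{
#'   \item `is_ccRCC`: a VHL mutation of class damaging / other
#'     non-conserving \emph{and} resistance to VHL knockout
#'     (CERES(VHL) > -0.5) — the clear-cell RCC definition;
#'   \item `smarcb1_functional`, `arid1a_functional`: a damaging / other
#'     non-conserving mutation, or any non-silent mutation flagged as a TCGA
#'     or COSMIC hotspot.
#' }
#'
#' @param mutations mutation table (see [read_mutation_table()]).
#' @param ceres CERES matrix with a `VHL` column.
#' @return A `data.frame` with columns `cell_line`, `is_ccRCC`,
#'   `smarcb1_functional`, `arid1a_functional`, one row per line of `ceres`.
#' @export
classify_ccle_mutants <- function(mutations, ceres) {
  if (!"VHL" %in% colnames(ceres)) stop("CERES matrix has no VHL column")
  lines <- rownames(ceres)
  nonconserving <- mutations$variant_classification %in%
    c("damaging", "other non-conserving")
  hotspot <- mutations$variant_classification != "silent" &
    (mutations$is_tcga_hotspot | mutations$is_cosmic_hotspot)

  has_class <- function(gene, keep) {
    lines %in% unique(mutations$cell_line[mutations$gene == gene & keep])
  }
  functional <- function(gene) has_class(gene, nonconserving) | has_class(gene, hotspot)

  vhl_mut <- has_class("VHL", nonconserving)
  data.frame(
    cell_line = lines,
    is_ccRCC = vhl_mut & !is.na(ceres[, "VHL"]) & ceres[, "VHL"] > -0.5,
    smarcb1_functional = functional("SMARCB1"),
    arid1a_functional = functional("ARID1A"),
    stringsAsFactors = FALSE, row.names = NULL)
}
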