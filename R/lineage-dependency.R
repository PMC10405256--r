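#' Lineages with enough cell lines to score
#'
#' Underrepresented lineages are excluded from scoring; only lineages with
#' at least `min_lineage_size` member lines are returned.
#'
#' @param annotations `data.frame` with columns `cell_line`, `lineage`.
#' @param min_lineage_size minimum member count. Default 10.
#' @return Character vector of lineage labels, sorted lexicographically.
#' @export
eligible_lineages <- function(annotations, min_lineage_size = 10L) {
  counts <- table(annotations$lineage)
  sort(names(counts)[counts >= min_lineage_size])
}

#' Lineage dependency (LD) scores for every TF x lineage
#'
#' For each eligible lineage x and each transcription factor t, the LD score
#' is the mean CERES of t in the lines of x minus its mean in the lines of
#' all other eligible lineages; strongly negative scores mark
#' lineage-specific dependencies. Significance comes from the two-group
#' Kruskal-Wallis test (tie-corrected) on the same in/out partition, with
#' Benjamini-Hochberg adjustment.
#'
#' Missing CERES values are excluded pairwise. TFs with fewer than two
#' non-missing values in either group get `p_value = NA` and are flagged.
#'
#' @param ceres numeric matrix, cell lines x genes (CERES scores).
#' @param annotations `data.frame` with columns `cell_line`, `lineage`.
#' @param tf_list character vector of TF symbols; must be a subset of
#'   `colnames(ceres)`.
#' @param min_lineage_size lineages below this size are skipped. Default 10.
#' @param p_adjust_scope `"per_lineage"` (BH within each lineage's TF
#'   family, the default) or `"global"` (one family over all records).
#' @return A `data.frame` with columns `tf`, `lineage`, `ld_score`,
#'   `p_value`, `p_adj`, `n_in`, `n_out`, `flag_insufficient`.
#' @export
compute_ld_scores <- function(ceres, annotations, tf_list,
                              min_lineage_size = 10L,
                              p_adjust_scope = c("per_lineage", "global")) {
  p_adjust_scope <- match.arg(p_adjust_scope)
  missing_tf <- setdiff(tf_list, colnames(ceres))
  if (length(missing_tf) > 0)
    stop("TFs absent from the gene-effect matrix: ", paste(missing_tf[1:min(3, length(missing_tf))], collapse = ", "))
  ann <- annotations[annotations$cell_line %in% rownames(ceres), , drop = FALSE]
  lineages <- eligible_lineages(ann, min_lineage_size)
  if (length(lineages) == 0) stop("no lineage reaches min_lineage_size")
  ann <- ann[ann$lineage %in% lineages, , drop = FALSE]

  X <- ceres[ann$cell_line, tf_list, drop = FALSE]
  grp <- factor(ann$lineage, levels = lineages)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0

  # group-wise sums and counts; out-group = complement within eligible lines
  gsum <- rowsum(X0, grp)                      # lineages x TFs
  gn <- rowsum(obs + 0, grp)
  tsum <- colSums(X0); tn <- colSums(obs)
  mean_in <- gsum / gn
  mean_out <- sweep(-gsum, 2, tsum, "+") / sweep(-gn, 2, tn, "+")
  ld <- mean_in - mean_out

  # two-group Kruskal-Wallis, vectorised: column ranks are shared by every
  # in/out partition of the same column
  R <- apply(X, 2, rank, na.last = "keep")
  R0 <- R; R0[!obs] <- 0
  grsum <- rowsum(R0, grp)                     # in-group rank sums
  trsum <- colSums(R0)
  tie_term <- apply(X, 2, function(v) {
    t <- table(v[!is.na(v)])
    sum(t^3 - t)
  })

  n_in <- gn; n_out <- sweep(-gn, 2, tn, "+")
  N <- matrix(tn, nrow = length(lineages), ncol = length(tf_list), byrow = TRUE)
  R_in <- grsum; R_out <- sweep(-grsum, 2, trsum, "+")
  H <- 12 / (N * (N + 1)) * (R_in^2 / n_in + R_out^2 / n_out) - 3 * (N + 1)
  Cmat <- 1 - matrix(tie_term, nrow = length(lineages), ncol = length(tf_list),
                     byrow = TRUE) / (N^3 - N)
  p <- stats::pchisq(H / Cmat, df = 1, lower.tail = FALSE)
  p[Cmat <= 0] <- 1                            # all values tied: no evidence
  insufficient <- n_in < 2 | n_out < 2
  p[insufficient] <- NA_real_

  rec <- data.frame(
    tf = rep(tf_list, each = length(lineages)),
    lineage = rep(lineages, times = length(tf_list)),
    ld_score = as.vector(ld),
    p_value = as.vector(p),
    n_in = as.integer(n_in),
    n_out = as.integer(n_out),
    flag_insufficient = as.vector(insufficient),
    stringsAsFactors = FALSE
  )
  if (p_adjust_scope == "per_lineage") {
    rec$p_adj <- stats::ave(rec$p_value, rec$lineage, FUN = function(p)
      stats::p.adjust(p, method = "BH", n = max(1L, sum(!is.na(p)))))
  } else {
    rec$p_adj <- stats::p.adjust(rec$p_value, method = "BH",
                                 n = max(1L, sum(!is.na(rec$p_value))))
  }
  rec <- rec[order(rec$lineage, rec$tf),
             c("tf", "lineage", "ld_score", "p_value", "p_adj",
               "n_in", "n_out", "flag_insufficient")]
  rownames(rec) <- NULL
  rec
}

#' Most negative LD score per TF
#'
#' Collapses the record table to one row per TF: the lineage in which the TF
#' has its most negative (strongest) LD score. Ties are broken by
#' lexicographic lineage.
#'
#' @param records LD record table from [compute_ld_scores()].
#' @return A `data.frame` with columns `tf`, `lineage`, `ld_score`, one row
#'   per TF, sorted by TF.
#' @export
max_ld_per_tf <- function(records) {
  if (nrow(records) == 0) stop("no LD records supplied")
  ord <- order(records$tf, records$ld_score, records$lineage)
  r <- records[ord, ]
  r <- r[!duplicated(r$tf), c("tf", "lineage", "ld_score")]
  rownames(r) <- NULL
  r
}

#' Three-stage filter cascade defining each lineage's dependency set
#'
#' Candidate (TF, lineage) pairs pass three filters in order:
#' \enumerate{
#'   \item effect and significance: `ld_score < ld_cutoff` and p below
#'     `ld_p_cutoff` (BH-adjusted by default);
#'   \item strong dependency in the lineage: strictly more than
#'     `strong_dep_fraction` of the lineage's lines (with a non-missing
#'     value) have CERES at or below `strong_dep_ceres`;
#'   \item not pan-essential: TFs whose median CERES across \emph{all} cell
#'     lines is at or below `pan_essential_median` are removed.
#' }
#' Each removed candidate records the first filter that removed it.
#' Lineages whose surviving set is empty are dropped from the result.
#'
#' @param records LD record table from [compute_ld_scores()].
#' @param ceres the full CERES matrix (all cell lines; filter 3 uses every
#'   line, not only eligible lineages).
#' @param annotations `data.frame` with columns `cell_line`, `lineage`.
#' @param config an [ld_config()] carrying `ld_cutoff`, `ld_p_cutoff`,
#'   `strong_dep_ceres`, `strong_dep_fraction`, `pan_essential_median`.
#' @param use_raw_p use the unadjusted Kruskal-Wallis p in filter 1 instead
#'   of the BH-adjusted value. Default `FALSE`.
#' @return Named list, one element per surviving lineage, each a list with
#'   `lineage`, `tfs` (character) and `filter_trace` (`data.frame` of `tf`,
#'   `removed_by` in `{1,2,3,NA}`); class `lineage_dependency_sets`.
#' @export
filter_lineage_dependencies <- function(records, ceres, annotations,
                                        config = ld_config(),
                                        use_raw_p = FALSE) {
  out <- list()
  if (nrow(records) == 0) return(structure(out, class = "lineage_dependency_sets"))
  pcol <- if (use_raw_p) records$p_value else records$p_adj
  med_all <- apply(ceres, 2, stats::median, na.rm = TRUE)

  for (lin in sort(unique(records$lineage))) {
    idx <- which(records$lineage == lin)
    r <- records[idx, ]
    p <- pcol[idx]
    removed_by <- rep(NA_integer_, nrow(r))

    pass1 <- !is.na(p) & r$ld_score < config$ld_cutoff & p < config$ld_p_cutoff
    removed_by[!pass1] <- 1L

    lines_in <- annotations$cell_line[annotations$lineage == lin]
    lines_in <- intersect(lines_in, rownames(ceres))
    for (i in which(pass1)) {
      v <- ceres[lines_in, r$tf[i]]
      v <- v[!is.na(v)]
      frac <- if (length(v) == 0) 0 else mean(v <= config$strong_dep_ceres)
      if (!(frac > config$strong_dep_fraction)) removed_by[i] <- 2L
    }
    pass2 <- pass1 & is.na(removed_by)
    fail3 <- pass2 & med_all[r$tf] <= config$pan_essential_median
    removed_by[fail3] <- 3L

    surv <- r$tf[is.na(removed_by)]
    if (length(surv) > 0) {
      out[[lin]] <- list(
        lineage = lin,
        tfs = surv,
        filter_trace = data.frame(tf = r$tf, removed_by = removed_by,
                                  stringsAsFactors = FALSE))
    }
  }
  structure(out, class = "lineage_dependency_sets")
}

#' @export
print.lineage_dependency_sets <- function(x, ...) {
  cat(sprintf("Lineage dependency sets for %d lineage(s)\n", length(x)))
  for (lin in names(x))
    cat(sprintf("  %-24s %s\n", lin, paste(x[[lin]]$tfs, collapse = ", ")))
  invisible(x)
}
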