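#' Most variable regions of a binary accessibility matrix
#'
#' Regions are ranked by the across-sample variance of their binary
#' open/closed vector (proportional to `p(1-p)`, maximal for regions open in
#' half the samples), descending, with ties broken by region coordinate.
#'
#' @param profiles a profile matrix object: list with `regions`
#'   (interval `data.frame`) and `values` (binary matrix, regions x
#'   samples), as built by [profile_matrix()].
#' @param top_k number of regions to return.
#' @return Integer vector of region row indices, length `top_k`.
#' @export
select_variable_regions <- function(profiles, top_k) {
  v <- profiles$values
  if (top_k > nrow(v)) stop("top_k exceeds the number of regions")
  p <- rowMeans(v)
  variance <- p * (1 - p)
  ord <- order(-variance, profiles$regions$chrom, profiles$regions$start)
  ord[seq_len(top_k)]
}

#' Assemble a profile matrix
#'
#' @param regions interval `data.frame` (`chrom`, `start`, `end`); no
#'   duplicate coordinates allowed.
#' @param values binary 0/1 matrix, regions x samples, with sample column
#'   names.
#' @return List of class `profile_matrix` with `regions`, `samples`,
#'   `values`.
#' @export
profile_matrix <- function(regions, values) {
  stopifnot(nrow(regions) == nrow(values))
  if (is.null(colnames(values))) stop("values needs sample column names")
  if (!all(values %in% c(0, 1))) stop("profile values must be 0/1")
  key <- paste(regions$chrom, regions$start, regions$end)
  if (anyDuplicated(key)) stop("duplicate region coordinates")
  structure(list(regions = regions, samples = colnames(values),
                 values = values), class = "profile_matrix")
}

#' Pairwise Pearson correlation of sample profiles
#'
#' Correlations are computed between sample columns over the selected
#' region subset. A constant column has no defined correlation; its entries
#' are recorded as 0 and the affected samples are listed in the
#' `constant_samples` attribute.
#'
#' @param profiles a [profile_matrix()].
#' @param region_subset integer indices of regions to use (>= 2), e.g. from
#'   [select_variable_regions()]. Default: all regions.
#' @return Symmetric correlation matrix with unit diagonal, samples x
#'   samples.
#' @export
sample_correlation <- function(profiles, region_subset = seq_len(nrow(profiles$values))) {
  if (length(region_subset) < 2) stop("need at least two regions")
  v <- profiles$values[region_subset, , drop = FALSE]
  constant <- apply(v, 2, function(x) stats::var(x) == 0)
  pcc <- suppressWarnings(stats::cor(v))
  pcc[is.na(pcc)] <- 0
  diag(pcc) <- 1
  structure(pcc, constant_samples = profiles$samples[constant])
}

#' Greedy correlation clustering of accessibility profiles
#'
#' Samples are ranked by how many other remaining samples they correlate
#' with above `pcc_threshold` (ties broken by sample id). The top-ranked
#' sample seeds a cluster containing itself and every remaining sample
#' correlated with the seed above the threshold. If the cluster is smaller
#' than `min_cluster_size` the loop stops (that cluster is not emitted);
#' otherwise the cluster is emitted, its members removed, and the ranking
#' recomputed. Remaining samples are reported unassigned.
#'
#' @param pcc square symmetric correlation matrix with sample dimnames.
#' @param pcc_threshold correlation cutoff (strict `>`). Default 0.6.
#' @param min_cluster_size stop rule. Default 5.
#' @param membership `"seed"` (default; membership is correlation with the
#'   seed, as in the greedy procedure) or `"all_pairs"` (every member must
#'   correlate with every other member).
#' @return List of class `cluster_result`: `clusters` (named list of sample
#'   vectors, `"cluster_1"`, `"cluster_2"`, ...), `unassigned`,
#'   `seed_sample` (named character vector).
#' @export
greedy_cluster <- function(pcc, pcc_threshold = 0.6, min_cluster_size = 5L,
                           membership = c("seed", "all_pairs")) {
  membership <- match.arg(membership)
  stopifnot(is.matrix(pcc), nrow(pcc) == ncol(pcc))
  if (is.null(rownames(pcc))) stop("pcc needs sample dimnames")
  if (max(abs(pcc - t(pcc))) > 1e-8) stop("pcc must be symmetric")
  samples <- rownames(pcc)
  remaining <- samples
  clusters <- list(); seeds <- character(0)
  repeat {
    if (length(remaining) < min_cluster_size) break
    sub <- pcc[remaining, remaining, drop = FALSE]
    adj <- sub > pcc_threshold
    diag(adj) <- FALSE
    degree <- rowSums(adj)
    seed <- remaining[order(-degree, remaining)][1]
    members <- remaining[adj[seed, ] | remaining == seed]
    if (membership == "all_pairs") {
      # drop members not correlated with every other member, farthest first
      repeat {
        a <- adj[members, members, drop = FALSE]
        diag(a) <- TRUE
        bad <- rowSums(!a)
        if (all(bad == 0) || length(members) <= 1) break
        worst <- members[order(-bad, members)][1]
        if (worst == seed) break
        members <- setdiff(members, worst)
      }
    }
    if (length(members) < min_cluster_size) break
    clusters[[length(clusters) + 1L]] <- sort(members)
    seeds <- c(seeds, seed)
    remaining <- setdiff(remaining, members)
  }
  names(clusters) <- if (length(clusters) > 0)
    paste0("cluster_", seq_along(clusters)) else character(0)
  structure(list(clusters = clusters, unassigned = sort(remaining),
                 seed_sample = stats::setNames(seeds, names(clusters))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%d cluster(s), %d sample(s) unassigned\n",
              length(x$clusters), length(x$unassigned)))
  for (nm in names(x$clusters))
    cat(sprintf("  %-12s n=%-3d seed=%s\n", nm, length(x$clusters[[nm]]),
                x$seed_sample[[nm]]))
  invisible(x)
}

#' Cluster-specific regions
#'
#' A region is "present in" a cluster when it is open in at least
#' `presence_fraction` of the cluster's samples; it is specific to a cluster
#' when it is present there and present in no more than
#' `max_additional_clusters` other clusters.
#'
#' @param profiles a [profile_matrix()].
#' @param clusters a [greedy_cluster()] result (or a named list of sample
#'   vectors).
#' @param presence_fraction presence cutoff (`>=`). Default 0.8.
#' @param max_additional_clusters tolerance for sharing. Default 2.
#' @return Named list, cluster id -> integer vector of region row indices.
#' @export
cluster_specific_regions <- function(profiles, clusters,
                                     presence_fraction = 0.8,
                                     max_additional_clusters = 2L) {
  cl <- if (inherits(clusters, "cluster_result")) clusters$clusters else clusters
  if (length(cl) == 0) return(stats::setNames(list(), character(0)))
  present <- vapply(cl, function(members) {
    rowMeans(profiles$values[, members, drop = FALSE]) >= presence_fraction
  }, logical(nrow(profiles$values)))           # regions x clusters
  present <- matrix(present, ncol = length(cl),
                    dimnames = list(NULL, names(cl)))
  n_present <- rowSums(present)
  out <- lapply(names(cl), function(id) {
    which(present[, id] & (n_present - 1) <= max_additional_clusters)
  })
  stats::setNames(out, names(cl))
}

#' Overlap enrichment of DA summit windows in cluster regions
#'
#' A peak "hits" a cluster's region set when its summit window
#' `[summit - summit_flank, summit + summit_flank + 1)` is fully contained
#' (100% overlap) in some region of the set. Enrichment of DA peaks among
#' hits is scored by the upper-tail hypergeometric: population = all
#' consensus peaks, successes = consensus peaks hitting the set, draws =
#' the DA peaks, observed = DA peaks hitting. Summit windows extending
#' below 0 or past a supplied chromosome end are excluded with a count.
#'
#' @param cluster_regions named list, cluster id -> interval `data.frame`
#'   (`chrom`, `start`, `end`).
#' @param da_peaks DA peak `data.frame` with summits; subset of
#'   `all_consensus`.
#' @param all_consensus consensus peak `data.frame` with summits.
#' @param summit_flank half-width of the summit window. Default 25.
#' @param genome optional `data.frame` (`chrom`, `length`) for right-bound
#'   checking.
#' @return A `data.frame`, one row per cluster, ranked by p-value:
#'   `cluster`, `n_da_hits`, `n_consensus_hits`, `n_da`, `n_consensus`,
#'   `p_value`; attribute `n_excluded` counts out-of-bounds peaks.
#' @export
overlap_enrichment <- function(cluster_regions, da_peaks, all_consensus,
                               summit_flank = 25L, genome = NULL) {
  if (!all(da_peaks$name %in% all_consensus$name))
    stop("da_peaks must be a subset of all_consensus")
  win <- data.frame(chrom = all_consensus$chrom,
                    start = all_consensus$summit - summit_flank,
                    end = all_consensus$summit + summit_flank + 1L,
                    strand = ".")
  ok <- win$start >= 0
  if (!is.null(genome)) {
    len <- genome$length[match(win$chrom, genome$chrom)]
    ok <- ok & !is.na(len) & win$end <= len
  }
  n_excluded <- sum(!ok)
  win <- win[ok, , drop = FALSE]
  names_ok <- all_consensus$name[ok]
  is_da <- names_ok %in% da_peaks$name
  wgr <- as_granges(win)

  rows <- lapply(names(cluster_regions), function(id) {
    reg <- cluster_regions[[id]]
    hit <- if (nrow(reg) == 0) logical(nrow(win)) else
      IRanges::overlapsAny(wgr, as_granges(data.frame(reg, strand = ".")),
                           type = "within")
    K <- sum(hit)                 # consensus peaks hitting the set
    k <- sum(hit & is_da)         # DA peaks hitting
    p <- stats::phyper(k - 1, K, length(hit) - K, sum(is_da), lower.tail = FALSE)
    data.frame(cluster = id, n_da_hits = k, n_consensus_hits = K,
               n_da = sum(is_da), n_consensus = length(hit), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded)
}
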