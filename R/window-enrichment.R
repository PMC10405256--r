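#' Genes captured by windows around regions
#'
#' Builds a window `[center - h, center + h)` around the centre of every
#' region (for summit-centred consensus peaks the centre is the summit) and
#' returns the deduplicated set of genes whose TSS falls in at least one
#' window (half-open: a TSS exactly at `center - h` is captured, one at
#' `center + h` is not). With `strategy = "body_overlap"` a gene is captured
#' when the window overlaps its body (`body_start`/`body_end` columns);
#' without those columns body capture falls back to the TSS rule.
#'
#' @param regions interval `data.frame` with `chrom`, `start`, `end` (and
#'   optionally `summit`).
#' @param genes gene table with `gene_id`, `chrom`, `tss`.
#' @param window_half_width half-width `h` in bases.
#' @param strategy `"tss"` (default) or `"body_overlap"`.
#' @return Character vector of captured `gene_id`s.
#' @export
capture_genes <- function(regions, genes, window_half_width,
                          strategy = c("tss", "body_overlap")) {
  strategy <- match.arg(strategy)
  if (nrow(regions) == 0 || nrow(genes) == 0) return(character(0))
  center <- region_center(regions)
  win <- data.frame(chrom = regions$chrom,
                    start = pmax(0, center - window_half_width),
                    end = center + window_half_width,
                    strand = ".")
  win <- win[win$end > win$start, , drop = FALSE]
  if (strategy == "tss" || !all(c("body_start", "body_end") %in% names(genes))) {
    g <- data.frame(chrom = genes$chrom, start = genes$tss,
                    end = genes$tss + 1, strand = ".")
  } else {
    g <- data.frame(chrom = genes$chrom, start = genes$body_start,
                    end = genes$body_end, strand = ".")
  }
  hits <- GenomicRanges::findOverlaps(as_granges(g), as_granges(win))
  unique(genes$gene_id[unique(S4Vectors::queryHits(hits))])
}

region_center <- function(regions) {
  if ("summit" %in% names(regions) && !anyNA(regions$summit)) regions$summit
  else regions$start + (regions$end - regions$start) %/% 2
}

#' Accessibility-expression coupling by sequential windows
#'
#' For each window half-width `h`, genes captured around the supplied
#' regions are intersected with the expressed-gene universe
#' (`de_status != "not_expressed"`) and with the differential set for the
#' requested direction. The capture ratio is `k / n` (DE captured over
#' universe captured) and significance is the upper tail of the
#' hypergeometric distribution: drawing `n` genes from the universe, how
#' surprising is capturing `k` or more DE genes.
#'
#' @param regions interval `data.frame` (e.g. LA regions, HA regions, or
#'   matched controls).
#' @param genes gene table with `gene_id`, `chrom`, `tss`, `de_status`.
#' @param window_sizes vector of half-widths in bases.
#' @param de_direction `"down"` or `"up"`.
#' @param region_class label copied into the output (default
#'   `"region"`).
#' @param strategy capture strategy passed to [capture_genes()].
#' @return A `data.frame` with one row per window size: columns
#'   `window_half_width`, `region_class`, `de_direction`,
#'   `n_universe_captured`, `n_de_captured`, `ratio`, `p_value`,
#'   `flag_empty` (TRUE when no universe gene was captured).
#' @export
window_enrichment <- function(regions, genes, window_sizes,
                              de_direction = c("down", "up"),
                              region_class = "region",
                              strategy = c("tss", "body_overlap")) {
  de_direction <- match.arg(de_direction)
  strategy <- match.arg(strategy)
  universe <- genes$gene_id[genes$de_status != "not_expressed"]
  if (length(universe) == 0) stop("empty expressed-gene universe")
  de_set <- genes$gene_id[genes$de_status == de_direction]

  rows <- lapply(window_sizes, function(h) {
    captured <- capture_genes(regions, genes, h, strategy = strategy)
    n <- length(intersect(captured, universe))
    k <- length(intersect(captured, de_set))
    ratio <- if (n == 0) 0 else k / n
    # P(X >= k), population |universe|, successes |DE|, draws n
    p <- stats::phyper(k - 1, length(de_set), length(universe) - length(de_set),
                       n, lower.tail = FALSE)
    data.frame(window_half_width = h, region_class = region_class,
               de_direction = de_direction, n_universe_captured = n,
               n_de_captured = k, ratio = ratio, p_value = p,
               flag_empty = n == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
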