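#' Filter peaks on -log10(q)
#'
#' Default direction keeps highly significant peaks
#' (`qvalue >= threshold`); the literal "keep weak" direction
#' (`qvalue < threshold`) is available via `direction`.
#'
#' @param peaks peak `data.frame` (see [read_narrowpeak()]).
#' @param threshold -log10(q) cutoff. Default 20.
#' @param direction `"keep_significant"` (default) or `"keep_below"`.
#' @return The retained subset of `peaks`.
#' @export
filter_peaks_by_q <- function(peaks, threshold = 20,
                              direction = c("keep_significant", "keep_below")) {
  direction <- match.arg(direction)
  keep <- if (direction == "keep_significant") peaks$qvalue >= threshold
          else peaks$qvalue < threshold
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summit-centred, significance-ranked consensus peaks
#'
#' Every input summit is extended to a fixed-width window
#' (`[summit - w, summit + w + 1)` with `w = (consensus_width - 1) / 2`).
#' Candidates are ranked by -log10(q) descending (ties broken by chromosome
#' then summit, making the result deterministic and independent of input
#' order) and greedily accepted iff they overlap no already-accepted window,
#' so each locus is represented by its most significant peak. Windows that
#' would start before position 0 are dropped (with a count in the
#' `n_out_of_bounds` attribute) unless `clip = TRUE`, which clips at 0
#' preserving the width toward the right.
#'
#' @param peaks peak `data.frame` with absolute `summit` positions.
#' @param consensus_width odd window width in bases. Default 501.
#' @param clip clip left-overhanging windows instead of dropping them.
#' @return `data.frame` of non-overlapping consensus peaks sorted by
#'   coordinate, with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit`, `source_peak`.
#' @export
build_consensus <- function(peaks, consensus_width = 501L, clip = FALSE) {
  if (consensus_width %% 2L != 1L) stop("consensus_width must be odd")
  w <- (consensus_width - 1L) %/% 2L
  cand <- peaks
  cand$start <- cand$summit - w
  cand$end <- cand$summit + w + 1L
  oob <- cand$start < 0L
  n_oob <- 0L
  if (any(oob)) {
    if (clip) {
      cand$end[oob] <- cand$end[oob] - cand$start[oob]
      cand$start[oob] <- 0L
    } else {
      n_oob <- sum(oob)
      cand <- cand[!oob, , drop = FALSE]
    }
  }
  ord <- order(-cand$qvalue, cand$chrom, cand$summit)
  cand <- cand[ord, , drop = FALSE]

  keep <- logical(nrow(cand))
  kept_start <- list(); kept_end <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    ks <- kept_start[[ch]]
    if (is.null(ks) || !any(cand$start[i] < kept_end[[ch]] & cand$end[i] > ks)) {
      keep[i] <- TRUE
      kept_start[[ch]] <- c(ks, cand$start[i])
      kept_end[[ch]] <- c(kept_end[[ch]], cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$source_peak <- out$name
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_out_of_bounds = n_oob)
}

#' Count 5'-extended reads in consensus peaks
#'
#' Each read is extended from its 5' end to `read_extension` bases in its
#' strand direction (minus-strand reads extend leftward, clipped at 0) and
#' counted into every consensus peak its extended interval overlaps by at
#' least one base. Unstranded reads are treated as plus-strand with a
#' warning.
#'
#' @param reads BED6 `data.frame` (see [read_bed6()]).
#' @param consensus consensus peak `data.frame` from [build_consensus()].
#' @param read_extension extended read length in bases. Default 250.
#' @return Integer vector of counts, one per consensus peak, named by peak
#'   name.
#' @export
count_reads <- function(reads, consensus, read_extension = 250L) {
  if (nrow(consensus) == 0) return(stats::setNames(integer(0), character(0)))
  r <- reads
  unstranded <- !r$strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sprintf("%d unstranded read(s) treated as '+'", sum(unstranded)))
    r$strand[unstranded] <- "+"
  }
  plus <- r$strand == "+"
  r$end[plus] <- r$start[plus] + read_extension
  r$start[!plus] <- pmax(0L, r$end[!plus] - read_extension)
  counts <- rep(0L, nrow(consensus))
  if (nrow(r) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(r), as_granges(consensus))
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(consensus))
    counts <- as.integer(tab)
  }
  stats::setNames(counts, consensus$name)
}

#' Call differentially accessible (DA) regions from a differential table
#'
#' Applies the study's thresholds to an externally computed differential
#' table (e.g. from a count-based differential engine): higher accessibility
#' (HA) at `log2fc >= log2(da_fc)`, lower accessibility (LA) at
#' `log2fc <= -log2(da_fc)`, both requiring `padj < da_padj`. Peaks missing
#' from the table are excluded; their count is reported in the `n_missing`
#' attribute.
#'
#' @param consensus consensus peak `data.frame`.
#' @param differential_table `data.frame` with columns `name`, `log2fc`,
#'   `padj`, keyed by consensus peak name.
#' @param da_fc linear fold-change threshold. Default 2.
#' @param da_padj adjusted-p threshold. Default 0.001.
#' @return The DA subset of `consensus` with added columns `log2fc`, `padj`,
#'   `da_class` in `{"LA", "HA"}`.
#' @export
call_da <- function(consensus, differential_table, da_fc = 2, da_padj = 0.001) {
  idx <- match(consensus$name, differential_table$name)
  n_missing <- sum(is.na(idx))
  out <- consensus[!is.na(idx), , drop = FALSE]
  dt <- differential_table[idx[!is.na(idx)], , drop = FALSE]
  out$log2fc <- dt$log2fc
  out$padj <- dt$padj
  lfc <- log2(da_fc)
  ha <- out$log2fc >= lfc & out$padj < da_padj
  la <- out$log2fc <= -lfc & out$padj < da_padj
  out$da_class <- ifelse(ha, "HA", ifelse(la, "LA", NA_character_))
  out <- out[!is.na(out$da_class), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_missing = n_missing)
}

#' Matched control peaks for a DA set
#'
#' Uniform random sample, without replacement, of non-DA consensus peaks;
#' the default size matches the DA set, mirroring heatmap-style
#' DA-versus-control comparisons.
#'
#' @param consensus consensus peak `data.frame`.
#' @param da_regions DA regions from [call_da()].
#' @param n sample size. Default `nrow(da_regions)`.
#' @param seed integer seed.
#' @return A `data.frame` of `n` control peaks.
#' @export
matched_controls <- function(consensus, da_regions, n = nrow(da_regions), seed = 1L) {
  pool <- consensus[!consensus$name %in% da_regions$name, , drop = FALSE]
  if (nrow(pool) < n)
    stop(sprintf("only %d non-DA peaks available, %d requested", nrow(pool), n))
  idx <- with_sub_seed(seed, "matched_controls", sample.int(nrow(pool), n))
  out <- pool[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
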