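#' Read ENCODE narrowPeak files
#'
#' Parses a 10-column BED6+4 narrowPeak file into a peak table. Coordinates
#' are kept in the file's native 0-based half-open convention. The summit is
#' returned as an absolute base position (`start + offset`). Records with a
#' summit offset of -1 (no summit called) are rejected; their count is
#' reported in a warning and in the `n_rejected` attribute.
#'
#' @param path path to a narrowPeak file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `pvalue`, `qvalue` (-log10 scale) and
#'   `summit` (absolute position), with attribute `n_rejected`.
#' @seealso [write_narrowpeak()]
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0) {
    return(structure(empty_peaks(), n_rejected = 0L))
  }
  bad <- which(nf != 10L)
  if (length(bad) > 0)
    stop(sprintf("narrowPeak parse error at line %d: expected 10 tab-separated columns, found %d",
                 bad[1], nf[bad[1]]))
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score",
                                        "strand", "signal", "pvalue", "qvalue", "offset"),
                          colClasses = c("character", "integer", "integer", "character",
                                         "numeric", "character", "numeric", "numeric",
                                         "numeric", "integer"))
  validate_intervals(df)
  if (any(df$qvalue < 0)) stop("negative -log10(q) value in ", path)
  no_summit <- df$offset < 0L
  n_rejected <- sum(no_summit)
  if (n_rejected > 0) {
    warning(sprintf("rejected %d narrowPeak record(s) without a summit (offset -1)", n_rejected))
    df <- df[!no_summit, , drop = FALSE]
  }
  df$summit <- df$start + df$offset
  df$offset <- NULL
  if (any(df$summit < df$start | df$summit >= df$end))
    stop("summit outside its peak interval in ", path)
  rownames(df) <- NULL
  structure(df, n_rejected = n_rejected)
}

#' Write a peak table as ENCODE narrowPeak
#'
#' Inverse of [read_narrowpeak()]: the summit is written back as an offset
#' from the interval start. Reading and re-writing a canonical file is
#' byte-identical.
#'
#' @param peaks peak `data.frame` as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  lines <- if (nrow(peaks) == 0) character(0) else
    paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
          num_chr(peaks$score), peaks$strand, num_chr(peaks$signal),
          num_chr(peaks$pvalue), num_chr(peaks$qvalue),
          peaks$summit - peaks$start, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 interval file
#'
#' @param path path to a 6-column BED file (0-based half-open).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0), strand = character(0)))
  bad <- which(nf != 6L)
  if (length(bad) > 0)
    stop(sprintf("BED6 parse error at line %d: expected 6 columns, found %d", bad[1], nf[bad[1]]))
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  validate_intervals(df)
  df
}

#' Write a BED6 interval file
#' @param x interval `data.frame` with BED6 columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  lines <- if (nrow(x) == 0) character(0) else
    paste(x$chrom, x$start, x$end, x$name, num_chr(x$score), x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = numeric(0), strand = character(0),
             signal = numeric(0), pvalue = numeric(0), qvalue = numeric(0),
             summit = integer(0))
}

validate_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  if (any(df$start < 0)) stop("negative interval start")
  if (any(df$end <= df$start)) stop("interval end must exceed start (0-based half-open)")
  ok <- df$strand %in% c("+", "-", ".")
  if (!all(ok)) stop("invalid strand value: ", df$strand[!ok][1])
  invisible(df)
}

# numeric -> minimal decimal text; round-trips through as.numeric
num_chr <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         character(1))
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(df, ignore_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (ignore_strand) "*" else ifelse(df$strand == ".", "*", df$strand))
}
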