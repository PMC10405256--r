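#' Read a DepMap-dialect gene-effect (CERES) matrix
#'
#' DepMap gene-effect CSVs carry cell lines in rows and genes in columns,
#' with header cells of the form `"SYMBOL (entrezid)"`; the symbol is the
#' token before the space. Empty cells become `NA` and are excluded pairwise
#' from all downstream means and tests.
#'
#' @param path path to the CSV; first column holds cell-line identifiers.
#' @return Numeric matrix, cell lines x genes, dimnames set to cell lines
#'   and gene symbols.
#' @export
read_dependency_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, colClasses = "character",
                          na.strings = NULL, data.table = FALSE)
  if (ncol(dt) < 2) stop("gene-effect CSV needs a cell-line column plus gene columns")
  lines <- dt[[1]]
  if (anyDuplicated(lines)) stop("duplicate cell-line identifiers")
  genes <- sub(" .*$", "", names(dt)[-1])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) stop("duplicate gene symbols after header normalization: ",
                            paste(unique(dup), collapse = ", "))
  mat <- matrix(NA_real_, nrow = nrow(dt), ncol = length(genes),
                dimnames = list(lines, genes))
  for (j in seq_along(genes)) {
    raw <- dt[[j + 1L]]
    blank <- !nzchar(raw) | is.na(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !blank)
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], genes[j], raw[bad[1]]))
    mat[, j] <- val
  }
  mat
}

#' Write a gene-effect matrix in DepMap dialect
#'
#' Header cells are `"SYMBOL (i)"` with a synthetic entrez-style index;
#' `NA` values become empty cells. Round-trips through
#' [read_dependency_csv()].
#'
#' @param mat numeric matrix, cell lines x genes, dimnames set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dependency_csv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste0(",", paste(sprintf("%s (%d)", colnames(mat), seq_len(ncol(mat))),
                              collapse = ","))
  body <- vapply(seq_len(nrow(mat)), function(i) {
    vals <- ifelse(is.na(mat[i, ]), "", num_chr_na(mat[i, ]))
    paste0(rownames(mat)[i], ",", paste(vals, collapse = ","))
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

num_chr_na <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v) format(v, scientific = FALSE, trim = TRUE,
                                              digits = 15), character(1))
  out
}

#' Read cell-line lineage annotations
#'
#' @param path CSV with columns `cell_line`, `lineage`; every cell line maps
#'   to exactly one lineage.
#' @return A `data.frame` with those two character columns.
#' @export
read_lineage_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("cell_line", "lineage")
  if (!all(req %in% names(df))) stop("annotation CSV must have columns cell_line, lineage")
  if (anyDuplicated(df$cell_line)) stop("a cell line maps to more than one lineage")
  df[, req]
}

#' Read a DepMap-dialect mutation table
#'
#' @param path CSV with columns `cell_line`, `gene`, `variant_classification`
#'   and logical flags `is_deleterious`, `is_tcga_hotspot`,
#'   `is_cosmic_hotspot`.
#' @return A `data.frame`, one row per mutation call.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_line", "gene", "variant_classification",
           "is_deleterious", "is_tcga_hotspot", "is_cosmic_hotspot")
  if (!all(req %in% names(df)))
    stop("mutation CSV missing columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  for (fl in c("is_deleterious", "is_tcga_hotspot", "is_cosmic_hotspot"))
    df[[fl]] <- as.logical(df[[fl]])
  df[, req]
}

#' Read a transcription-factor gene list
#' @param path plain-text file, one gene symbol per line.
#' @return Character vector of unique symbols.
#' @export
read_tf_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read a gene model table with differential-expression labels
#'
#' @param path TSV with header and columns `gene_id`, `chrom`, `tss`,
#'   `strand`, `de_status` (`up`, `down`, `unchanged`, `not_expressed`),
#'   `log2fc`, `padj` (empty when not tested).
#' @return A `data.frame` with typed columns.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("gene_id", "chrom", "tss", "strand", "de_status", "log2fc", "padj")
  if (!all(req %in% names(df)))
    stop("gene table missing columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  ok <- df$de_status %in% c("up", "down", "unchanged", "not_expressed")
  if (!all(ok)) stop("invalid de_status: ", df$de_status[!ok][1])
  bad_up <- df$de_status == "up" & !is.na(df$log2fc) & df$log2fc <= 0
  if (any(bad_up)) stop("de_status 'up' with non-positive log2fc: ", df$gene_id[bad_up][1])
  df$tss <- as.integer(df$tss)
  df[, req]
}

#' Write a gene model table
#' @param genes gene `data.frame` as produced by the simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
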