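#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults are the published cutoffs of the analysis this package
#' implements; each consuming function also exposes the relevant threshold
#' as an argument so the config is a convenience, not a requirement.
#'
#' @param ld_cutoff LD-score cutoff for filter 1 (dimensionless CERES
#'   difference; dependencies are negative). Default -1.2.
#' @param ld_p_cutoff significance cutoff for filter 1. Default 0.05.
#' @param min_lineage_size minimum number of cell lines for a lineage to be
#'   scored. Default 10.
#' @param strong_dep_ceres CERES value at or below which a line counts as a
#'   strong dependency for filter 2. Default -0.5.
#' @param strong_dep_fraction fraction of in-lineage lines that must be
#'   strong dependencies (strictly exceeded) for filter 2. Default 0.5.
#' @param pan_essential_median pan-essential cutoff for filter 3: TFs whose
#'   median CERES across all lines is at or below this are removed.
#'   Default -0.2.
#' @param resistance_cutoff average CERES above which a line is called
#'   lineage-factor resistant. Default -0.45.
#' @param n_permutations label permutations for the acquired-dependency
#'   FDR. Default 1000.
#' @param q_threshold q-value cutoff for calling acquired dependencies.
#'   Default 0.1.
#' @param consensus_width fixed consensus peak width in bases (odd).
#'   Default 501.
#' @param peak_q_filter -log10(q) threshold for peak filtering. Default 20.
#' @param read_extension length in bases to which reads are extended from
#'   their 5' end. Default 250.
#' @param da_fc fold-change threshold (linear scale) for differential
#'   accessibility. Default 2.
#' @param da_padj adjusted-p threshold for differential accessibility.
#'   Default 0.001.
#' @param pcc_threshold Pearson correlation above which two accessibility
#'   profiles count as correlated. Default 0.6.
#' @param top_variable_regions number of most-variable regions used for
#'   profile correlation. Default 250000.
#' @param min_cluster_size greedy clustering stop rule: the loop halts when
#'   a candidate cluster is smaller than this. Default 5.
#' @param presence_fraction fraction of cluster samples in which a region
#'   must be open to be "present" in the cluster. Default 0.8.
#' @param max_additional_clusters maximum number of other clusters a
#'   cluster-specific region may be present in. Default 2.
#' @param summit_flank half-width in bases of the summit window used for
#'   overlap enrichment. Default 25.
#' @param window_sizes half-widths in bases of the sequentially larger
#'   windows for accessibility-expression coupling; strictly increasing.
#' @param rng_seed integer seed from which all stochastic operations derive
#'   their sub-streams.
#' @return A list of class `ld_config`.
#' @examples
#' cfg <- ld_config(n_permutations = 100)
#' cfg$ld_cutoff
#' @export
ld_config <- function(ld_cutoff = -1.2,
                      ld_p_cutoff = 0.05,
                      min_lineage_size = 10L,
                      strong_dep_ceres = -0.5,
                      strong_dep_fraction = 0.5,
                      pan_essential_median = -0.2,
                      resistance_cutoff = -0.45,
                      n_permutations = 1000L,
                      q_threshold = 0.1,
                      consensus_width = 501L,
                      peak_q_filter = 20,
                      read_extension = 250L,
                      da_fc = 2,
                      da_padj = 0.001,
                      pcc_threshold = 0.6,
                      top_variable_regions = 250000L,
                      min_cluster_size = 5L,
                      presence_fraction = 0.8,
                      max_additional_clusters = 2L,
                      summit_flank = 25L,
                      window_sizes = c(5e3, 1e4, 2.5e4, 5e4, 1e5, 2.5e5, 5e5, 1e6),
                      rng_seed = 1L) {
  cfg <- list(
    ld_cutoff = ld_cutoff, ld_p_cutoff = ld_p_cutoff,
    min_lineage_size = as.integer(min_lineage_size),
    strong_dep_ceres = strong_dep_ceres,
    strong_dep_fraction = strong_dep_fraction,
    pan_essential_median = pan_essential_median,
    resistance_cutoff = resistance_cutoff,
    n_permutations = as.integer(n_permutations),
    q_threshold = q_threshold,
    consensus_width = as.integer(consensus_width),
    peak_q_filter = peak_q_filter,
    read_extension = as.integer(read_extension),
    da_fc = da_fc, da_padj = da_padj,
    pcc_threshold = pcc_threshold,
    top_variable_regions = as.integer(top_variable_regions),
    min_cluster_size = as.integer(min_cluster_size),
    presence_fraction = presence_fraction,
    max_additional_clusters = as.integer(max_additional_clusters),
    summit_flank = as.integer(summit_flank),
    window_sizes = as.numeric(window_sizes),
    rng_seed = as.integer(rng_seed)
  )
  num <- cfg[!names(cfg) %in% "window_sizes"]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all config thresholds must be finite scalars")
  ws <- cfg$window_sizes
  if (length(ws) == 0 || any(ws <= 0) || any(diff(ws) <= 0) || any(ws != round(ws)))
    stop("window_sizes must be strictly increasing positive integers")
  if (cfg$consensus_width %% 2L != 1L)
    stop("consensus_width must be odd (symmetric around the summit)")
  structure(cfg, class = "ld_config")
}

#' @export
print.ld_config <- function(x, ...) {
  cat("lineagedep pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(val, trim = TRUE), collapse = " ")))
  }
  invisible(x)
}

# Stable sub-seed: stochastic operations draw from streams derived from the
# master seed by label, so adding an operation does not perturb the others.
# Constraint: result must stay below 2^31 (R integers are 32-bit).
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate expr with a temporary RNG state seeded by (seed, label); restores
# the caller's RNG state afterwards.
with_sub_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, label))
  expr
}
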