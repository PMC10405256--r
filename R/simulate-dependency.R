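#' Parameters for the dependency-bundle simulator
#'
#' Defaults define the simulated study conditions: Gaussian background noise
#' well below the planted effects, a lineage-dependency shift matching a
#' strong lineage-specific TF, a pan-essential mean at the essential-gene
#' scale, and a resistant-line fraction and mutation contrast shaped like
#' the melanoma cohort the analysis is designed around.
#'
#' @param sigma background CERES noise SD. Default 0.15.
#' @param delta_ld in-lineage mean shift of planted LD TFs (sensitive lines
#'   only). Default -1.5.
#' @param pan_essential_mean mean CERES of pan-essential genes in every
#'   line. Default -1.0.
#' @param resistant_fraction fraction of each LD lineage's lines that are
#'   resistant. Default 0.3.
#' @param acquired_shift mean shift of acquired-dependency genes in
#'   resistant lines only. Default -0.8.
#' @param n_ld_lineages lineages that receive a planted LD TF. Default:
#'   all.
#' @param ld_tfs_per_lineage planted LD TFs per such lineage. Default 1.
#' @param n_pan_essential pan-essential decoy genes; each also gets the LD
#'   shift in one lineage so it reaches the pan-essential filter. Default 2.
#' @param n_acquired_per_lineage acquired-dependency genes per LD lineage.
#'   Default 1.
#' @param n_mutation_genes_per_lineage genes with resistant-enriched
#'   mutations per LD lineage. Default 1.
#' @param mutation_p_resistant,mutation_p_sensitive mutation probabilities
#'   in resistant / sensitive lines. Defaults 0.47 / 0.28.
#' @param plant_ccle also plant VHL/SMARCB1/ARID1A mutation classes and
#'   hotspot flags. Default TRUE.
#' @return Named list of parameters.
#' @export
dependency_sim_params <- function(sigma = 0.15, delta_ld = -1.5,
                                  pan_essential_mean = -1.0,
                                  resistant_fraction = 0.3,
                                  acquired_shift = -0.8,
                                  n_ld_lineages = NULL,
                                  ld_tfs_per_lineage = 1L,
                                  n_pan_essential = 2L,
                                  n_acquired_per_lineage = 1L,
                                  n_mutation_genes_per_lineage = 1L,
                                  mutation_p_resistant = 0.47,
                                  mutation_p_sensitive = 0.28,
                                  plant_ccle = TRUE) {
  list(sigma = sigma, delta_ld = delta_ld,
       pan_essential_mean = pan_essential_mean,
       resistant_fraction = resistant_fraction,
       acquired_shift = acquired_shift,
       n_ld_lineages = n_ld_lineages,
       ld_tfs_per_lineage = as.integer(ld_tfs_per_lineage),
       n_pan_essential = as.integer(n_pan_essential),
       n_acquired_per_lineage = as.integer(n_acquired_per_lineage),
       n_mutation_genes_per_lineage = as.integer(n_mutation_genes_per_lineage),
       mutation_p_resistant = mutation_p_resistant,
       mutation_p_sensitive = mutation_p_sensitive,
       plant_ccle = plant_ccle)
}

#' Simulate a CRISPR dependency bundle with planted ground truth
#'
#' Emulates the four dependency inputs of the pipeline: a CERES gene-effect
#' matrix (background `Normal(0, sigma)` plus planted shifts), lineage
#' annotations, a TF list, and a mutation table. Planted structure:
#' \itemize{
#'   \item LD TFs: sensitive lines of their lineage shift by `delta_ld`;
#'     resistant lines stay at background;
#'   \item pan-essential decoys: mean `pan_essential_mean` in every line,
#'     plus the LD shift in one lineage, so they pass the effect filter but
#'     fail the pan-essential filter;
#'   \item acquired dependencies: non-TF genes shifted by `acquired_shift`
#'     in resistant lines only;
#'   \item mutation enrichment: Bernoulli mutations at
#'     `mutation_p_resistant` / `mutation_p_sensitive`.
#' }
#'
#' @param n_lineages number of lineages. Default 25.
#' @param lines_per_lineage cell lines per lineage. Default 20.
#' @param n_genes total genes (columns). Default 2000.
#' @param n_tfs genes flagged as TFs (must be <= `n_genes`). Default 1600.
#' @param params a [dependency_sim_params()] list.
#' @param seed integer seed; the bundle is a pure function of (params,
#'   seed).
#' @return List with `bundle` (list `ceres`, `annotations`, `tf_list`,
#'   `mutations`) and `truth` (class `dependency_ground_truth`).
#' @export
generate_dependency_bundle <- function(n_lineages = 25L, lines_per_lineage = 20L,
                                       n_genes = 2000L, n_tfs = 1600L,
                                       params = dependency_sim_params(),
                                       seed = 1L) {
  if (n_tfs > n_genes) stop("n_tfs must not exceed n_genes")
  n_ld <- if (is.null(params$n_ld_lineages)) n_lineages else params$n_ld_lineages
  if (n_ld > n_lineages) stop("n_ld_lineages exceeds n_lineages")
  n_resistant <- round(params$resistant_fraction * lines_per_lineage)
  if (params$n_acquired_per_lineage > 0 && n_ld > 0 && n_resistant < 1)
    stop("acquired-dependency genes requested but resistant_fraction * lines_per_lineage < 1")

  lineages <- sprintf("tissue%02d_subtype", seq_len(n_lineages))
  lines <- sprintf("ACH-%06d", seq_len(n_lineages * lines_per_lineage))
  lineage_of <- rep(lineages, each = lines_per_lineage)
  tf_list <- sprintf("TF%04d", seq_len(n_tfs))
  extra <- c("VHL", "SMARCB1", "ARID1A")
  n_other <- n_genes - n_tfs
  if (params$plant_ccle && n_other < length(extra))
    stop("need at least 3 non-TF genes to plant CCLE mutation columns")
  others <- if (n_other > 0) c(extra[seq_len(min(length(extra), n_other))],
                               sprintf("G%04d", seq_len(max(0, n_other - length(extra)))))
            else character(0)
  genes <- c(tf_list, others)

  ceres <- with_sub_seed(seed, "dependency_background", {
    matrix(stats::rnorm(length(lines) * n_genes, 0, params$sigma),
           nrow = length(lines), ncol = n_genes,
           dimnames = list(lines, genes))
  })

  # deterministic assignment of planted genes (no draw needed)
  ld_lineages <- lineages[seq_len(n_ld)]
  planted_ld <- list(); resistant_lines <- list()
  acquired <- list(); mut_genes <- list()
  tf_pool <- tf_list
  pan_genes <- character(0)
  if (params$n_pan_essential > 0) {
    pan_genes <- tf_pool[seq_len(params$n_pan_essential)]
    tf_pool <- setdiff(tf_pool, pan_genes)
    ceres[, pan_genes] <- ceres[, pan_genes] + params$pan_essential_mean
    # decoy shift: each pan gene is extra-depleted in one lineage
    for (i in seq_along(pan_genes)) {
      lin <- lineages[((i - 1L) %% n_lineages) + 1L]
      in_lin <- lineage_of == lin
      ceres[in_lin, pan_genes[i]] <- ceres[in_lin, pan_genes[i]] + params$delta_ld
    }
  }
  other_pool <- setdiff(others, extra)
  if (length(other_pool) < n_ld * (params$n_acquired_per_lineage +
                                   params$n_mutation_genes_per_lineage))
    stop("not enough non-TF genes for the requested acquired/mutation plants")

  with_sub_seed(seed, "dependency_planting", {
    for (lin in ld_lineages) {
      in_lin <- which(lineage_of == lin)
      res_idx <- if (n_resistant > 0) sort(sample(in_lin, n_resistant)) else integer(0)
      sens_idx <- setdiff(in_lin, res_idx)
      resistant_lines[[lin]] <- lines[res_idx]

      tfs <- tf_pool[seq_len(params$ld_tfs_per_lineage)]
      tf_pool <- setdiff(tf_pool, tfs)
      ceres[sens_idx, tfs] <- ceres[sens_idx, tfs] + params$delta_ld
      planted_ld[[lin]] <- data.frame(tf = tfs, shift = params$delta_ld,
                                       stringsAsFactors = FALSE)

      if (params$n_acquired_per_lineage > 0) {
        ag <- other_pool[seq_len(params$n_acquired_per_lineage)]
        other_pool <- setdiff(other_pool, ag)
        ceres[res_idx, ag] <- ceres[res_idx, ag] + params$acquired_shift
        acquired[[lin]] <- data.frame(gene = ag, shift = params$acquired_shift,
                                       stringsAsFactors = FALSE)
      }
      if (params$n_mutation_genes_per_lineage > 0) {
        mg <- other_pool[seq_len(params$n_mutation_genes_per_lineage)]
        other_pool <- setdiff(other_pool, mg)
        mut_genes[[lin]] <- data.frame(gene = mg,
                                        p_resistant = params$mutation_p_resistant,
                                        p_sensitive = params$mutation_p_sensitive,
                                        stringsAsFactors = FALSE)
      }
    }
  })

  mutations <- with_sub_seed(seed, "dependency_mutations", {
    rows <- list()
    for (lin in names(mut_genes)) {
      in_lin <- lines[lineage_of == lin]
      is_res <- in_lin %in% resistant_lines[[lin]]
      for (g in mut_genes[[lin]]$gene) {
        p <- ifelse(is_res, params$mutation_p_resistant, params$mutation_p_sensitive)
        hit <- stats::runif(length(in_lin)) < p
        if (any(hit))
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = in_lin[hit], gene = g,
            variant_classification = "damaging",
            is_deleterious = TRUE, is_tcga_hotspot = FALSE,
            is_cosmic_hotspot = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (params$plant_ccle) {
      classes <- c("damaging", "other non-conserving", "other conserving", "silent")
      for (g in extra) {
        hit <- stats::runif(length(lines)) < 0.3
        if (any(hit)) {
          cls <- sample(classes, sum(hit), replace = TRUE,
                        prob = c(0.35, 0.25, 0.2, 0.2))
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = lines[hit], gene = g,
            variant_classification = cls,
            is_deleterious = cls == "damaging",
            is_tcga_hotspot = stats::runif(sum(hit)) < 0.15,
            is_cosmic_hotspot = stats::runif(sum(hit)) < 0.15,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0)
      data.frame(cell_line = character(0), gene = character(0),
                 variant_classification = character(0),
                 is_deleterious = logical(0), is_tcga_hotspot = logical(0),
                 is_cosmic_hotspot = logical(0))
    else do.call(rbind, rows)
  })
  rownames(mutations) <- NULL

  truth <- structure(list(
    planted_ld = planted_ld,
    pan_essential_genes = pan_genes,
    resistant_lines = resistant_lines,
    acquired_dep_genes = acquired,
    enriched_mutation_genes = mut_genes
  ), class = "dependency_ground_truth")

  list(bundle = list(
         ceres = ceres,
         annotations = data.frame(cell_line = lines, lineage = lineage_of,
                                  stringsAsFactors = FALSE),
         tf_list = tf_list,
         mutations = mutations),
       truth = truth)
}

#' Write a dependency bundle to disk in the pipeline's input formats
#'
#' @param sim result of [generate_dependency_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly. Writes `ceres.csv` (DepMap dialect),
#'   `annotations.csv`, `tfs.txt`, `mutations.csv`,
#'   `ground_truth_dependency.json`.
#' @export
write_dependency_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dependency_csv(sim$bundle$ceres, file.path(dir, "ceres.csv"))
  utils::write.csv(sim$bundle$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(sim$bundle$tf_list, file.path(dir, "tfs.txt"))
  utils::write.csv(sim$bundle$mutations, file.path(dir, "mutations.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(sim$truth),
                       file.path(dir, "ground_truth_dependency.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
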