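#' Parameters for the regulatory-bundle simulator
#'
#' @param overlap_pair_fraction fraction of peaks turned into deliberately
#'   overlapping pairs (each pair gets one extra peak whose 501 bp summit
#'   window overlaps the base peak's), exercising consensus de-overlap.
#'   Default 0.2.
#' @param read_dispersion SD in bases of read scatter around open-peak
#'   summits. Default 80.
#' @param read_length simulated read length in bases. Default 50.
#' @param da_la_fraction,da_ha_fraction fractions of peaks planted as lower
#'   / higher accessibility. Defaults 0.15 / 0.05 (about the 3:1 LA:HA
#'   shape of a strong chromatin perturbation).
#' @param de_da_coupling odds multiplier for a gene near a DA peak to be
#'   differentially expressed in the concordant direction; 1 = no coupling
#'   (null). Default 5.
#' @param coupling_window distance in bases within which a TSS counts as
#'   near a DA peak. Default 50000.
#' @param expressed_fraction fraction of genes in the expressed universe.
#'   Default 0.8.
#' @param de_base_rate baseline probability that an expressed gene is DE in
#'   a given direction, before coupling. Default 0.1.
#' @param n_profile_regions regions in the binary accessibility matrix.
#'   Default 2000.
#' @param backbone_fraction fraction of profile regions open in every
#'   sample. Default 0.3.
#' @param specific_regions_per_cluster planted cluster-specific regions.
#'   Default 100.
#' @param flip_noise probability that any profile bit is flipped. Default
#'   0.02.
#' @return Named list of parameters.
#' @export
regulatory_sim_params <- function(overlap_pair_fraction = 0.2,
                                  read_dispersion = 80,
                                  read_length = 50L,
                                  da_la_fraction = 0.15,
                                  da_ha_fraction = 0.05,
                                  de_da_coupling = 5,
                                  coupling_window = 50000L,
                                  expressed_fraction = 0.8,
                                  de_base_rate = 0.1,
                                  n_profile_regions = 2000L,
                                  backbone_fraction = 0.3,
                                  specific_regions_per_cluster = 100L,
                                  flip_noise = 0.02) {
  list(overlap_pair_fraction = overlap_pair_fraction,
       read_dispersion = read_dispersion,
       read_length = as.integer(read_length),
       da_la_fraction = da_la_fraction, da_ha_fraction = da_ha_fraction,
       de_da_coupling = de_da_coupling,
       coupling_window = as.integer(coupling_window),
       expressed_fraction = expressed_fraction,
       de_base_rate = de_base_rate,
       n_profile_regions = as.integer(n_profile_regions),
       backbone_fraction = backbone_fraction,
       specific_regions_per_cluster = as.integer(specific_regions_per_cluster),
       flip_noise = flip_noise)
}

default_genome <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(5e6, 5e6),
             stringsAsFactors = FALSE)
}

#' Simulate a regulatory (chromatin) bundle with planted ground truth
#'
#' Emulates the four chromatin inputs: narrowPeak-style peak calls with
#' summits and heavy-tailed -log10(q) scores (including planted overlapping
#' pairs), BED6 reads scattered around open-peak summits, a gene model table
#' whose DE labels are coupled to DA-peak proximity by logistic odds, and a
#' binary regions x samples accessibility matrix with block-structured
#' clusters (shared backbone + cluster-specific regions + flip noise).
#'
#' @param genome `data.frame` with columns `chrom`, `length`.
#' @param n_peaks number of base peaks before pair planting. Default 400.
#' @param n_reads simulated reads. Default 5000.
#' @param n_genes genes in the gene model. Default 600.
#' @param n_samples accessibility profile samples. Default 60.
#' @param n_clusters planted sample clusters. Default 6.
#' @param params a [regulatory_sim_params()] list.
#' @param seed integer seed; the bundle is a pure function of (params,
#'   seed).
#' @return List with `bundle` (list `peaks`, `differential_table`, `reads`,
#'   `genes`, `profiles`) and `truth` (class `regulatory_ground_truth` with
#'   `true_clusters`, `true_specific_regions`, `da_truth`,
#'   `de_da_coupling`, `overlapping_pairs`).
#' @export
generate_regulatory_bundle <- function(genome = default_genome(),
                                       n_peaks = 400L, n_reads = 5000L,
                                       n_genes = 600L, n_samples = 60L,
                                       n_clusters = 6L,
                                       params = regulatory_sim_params(),
                                       seed = 1L) {
  margin <- 2000L
  if (any(genome$length < 2L * margin))
    stop("genome too small to place peaks without exceeding bounds")
  per_chrom_cap <- sum(floor((genome$length - 2 * margin) / 1500))
  if (n_peaks > per_chrom_cap)
    stop("genome too small to place the requested number of peaks")

  n_pairs <- round(params$overlap_pair_fraction * n_peaks)

  peaks <- with_sub_seed(seed, "regulatory_peaks", {
    # spread base summits over chromosomes proportionally to length, on a
    # jittered grid so base peaks never collide by construction
    n_per <- round(n_peaks * genome$length / sum(genome$length))
    n_per[length(n_per)] <- n_peaks - sum(n_per[-length(n_per)])
    rows <- list()
    for (ci in seq_len(nrow(genome))) {
      if (n_per[ci] == 0) next
      slots <- seq(margin, genome$length[ci] - margin, length.out = n_per[ci])
      summit <- as.integer(round(slots + stats::runif(n_per[ci], -200, 200)))
      rows[[ci]] <- data.frame(chrom = genome$chrom[ci], summit = summit,
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    df$qvalue <- round(stats::rlnorm(nrow(df), meanlog = log(15), sdlog = 1), 4)
    df
  })

  pair_truth <- data.frame(base = character(0), partner = character(0))
  if (n_pairs > 0) {
    if (2L * n_pairs > n_peaks)
      stop("overlap_pair_fraction too high: need 2 partners per pair from the base set")
    partners <- with_sub_seed(seed, "regulatory_pairs", {
      base_idx <- seq_len(n_pairs)   # deterministic choice; offsets random
      off <- sample(50:400, n_pairs, replace = TRUE)
      data.frame(base_idx = base_idx,
                 summit = peaks$summit[base_idx] + off,
                 chrom = peaks$chrom[base_idx],
                 qvalue = round(stats::rlnorm(n_pairs, log(15), 1), 4),
                 stringsAsFactors = FALSE)
    })
    pair_peaks <- data.frame(chrom = partners$chrom, summit = partners$summit,
                             qvalue = partners$qvalue, stringsAsFactors = FALSE)
    pair_truth <- data.frame(base = sprintf("peak_%05d", partners$base_idx),
                             partner = sprintf("peak_%05d", nrow(peaks) + seq_len(n_pairs)),
                             stringsAsFactors = FALSE)
    peaks <- rbind(peaks, pair_peaks)
  }
  peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  peaks$start <- peaks$summit - 300L
  peaks$end <- peaks$summit + 300L
  peaks$score <- as.integer(pmin(1000, round(peaks$qvalue * 10)))
  peaks$strand <- "."
  peaks$signal <- round(peaks$qvalue / 3, 4)
  peaks$pvalue <- round(peaks$qvalue + 2, 4)
  peaks <- peaks[, c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "pvalue", "qvalue", "summit")]

  # planted DA labels and a differential table the DA caller consumes
  da_truth <- with_sub_seed(seed, "regulatory_da", {
    lab <- rep("none", nrow(peaks))
    n_la <- round(params$da_la_fraction * nrow(peaks))
    n_ha <- round(params$da_ha_fraction * nrow(peaks))
    pick <- sample.int(nrow(peaks), n_la + n_ha)
    lab[pick[seq_len(n_la)]] <- "LA"
    lab[pick[n_la + seq_len(n_ha)]] <- "HA"
    lab
  })
  differential_table <- with_sub_seed(seed, "regulatory_differential", {
    lfc <- stats::rnorm(nrow(peaks), 0, 0.3)
    padj <- stats::runif(nrow(peaks), 0.01, 1)
    la <- da_truth == "LA"; ha <- da_truth == "HA"
    lfc[la] <- -(1 + stats::rexp(sum(la), 1))
    lfc[ha] <- 1 + stats::rexp(sum(ha), 1)
    padj[la | ha] <- stats::runif(sum(la | ha), 0, 1e-4)
    data.frame(name = peaks$name, log2fc = round(lfc, 4),
               padj = signif(padj, 4), stringsAsFactors = FALSE)
  })

  reads <- with_sub_seed(seed, "regulatory_reads", {
    open_idx <- which(da_truth != "LA")   # LA peaks are closed in this state
    src <- sample(open_idx, n_reads, replace = TRUE)
    pos <- peaks$summit[src] +
      as.integer(round(stats::rnorm(n_reads, 0, params$read_dispersion)))
    chrom_len <- genome$length[match(peaks$chrom[src], genome$chrom)]
    start <- pmax(0L, pmin(pos, chrom_len - params$read_length))
    data.frame(chrom = peaks$chrom[src], start = start,
               end = start + params$read_length,
               name = sprintf("read_%06d", seq_len(n_reads)),
               score = 0,
               strand = sample(c("+", "-"), n_reads, replace = TRUE),
               stringsAsFactors = FALSE)
  })

  genes <- with_sub_seed(seed, "regulatory_genes", {
    chrom <- sample(genome$chrom, n_genes, replace = TRUE,
                    prob = genome$length / sum(genome$length))
    tss <- as.integer(floor(stats::runif(n_genes, 0, genome$length[match(chrom, genome$chrom)])))
    expressed <- stats::runif(n_genes) < params$expressed_fraction

    near_da <- function(cls) {
      idx <- which(da_truth == cls)
      if (length(idx) == 0) return(rep(FALSE, n_genes))
      near <- rep(FALSE, n_genes)
      for (ci in unique(chrom)) {
        s <- peaks$summit[idx][peaks$chrom[idx] == ci]
        g <- which(chrom == ci)
        if (length(s) == 0 || length(g) == 0) next
        d <- vapply(tss[g], function(t) min(abs(s - t)), numeric(1))
        near[g] <- d <= params$coupling_window
      }
      near
    }
    near_la <- near_da("LA"); near_ha <- near_da("HA")

    base_odds <- params$de_base_rate / (1 - params$de_base_rate)
    p_from_odds <- function(mult) {
      o <- base_odds * mult
      o / (1 + o)
    }
    p_down <- ifelse(near_la, p_from_odds(params$de_da_coupling), params$de_base_rate)
    p_up <- ifelse(near_ha, p_from_odds(params$de_da_coupling), params$de_base_rate)

    status <- rep("not_expressed", n_genes)
    u <- stats::runif(n_genes)
    for (i in which(expressed)) {
      status[i] <- if (u[i] < p_down[i]) "down"
                   else if (u[i] < p_down[i] + p_up[i]) "up"
                   else "unchanged"
    }
    log2fc <- rep(NA_real_, n_genes)
    padj <- rep(NA_real_, n_genes)
    ex <- which(expressed)
    log2fc[ex] <- round(stats::rnorm(length(ex), 0, 0.2), 4)
    padj[ex] <- round(stats::runif(length(ex), 0.05, 1), 4)
    dn <- status == "down"; up <- status == "up"
    log2fc[dn] <- round(-(0.8 + stats::rexp(sum(dn), 1)), 4)
    log2fc[up] <- round(0.8 + stats::rexp(sum(up), 1), 4)
    padj[dn | up] <- signif(stats::runif(sum(dn | up), 0, 0.04), 4)
    data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
               chrom = chrom, tss = tss, strand = sample(c("+", "-"), n_genes, TRUE),
               de_status = status, log2fc = log2fc, padj = padj,
               stringsAsFactors = FALSE)
  })

  # binary accessibility profiles with planted block structure
  samples <- sprintf("sample_%03d", seq_len(n_samples))
  cluster_of <- rep(seq_len(n_clusters), length.out = n_samples)
  cluster_of <- sort(cluster_of)
  true_clusters <- split(samples, paste0("cluster_", cluster_of))
  nr <- params$n_profile_regions
  n_backbone <- round(params$backbone_fraction * nr)
  n_spec <- params$specific_regions_per_cluster
  if (n_backbone + n_clusters * n_spec > nr)
    stop("n_profile_regions too small for backbone plus cluster-specific regions")
  spec_idx <- lapply(seq_len(n_clusters), function(k)
    n_backbone + (k - 1L) * n_spec + seq_len(n_spec))
  names(spec_idx) <- paste0("cluster_", seq_len(n_clusters))

  values <- matrix(0L, nr, n_samples, dimnames = list(NULL, samples))
  values[seq_len(n_backbone), ] <- 1L
  for (k in seq_len(n_clusters))
    values[spec_idx[[k]], cluster_of == k] <- 1L
  values <- with_sub_seed(seed, "regulatory_profiles", {
    flip <- matrix(stats::runif(length(values)) < params$flip_noise,
                   nrow(values), ncol(values))
    out <- values
    out[flip] <- 1L - out[flip]
    out
  })
  profile_regions <- data.frame(
    chrom = genome$chrom[1 + (seq_len(nr) - 1L) %% nrow(genome)],
    start = 1000L + 600L * (seq_len(nr) - 1L),
    end = 1000L + 600L * (seq_len(nr) - 1L) + 500L,
    stringsAsFactors = FALSE)
  profiles <- profile_matrix(profile_regions, values)

  truth <- structure(list(
    true_clusters = true_clusters,
    true_specific_regions = spec_idx,
    da_truth = stats::setNames(da_truth, peaks$name),
    de_da_coupling = params$de_da_coupling,
    overlapping_pairs = pair_truth
  ), class = "regulatory_ground_truth")

  list(bundle = list(peaks = peaks, differential_table = differential_table,
                     reads = reads, genes = genes, profiles = profiles),
       truth = truth)
}

#' Write a regulatory bundle to disk in the pipeline's input formats
#'
#' @param sim result of [generate_regulatory_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly. Writes `peaks.narrowPeak`, `reads.bed`,
#'   `genes.tsv`, `differential_table.tsv`, `profile_regions.bed`,
#'   `profiles.tsv`, `ground_truth_regulatory.json`.
#' @export
write_regulatory_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_narrowpeak(sim$bundle$peaks, file.path(dir, "peaks.narrowPeak"))
  write_bed6(sim$bundle$reads, file.path(dir, "reads.bed"))
  write_gene_table(sim$bundle$genes, file.path(dir, "genes.tsv"))
  utils::write.table(sim$bundle$differential_table,
                     file.path(dir, "differential_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- sim$bundle$profiles$regions
  reg$name <- sprintf("region_%05d", seq_len(nrow(reg)))
  reg$score <- 0; reg$strand <- "."
  write_bed6(reg, file.path(dir, "profile_regions.bed"))
  utils::write.table(sim$bundle$profiles$values, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth),
                       file.path(dir, "ground_truth_regulatory.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
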