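# Synthetic-data generators emulating the two-cohort renal tumor study
# design: 15 chRCC + 15 oncocytoma tumor expression profiles against a
# 12-sample normal kidney reference, probes on a miniature genome with
# cytoband annotation, class-specific arm-level expression biases, and an
# independent 6 + 8 sample SNP copy-number cohort with injected segments.
# Every generator returns a truth ledger for parameter-recovery tests.
#
# Stream splitting: one seed governs a run; simulate_expression seeds the
# RNG at `seed`, simulate_cn at `seed + 1`, simulate_contingency at
# `seed + 2`, so the three generators draw from disjoint, reproducible
# streams under a single pipeline seed.

#' Default per-arm expression bias specification
#'
#' Encodes the qualitative cytogenetic profile of the two tumor classes:
#' chRCC loses whole chromosomes 1, 2, 6, 10, 13, 17 and 21; oncocytoma
#' loses only the distal (terminal) portion of 1p.
#'
#' @param shift Log2 shift applied to biased arms (negative = loss).
#' @param distal_fraction Terminal fraction of an arm's probes, by position,
#'   taken as "distal" (telomeric end).
#' @return Data frame with columns `class`, `chromosome`, `arm`
#'   (`"p"`, `"q"` or `"both"`), `fraction`, `shift`.
#' @export
default_arm_biases <- function(shift = -1.0, distal_fraction = 0.3) {
  loss_chr <- c("1", "2", "6", "10", "13", "17", "21")
  rbind(
    data.frame(class = "chRCC", chromosome = loss_chr, arm = "both",
               fraction = 1, shift = shift, stringsAsFactors = FALSE),
    data.frame(class = "oncocytoma", chromosome = "1", arm = "p",
               fraction = distal_fraction, shift = shift,
               stringsAsFactors = FALSE)
  )
}

#' Default injected copy-number segments
#'
#' chRCC: whole-chromosome losses (CN ~ 1.0) on chromosomes 1, 2, 6, 10, 13,
#' 17, 21. Oncocytoma: loss restricted to distal 1p. `fraction` is the
#' penetrance (fraction of cohort samples carrying the segment).
#'
#' @param cn_mean,cn_sd Segment copy-number mean and SD.
#' @param fraction Fraction of cohort samples carrying each segment.
#' @param distal_fraction Fraction of the chromosome taken as distal 1p.
#' @return Data frame with columns `cohort`, `chromosome`, `start_frac`,
#'   `end_frac` (fractions of the chromosome span), `cn_mean`, `cn_sd`,
#'   `fraction`, `type`.
#' @export
default_cn_segments <- function(cn_mean = 1.0, cn_sd = 0.15, fraction = 0.8,
                                distal_fraction = 0.15) {
  loss_chr <- c("1", "2", "6", "10", "13", "17", "21")
  rbind(
    data.frame(cohort = "chRCC", chromosome = loss_chr, start_frac = 0,
               end_frac = 1, cn_mean = cn_mean, cn_sd = cn_sd,
               fraction = fraction, type = "loss", stringsAsFactors = FALSE),
    data.frame(cohort = "oncocytoma", chromosome = "1", start_frac = 0,
               end_frac = distal_fraction, cn_mean = cn_mean, cn_sd = cn_sd,
               fraction = fraction, type = "loss", stringsAsFactors = FALSE)
  )
}

#' Simulation configuration
#'
#' Desk-scale defaults: 2,000 probes over ~1,000 genes on a miniature genome
#' (22 autosomes + X, two arms each, 4 cytobands per arm), 15 + 15 tumors,
#' 12 normals, 20 discriminative probes at log2 effect 2.0, i.i.d. Gaussian
#' noise (sd 0.5) on the log2 scale; 200 SNPs per chromosome, 6 chRCC + 8
#' oncocytoma CN samples with background CN ~ Normal(2, 0.3).
#'
#' @param n_probes,n_genes Probe and gene counts.
#' @param n_per_class Named vector of tumor sample counts per class.
#' @param n_normals Normal reference sample count.
#' @param n_discriminative Number of class-discriminative probes.
#' @param effect_size Log2 effect added (with alternating sign) to
#'   discriminative probes in the chRCC class.
#' @param arm_biases Data frame as from [default_arm_biases()]; `NULL`
#'   disables arm biases.
#' @param noise_sd Log2-scale Gaussian noise SD.
#' @param baseline_mean,baseline_sd Probe baseline log2 intensity
#'   distribution.
#' @param snps_per_chromosome SNPs simulated per chromosome.
#' @param cn_cohorts Named vector of CN cohort sizes.
#' @param cn_background_sd SD of the diploid background CN.
#' @param cn_segments Data frame as from [default_cn_segments()]; `NULL`
#'   disables injection.
#' @param chromosome_length Simulated chromosome length in base pairs
#'   (arms split at the midpoint).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_probes = 2000, n_genes = 1000,
                              n_per_class = c(chRCC = 15, oncocytoma = 15),
                              n_normals = 12,
                              n_discriminative = 20, effect_size = 2.0,
                              arm_biases = default_arm_biases(),
                              noise_sd = 0.5,
                              baseline_mean = 8, baseline_sd = 1.5,
                              snps_per_chromosome = 200,
                              cn_cohorts = c(chRCC = 6, oncocytoma = 8),
                              cn_background_sd = 0.3,
                              cn_segments = default_cn_segments(),
                              chromosome_length = 1e8) {
  cfg <- list(n_probes = n_probes, n_genes = n_genes,
              n_per_class = n_per_class, n_normals = n_normals,
              n_discriminative = n_discriminative, effect_size = effect_size,
              arm_biases = arm_biases, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              snps_per_chromosome = snps_per_chromosome,
              cn_cohorts = cn_cohorts, cn_background_sd = cn_background_sd,
              cn_segments = cn_segments,
              chromosome_length = chromosome_length)
  counts <- c(n_probes, n_genes, n_per_class, n_normals,
              snps_per_chromosome, cn_cohorts)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_discriminative < 0 || n_discriminative > n_probes)
    stop("n_discriminative must lie in [0, n_probes]")
  if (!is.finite(effect_size)) stop("effect size must be finite")
  if (is.null(names(cfg$n_per_class)) || length(cfg$n_per_class) != 2)
    stop("n_per_class must name exactly two classes")
  if (!is.null(cn_segments)) {
    fr <- c(cn_segments$start_frac, cn_segments$end_frac, cn_segments$fraction)
    if (any(fr < 0 | fr > 1)) stop("segment fractions must lie in [0, 1]")
  }
  if (!is.null(arm_biases) && any(arm_biases$fraction < 0 | arm_biases$fraction > 1))
    stop("arm-bias fractions must lie in [0, 1]")
  structure(cfg, class = "SimulationConfig")
}

# Miniature-genome probe annotation: genes dealt cyclically across 22
# autosomes + X at evenly spaced positions; probes inherit their gene's
# locus; 4 cytobands per arm, named e.g. "5q3".
simulate_probe_annotation <- function(cfg) {
  chroms <- c(as.character(1:22), "X")
  gene_chrom <- rep(chroms, length.out = cfg$n_genes)
  gene_pos <- numeric(cfg$n_genes)
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    gene_pos[idx] <- round(seq(1e6, cfg$chromosome_length - 1e6,
                               length.out = length(idx)))
  }
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  probe_gene <- rep(seq_len(cfg$n_genes), length.out = cfg$n_probes)
  pos <- gene_pos[probe_gene] + (seq_len(cfg$n_probes) %% 7)  # probe offsets
  chrom <- gene_chrom[probe_gene]
  half <- cfg$chromosome_length / 2
  arm <- ifelse(pos <= half, "p", "q")
  within <- ifelse(arm == "p", pos / half, (pos - half) / half)
  band <- pmin(4L, 1L + floor(within * 4))
  probe_annotation(data.frame(
    probe_id = sprintf("P%05d", seq_len(cfg$n_probes)),
    gene_symbol = gene_ids[probe_gene],
    chromosome = chrom, arm = arm,
    cytoband = paste0(chrom, arm, band),
    position = pos, stringsAsFactors = FALSE))
}

# Rows of `ann` targeted by one arm-bias row: the terminal `fraction` of the
# arm's probes by position (telomeric end: low positions on p, high on q).
arm_bias_rows <- function(ann, chromosome, arm, fraction) {
  arms <- if (arm == "both") c("p", "q") else arm
  out <- integer(0)
  for (a in arms) {
    idx <- which(ann$chromosome == chromosome & ann$arm == a)
    if (!length(idx))
      stop(sprintf("arm %s%s named in bias spec is absent from annotation",
                   chromosome, a))
    if (fraction >= 1) { out <- c(out, idx); next }
    k <- ceiling(fraction * length(idx))
    ord <- order(ann$position[idx])
    sel <- if (a == "p") utils::head(ord, k) else utils::tail(ord, k)
    out <- c(out, idx[sel])
  }
  out
}

#' Simulate tumor and normal expression cohorts
#'
#' Probe baselines are drawn once and shared across all samples; the
#' chRCC-oriented discriminative effect (alternating sign) and the
#' class-specific arm biases are added on top, then i.i.d. Gaussian noise.
#' Deterministic given `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (this generator uses stream `seed`).
#' @return List with elements `tumors` and `normals`
#'   ([expression_matrix()]s), `annotation` ([probe_annotation()]) and
#'   `truth` (ledger: discriminative probes with signed effects, the arm
#'   bias table with affected probe ids).
#' @export
simulate_expression <- function(config = simulation_config(), seed = 1) {
  cfg <- config
  set.seed(as.integer(seed))
  ann <- simulate_probe_annotation(cfg)
  classes <- names(cfg$n_per_class)
  n_t <- sum(cfg$n_per_class)
  labels <- factor(rep(classes, cfg$n_per_class), levels = classes)
  sample_ids <- paste0(rep(classes, cfg$n_per_class), "_",
                       unlist(lapply(cfg$n_per_class, seq_len)))
  baseline <- stats::rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
  mu <- matrix(baseline, cfg$n_probes, n_t)
  disc_idx <- if (cfg$n_discriminative > 0)
    sort(sample.int(cfg$n_probes, cfg$n_discriminative)) else integer(0)
  disc_sign <- rep_len(c(1, -1), length(disc_idx))
  in_class1 <- labels == classes[1]
  if (length(disc_idx))
    mu[disc_idx, in_class1] <- mu[disc_idx, in_class1] +
      disc_sign * cfg$effect_size
  bias_probes <- list()
  if (!is.null(cfg$arm_biases) && nrow(cfg$arm_biases)) {
    for (i in seq_len(nrow(cfg$arm_biases))) {
      b <- cfg$arm_biases[i, ]
      rows <- arm_bias_rows(ann, b$chromosome, b$arm, b$fraction)
      cols <- labels == b$class
      if (!any(cols)) stop("arm bias names unknown class: ", b$class)
      mu[rows, cols] <- mu[rows, cols] + b$shift
      bias_probes[[i]] <- ann$probe_id[rows]
    }
  }
  tum <- mu + matrix(stats::rnorm(cfg$n_probes * n_t, 0, cfg$noise_sd),
                     cfg$n_probes, n_t)
  dimnames(tum) <- list(ann$probe_id, sample_ids)
  nor <- matrix(baseline, cfg$n_probes, cfg$n_normals) +
    matrix(stats::rnorm(cfg$n_probes * cfg$n_normals, 0, cfg$noise_sd),
           cfg$n_probes, cfg$n_normals)
  dimnames(nor) <- list(ann$probe_id, sprintf("normal_%02d", seq_len(cfg$n_normals)))
  truth <- list(
    discriminative = data.frame(
      probe_id = ann$probe_id[disc_idx],
      effect = disc_sign * cfg$effect_size,
      stringsAsFactors = FALSE),
    arm_biases = cfg$arm_biases,
    arm_bias_probes = bias_probes)
  list(tumors = expression_matrix(tum, stats::setNames(labels, sample_ids)),
       normals = expression_matrix(nor),
       annotation = ann, truth = truth)
}

#' Simulate a SNP copy-number cohort
#'
#' Background CN is Normal(2, sd), truncated at 0; injected segments
#' overwrite the background with segment-level draws in a random subset of
#' cohort samples (`round(fraction * n)`). Deterministic given
#' `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (this generator uses stream `seed + 1`).
#' @return List with `cn` ([cn_matrix()]), `annotation`
#'   ([snp_annotation()]) and `truth` (injected segments with SNP index
#'   ranges and affected samples).
#' @export
simulate_cn <- function(config = simulation_config(), seed = 1) {
  cfg <- config
  set.seed(as.integer(seed) + 1L)
  chroms <- c(as.character(1:22), "X")
  ann <- snp_annotation(data.frame(
    snp_id = sprintf("SNP%05d", seq_len(length(chroms) * cfg$snps_per_chromosome)),
    chromosome = rep(chroms, each = cfg$snps_per_chromosome),
    position = rep(round(seq(1e5, cfg$chromosome_length,
                             length.out = cfg$snps_per_chromosome)),
                   times = length(chroms)),
    stringsAsFactors = FALSE))
  cohorts <- names(cfg$cn_cohorts)
  n_s <- sum(cfg$cn_cohorts)
  sample_ids <- paste0("cn_", rep(cohorts, cfg$cn_cohorts), "_",
                       unlist(lapply(cfg$cn_cohorts, seq_len)))
  cohort <- stats::setNames(rep(cohorts, cfg$cn_cohorts), sample_ids)
  vals <- matrix(pmax(0, stats::rnorm(nrow(ann) * n_s, 2, cfg$cn_background_sd)),
                 nrow(ann), n_s, dimnames = list(ann$snp_id, sample_ids))
  truth <- list()
  if (!is.null(cfg$cn_segments) && nrow(cfg$cn_segments)) {
    for (i in seq_len(nrow(cfg$cn_segments))) {
      sg <- cfg$cn_segments[i, ]
      idx <- which(ann$chromosome == sg$chromosome)
      if (!length(idx)) stop("segment on unknown chromosome: ", sg$chromosome)
      if (sg$start_frac < 0 || sg$end_frac > 1 || sg$start_frac >= sg$end_frac)
        stop("segment outside chromosome span: row ", i)
      span <- idx[ceiling(sg$start_frac * length(idx) + 1e-9):
                    max(1, floor(sg$end_frac * length(idx)))]
      span <- span[span >= min(idx) & span <= max(idx)]
      members <- sample_ids[cohort == sg$cohort]
      n_aff <- round(sg$fraction * length(members))
      affected <- sort(sample(members, n_aff))
      for (sm in affected)
        vals[span, sm] <- pmax(0, stats::rnorm(length(span), sg$cn_mean, sg$cn_sd))
      truth[[i]] <- data.frame(
        cohort = sg$cohort, chromosome = sg$chromosome,
        first_snp = min(span), last_snp = max(span),
        cn_mean = sg$cn_mean, type = sg$type,
        samples = paste(affected, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cohort = character(0), chromosome = character(0),
               first_snp = integer(0), last_snp = integer(0),
               cn_mean = numeric(0), type = character(0),
               samples = character(0))
  list(cn = cn_matrix(vals, cohort), annotation = ann,
       truth = list(segments = truth_df))
}

#' Simulate a 2x2 marker contingency table
#'
#' Independent binomial positives per group. Deterministic given the seed
#' (this generator uses stream `seed + 2`).
#'
#' @param p_pos_group1,p_pos_group2 Marker-positive probability per group.
#' @param n1,n2 Group sizes.
#' @param seed Integer seed.
#' @return A [contingency_2x2()] table.
#' @export
simulate_contingency <- function(p_pos_group1, p_pos_group2, n1, n2, seed = 1) {
  if (any(c(p_pos_group1, p_pos_group2) < 0 | c(p_pos_group1, p_pos_group2) > 1))
    stop("probabilities must lie in [0, 1]")
  set.seed(as.integer(seed) + 2L)
  a <- stats::rbinom(1, n1, p_pos_group1)
  c_ <- stats::rbinom(1, n2, p_pos_group2)
  contingency_2x2(a, n1 - a, c_, n2 - c_)
}
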