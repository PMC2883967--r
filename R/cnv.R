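# SNP-array copy-number segment calling by run-length rules: a loss (gain)
# is at least `min_run` consecutive SNPs with CN strictly below 1.6
# (strictly above 3.5); recurrent CNA regions are maximal runs of SNPs
# where strictly more than `min_fraction` of a cohort's samples carry a
# call of the same type.

check_canonical <- function(annotation) {
  ord <- order(match(annotation$chromosome, CHROMOSOMES), annotation$position)
  if (!identical(ord, seq_len(nrow(annotation))))
    stop("SNP annotation is not canonically sorted; sort by chromosome ",
         "(1-22, X, Y) then position (snp_annotation() does this)")
  invisible(TRUE)
}

empty_calls <- function() {
  data.frame(sample = character(0), chromosome = character(0),
             start_index = integer(0), end_index = integer(0),
             start_pos = numeric(0), end_pos = numeric(0),
             type = character(0), n_snps = integer(0), mean_cn = numeric(0),
             stringsAsFactors = FALSE)
}

#' Call per-sample copy-number loss/gain segments
#'
#' Per sample and chromosome, maximal runs of consecutive SNPs strictly
#' below `loss_cut` become loss calls and strictly above `gain_cut` gain
#' calls; runs shorter than `min_run` are discarded. Missing CN values
#' break runs.
#'
#' @param cn A [cn_matrix()].
#' @param annotation A [snp_annotation()] in canonical order covering the
#'   matrix's SNPs.
#' @param loss_cut,gain_cut CN thresholds (defaults 1.6 and 3.5, strict
#'   inequalities).
#' @param min_run Minimum run length (default 4 consecutive SNPs).
#' @return Data frame of class `CnCallTable`: `sample`, `chromosome`,
#'   `start_index`/`end_index` (row indices into the canonical annotation),
#'   `start_pos`/`end_pos` (1-based inclusive), `type`, `n_snps`,
#'   `mean_cn`.
#' @export
call_cn_segments <- function(cn, annotation, loss_cut = 1.6, gain_cut = 3.5,
                             min_run = 4) {
  if (loss_cut >= gain_cut) stop("loss_cut must be below gain_cut")
  check_canonical(annotation)
  v <- cn$values
  missing_ann <- setdiff(rownames(v), annotation$snp_id)
  if (length(missing_ann))
    stop("SNP(s) missing from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  ann <- annotation[annotation$snp_id %in% rownames(v), , drop = FALSE]
  v <- v[ann$snp_id, , drop = FALSE]
  ann_index <- match(ann$snp_id, annotation$snp_id)
  out <- list()
  chrom_split <- split(seq_len(nrow(ann)), ann$chromosome)
  for (sm in colnames(v)) {
    for (ch in unique(ann$chromosome)) {
      rows <- chrom_split[[ch]]
      cnv <- v[rows, sm]
      status <- ifelse(is.na(cnv), "na",
                       ifelse(cnv < loss_cut, "loss",
                              ifelse(cnv > gain_cut, "gain", "none")))
      r <- rle(status)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values %in% c("loss", "gain") & r$lengths >= min_run
      for (j in which(keep)) {
        i1 <- rows[starts[j]]; i2 <- rows[ends[j]]
        out[[length(out) + 1L]] <- data.frame(
          sample = sm, chromosome = ch,
          start_index = ann_index[i1], end_index = ann_index[i2],
          start_pos = ann$position[i1], end_pos = ann$position[i2],
          type = r$values[j], n_snps = r$lengths[j],
          mean_cn = mean(cnv[starts[j]:ends[j]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_calls()
  if (nrow(res)) {
    res <- res[order(res$sample, match(res$chromosome, CHROMOSOMES),
                     res$start_index), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("CnCallTable", "data.frame")
  res
}

#' Recurrent copy-number alteration (CNA) regions across a cohort
#'
#' For each SNP and call type, the fraction of cohort samples whose calls
#' cover that SNP is computed; CNA regions are maximal runs of at least
#' `min_run` SNPs where that fraction is strictly greater than
#' `min_fraction`.
#'
#' @param calls A [call_cn_segments()] table.
#' @param cohort_samples Character vector of the cohort's sample ids (the
#'   prevalence denominator; samples without calls still count).
#' @param annotation The [snp_annotation()] used for calling.
#' @param min_fraction Strict prevalence threshold (default 0.30).
#' @param min_run Minimum CNA span in SNPs (default 4).
#' @return Data frame of class `CnaRegionTable`: `chromosome`,
#'   `start_index`, `end_index`, `start_pos`, `end_pos`, `type`, `n_snps`,
#'   `prevalence_min`, `prevalence_max`.
#' @export
cna_regions <- function(calls, cohort_samples, annotation,
                        min_fraction = 0.30, min_run = 4) {
  if (!length(cohort_samples)) stop("empty cohort")
  check_canonical(annotation)
  n_snp <- nrow(annotation)
  calls <- calls[calls$sample %in% cohort_samples, , drop = FALSE]
  out <- list()
  for (type in c("loss", "gain")) {
    cov <- numeric(n_snp)
    tc <- calls[calls$type == type, , drop = FALSE]
    for (j in seq_len(nrow(tc)))
      cov[tc$start_index[j]:tc$end_index[j]] <-
        cov[tc$start_index[j]:tc$end_index[j]] + 1
    frac <- cov / length(cohort_samples)
    hot <- frac > min_fraction
    # regions must not straddle chromosomes
    for (ch in unique(annotation$chromosome)) {
      rows <- which(annotation$chromosome == ch)
      r <- rle(hot[rows])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_run
      for (j in which(keep)) {
        i1 <- rows[starts[j]]; i2 <- rows[ends[j]]
        out[[length(out) + 1L]] <- data.frame(
          chromosome = ch, start_index = i1, end_index = i2,
          start_pos = annotation$position[i1],
          end_pos = annotation$position[i2],
          type = type, n_snps = i2 - i1 + 1L,
          prevalence_min = min(frac[i1:i2]),
          prevalence_max = max(frac[i1:i2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chromosome = character(0), start_index = integer(0),
               end_index = integer(0), start_pos = numeric(0),
               end_pos = numeric(0), type = character(0),
               n_snps = integer(0), prevalence_min = numeric(0),
               prevalence_max = numeric(0), stringsAsFactors = FALSE)
  if (nrow(res)) {
    res <- res[order(match(res$chromosome, CHROMOSOMES), res$start_index), ]
    rownames(res) <- NULL
  }
  class(res) <- c("CnaRegionTable", "data.frame")
  res
}

#' Per-chromosome alteration summary of CNA regions
#'
#' @param regions A [cna_regions()] table.
#' @param annotation The [snp_annotation()] used for calling.
#' @return Data frame with, per chromosome and type, the fraction of the
#'   chromosome's SNPs inside CNA regions (all chromosome/type pairs are
#'   reported; zero when quiet).
#' @export
cnv_cohort_profile <- function(regions, annotation) {
  chroms <- unique(annotation$chromosome)
  rows <- list()
  for (ch in chroms) {
    idx <- which(annotation$chromosome == ch)
    for (type in c("loss", "gain")) {
      rg <- regions[regions$chromosome == ch & regions$type == type, ,
                    drop = FALSE]
      covered <- logical(length(idx))
      for (j in seq_len(nrow(rg))) {
        lo <- max(rg$start_index[j], min(idx)); hi <- min(rg$end_index[j], max(idx))
        covered[(lo:hi) - min(idx) + 1L] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = ch, type = type, n_snps = length(idx),
        altered_fraction = mean(covered), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$chromosome, CHROMOSOMES), out$type), ]
}
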