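# Comparative genomic microarray analysis (CGMA): infer regional
# cytogenetic alteration from expression. Relative profiles R = log2(T) -
# mean log2(N) are collapsed to gene level and each chromosome arm is
# scored per sample with a sign-test z on the count of positively shifted
# genes.

#' Relative expression against a normal reference cohort
#'
#' `R[i, s] = T[i, s] - mean_n N[i, n]`, all in log2 space.
#'
#' @param tumors,normals [expression_matrix()]s over the identical probe
#'   set (order may differ; normals are aligned to the tumor probes).
#' @return An object of class `RelativeExpressionMatrix`: list with the `R`
#'   matrix and the tumor labels.
#' @export
relative_expression <- function(tumors, normals) {
  tv <- tumors$values; nv <- normals$values
  if (!setequal(rownames(tv), rownames(nv))) {
    only_t <- setdiff(rownames(tv), rownames(nv))
    only_n <- setdiff(rownames(nv), rownames(tv))
    stop("probe sets differ; tumor-only: ",
         paste(utils::head(only_t, 5), collapse = ", "),
         "; normal-only: ", paste(utils::head(only_n, 5), collapse = ", "))
  }
  nv <- nv[rownames(tv), , drop = FALSE]
  R <- tv - rowMeans(nv)
  structure(list(R = R, labels = tumors$labels),
            class = "RelativeExpressionMatrix")
}

# Collapse probe-level R to gene level by the mean across each gene's
# probes, and attach each gene's arm (majority vote over its probes).
collapse_to_genes <- function(R, annotation) {
  ann <- annotation[match(rownames(R), annotation$probe_id), , drop = FALSE]
  if (any(is.na(ann$probe_id)))
    stop("probe(s) missing from annotation: ",
         paste(utils::head(setdiff(rownames(R), annotation$probe_id), 5),
               collapse = ", "))
  placed <- ann$placed
  R <- R[placed, , drop = FALSE]
  ann <- ann[placed, , drop = FALSE]
  gene <- ann$gene_symbol
  gr <- rowsum(R, gene) / as.vector(table(gene)[sort(unique(gene))])
  arm_of <- vapply(split(paste0(ann$chromosome, ann$arm), gene), function(a) {
    names(sort(table(a), decreasing = TRUE))[1]
  }, "")
  list(R = gr, region = arm_of[rownames(gr)])
}

#' Per-sample regional expression bias by chromosome arm
#'
#' Probes are collapsed to genes (mean R); per sample and arm, genes with
#' R exactly 0 are excluded, and with n remaining genes of which k have
#' R > 0, `z = (k - n/2) / sqrt(n/4)` (sign-test z, no continuity
#' correction). Calls: gain when `z >= z_threshold`, loss when
#' `z <= -z_threshold`, else neutral. Arms with fewer than `min_genes`
#' eligible genes are skipped and reported in the `"skipped"` attribute.
#'
#' @param rel A [relative_expression()] result (or a plain numeric R
#'   matrix).
#' @param annotation A [probe_annotation()] covering the probes of `rel`.
#' @param z_threshold Two-sided call threshold on z (default 1.96).
#' @param min_genes Minimum eligible genes per arm (default 10).
#' @return Data frame of class `RegionalBias` with columns `sample`,
#'   `chromosome`, `arm`, `region`, `n_genes`, `n_positive`, `z`, `call`.
#' @export
regional_bias <- function(rel, annotation, z_threshold = 1.96,
                          min_genes = 10) {
  R <- if (inherits(rel, "RelativeExpressionMatrix")) rel$R else as.matrix(rel)
  g <- collapse_to_genes(R, annotation)
  regions <- sort(unique(g$region))
  out <- list(); skipped <- list()
  for (rg in regions) {
    gr <- g$R[g$region == rg, , drop = FALSE]
    for (s in colnames(gr)) {
      vals <- gr[, s]
      vals <- vals[vals != 0]
      n <- length(vals)
      if (n < min_genes) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(sample = s, region = rg, n_genes = n,
                     stringsAsFactors = FALSE)
        next
      }
      k <- sum(vals > 0)
      z <- (k - n / 2) / sqrt(n / 4)
      call <- if (z >= z_threshold) "gain"
              else if (z <= -z_threshold) "loss" else "neutral"
      out[[length(out) + 1L]] <- data.frame(
        sample = s,
        chromosome = sub("[pq]$", "", rg),
        arm = substr(rg, nchar(rg), nchar(rg)),
        region = rg, n_genes = n, n_positive = k, z = z, call = call,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), chromosome = character(0),
               arm = character(0), region = character(0),
               n_genes = integer(0), n_positive = integer(0),
               z = numeric(0), call = character(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(res) <- c("RegionalBias", "data.frame")
  res
}

#' Cohort-level summary of regional bias calls
#'
#' @param bias A [regional_bias()] table.
#' @param cohorts Named vector mapping sample id to cohort (e.g. tumor
#'   labels); `NULL` treats all samples as one cohort.
#' @return Data frame with per (cohort, region): number of samples scored
#'   and the fractions called gain / loss / altered.
#' @export
cohort_bias_summary <- function(bias, cohorts = NULL) {
  if (!nrow(bias))
    return(data.frame(cohort = character(0), region = character(0),
                      chromosome = character(0), arm = character(0),
                      n_samples = integer(0), frac_gain = numeric(0),
                      frac_loss = numeric(0), frac_altered = numeric(0)))
  if (is.null(cohorts))
    cohorts <- stats::setNames(rep("all", length(unique(bias$sample))),
                               unique(bias$sample))
  bias$cohort <- as.character(cohorts[bias$sample])
  if (any(is.na(bias$cohort)))
    stop("sample(s) without a cohort label: ",
         paste(unique(bias$sample[is.na(bias$cohort)]), collapse = ", "))
  split_by <- interaction(bias$cohort, bias$region, drop = TRUE)
  rows <- lapply(split(bias, split_by), function(b) {
    data.frame(cohort = b$cohort[1], region = b$region[1],
               chromosome = b$chromosome[1], arm = b$arm[1],
               n_samples = nrow(b),
               frac_gain = mean(b$call == "gain"),
               frac_loss = mean(b$call == "loss"),
               frac_altered = mean(b$call != "neutral"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cohort, match(out$chromosome, CHROMOSOMES), out$arm), ]
  rownames(out) <- NULL
  out
}
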