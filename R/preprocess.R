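# Probe filtering and unsupervised hierarchical clustering of expression
# profiles.

#' Probe filter specification
#'
#' A probe is kept when its coefficient of variation is at least `cv_min`
#' AND at least `min_samples_at_expr` samples show log2 expression at or
#' above `expr_min`.
#'
#' @param cv_min Minimum coefficient of variation (default 0.05).
#' @param expr_min Log2 expression floor (default 8).
#' @param min_samples_at_expr Minimum number of samples at/above the floor
#'   (default 2).
#' @param cv_scale Scale on which the CV is computed: `"log2"` (default,
#'   sd/mean of the log2 intensities) or `"linear"` (CV of 2^x).
#' @return A list of class `FilterSpec`.
#' @export
filter_spec <- function(cv_min = 0.05, expr_min = 8, min_samples_at_expr = 2,
                        cv_scale = c("log2", "linear")) {
  cv_scale <- match.arg(cv_scale)
  if (cv_min < 0) stop("cv_min must be >= 0")
  if (min_samples_at_expr < 1) stop("min_samples_at_expr must be >= 1")
  structure(list(cv_min = cv_min, expr_min = expr_min,
                 min_samples_at_expr = min_samples_at_expr,
                 cv_scale = cv_scale), class = "FilterSpec")
}

#' Filter probes by coefficient of variation and expression floor
#'
#' @param x An [expression_matrix()] in log2 space.
#' @param spec A [filter_spec()].
#' @return An `ExpressionMatrix` containing the kept probes, in their
#'   original order. Emits a warning (not an error) when no probe survives.
#' @export
filter_probes <- function(x, spec = filter_spec()) {
  v <- x$values
  cvv <- if (spec$cv_scale == "linear") 2^v else v
  mu <- rowMeans(cvv)
  sdv <- apply(cvv, 1, stats::sd)
  cv <- sdv / mu
  cv[!is.finite(cv)] <- -Inf  # zero/negative mean: fails the CV criterion
  keep <- cv >= spec$cv_min &
    rowSums(v >= spec$expr_min) >= spec$min_samples_at_expr
  if (!any(keep)) {
    warning("no probe passed the filter")
    keep <- rep(FALSE, nrow(v))
  }
  x[which(keep), seq_len(ncol(v))]
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Distances are 1 - Pearson correlation across probes (the conventional
#' choice for expression profiles) or Euclidean; agglomeration is
#' complete-linkage.
#'
#' @param x An [expression_matrix()] with at least two samples.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage Only `"complete"` is exposed.
#' @return An object of class `Dendrogram`: list with the underlying
#'   `stats::hclust` fit plus `merge`, `height`, `order` and `labels`.
#' @export
hierarchical_cluster <- function(x, metric = c("correlation", "euclidean"),
                                 linkage = "complete") {
  metric <- match.arg(metric)
  if (!identical(linkage, "complete")) stop("only complete linkage is exposed")
  v <- x$values
  if (ncol(v) < 2) stop("clustering requires at least 2 samples")
  d <- if (metric == "correlation") stats::as.dist(1 - stats::cor(v))
       else stats::dist(t(v))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels, metric = metric),
            class = "Dendrogram")
}

#' Cut a dendrogram into k groups
#'
#' Removes the k - 1 highest merges.
#'
#' @param dend A [hierarchical_cluster()] result.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return Named integer vector of cluster labels per sample.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(dend$hclust, k = k)
}

#' Export a dendrogram as Newick text
#'
#' @param dend A [hierarchical_cluster()] result.
#' @return A single Newick string.
#' @export
dendrogram_newick <- function(dend) {
  ape::write.tree(ape::as.phylo(dend$hclust))
}

#' Export a dendrogram as a JSON merge list
#'
#' @param dend A [hierarchical_cluster()] result.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
dendrogram_json <- function(dend, path = NULL) {
  obj <- list(labels = dend$labels, merge = dend$merge, height = dend$height,
              order = dend$order, metric = dend$metric)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
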