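# Core data containers shared by every analysis stage.
#
# All expression values live in log2 space; linear-scale quantities such as
# fold changes are derived on demand. Missing values are permitted in copy
# number matrices (SNP arrays have no-calls) but never in expression matrices.

CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Construct an expression matrix
#'
#' A log2 probe-by-sample intensity matrix with optional two-class sample
#' labels. Tumor cohorts carry labels; a normal reference cohort is stored as
#' a separate unlabelled `ExpressionMatrix`.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). All values must be finite.
#' @param labels Optional character/factor vector of class labels, either
#'   named by sample id or in column order. Must cover every sample.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `labels` (a named factor or `NULL`).
#' @export
expression_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("expression matrix requires probe rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("expression matrix requires sample colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at probe '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (is.null(names(labels))) {
      if (length(labels) != ncol(values))
        stop("unnamed labels must have one entry per sample")
      names(labels) <- colnames(values)
    }
    unknown <- setdiff(names(labels), colnames(values))
    if (length(unknown))
      stop("label(s) refer to unknown sample(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("sample(s) without a class label: ", paste(missing, collapse = ", "))
    labels <- droplevels(labels[colnames(values)])
  }
  structure(list(values = values, labels = labels), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels))
    print(table(class = x$labels))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by probe and/or sample
#'
#' @param x An `ExpressionMatrix`.
#' @param i Probe selector (indices, names or logical).
#' @param j Sample selector.
#' @param ... Unused.
#' @return An `ExpressionMatrix`.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  lab <- if (!is.null(x$labels)) droplevels(x$labels[colnames(v)]) else NULL
  expression_matrix(v, lab)
}

#' Construct a probe annotation table
#'
#' Maps microarray probes to gene symbols and cytogenetic coordinates.
#' Probes on a chromosome outside 1-22/X/Y are retained but flagged
#' unplaced (`placed = FALSE`) so no row is silently dropped.
#'
#' @param df Data frame with columns `probe_id`, `gene_symbol`,
#'   `chromosome`, `arm` (`"p"` or `"q"`), `cytoband`, `position`
#'   (1-based base pairs).
#' @return A data frame of class `ProbeAnnotation` with an added logical
#'   `placed` column.
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "gene_symbol", "chromosome", "arm", "cytoband", "position")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$probe_id <- as.character(df$probe_id)
  df$chromosome <- as.character(df$chromosome)
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  df$position <- as.numeric(df$position)
  if (any(!is.na(df$position) & df$position <= 0))
    stop("probe positions must be positive (1-based)")
  df$placed <- df$chromosome %in% CHROMOSOMES & df$arm %in% c("p", "q")
  ok <- df$placed & !is.na(df$cytoband) & nzchar(df$cytoband)
  bad <- ok & substr(df$cytoband, nchar(df$chromosome) + 1,
                     nchar(df$chromosome) + 1) != df$arm
  if (any(bad))
    stop("arm/cytoband mismatch for probe(s): ",
         paste(utils::head(df$probe_id[bad], 5), collapse = ", "))
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Construct a SNP annotation table
#'
#' @param df Data frame with columns `snp_id`, `chromosome`, `position`.
#'   Rows are put in canonical order (chromosome 1-22, X, Y; then position);
#'   within a chromosome positions must be strictly increasing after the sort.
#' @return A data frame of class `SnpAnnotation` in canonical order.
#' @export
snp_annotation <- function(df) {
  req <- c("snp_id", "chromosome", "position")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$snp_id <- as.character(df$snp_id)
  df$chromosome <- as.character(df$chromosome)
  dup <- df$snp_id[duplicated(df$snp_id)]
  if (length(dup)) stop("duplicate SNP id(s): ", paste(unique(dup), collapse = ", "))
  unknown <- setdiff(unique(df$chromosome), CHROMOSOMES)
  if (length(unknown))
    stop("unknown chromosome(s) in SNP annotation: ", paste(unknown, collapse = ", "))
  ord <- order(match(df$chromosome, CHROMOSOMES), df$position)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  tied <- stats::ave(df$position, df$chromosome,
                     FUN = function(p) c(FALSE, diff(p) <= 0))
  if (any(tied == 1))
    stop("SNP positions must be strictly increasing within a chromosome")
  class(df) <- c("SnpAnnotation", "data.frame")
  df
}

#' Construct a copy-number matrix
#'
#' Per-SNP copy-number estimates for one or more sample cohorts. Missing
#' values (`NA`) are allowed and represent array no-calls; they break runs
#' during segment calling.
#'
#' @param values Numeric matrix, SNPs in rows (rownames = SNP ids), samples
#'   in columns. Values must be `NA` or `>= 0`.
#' @param cohort Character/factor cohort label per sample (named by sample id
#'   or in column order).
#' @return An object of class `CnMatrix`: list with `values` and `cohort`.
#' @export
cn_matrix <- function(values, cohort) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("CN matrix requires SNP rownames and sample colnames")
  if (any(!is.na(values) & values < 0)) stop("copy numbers must be >= 0 or NA")
  cohort <- as.factor(cohort)
  if (is.null(names(cohort))) {
    if (length(cohort) != ncol(values)) stop("one cohort label per sample required")
    names(cohort) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(cohort))
  if (length(missing)) stop("sample(s) without cohort: ", paste(missing, collapse = ", "))
  structure(list(values = values, cohort = droplevels(cohort[colnames(values)])),
            class = "CnMatrix")
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (members are de-duplicated;
#'   empty sets are rejected).
#' @param description Optional named character vector of term descriptions.
#' @param relations Optional data frame with columns `parent`, `child`
#'   giving a directed acyclic parent-to-child relation among set ids,
#'   used by DAG-conditional enrichment testing.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, description = NULL, relations = NULL) {
  if (is.null(names(sets)) && length(sets))
    stop("sets must be named by set id")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(!lengths(sets)))
    stop("empty set(s): ", paste(names(sets)[!lengths(sets)], collapse = ", "))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  if (!is.null(relations)) {
    relations <- as.data.frame(relations)[c("parent", "child")]
    unknown <- setdiff(unique(c(relations$parent, relations$child)), names(sets))
    if (length(unknown))
      stop("relation refers to unknown set(s): ", paste(unknown, collapse = ", "))
    topological_order(names(sets), relations)  # errors on cycles
  }
  structure(list(sets = sets, description = description, relations = relations),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, %d relations\n", length(x$sets),
              if (is.null(x$relations)) 0L else nrow(x$relations)))
  invisible(x)
}

# Kahn topological sort over parent -> child edges; returns ids ordered
# parents-before-children, or errors if the relation graph has a cycle.
topological_order <- function(ids, relations) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  children <- split(relations$child, relations$parent)
  tab <- table(relations$child)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(ids)) stop("set relations contain a cycle")
  out
}

#' Construct a 2x2 contingency table
#'
#' Rows are groups (e.g. chRCC, oncocytoma), columns marker-positive /
#' marker-negative counts.
#'
#' @param a,b,c,d Nonnegative integer counts: `a`,`b` = group-1
#'   positive/negative; `c`,`d` = group-2 positive/negative.
#' @return A 2x2 integer matrix of class `ContingencyTable2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) <= 0) stop("table total must be positive")
  m <- matrix(as.integer(round(counts)), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("group1", "group2"),
                              status = c("positive", "negative")))
  class(m) <- c("ContingencyTable2x2", class(m))
  m
}
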