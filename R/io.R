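# Readers and writers for the plain-text formats the pipeline consumes and
# emits. TSV dialect is fixed: tab separator, UTF-8, '.' decimal, no quoting.

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "")
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of probe ids, and
#' tab-separated numeric cells ('.' decimal). Optionally attaches per-sample
#' class labels from a two-column TSV (`sample_id`, `label`).
#'
#' @param path Path to the expression TSV.
#' @param labels_path Optional path to a label TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, labels_path = NULL) {
  df <- read_tsv_strict(path)
  probe_ids <- df[[1]]
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup))
    stop("duplicate probe id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at probe '%s', sample '%s' in %s",
                 probe_ids[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  dimnames(num) <- list(probe_ids, colnames(vals))
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- read_tsv_strict(labels_path)
    if (ncol(lab) < 2) stop("label file needs columns sample_id, label")
    unknown <- setdiff(lab[[1]], colnames(num))
    if (length(unknown))
      stop("label file refers to unknown sample(s): ", paste(unknown, collapse = ", "))
    labels <- stats::setNames(lab[[2]], lab[[1]])
  }
  expression_matrix(num, labels)
}

#' Write an expression matrix (and optional labels) to TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param labels_path Optional path for a `sample_id`/`label` TSV; written
#'   only when `x` carries labels.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path, labels_path = NULL) {
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(labels_path) && !is.null(x$labels)) {
    utils::write.table(
      data.frame(sample_id = names(x$labels), label = as.character(x$labels)),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read probe annotation from TSV
#'
#' Requires columns `probe_id`, `gene_symbol`, `chromosome`, `arm`,
#' `cytoband`, `position`. Rows with an unmappable chromosome are retained
#' and flagged `placed = FALSE`.
#'
#' @param path Path to annotation TSV.
#' @return A [probe_annotation()] data frame.
#' @export
read_probe_annotation <- function(path) {
  df <- read_tsv_strict(path)
  df$position <- suppressWarnings(as.numeric(df$position))
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param ann A `ProbeAnnotation`.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(
    as.data.frame(ann)[c("probe_id", "gene_symbol", "chromosome", "arm",
                         "cytoband", "position")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read SNP annotation from TSV
#'
#' @param path Path to a TSV with columns `snp_id`, `chromosome`, `position`.
#' @return A [snp_annotation()] data frame in canonical order.
#' @export
read_snp_annotation <- function(path) {
  df <- read_tsv_strict(path)
  df$position <- suppressWarnings(as.numeric(df$position))
  snp_annotation(df)
}

#' @rdname read_snp_annotation
#' @param ann A `SnpAnnotation`.
#' @export
write_snp_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann)[c("snp_id", "chromosome", "position")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a copy-number matrix from TSV
#'
#' Same layout as the expression TSV (first column SNP ids, header sample
#' ids), but empty cells / `NA` are allowed and kept as missing.
#'
#' @param path Path to the CN TSV.
#' @param cohorts_path Path to a two-column TSV (`sample_id`, `cohort`).
#' @return A [cn_matrix()].
#' @export
read_cn_matrix <- function(path, cohorts_path) {
  df <- read_tsv_strict(path)
  snp_ids <- df[[1]]
  dup <- snp_ids[duplicated(snp_ids)]
  if (length(dup))
    stop("duplicate SNP id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[-1])
  vals[vals == "" | vals == "NA"] <- NA
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at SNP '%s', sample '%s' in %s",
                 snp_ids[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  dimnames(num) <- list(snp_ids, colnames(vals))
  coh <- read_tsv_strict(cohorts_path)
  cn_matrix(num, stats::setNames(coh[[2]], coh[[1]]))
}

#' @rdname read_cn_matrix
#' @param x A `CnMatrix`.
#' @export
write_cn_matrix <- function(x, path, cohorts_path = NULL) {
  df <- data.frame(snp_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  if (!is.null(cohorts_path)) {
    utils::write.table(
      data.frame(sample_id = names(x$cohort), cohort = as.character(x$cohort)),
      cohorts_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT: one set per line, `set_id <tab> description <tab> member...`.
#' Members are de-duplicated per set.
#'
#' @param path Path to a GMT file.
#' @param relations_path Optional TSV (`parent`, `child`) with DAG relations.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets_gmt <- function(path, relations_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2), ids)
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  relations <- NULL
  if (!is.null(relations_path)) relations <- read_tsv_strict(relations_path)
  if (!length(sets))
    return(gene_set_collection(stats::setNames(list(), character(0))))
  gene_set_collection(sets, desc, relations)
}

#' @rdname read_gene_sets_gmt
#' @param collection A `GeneSetCollection`.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$description[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write copy-number calls as BED
#'
#' Converts 1-based inclusive call coordinates to BED's 0-based half-open
#' convention; the name field is `sample|type`. Output is sorted by
#' chromosome (1-22, X, Y) then start. An empty call set yields a file with
#' only the header comment.
#'
#' @param calls A data frame of CN calls from [call_cn_segments()] (needs
#'   columns `sample`, `chromosome`, `start_pos`, `end_pos`, `type`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cn_calls_bed <- function(calls, path) {
  header <- "# chrom\tstart\tend\tname"
  if (is.null(calls) || nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(match(calls$chromosome, CHROMOSOMES), calls$start_pos)
  calls <- calls[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t%d\t%s", calls$chromosome,
                  as.integer(calls$start_pos) - 1L, as.integer(calls$end_pos),
                  paste(calls$sample, calls$type, sep = "|"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a batch of 2x2 marker tables from TSV
#'
#' Expects columns `marker`, `a`, `b`, `c`, `d` (group1 pos/neg, group2
#' pos/neg).
#'
#' @param path Path to the TSV.
#' @return Named list of [contingency_2x2()] tables.
#' @export
read_contingency_tables <- function(path) {
  df <- read_tsv_strict(path)
  req <- c("marker", "a", "b", "c", "d")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  tabs <- lapply(seq_len(nrow(df)), function(i) {
    contingency_2x2(as.numeric(df$a[i]), as.numeric(df$b[i]),
                    as.numeric(df$c[i]), as.numeric(df$d[i]))
  })
  stats::setNames(tabs, df$marker)
}
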