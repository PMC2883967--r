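# End-to-end driver wiring the stages in dependency order:
# simulate -> filter -> cluster / sam / nsc / cgma on expression;
# cn-call -> cna on copy number; enrichment on the SAM calls; exact tests
# standalone. Emits all result tables plus a manifest with content hashes,
# so a rerun under the same (config, seed) is byte-identical.

#' Pipeline configuration
#'
#' All stage parameters with their documented defaults, stage toggles and a
#' single global seed. Input paths may be `NULL`, in which case the
#' synthetic generators provide the corresponding inputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global seed; generator substreams are derived from it.
#' @param simulation A [simulation_config()].
#' @param stages Character vector of stages to run; any subset of
#'   `c("filter", "cluster", "sam", "nsc", "cgma", "cnv", "enrichment",
#'   "exact_tests")`.
#' @param expression_path,labels_path,normals_path Optional TSV inputs
#'   replacing simulated expression data (tumors + labels, normals).
#' @param annotation_path Optional probe annotation TSV.
#' @param cn_path,cn_cohorts_path,snp_annotation_path Optional CN inputs.
#' @param gene_sets_path Optional GMT; when absent the enrichment stage is
#'   skipped unless synthetic sets are requested.
#' @param contingency_path Optional marker-table TSV; defaults to the
#'   bundled immunohistochemistry counts.
#' @param filter Probe [filter_spec()].
#' @param sam_n_perm,sam_max_fdr SAM permutation count and FDR ceiling.
#' @param nsc_folds,nsc_thresholds,nsc_offset,nsc_max_error NSC settings.
#' @param cgma_z,cgma_min_genes CGMA settings.
#' @param cnv_loss_cut,cnv_gain_cut,cnv_min_run,cnv_min_fraction CN calling
#'   settings.
#' @param enrich_p,enrich_conditional_p Enrichment thresholds.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            simulation = simulation_config(),
                            stages = c("filter", "cluster", "sam", "nsc",
                                       "cgma", "cnv", "enrichment",
                                       "exact_tests"),
                            expression_path = NULL, labels_path = NULL,
                            normals_path = NULL, annotation_path = NULL,
                            cn_path = NULL, cn_cohorts_path = NULL,
                            snp_annotation_path = NULL,
                            gene_sets_path = NULL, contingency_path = NULL,
                            filter = filter_spec(),
                            sam_n_perm = 300, sam_max_fdr = 0.05,
                            nsc_folds = 10, nsc_thresholds = 100,
                            nsc_offset = 30, nsc_max_error = 0.10,
                            cgma_z = 1.96, cgma_min_genes = 10,
                            cnv_loss_cut = 1.6, cnv_gain_cut = 3.5,
                            cnv_min_run = 4, cnv_min_fraction = 0.30,
                            enrich_p = 0.01, enrich_conditional_p = 0.001) {
  known <- c("filter", "cluster", "sam", "nsc", "cgma", "cnv",
             "enrichment", "exact_tests")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- as.list(environment())
  paths <- cfg[grepl("_path$", names(cfg))]
  missing <- names(paths)[!vapply(paths, function(p)
    is.null(p) || file.exists(p), TRUE)]
  if (length(missing))
    stop("input path(s) do not exist: ",
         paste(unlist(paths[missing]), collapse = ", "))
  structure(cfg, class = "PipelineConfig")
}

write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  path
}

#' Run the full discriminative analysis pipeline
#'
#' Executes the enabled stages in dependency order on provided or simulated
#' inputs, writes every result table under `config$out_dir` and a
#' `manifest.json` naming each output with its MD5 content hash, the seed
#' and per-stage row counts. Any stage error aborts with the failing stage
#' named.
#'
#' @param config A [pipeline_config()] (or a path to a JSON/YAML file with
#'   its fields; `out_dir` required).
#' @return Invisibly, a list with the in-memory results per stage and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(tool = "renaldx",
                   version = as.character(utils::packageVersion("renaldx")),
                   seed = config$seed, stages = list(), files = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit <- function(name, df, file) {
    p <- write_result_tsv(df, file.path(config$out_dir, file))
    manifest$files[[file]] <<- list(md5 = unname(tools::md5sum(p)),
                                    rows = nrow(df))
    invisible(p)
  }

  # inputs: read when paths given, simulate otherwise
  sim <- NULL
  if (is.null(config$expression_path)) {
    sim <- stage("simulate",
                 simulate_expression(config$simulation, config$seed))
    tumors <- sim$tumors; normals <- sim$normals; ann <- sim$annotation
    emit("simulate", data.frame(probe_id = sim$truth$discriminative$probe_id,
                                effect = sim$truth$discriminative$effect),
         "truth_discriminative.tsv")
    manifest$stages$simulate <- list(n_probes = nrow(tumors$values),
                                     n_tumors = ncol(tumors$values),
                                     n_normals = ncol(normals$values))
  } else {
    tumors <- stage("read", read_expression_matrix(config$expression_path,
                                                   config$labels_path))
    normals <- if (!is.null(config$normals_path))
      stage("read", read_expression_matrix(config$normals_path)) else NULL
    ann <- if (!is.null(config$annotation_path))
      stage("read", read_probe_annotation(config$annotation_path)) else NULL
  }

  filtered <- tumors
  if ("filter" %in% config$stages) {
    filtered <- stage("filter", filter_probes(tumors, config$filter))
    emit("filter", data.frame(probe_id = rownames(filtered$values)),
         "filtered_probes.tsv")
    manifest$stages$filter <- list(kept = nrow(filtered$values),
                                   total = nrow(tumors$values))
  }
  if ("cluster" %in% config$stages) {
    dend <- stage("cluster", hierarchical_cluster(filtered))
    k2 <- cut_tree(dend, 2)
    emit("cluster", data.frame(sample = names(k2), cluster = unname(k2)),
         "cluster_k2.tsv")
    writeLines(dendrogram_newick(dend),
               file.path(config$out_dir, "dendrogram.nwk"))
    manifest$files[["dendrogram.nwk"]] <- list(
      md5 = unname(tools::md5sum(file.path(config$out_dir, "dendrogram.nwk"))),
      rows = 1L)
    results$cluster <- dend
  }
  sam_calls <- NULL
  if ("sam" %in% config$stages) {
    fit <- stage("sam", sam_fit(tumors, n_perm = config$sam_n_perm,
                                seed = config$seed))
    delta <- stage("sam", sam_select_delta(fit, config$sam_max_fdr))
    cc <- sam_call(fit, as.numeric(delta))
    fc <- fold_changes(tumors)
    tab <- data.frame(probe_id = names(fit$d), d = unname(fit$d),
                      s = unname(fit$s), fold_change = unname(fc),
                      called = names(fit$d) %in% cc$called$probe_id,
                      stringsAsFactors = FALSE)
    tab$direction <- ifelse(!tab$called, "",
      cc$called$direction[match(tab$probe_id, cc$called$probe_id)])
    emit("sam", tab, "sam_probes.tsv")
    emit("sam", attr(delta, "table"), "sam_delta_table.tsv")
    manifest$stages$sam <- list(delta = as.numeric(delta),
                                called = cc$n_called, fdr = cc$fdr)
    sam_calls <- cc
    results$sam <- list(fit = fit, call = cc)
  }
  if ("nsc" %in% config$stages) {
    curve <- stage("nsc", nsc_cross_validate(
      tumors, n_folds = config$nsc_folds,
      s0_percentile = config$nsc_offset,
      n_thresholds = config$nsc_thresholds, seed = config$seed))
    sel <- stage("nsc", nsc_select_threshold(curve, config$nsc_max_error))
    pred <- nsc_predict(curve$model, sel$threshold, tumors$values)
    ev <- evaluate_predictions(tumors$labels, pred$class)
    emit("nsc", data.frame(threshold = curve$threshold,
                           cv_error = curve$cv_error,
                           n_probes = curve$n_probes), "nsc_cv_curve.tsv")
    surv <- nsc_survivors(curve$model, sel$threshold)
    emit("nsc", data.frame(
      probe_id = curve$model$probe_ids[surv],
      curve$model$d[surv, , drop = FALSE]), "nsc_predictor.tsv")
    manifest$stages$nsc <- list(threshold = sel$threshold,
                                n_probes = sel$n_probes,
                                cv_error = sel$cv_error,
                                resubstitution_accuracy = ev$accuracy)
    results$nsc <- list(curve = curve, selection = sel, evaluation = ev)
  }
  if ("cgma" %in% config$stages && !is.null(normals) && !is.null(ann)) {
    rel <- stage("cgma", relative_expression(tumors, normals))
    bias <- stage("cgma", regional_bias(rel, ann, config$cgma_z,
                                        config$cgma_min_genes))
    summ <- cohort_bias_summary(bias, tumors$labels)
    emit("cgma", as.data.frame(bias), "cgma_bias.tsv")
    emit("cgma", summ, "cgma_cohort_summary.tsv")
    manifest$stages$cgma <- list(n_calls = sum(bias$call != "neutral"))
    results$cgma <- list(bias = bias, summary = summ)
  }
  if ("cnv" %in% config$stages) {
    if (is.null(config$cn_path)) {
      cn_sim <- stage("simulate", simulate_cn(config$simulation, config$seed))
      cn <- cn_sim$cn; snp_ann <- cn_sim$annotation
    } else {
      cn <- stage("read", read_cn_matrix(config$cn_path,
                                         config$cn_cohorts_path))
      snp_ann <- stage("read",
                       read_snp_annotation(config$snp_annotation_path))
    }
    calls <- stage("cnv", call_cn_segments(cn, snp_ann, config$cnv_loss_cut,
                                           config$cnv_gain_cut,
                                           config$cnv_min_run))
    emit("cnv", as.data.frame(calls), "cn_calls.tsv")
    write_cn_calls_bed(calls, file.path(config$out_dir, "cn_calls.bed"))
    manifest$files[["cn_calls.bed"]] <- list(
      md5 = unname(tools::md5sum(file.path(config$out_dir, "cn_calls.bed"))),
      rows = nrow(calls))
    all_regions <- list()
    for (coh in levels(cn$cohort)) {
      members <- names(cn$cohort)[cn$cohort == coh]
      rg <- stage("cnv", cna_regions(calls, members, snp_ann,
                                     config$cnv_min_fraction,
                                     config$cnv_min_run))
      rg$cohort <- if (nrow(rg)) coh else character(0)
      all_regions[[coh]] <- rg
    }
    regions <- do.call(rbind, all_regions)
    emit("cnv", as.data.frame(regions), "cna_regions.tsv")
    manifest$stages$cnv <- list(n_calls = nrow(calls),
                                n_regions = nrow(regions))
    results$cnv <- list(calls = calls, regions = regions,
                        annotation = snp_ann)
  }
  if ("enrichment" %in% config$stages && !is.null(config$gene_sets_path) &&
      !is.null(sam_calls) && !is.null(ann)) {
    gs <- stage("enrichment", read_gene_sets_gmt(config$gene_sets_path))
    sel_genes <- unique(ann$gene_symbol[match(sam_calls$called$probe_id,
                                              ann$probe_id)])
    uni <- unique(ann$gene_symbol)
    enr <- stage("enrichment",
                 enrich_collection(sel_genes, gs, uni, config$enrich_p))
    emit("enrichment", enr, "enrichment.tsv")
    manifest$stages$enrichment <- list(n_significant = nrow(enr))
    results$enrichment <- enr
  }
  if ("exact_tests" %in% config$stages) {
    tabs <- if (is.null(config$contingency_path)) ihc_marker_tables()
            else stage("read", read_contingency_tables(config$contingency_path))
    ihc <- stage("exact_tests", ihc_batch(tabs))
    emit("exact_tests", ihc, "exact_tests.tsv")
    manifest$stages$exact_tests <- list(n_markers = nrow(ihc))
    results$exact_tests <- ihc
  }
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_to_json(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_json))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

config_to_json <- function(config) {
  cfg <- unclass(config)
  cfg$simulation <- unclass(cfg$simulation)
  cfg$filter <- unclass(cfg$filter)
  cfg
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Fields mirror [pipeline_config()] arguments; unknown fields error.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `PipelineConfig`.
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), c(known, "simulation", "filter"))
  if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "))
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulation_config, raw$simulation)
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_spec, raw$filter)
  do.call(pipeline_config, raw)
}
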