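# Hypergeometric over-representation tests for gene-set collections, with
# odds ratio and expected count, plus DAG-conditional testing in which a
# significant child term's genes are removed from its ancestors before
# those are tested.

#' Hypergeometric over-representation test for one gene set
#'
#' With universe size `U`, set size within the universe `m`, selected size
#' `s` and overlap `k`: `p = P(X >= k)` for `X ~ hypergeometric(U, m, s)`
#' (upper tail), expected count `s * m / U`, and the sample odds ratio
#' `(k / (s - k)) / ((m - k) / (U - m - s + k))` (reported as `Inf` when a
#' denominator cell is 0).
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param set Character vector of the gene set's members (intersected with
#'   the universe first).
#' @param universe Character vector of background genes.
#' @return List of class `EnrichmentResult` with `p`, `odds_ratio`,
#'   `expected`, `observed`, `size`, `universe_size`, `selected_size`.
#' @export
hypergeometric_test <- function(selected, set, universe) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside))
    stop("selected gene(s) absent from universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  set <- intersect(unique(as.character(set)), universe)
  U <- length(universe); m <- length(set); s <- length(selected)
  k <- length(intersect(selected, set))
  p <- stats::phyper(k - 1, m, U - m, s, lower.tail = FALSE)
  expected <- s * m / U
  num_a <- k; num_b <- s - k; den_a <- m - k; den_b <- U - m - s + k
  odds <- if (num_b == 0 || den_a == 0) {
    if (num_a == 0) NaN else Inf
  } else (num_a / num_b) / (den_a / den_b)
  structure(list(p = p, odds_ratio = odds, expected = expected,
                 observed = k, size = m, universe_size = U,
                 selected_size = s),
            class = "EnrichmentResult")
}

enrich_one_row <- function(id, desc, res) {
  data.frame(set_id = id, term = desc, p = res$p,
             odds_ratio = res$odds_ratio, expected = res$expected,
             observed = res$observed, size = res$size,
             stringsAsFactors = FALSE)
}

# GOstats-style default universe: array genes carrying at least one
# annotation in the tested collection.
restrict_universe <- function(universe, collection, annotated_only) {
  universe <- unique(as.character(universe))
  if (annotated_only)
    universe <- intersect(universe, unique(unlist(collection$sets)))
  universe
}

#' Test every set of a collection for over-representation
#'
#' Selected genes falling outside the (possibly annotation-restricted)
#' universe are dropped with a message before testing. A Benjamini-Hochberg
#' column (`p_bh`) is reported for reference but never used for filtering.
#'
#' @param selected Character vector of selected genes.
#' @param collection A [gene_set_collection()].
#' @param universe Background genes (typically all genes on the array).
#' @param p_threshold Report sets with `p < p_threshold` (default 1 keeps
#'   all).
#' @param annotated_only Restrict the universe to genes carrying at least
#'   one annotation in the collection (default `TRUE`, the conventional
#'   behavior); `FALSE` uses `universe` as given.
#' @return Data frame with columns `set_id`, `term`, `p`, `odds_ratio`,
#'   `expected`, `observed`, `size`, `p_bh`, sorted by `p` then `set_id`.
#' @export
enrich_collection <- function(selected, collection, universe,
                              p_threshold = 1, annotated_only = TRUE) {
  universe <- restrict_universe(universe, collection, annotated_only)
  selected <- unique(as.character(selected))
  dropped <- setdiff(selected, universe)
  if (length(dropped)) {
    message(length(dropped), " selected gene(s) outside the universe dropped")
    selected <- intersect(selected, universe)
  }
  rows <- lapply(names(collection$sets), function(id) {
    res <- hypergeometric_test(selected, collection$sets[[id]], universe)
    enrich_one_row(id, collection$description[[id]], res)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(0), term = character(0), p = numeric(0),
               odds_ratio = numeric(0), expected = numeric(0),
               observed = integer(0), size = integer(0))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[out$p < p_threshold, , drop = FALSE]
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DAG-conditional over-representation testing
#'
#' Terms are processed children-before-parents (reverse topological order
#' of the collection's parent-to-child relations). When a term tests
#' significant (`p < p_threshold`), its current member genes are removed
#' from the sets of all its ancestors before those are tested, so a parent
#' whose signal is entirely inherited from a significant child no longer
#' appears significant. With no relations this reduces exactly to
#' [enrich_collection()].
#'
#' @inheritParams enrich_collection
#' @param p_threshold Significance threshold driving both the conditioning
#'   and the reported filter (default 0.001).
#' @param filter Return only terms with `p < p_threshold` (default `TRUE`).
#' @return Data frame as [enrich_collection()], conditional p-values.
#' @export
conditional_enrich <- function(selected, collection, universe,
                               p_threshold = 0.001, annotated_only = TRUE,
                               filter = TRUE) {
  universe <- restrict_universe(universe, collection, annotated_only)
  selected <- unique(as.character(selected))
  dropped <- setdiff(selected, universe)
  if (length(dropped)) {
    message(length(dropped), " selected gene(s) outside the universe dropped")
    selected <- intersect(selected, universe)
  }
  ids <- names(collection$sets)
  rel <- collection$relations
  order_cp <- if (is.null(rel) || !nrow(rel)) ids
              else topological_order(ids, rel)   # parents before children
  eval_order <- rev(order_cp)                    # children before parents
  parents_of <- if (!is.null(rel)) split(rel$parent, rel$child) else list()
  ancestors <- function(id) {
    seen <- character(0); frontier <- id
    while (length(frontier)) {
      ps <- unique(unlist(parents_of[frontier]))
      ps <- setdiff(ps, seen)
      seen <- c(seen, ps); frontier <- ps
    }
    seen
  }
  sets <- collection$sets
  rows <- list()
  for (id in eval_order) {
    res <- hypergeometric_test(selected, sets[[id]], universe)
    rows[[id]] <- enrich_one_row(id, collection$description[[id]], res)
    if (res$p < p_threshold) {
      for (anc in ancestors(id))
        sets[[anc]] <- setdiff(sets[[anc]], sets[[id]])
    }
  }
  out <- do.call(rbind, rows[ids])
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  if (filter) out <- out[out$p < p_threshold, , drop = FALSE]
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
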