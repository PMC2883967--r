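# Two-class unpaired SAM-style differential expression with permutation
# false discovery rates: a moderated t-like statistic d_i with an
# exchangeability constant s0, expected order statistics from label
# permutations, and the asymmetric delta calling rule.

sam_group_stats <- function(v, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(v[, idx1, drop = FALSE])
  m2 <- rowMeans(v[, idx2, drop = FALSE])
  var1 <- rowSums((v[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  var2 <- rowSums((v[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  s <- sqrt(var1 / n1 + var2 / n2)  # unequal-variance (Welch) form
  list(m1 = m1, m2 = m2, s = s)
}

sam_pooled_scale <- function(v, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(v[, idx1, drop = FALSE])
  m2 <- rowMeans(v[, idx2, drop = FALSE])
  ss <- rowSums((v[, idx1, drop = FALSE] - m1)^2) +
    rowSums((v[, idx2, drop = FALSE] - m2)^2)
  sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
}

sam_classes <- function(labels, class2 = NULL) {
  labels <- as.factor(labels)
  lev <- sort(levels(labels))
  if (length(lev) != 2) stop("SAM requires exactly two classes")
  if (is.null(class2)) class2 <- lev[2]  # lexicographically larger label
  if (!class2 %in% lev) stop("unknown class: ", class2)
  class1 <- setdiff(lev, class2)
  tab <- table(labels)
  if (any(tab < 2)) stop("each class needs at least 2 samples")
  list(class1 = class1, class2 = class2,
       idx1 = which(labels == class1), idx2 = which(labels == class2))
}

#' SAM d statistic
#'
#' `d_i = (mean2_i - mean1_i) / (s_i + s0)` with the unequal-variance scale
#' `s_i = sqrt(var1_i/n1 + var2_i/n2)` (unbiased variances); class 2 is the
#' lexicographically larger label unless overridden. A classic
#' pooled-variance scale is available via `variance = "pooled"`.
#'
#' @param x An [expression_matrix()] with two-class labels, or a numeric
#'   matrix (then `labels` is required).
#' @param labels Two-class labels (defaults to `x$labels`).
#' @param s0 Exchangeability constant (>= 0).
#' @param class2 Label treated as class 2 (numerator `mean2 - mean1`).
#' @param variance `"unequal"` (default) or `"pooled"`.
#' @return List with named per-probe vectors `d` and `s`.
#' @export
sam_statistic <- function(x, labels = NULL, s0 = 0, class2 = NULL,
                          variance = c("unequal", "pooled")) {
  variance <- match.arg(variance)
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "ExpressionMatrix")) labels <- x$labels
  if (s0 < 0) stop("s0 must be >= 0")
  cl <- sam_classes(labels, class2)
  st <- sam_group_stats(v, cl$idx1, cl$idx2)
  s <- if (variance == "pooled") sam_pooled_scale(v, cl$idx1, cl$idx2) else st$s
  list(d = (st$m2 - st$m1) / (s + s0), s = s,
       class1 = cl$class1, class2 = cl$class2)
}

#' Estimate the SAM exchangeability constant s0
#'
#' Tusher-style selection: candidate s0 values are the percentiles
#' 0, 5, ..., 100 of the per-probe scales `s_i`; for each candidate the
#' probes are windowed by `s_i` quantiles, the median absolute deviation of
#' `d` is computed per window, and the candidate minimizing the coefficient
#' of variation of those MADs is chosen (ties to the lowest percentile).
#' A fixed-percentile override bypasses the search.
#'
#' @inheritParams sam_statistic
#' @param percentile Optional fixed percentile (0-100) of `s_i`; when given,
#'   `s0 = quantile(s, percentile/100)` directly.
#' @param n_windows Number of `s_i`-quantile windows for the dispersion
#'   criterion.
#' @return The chosen s0 (numeric scalar) with attribute `"percentile"`.
#' @export
estimate_s0 <- function(x, labels = NULL, percentile = NULL, n_windows = 100,
                        variance = c("unequal", "pooled")) {
  variance <- match.arg(variance)
  base <- sam_statistic(x, labels, s0 = 0, variance = variance)
  s <- base$s
  if (!is.null(percentile)) {
    s0 <- unname(stats::quantile(s, percentile / 100, type = 7))
    return(structure(s0, percentile = percentile))
  }
  pcts <- seq(0, 100, by = 5)
  cand <- unname(stats::quantile(s, pcts / 100, type = 7))
  nw <- max(2L, min(as.integer(n_windows), floor(length(s) / 2)))
  win <- cut(rank(s, ties.method = "first"),
             breaks = nw, labels = FALSE, include.lowest = TRUE)
  num <- base$d * (s + 0)  # numerator mean difference, reused per candidate
  cvs <- vapply(cand, function(a) {
    d_a <- num / (s + a)
    mads <- tapply(d_a, win, stats::mad)
    mads <- mads[is.finite(mads)]
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(mads) / m
  }, 0)
  if (all(!is.finite(cvs))) {
    best <- 1L  # degenerate: all scales equal; lowest percentile by tie-break
  } else best <- which.min(cvs)
  structure(cand[best], percentile = pcts[best])
}

#' Fit a SAM analysis with label permutations
#'
#' Computes the observed statistics and, over `n_perm` label permutations,
#' the expected order statistics `dbar_(i)` (mean of the i-th sorted
#' permuted d). All distinct label assignments are enumerated when their
#' number is at most `n_perm`; otherwise permutations are sampled uniformly
#' with replacement. Deterministic given `seed`.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for permutation sampling.
#' @param s0 Exchangeability constant; `NULL` (default) estimates it with
#'   [estimate_s0()] on the observed labels and reuses it for every
#'   permutation.
#' @return An object of class `SamFit` with the observed `d`, `s`, `s0`,
#'   sorted observed statistics, `dbar`, the per-permutation sorted
#'   statistics, the permutation count and whether enumeration was used.
#' @export
sam_fit <- function(x, labels = NULL, n_perm = 1000, seed = 1, s0 = NULL,
                    class2 = NULL, variance = c("unequal", "pooled")) {
  variance <- match.arg(variance)
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "ExpressionMatrix")) labels <- x$labels
  if (n_perm < 1) stop("n_perm must be >= 1")
  cl <- sam_classes(labels, class2)
  if (is.null(s0))
    s0 <- as.numeric(estimate_s0(x, labels, variance = variance))
  obs <- sam_statistic(x, labels, s0 = s0, class2 = class2, variance = variance)
  n <- ncol(v); n1 <- length(cl$idx1)
  n_distinct <- choose(n, n1)
  enumerated <- is.finite(n_distinct) && n_distinct <= n_perm
  stat_for <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    st <- sam_group_stats(v, idx1, idx2)
    s <- if (variance == "pooled") sam_pooled_scale(v, idx1, idx2) else st$s
    (st$m2 - st$m1) / (s + s0)
  }
  if (enumerated) {
    combos <- utils::combn(n, n1)
    perm_sorted <- apply(combos, 2, function(i1) sort(stat_for(i1)))
    B <- ncol(combos)
  } else {
    set.seed(as.integer(seed))
    B <- as.integer(n_perm)
    perm_sorted <- vapply(seq_len(B), function(b) {
      sort(stat_for(sample.int(n, n1)))
    }, numeric(nrow(v)))
  }
  structure(list(
    d = obs$d, s = obs$s, s0 = s0,
    d_sorted = sort(obs$d), dbar = rowMeans(perm_sorted),
    perm_sorted = perm_sorted, n_perm = B, enumerated = enumerated,
    seed = seed, class1 = obs$class1, class2 = obs$class2),
    class = "SamFit")
}

#' @export
print.SamFit <- function(x, ...) {
  cat(sprintf("SamFit: %d probes, s0 = %.4g, %d permutations (%s)\n",
              length(x$d), x$s0, x$n_perm,
              if (x$enumerated) "enumerated" else "sampled"))
  invisible(x)
}

#' Call differentially expressed probes at a delta threshold
#'
#' Asymmetric rule: the upper cut is the smallest sorted observed statistic
#' with `d_(i) - dbar_(i) >= delta` and the lower cut the largest with
#' `dbar_(i) - d_(i) >= delta`; probes beyond the cuts are called. False
#' calls are the median (optionally mean) across permutations of permuted
#' statistics beyond the same cuts; FDR = pi0 * false calls / called with
#' pi0 fixed at 1 by default (conservative).
#'
#' @param fit A [sam_fit()] result.
#' @param delta Nonnegative calling threshold.
#' @param pi0 Proportion of truly null probes assumed in the FDR (default 1).
#' @param false_call_summary `"median"` (default) or `"mean"` across
#'   permutations.
#' @return An object of class `SamCall`: the cuts, a data frame of called
#'   probes with direction (`"up"` = higher in class 2), the estimated
#'   number of false calls and the estimated FDR (reported as 0 with
#'   `zero_called = TRUE` when nothing is called).
#' @export
sam_call <- function(fit, delta, pi0 = 1,
                     false_call_summary = c("median", "mean")) {
  false_call_summary <- match.arg(false_call_summary)
  if (delta < 0) stop("delta must be >= 0")
  diffs <- fit$d_sorted - fit$dbar
  p <- length(diffs)
  # scan outward from the origin (where the expected order statistics cross
  # zero): first index above with d - dbar >= delta sets the upper cut,
  # first index below with dbar - d >= delta sets the lower cut
  origin <- if (any(fit$dbar >= 0)) which(fit$dbar >= 0)[1] else p + 1L
  up_idx <- which(seq_len(p) >= origin & diffs >= delta)
  lo_idx <- which(seq_len(p) < origin & -diffs >= delta)
  cut_up <- if (length(up_idx)) fit$d_sorted[up_idx[1]] else Inf
  cut_low <- if (length(lo_idx)) fit$d_sorted[lo_idx[length(lo_idx)]] else -Inf
  called_up <- fit$d >= cut_up
  called_down <- fit$d <= cut_low
  called <- called_up | called_down
  per_perm <- colSums(fit$perm_sorted >= cut_up) +
    colSums(fit$perm_sorted <= cut_low)
  false_calls <- if (false_call_summary == "median") stats::median(per_perm)
                 else mean(per_perm)
  n_called <- sum(called)
  fdr <- if (n_called == 0) 0 else min(1, pi0 * false_calls / n_called)
  calls <- data.frame(
    probe_id = names(fit$d)[called], d = unname(fit$d[called]),
    direction = ifelse(fit$d[called] >= cut_up, "up", "down"),
    stringsAsFactors = FALSE)
  calls <- calls[order(-abs(calls$d)), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(delta = delta, cut_up = cut_up, cut_low = cut_low,
                 called = calls, n_called = n_called,
                 false_calls = false_calls, fdr = fdr,
                 zero_called = n_called == 0),
            class = "SamCall")
}

#' @export
print.SamCall <- function(x, ...) {
  cat(sprintf("SamCall: delta = %.3g, called = %d (FDR = %.4g, false calls = %.3g)\n",
              x$delta, x$n_called, x$fdr, x$false_calls))
  invisible(x)
}

#' Tabulate SAM calls over a delta grid
#'
#' @param fit A [sam_fit()] result.
#' @param deltas Numeric vector of thresholds; defaults to an even grid from
#'   0 to the largest deviation `|d_(i) - dbar_(i)|`.
#' @param n_grid Grid size when `deltas` is `NULL`.
#' @inheritParams sam_call
#' @return Data frame with columns `delta`, `called`, `false_calls`, `fdr`.
#' @export
sam_delta_table <- function(fit, deltas = NULL, n_grid = 50, pi0 = 1) {
  if (is.null(deltas))
    deltas <- seq(0, max(abs(fit$d_sorted - fit$dbar)), length.out = n_grid)
  rows <- lapply(deltas, function(dl) {
    cc <- sam_call(fit, dl, pi0 = pi0)
    data.frame(delta = dl, called = cc$n_called,
               false_calls = cc$false_calls, fdr = cc$fdr)
  })
  do.call(rbind, rows)
}

#' Choose the smallest delta with estimated FDR at or below a ceiling
#'
#' Implements the "maximum FDR threshold" decision: among grid deltas whose
#' estimated FDR is `<= max_fdr`, return the smallest (maximizing the called
#' set subject to the FDR ceiling).
#'
#' @inheritParams sam_delta_table
#' @param max_fdr FDR ceiling (default 0.05).
#' @return The chosen delta (numeric scalar), with the grid table attached
#'   as attribute `"table"`.
#' @export
sam_select_delta <- function(fit, max_fdr = 0.05, deltas = NULL, n_grid = 50,
                             pi0 = 1) {
  tab <- sam_delta_table(fit, deltas, n_grid, pi0)
  ok <- tab$fdr <= max_fdr & tab$called > 0
  if (!any(ok)) {
    delta <- tab$delta[nrow(tab)]  # nothing callable under the ceiling
  } else delta <- min(tab$delta[ok])
  structure(delta, table = tab)
}

#' Per-probe linear-scale fold change between the two classes
#'
#' `FC_i = 2^(mean log2 in class 1 - mean log2 in class 2)`; with the
#' default lexicographic orientation class 1 is chRCC when the labels are
#' chRCC/oncocytoma, so `FC < 1` means lower expression in chRCC.
#'
#' @inheritParams sam_statistic
#' @param class1 Label treated as the numerator class (default: the
#'   lexicographically smaller label).
#' @return Named numeric vector of per-probe fold changes (linear scale).
#' @export
fold_changes <- function(x, labels = NULL, class1 = NULL) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "ExpressionMatrix")) labels <- x$labels
  labels <- as.factor(labels)
  lev <- sort(levels(labels))
  if (length(lev) != 2) stop("fold changes require exactly two classes")
  if (is.null(class1)) class1 <- lev[1]
  if (!class1 %in% lev) stop("unknown class: ", class1)
  class2 <- setdiff(lev, class1)
  m1 <- rowMeans(v[, labels == class1, drop = FALSE])
  m2 <- rowMeans(v[, labels == class2, drop = FALSE])
  2^(m1 - m2)
}
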