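# Two-sided exact tests on 2x2 marker contingency tables (the
# immunohistochemistry discrimination analysis), by the point-probability
# convention: sum the hypergeometric probabilities of all tables with the
# observed margins that are no more probable than the observed one.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' With margins fixed, the support of the first cell is enumerated, its
#' hypergeometric point probabilities computed, and
#' `p = sum of probabilities <= observed probability * (1 + 1e-7)` (the
#' relative tolerance guards the comparison of mathematically equal
#' probabilities computed by different floating-point paths).
#'
#' @param table A [contingency_2x2()] (or any 2x2 nonnegative integer
#'   matrix; rows = groups, columns = positive/negative).
#' @return An object of class `ExactTestResult`: `p` (two-sided),
#'   `odds_ratio` (sample odds ratio `ad/bc`; `Inf` when `bc = 0` and
#'   `ad > 0`, `NaN` for 0/0), and the table echo.
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(unclass(table))
  if (!all(dim(m) == c(2, 2))) stop("a 2x2 table is required")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers")
  if (sum(m) <= 0) stop("table total must be positive")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  odds <- if (b * c_ == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c_)
  structure(list(p = p, odds_ratio = odds, table = m),
            class = "ExactTestResult")
}

#' @export
print.ExactTestResult <- function(x, ...) {
  cat(sprintf("Two-sided exact test: p = %.6g, odds ratio = %.4g\n",
              x$p, x$odds_ratio))
  invisible(x)
}

# Table 4-style presentation: three decimals below 0.01, two otherwise.
round_presentation <- function(p) {
  ifelse(round(p, 2) < 0.01, round(p, 3), round(p, 2))
}

#' Batch exact tests over named marker tables
#'
#' @param tables Named list of 2x2 tables ([contingency_2x2()] or plain
#'   matrices); rows are chRCC / oncocytoma, columns positive / negative.
#' @return Data frame with per-marker counts, the full-precision two-sided
#'   `p`, the presentation-precision `p_rounded` (two decimals, three below
#'   0.01) and the sample odds ratio.
#' @export
ihc_batch <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be named by marker")
  rows <- lapply(names(tables), function(mk) {
    res <- fisher_exact_two_sided(tables[[mk]])
    m <- res$table
    data.frame(marker = mk, a = m[1, 1], b = m[1, 2], c = m[2, 1],
               d = m[2, 2], p = res$p, p_rounded = round_presentation(res$p),
               odds_ratio = res$odds_ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled immunohistochemistry marker counts
#'
#' Staining counts for candidate discriminating markers on an independent
#' renal tumor cohort (11 chromophobe RCC vs 7 oncocytomas; the
#' phospho-AKT rows come from a larger 22 vs 8 cohort). Rows of each 2x2
#' table are chRCC / oncocytoma, columns positive / negative.
#'
#' @return Named list of [contingency_2x2()] tables (AQP6, Parafibromin,
#'   CK7, SYNGR3, p-AKT stromal and tumor compartments).
#' @export
ihc_marker_tables <- function() {
  path <- system.file("extdata", "ihc_marker_counts.tsv", package = "renaldx",
                      mustWork = TRUE)
  read_contingency_tables(path)
}
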