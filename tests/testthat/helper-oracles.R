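# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# Two-sided exact p by full enumeration over tables with the observed
# margins, using ratios of choose() only.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, 0)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct combinatorial summation.
oracle_hyper_tail <- function(U, m, s, k) {
  hi <- min(m, s)
  if (k > hi) return(0)
  xs <- max(k, max(0, s - (U - m))):hi
  sum(vapply(xs, function(x) {
    choose(m, x) * choose(U - m, s - x) / choose(U, s)
  }, 0))
}

# NSC discriminant by explicit loops over probes and classes.
oracle_nsc_scores <- function(model, threshold, xvec) {
  K <- length(model$classes)
  out <- numeric(K)
  for (k in seq_len(K)) {
    acc <- 0
    for (i in seq_along(model$probe_ids)) {
      dik <- model$d[i, k]
      dprime <- sign(dik) * max(abs(dik) - threshold, 0)
      survives <- any(abs(model$d[i, ]) > threshold)
      if (!survives) next
      cent <- model$xbar[i] + model$mk[k] * (model$s[i] + model$s0) * dprime
      acc <- acc + (xvec[i] - cent)^2 / (model$s[i] + model$s0)^2
    }
    out[k] <- acc - 2 * log(model$priors[k])
  }
  names(out) <- model$classes
  out
}

# Complete-linkage agglomeration by exhaustive search over merge
# candidates; returns merge heights in order.
oracle_complete_linkage_heights <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(dmat[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Small labelled expression fixture with named dimensions.
make_expr <- function(values, labels = NULL, probe_prefix = "p",
                      sample_prefix = "s") {
  values <- as.matrix(values)
  rownames(values) <- sprintf("%s%02d", probe_prefix, seq_len(nrow(values)))
  colnames(values) <- sprintf("%s%02d", sample_prefix, seq_len(ncol(values)))
  expression_matrix(values, labels)
}

# Null two-class matrix: pure Gaussian noise around a log2 baseline.
make_null_expr <- function(n_probes, n1, n2, sd = 0.5, baseline = 8) {
  v <- matrix(stats::rnorm(n_probes * (n1 + n2), baseline, sd), n_probes)
  make_expr(v, rep(c("A", "B"), c(n1, n2)))
}

# Minimal probe annotation placing probes consecutively on given arms.
make_annotation <- function(probe_ids, regions, genes = NULL) {
  chrom <- sub("[pq]$", "", regions)
  arm <- substr(regions, nchar(regions), nchar(regions))
  if (is.null(genes)) genes <- paste0("G_", probe_ids)
  probe_annotation(data.frame(
    probe_id = probe_ids, gene_symbol = genes, chromosome = chrom,
    arm = arm, cytoband = paste0(regions, "1"),
    position = stats::ave(seq_along(probe_ids), regions, FUN = seq_along) * 1e6 +
      ifelse(arm == "q", 6e7, 0),
    stringsAsFactors = FALSE))
}
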