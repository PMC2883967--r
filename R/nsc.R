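# Nearest-shrunken-centroid (PAM-style) classification with the
# cross-validated minimal-predictor selection rule: soft-thresholded
# standardized class-centroid deviations, a 100-point threshold grid, an
# offset s0 set at a percentile of the pooled within-class SDs, stratified
# 10-fold cross-validation, and selection of the smallest predictor whose
# CV misclassification error stays within a ceiling.

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

#' Train a nearest-shrunken-centroid model
#'
#' Per probe i and class k: pooled within-class SD `s_i` (divisor n - K),
#' offset `s0` = the `s0_percentile`-th percentile of the `s_i`, class scale
#' `m_k = sqrt(1/n_k - 1/n)`, raw score
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))`, and a threshold grid of
#' `n_thresholds` values equally spaced on `[0, max|d_ik|]` (both ends
#' included). Shrunken scores are the soft-thresholded `d_ik`.
#'
#' @param x An [expression_matrix()] with class labels, or a numeric matrix.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples).
#' @param s0_percentile Offset percentage: `s0` is this percentile of the
#'   pooled SDs (default 30).
#' @param n_thresholds Size of the threshold grid (default 100).
#' @param mk_form `"subtract"` (default, `sqrt(1/n_k - 1/n)`) or `"sum"`
#'   (`sqrt(1/n_k + 1/n)`).
#' @param priors Class prior probabilities (default: class frequencies).
#' @param s0 Optional fixed offset overriding the percentile rule.
#' @return An object of class `NscModel` holding centroids, scales, scores,
#'   the threshold grid and per-threshold surviving-probe counts.
#' @export
nsc_train <- function(x, labels = NULL, s0_percentile = 30,
                      n_thresholds = 100, mk_form = c("subtract", "sum"),
                      priors = NULL, s0 = NULL) {
  mk_form <- match.arg(mk_form)
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "ExpressionMatrix")) labels <- x$labels
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  K <- length(classes)
  if (K < 2) stop("need at least two classes")
  nk <- table(labels)
  if (any(nk < 2)) stop("each class needs at least 2 samples")
  n <- ncol(v)
  xbar <- rowMeans(v)
  cent <- vapply(classes, function(k) rowMeans(v[, labels == k, drop = FALSE]),
                 numeric(nrow(v)))
  cent <- matrix(cent, nrow(v), K, dimnames = list(rownames(v), classes))
  ss <- matrix(0, nrow(v), 1)
  for (k in classes)
    ss <- ss + rowSums((v[, labels == k, drop = FALSE] - cent[, k])^2)
  s <- sqrt(as.numeric(ss) / (n - K))
  if (is.null(s0))
    s0 <- unname(stats::quantile(s, s0_percentile / 100, type = 7))
  mk <- if (mk_form == "subtract") sqrt(1 / as.numeric(nk) - 1 / n)
        else sqrt(1 / as.numeric(nk) + 1 / n)
  names(mk) <- classes
  # centroid deviations as weighted pairwise class differences:
  # algebraically cent_k - xbar, but for balanced two-class data the IEEE
  # symmetry of subtraction then makes d_i1 = -d_i2 bit-exact
  dev <- matrix(0, nrow(v), K, dimnames = dimnames(cent))
  for (k in seq_len(K))
    for (j in seq_len(K))
      if (j != k) dev[, k] <- dev[, k] +
        (as.numeric(nk)[j] / n) * (cent[, k] - cent[, j])
  d <- sweep(dev, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  grid <- seq(0, max(abs(d)), length.out = n_thresholds)
  survivors <- vapply(grid, function(dl) sum(apply(abs(d) > dl, 1, any)), 0L)
  if (is.null(priors)) priors <- as.numeric(nk) / n
  names(priors) <- classes
  structure(list(
    probe_ids = rownames(v), classes = classes, n = n, nk = as.numeric(nk),
    xbar = xbar, centroids = cent, s = s, s0 = s0,
    s0_percentile = s0_percentile, mk = mk, d = d, grid = grid,
    survivors = survivors, priors = priors, mk_form = mk_form),
    class = "NscModel")
}

#' @export
print.NscModel <- function(x, ...) {
  cat(sprintf("NscModel: %d probes, classes %s, s0 = %.4g (%g%% offset)\n",
              length(x$probe_ids), paste(x$classes, collapse = "/"),
              x$s0, x$s0_percentile))
  invisible(x)
}

# Probes with any nonzero shrunken score at threshold delta.
nsc_survivors <- function(model, delta) {
  dprime <- soft_threshold(model$d, delta)
  which(rowSums(abs(dprime) > 0) > 0)
}

#' Classify samples with a trained NSC model at a threshold
#'
#' Discriminant per class:
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`,
#' summed over probes surviving the shrinkage at `threshold`, with shrunken
#' centroids `xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik`. The predicted class
#' minimizes the discriminant; ties break toward the larger prior, then
#' class order. With no surviving probes, classification is by prior alone.
#'
#' @param model An [nsc_train()] result.
#' @param threshold Shrinkage threshold.
#' @param newx Numeric matrix (probes x samples) or vector aligned to
#'   `model$probe_ids`; named rows are checked against the model.
#' @return List with `class` (factor of predictions) and `scores`
#'   (samples x classes discriminant matrix).
#' @export
nsc_predict <- function(model, threshold, newx) {
  if (inherits(newx, "ExpressionMatrix")) newx <- newx$values
  if (is.null(dim(newx))) newx <- matrix(newx, ncol = 1)
  if (!is.null(rownames(newx))) {
    if (!identical(rownames(newx), model$probe_ids)) {
      if (!setequal(rownames(newx), model$probe_ids))
        stop("probes of new data do not match the model")
      newx <- newx[model$probe_ids, , drop = FALSE]
    }
  } else if (nrow(newx) != length(model$probe_ids)) {
    stop("probes of new data do not match the model")
  }
  dprime <- soft_threshold(model$d, threshold)
  surv <- which(rowSums(abs(dprime) > 0) > 0)
  K <- length(model$classes)
  m <- ncol(newx)
  scores <- matrix(rep(-2 * log(model$priors), each = m), m, K,
                   dimnames = list(colnames(newx), model$classes))
  if (length(surv)) {
    denom <- (model$s + model$s0)[surv]
    for (k in seq_len(K)) {
      shrunk <- model$xbar[surv] + model$mk[k] * denom * dprime[surv, k]
      scores[, k] <- scores[, k] +
        colSums(((newx[surv, , drop = FALSE] - shrunk) / denom)^2)
    }
  }
  pred <- apply(scores, 1, function(sc) {
    best <- which(sc == min(sc))
    if (length(best) > 1) {
      pr <- model$priors[best]
      best <- best[pr == max(pr)][1]  # larger prior, then class order
    }
    model$classes[best]
  })
  list(class = factor(pred, levels = model$classes), scores = scores)
}

#' Cross-validate an NSC model over its threshold grid
#'
#' Stratified, seeded folds; within each fold the model (including `s0` and
#' the threshold grid) is re-trained on the remaining samples, and held-out
#' samples are scored at every one of the `n_thresholds` shared grid
#' positions (the fold grid spans `[0, max|d_ik|]` of the training split, so
#' position g corresponds to the same grid quantile across folds).
#'
#' @inheritParams nsc_train
#' @param n_folds Number of CV folds (reduced with a warning when a class
#'   has fewer samples).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `CvCurve`: per grid position the pooled CV
#'   misclassification error, the full-data model's surviving-probe count
#'   and the mean training-fold survivor count; plus the fold assignment,
#'   the full-data model and the seed.
#' @export
nsc_cross_validate <- function(x, labels = NULL, n_folds = 10,
                               s0_percentile = 30, n_thresholds = 100,
                               seed = 1, mk_form = c("subtract", "sum")) {
  mk_form <- match.arg(mk_form)
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "ExpressionMatrix")) labels <- x$labels
  labels <- droplevels(as.factor(labels))
  nk <- table(labels)
  if (min(nk) < n_folds) {
    n_folds <- min(nk)
    warning("reducing folds to smallest class size: ", n_folds)
  }
  if (n_folds < 2) stop("cross-validation needs at least 2 folds")
  set.seed(as.integer(seed))
  fold <- integer(ncol(v))
  for (k in levels(labels)) {
    idx <- which(labels == k)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  full <- nsc_train(v, labels, s0_percentile, n_thresholds, mk_form)
  G <- n_thresholds
  wrong <- numeric(G)
  fold_surv <- matrix(0, n_folds, G)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < length(levels(labels)))
      stop("fold ", f, " would lose an entire class from training")
    mod <- nsc_train(v[, tr, drop = FALSE], labels[tr],
                     s0_percentile, n_thresholds, mk_form)
    fold_surv[f, ] <- mod$survivors
    test <- v[, !tr, drop = FALSE]
    truth <- labels[!tr]
    for (g in seq_len(G)) {
      pred <- nsc_predict(mod, mod$grid[g], test)$class
      wrong[g] <- wrong[g] + sum(as.character(pred) != as.character(truth))
    }
  }
  structure(list(threshold = full$grid, cv_error = wrong / ncol(v),
                 n_probes = full$survivors,
                 mean_fold_probes = colMeans(fold_surv),
                 fold = stats::setNames(fold, colnames(v)),
                 model = full, seed = seed),
            class = "CvCurve")
}

#' @export
print.CvCurve <- function(x, ...) {
  cat(sprintf("CvCurve: %d thresholds, min CV error %.3f\n",
              length(x$threshold), min(x$cv_error)))
  invisible(x)
}

#' Select the smallest predictor within an error ceiling
#'
#' Among thresholds whose CV misclassification error is at most
#' `max_error`, returns the one minimizing the surviving-probe count; ties
#' break toward the largest threshold. Errors with the minimum achieved CV
#' error attached when no threshold qualifies.
#'
#' @param curve A [nsc_cross_validate()] result (or any list with
#'   `threshold`, `cv_error`, `n_probes`).
#' @param max_error Maximum acceptable CV misclassification error
#'   (default 0.10).
#' @return List with `threshold`, `index`, `n_probes`, `cv_error`.
#' @export
nsc_select_threshold <- function(curve, max_error = 0.10) {
  if (!length(curve$threshold)) stop("empty CV curve")
  ok <- which(curve$cv_error <= max_error)
  if (!length(ok)) {
    min_err <- min(curve$cv_error)
    stop(sprintf(
      "no threshold meets the %.0f%% error ceiling (minimum achieved CV error: %.3f)",
      100 * max_error, min_err))
  }
  best_count <- min(curve$n_probes[ok])
  cand <- ok[curve$n_probes[ok] == best_count]
  idx <- cand[which.max(curve$threshold[cand])]
  list(threshold = curve$threshold[idx], index = idx,
       n_probes = curve$n_probes[idx], cv_error = curve$cv_error[idx])
}

#' Confusion matrix and accuracy of predicted labels
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels; every predicted label must be
#'   one of the declared true classes.
#' @return List with `confusion` (true x predicted table), `accuracy`,
#'   `n_correct`, `n`.
#' @export
evaluate_predictions <- function(truth, predicted) {
  truth <- as.factor(truth)
  if (length(truth) != length(predicted))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(as.character(predicted)), levels(truth))
  if (length(bad))
    stop("predicted label(s) outside declared classes: ",
         paste(bad, collapse = ", "))
  predicted <- factor(as.character(predicted), levels = levels(truth))
  confusion <- table(truth = truth, predicted = predicted)
  n_correct <- sum(diag(confusion))
  list(confusion = confusion, accuracy = n_correct / length(truth),
       n_correct = n_correct, n = length(truth))
}
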