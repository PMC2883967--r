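# Nearest-shrunken-centroid training, prediction, cross-validation and the
# minimal-predictor selection rule.

test_that("training matches the hand-computed one-probe example", {
  x <- make_expr(matrix(c(0, 2, 4, 6), 1), rep(c("A", "B"), each = 2))
  m <- nsc_train(x, s0 = 0)
  expect_equal(m$s, sqrt(2), tolerance = 1e-4)
  expect_equal(unname(m$mk), rep(0.5, 2))
  expect_equal(unname(m$d[1, ]), c(-2.8284, 2.8284), tolerance = 1e-4)
  dprime <- renaldx:::soft_threshold(m$d, 1)
  expect_equal(unname(dprime[1, ]), c(-1.8284, 1.8284), tolerance = 1e-4)
})

test_that("balanced two-class scores are exactly antisymmetric", {
  set.seed(4)
  for (rep in 1:3) {
    x <- make_null_expr(40, 8, 8)
    m <- nsc_train(x)
    expect_identical(m$d[, 1], -m$d[, 2])
  }
})

test_that("shrinkage empties the predictor at the grid maximum", {
  set.seed(5)
  x <- make_null_expr(30, 5, 5)
  m <- nsc_train(x)
  expect_identical(m$survivors[length(m$survivors)], 0L)
  expect_true(all(diff(m$survivors) <= 0))
})

test_that("prediction falls back to priors under full shrinkage", {
  set.seed(6)
  x <- make_expr(matrix(rnorm(20 * 7, 8), 20), c(rep("A", 4), rep("B", 3)))
  m <- nsc_train(x)
  beyond <- max(m$grid) + 1
  pred <- nsc_predict(m, beyond, x$values)
  expect_true(all(pred$class == "A"))  # the larger prior class
})

test_that("a class's shrunken centroid is classified into that class", {
  set.seed(7)
  x <- make_null_expr(25, 6, 6)
  m <- nsc_train(x, priors = c(0.5, 0.5))
  delta <- m$grid[10]
  dprime <- renaldx:::soft_threshold(m$d, delta)
  for (k in 1:2) {
    cent <- m$xbar + m$mk[k] * (m$s + m$s0) * dprime[, k]
    pred <- nsc_predict(m, delta, cent)
    expect_identical(as.character(pred$class), m$classes[k])
  }
})

test_that("discriminants equal a direct loop evaluation on random instances", {
  set.seed(8)
  for (rep in 1:5) {
    x <- make_expr(matrix(rnorm(5 * 9, 8, 1), 5), c(rep("A", 5), rep("B", 4)))
    m <- nsc_train(x)
    delta <- stats::runif(1, 0, max(m$grid))
    probe <- stats::rnorm(5, 8, 1)
    got <- nsc_predict(m, delta, probe)$scores
    expect_equal(got[1, ], oracle_nsc_scores(m, delta, probe),
                 tolerance = 1e-10)
  }
})

test_that("prediction rejects misaligned probes", {
  x <- make_null_expr(10, 4, 4)
  m <- nsc_train(x)
  bad <- x$values[1:8, ]
  expect_error(nsc_predict(m, 0, bad), "do not match")
})

test_that("cross-validation separates strong classes and is reproducible", {
  sim <- simulate_expression(
    simulation_config(n_probes = 200, n_genes = 100), seed = 14)
  cv1 <- nsc_cross_validate(sim$tumors, seed = 5, n_thresholds = 30)
  cv2 <- nsc_cross_validate(sim$tumors, seed = 5, n_thresholds = 30)
  expect_identical(cv1$cv_error, cv2$cv_error)
  expect_identical(cv1$fold, cv2$fold)
  expect_equal(min(cv1$cv_error), 0)
  expect_lte(cv1$cv_error[2], 0.05)  # small thresholds separate perfectly
})

test_that("label permutation drives CV error to chance", {
  set.seed(15)
  sim <- simulate_expression(
    simulation_config(n_probes = 150, n_genes = 80, arm_biases = NULL),
    seed = 15)
  perm_labels <- sample(as.character(sim$tumors$labels))
  names(perm_labels) <- names(sim$tumors$labels)
  x <- expression_matrix(sim$tumors$values, perm_labels)
  cv <- nsc_cross_validate(x, seed = 2, n_thresholds = 20)
  expect_gt(mean(cv$cv_error), 0.3)
  expect_lt(mean(cv$cv_error), 0.7)
})

test_that("fold handling warns on small classes and errors on empty folds", {
  x <- make_expr(matrix(rnorm(20 * 9, 8), 20), c(rep("A", 4), rep("B", 5)))
  expect_warning(nsc_cross_validate(x, n_folds = 10, seed = 1,
                                    n_thresholds = 10),
                 "reducing folds")
})

test_that("the selection rule returns the smallest qualifying predictor", {
  curve <- list(threshold = c(0.5, 1.0, 1.5, 2.0),
                cv_error = c(0.20, 0.08, 0.05, 0.12),
                n_probes = c(500L, 40L, 14L, 6L))
  sel <- nsc_select_threshold(curve, max_error = 0.10)
  # the 6-probe threshold fails the error bound; 14 is the smallest allowed
  expect_identical(sel$n_probes, 14L)
  expect_identical(sel$threshold, 1.5)

  all_bad <- list(threshold = 1:3, cv_error = c(0.3, 0.2, 0.4),
                  n_probes = c(9L, 5L, 2L))
  expect_error(nsc_select_threshold(all_bad), "0.200")

  tie <- list(threshold = c(1, 2, 3), cv_error = c(0.05, 0.05, 0.5),
              n_probes = c(10L, 10L, 1L))
  expect_identical(nsc_select_threshold(tie)$threshold, 2)
})

test_that("the selected predictor consists of truly discriminative probes", {
  # at a 4-sd effect the error curve never exceeds 10% until the predictor
  # is almost empty, so the minimal rule returns a small predictor; that
  # predictor must be drawn entirely from the injected probes, and a
  # threshold between the null and injected score bands recovers the
  # injected set exactly
  sim <- simulate_expression(
    simulation_config(n_probes = 200, n_genes = 100, arm_biases = NULL),
    seed = 16)
  cv <- nsc_cross_validate(sim$tumors, seed = 16)
  sel <- nsc_select_threshold(cv, max_error = 0.10)
  expect_lte(sel$cv_error, 0.10)
  chosen <- cv$model$probe_ids[renaldx:::nsc_survivors(cv$model, sel$threshold)]
  truth <- sim$truth$discriminative$probe_id
  expect_true(all(chosen %in% truth))

  null_scores <- apply(abs(cv$model$d[setdiff(cv$model$probe_ids, truth), ]),
                       1, max)
  true_scores <- apply(abs(cv$model$d[truth, ]), 1, max)
  mid <- (max(null_scores) + min(true_scores)) / 2
  expect_gt(min(true_scores), max(null_scores))
  recovered <- cv$model$probe_ids[renaldx:::nsc_survivors(cv$model, mid)]
  expect_setequal(recovered, truth)
})

test_that("confusion-matrix arithmetic reproduces the headline accuracies", {
  truth <- rep(c("chRCC", "oncocytoma"), each = 15)
  pred <- truth
  pred[1:2] <- "oncocytoma"  # 13/15 + 15/15 correct
  ev <- evaluate_predictions(truth, pred)
  expect_identical(ev$n_correct, 28L)
  expect_equal(ev$accuracy, 28 / 30)
  expect_identical(round(100 * ev$accuracy), 93)

  truth2 <- rep(c("chRCC", "oncocytoma"), c(9, 9))
  pred2 <- truth2
  pred2[1] <- "oncocytoma"  # 8/9 + 9/9 correct
  ev2 <- evaluate_predictions(truth2, pred2)
  expect_identical(ev2$n_correct, 17L)
  expect_identical(round(100 * ev2$accuracy), 94)

  expect_equal(evaluate_predictions(truth, truth)$accuracy, 1)
  expect_error(evaluate_predictions(truth, rep("other", 30)),
               "outside declared classes")
})
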