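# Hypergeometric over-representation with odds ratio / expected count, and
# DAG-conditional testing.

test_that("tail probabilities match exact combinatorial values", {
  uni <- sprintf("g%02d", 1:10)
  res <- hypergeometric_test(uni[1:5], uni[1:5], uni)
  expect_equal(res$p, 1 / choose(10, 5))       # = 1/252
  expect_equal(res$p, 0.003968, tolerance = 1e-4)
  expect_identical(res$observed, 5L)
  expect_identical(res$odds_ratio, Inf)

  # zero overlap: P(X >= 0) = 1
  res0 <- hypergeometric_test(uni[1:3], uni[8:10], uni)
  expect_equal(res0$p, oracle_hyper_tail(10, 3, 3, 0))
  expect_equal(res0$p, 1)
})

test_that("expected counts follow s*m/U", {
  uni <- sprintf("g%04d", 1:1000)
  res <- hypergeometric_test(uni[1:100], uni[51:164], uni)
  expect_equal(res$expected, 100 * 114 / 1000)  # = 11.4
  expect_identical(res$size, 114L)
})

test_that("the pmf sums to one and the tail is monotone in the overlap", {
  set.seed(31)
  for (rep in 1:20) {
    U <- sample(5:60, 1); m <- sample(0:U, 1); s <- sample(0:U, 1)
    support <- max(0, s - (U - m)):min(m, s)
    expect_equal(sum(stats::dhyper(support, m, U - m, s)), 1,
                 tolerance = 1e-12)
    tails <- stats::phyper(support - 1, m, U - m, s, lower.tail = FALSE)
    expect_true(all(diff(tails) <= 1e-12))
  }
})

test_that("tails agree with brute-force sums on random small instances", {
  set.seed(32)
  uni_all <- sprintf("g%02d", 1:30)
  for (rep in 1:25) {
    U <- sample(4:30, 1)
    uni <- uni_all[1:U]
    m <- sample(1:U, 1); s <- sample(1:U, 1)
    set_genes <- sample(uni, m)
    sel <- sample(uni, s)
    res <- hypergeometric_test(sel, set_genes, uni)
    expect_equal(res$p,
                 oracle_hyper_tail(U, m, s, length(intersect(sel, set_genes))),
                 tolerance = 1e-12)
  }
})

test_that("selected genes outside the universe are a hard error", {
  expect_error(hypergeometric_test(c("a", "zzz"), "a", c("a", "b")), "zzz")
})

test_that("collection testing filters, sorts, and ranks seeded signal first", {
  set.seed(33)
  uni <- sprintf("g%03d", 1:300)
  sets <- c(list(HIT = uni[1:25]),
            lapply(1:9, function(i) sample(uni, 25)))
  names(sets) <- c("HIT", sprintf("S%02d", 1:9))
  coll <- gene_set_collection(sets)
  selected <- c(uni[1:20], sample(uni[26:300], 20))
  all_rows <- enrich_collection(selected, coll, uni, p_threshold = 1)
  expect_identical(nrow(all_rows), 10L)
  expect_identical(all_rows$set_id[1], "HIT")
  expect_true(all(diff(all_rows$p) >= 0))
  expect_true("p_bh" %in% names(all_rows))
  few <- enrich_collection(selected, coll, uni, p_threshold = 0.01)
  expect_true(all(few$p < 0.01))
  expect_true("HIT" %in% few$set_id)
})

test_that("uniformly drawn selections pass the threshold at the nominal rate", {
  set.seed(34)
  uni <- sprintf("g%03d", 1:400)
  n_sets <- 60; n_rep <- 40
  hits <- 0; trials <- 0
  for (r in seq_len(n_rep)) {
    sets <- lapply(seq_len(n_sets), function(i) sample(uni, 20))
    names(sets) <- sprintf("S%02d", seq_len(n_sets))
    coll <- gene_set_collection(sets)
    selected <- sample(uni, 40)
    ps <- enrich_collection(selected, coll, uni, p_threshold = 1,
                            annotated_only = FALSE)$p
    hits <- hits + sum(ps < 0.05)
    trials <- trials + n_sets
  }
  # discrete p-values make the exact rate sub-nominal; it must not exceed it
  expect_lte(hits / trials, 0.05 + 2 * sqrt(0.05 * 0.95 / trials))
  expect_gt(hits / trials, 0.005)
})

test_that("a flat collection makes conditional testing identical to plain", {
  set.seed(35)
  uni <- sprintf("g%03d", 1:200)
  sets <- lapply(1:8, function(i) sample(uni, 15))
  names(sets) <- sprintf("S%02d", 1:8)
  coll <- gene_set_collection(sets)
  selected <- sample(uni, 30)
  plain <- enrich_collection(selected, coll, uni, p_threshold = 1)
  cond <- conditional_enrich(selected, coll, uni, p_threshold = 1,
                             filter = FALSE)
  expect_equal(cond[names(plain)], plain)
})

test_that("a parent absorbed by its significant child loses significance", {
  uni <- sprintf("g%03d", 1:200)
  child <- uni[1:15]
  parent <- uni[1:30]  # child's genes plus 15 unselected ones
  coll <- gene_set_collection(
    list(parent = parent, child = child),
    relations = data.frame(parent = "parent", child = "child"))
  selected <- child
  un <- enrich_collection(selected, coll, uni, p_threshold = 1,
                          annotated_only = FALSE)
  expect_lt(un$p[un$set_id == "parent"], 1e-6)
  cond <- conditional_enrich(selected, coll, uni, p_threshold = 0.001,
                             annotated_only = FALSE, filter = FALSE)
  expect_lt(cond$p[cond$set_id == "child"], 1e-6)
  expect_equal(cond$p[cond$set_id == "parent"], 1)  # nothing left to explain
})

test_that("conditioning cascades leaf -> middle -> root along a chain", {
  uni <- sprintf("g%03d", 1:300)
  leaf <- uni[1:12]
  middle <- uni[1:24]
  root <- uni[1:36]
  coll <- gene_set_collection(
    list(root = root, middle = middle, leaf = leaf),
    relations = data.frame(parent = c("root", "middle"),
                           child = c("middle", "leaf")))
  selected <- uni[1:24]  # saturates leaf and middle
  cond <- conditional_enrich(selected, coll, uni, p_threshold = 0.001,
                             annotated_only = FALSE, filter = FALSE)
  expect_lt(cond$p[cond$set_id == "leaf"], 0.001)
  # middle tested on its 12 non-leaf genes, all selected: still significant
  expect_identical(cond$observed[cond$set_id == "middle"], 12L)
  expect_lt(cond$p[cond$set_id == "middle"], 0.001)
  # root tested after both removals: no selected genes left
  expect_identical(cond$observed[cond$set_id == "root"], 0L)
  expect_equal(cond$p[cond$set_id == "root"], 1)
})
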