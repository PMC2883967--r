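# Containers, invariant enforcement, and TSV/GMT/BED round-trips.

test_that("expression matrix enforces its invariants", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  x <- expression_matrix(v, c("t", "t", "n"))
  expect_identical(dim(x), c(2L, 3L))
  expect_identical(levels(x$labels), c("n", "t"))

  vd <- v; rownames(vd) <- c("p1", "p1")
  expect_error(expression_matrix(vd), "p1")
  vn <- v; vn[1, 2] <- NA
  expect_error(expression_matrix(vn), "non-finite")
  expect_error(expression_matrix(v, c("t", "t")), "one entry per sample")
  expect_error(expression_matrix(v, c(a = "t", b = "t")), "without a class label")
  expect_error(expression_matrix(v, c(a = "t", b = "t", z = "n")), "unknown sample")
})

test_that("expression TSV round-trip is the identity, with labels", {
  x <- make_expr(matrix(rnorm(15, 8), 5, 3), c("chRCC", "chRCC", "onco"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, tsv, lab)
  y <- read_expression_matrix(tsv, lab)
  expect_equal(y$values, x$values)
  expect_identical(as.character(y$labels), as.character(x$labels))
})

test_that("expression reader rejects duplicates and non-numeric cells by name", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "pX\t1.0\t2.0", "pX\t3.0\t4.0"), tsv)
  expect_error(read_expression_matrix(tsv), "pX")
  writeLines(c("probe_id\ts1\ts2", "p1\t1.0\t2.0", "p2\tbad\t4.0"), tsv)
  expect_error(read_expression_matrix(tsv), "probe 'p2', sample 's1'")
})

test_that("large synthetic fixture survives the round-trip entry for entry", {
  sim <- simulate_expression(simulation_config(n_probes = 1000, n_genes = 500),
                             seed = 11)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$tumors, tsv)
  y <- read_expression_matrix(tsv)
  expect_equal(y$values, sim$tumors$values, tolerance = 1e-12)
  expect_identical(rownames(y$values), rownames(sim$tumors$values))
})

test_that("probe annotation parses, flags unplaced rows, and round-trips", {
  df <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("GENE1", "ND1"),
                   chromosome = c("1", "MT"), arm = c("p", "p"),
                   cytoband = c("1p36.3", ""), position = c(1200000, 5000))
  ann <- probe_annotation(df)
  expect_true(ann$placed[1])
  expect_false(ann$placed[2])   # MT retained but unplaced
  expect_identical(nrow(ann), 2L)  # nothing silently dropped

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(ann, tsv)
  back <- read_probe_annotation(tsv)
  expect_equal(as.data.frame(back)[names(df)], df)
  expect_error(probe_annotation(df[-1]), "probe_id")
})

test_that("SNP annotation canonically sorts and rejects ties", {
  df <- data.frame(snp_id = c("s3", "s1", "s2"),
                   chromosome = c("2", "1", "1"),
                   position = c(50, 300, 100))
  ann <- snp_annotation(df)
  expect_identical(ann$snp_id, c("s2", "s1", "s3"))
  df$position <- c(50, 100, 100)
  expect_error(snp_annotation(df), "strictly increasing")
})

test_that("GMT reading de-duplicates, errors on short lines, and round-trips", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB\tA", gmt)
  gs <- read_gene_sets_gmt(gmt)
  expect_identical(gs$sets$S1, c("A", "B"))

  writeLines(c("S1\tdesc\tA", "S2\tonly-two"), gmt)
  expect_error(read_gene_sets_gmt(gmt), "line 2")

  writeLines(character(0), gmt)
  expect_length(read_gene_sets_gmt(gmt)$sets, 0)

  set.seed(42)
  sets <- lapply(1:50, function(i) sprintf("G%03d", sample(500, sample(5:30, 1))))
  names(sets) <- sprintf("SET%02d", 1:50)
  coll <- gene_set_collection(sets, stats::setNames(paste("term", 1:50), names(sets)))
  write_gene_sets_gmt(coll, gmt)
  back <- read_gene_sets_gmt(gmt)
  expect_identical(lengths(back$sets), lengths(coll$sets))
  expect_identical(back$sets, coll$sets)
})

test_that("BED writer converts coordinates, sorts, and handles empty input", {
  calls <- data.frame(
    sample = c("t1", "t2"), chromosome = c("10", "2"),
    start_pos = c(700, 100), end_pos = c(900, 500),
    type = c("gain", "loss"), stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_cn_calls_bed(calls, bed)
  lines <- readLines(bed)
  expect_identical(lines[1], "# chrom\tstart\tend\tname")
  # 1-based inclusive 100-500 becomes 0-based half-open 99-500; chr2 sorts
  # before chr10
  expect_identical(lines[2], "2\t99\t500\tt2|loss")
  expect_identical(lines[3], "10\t699\t900\tt1|gain")

  write_cn_calls_bed(calls[0, ], bed)
  expect_identical(readLines(bed), "# chrom\tstart\tend\tname")
})

test_that("gene set collections validate relations and reject cycles", {
  sets <- list(A = c("g1", "g2"), B = "g1", C = "g3")
  rel <- data.frame(parent = c("A", "B"), child = c("B", "C"))
  gs <- gene_set_collection(sets, relations = rel)
  expect_identical(nrow(gs$relations), 2L)
  cyc <- data.frame(parent = c("A", "B"), child = c("B", "A"))
  expect_error(gene_set_collection(sets, relations = cyc), "cycle")
  expect_error(gene_set_collection(list(A = character(0))), "empty")
})

test_that("contingency tables require nonnegative integer counts", {
  tab <- contingency_2x2(9, 2, 0, 7)
  expect_identical(as.integer(tab), c(9L, 0L, 2L, 7L))
  expect_error(contingency_2x2(-1, 2, 0, 7), "nonnegative")
  expect_error(contingency_2x2(1.5, 2, 0, 7), "integer")
  expect_error(contingency_2x2(0, 0, 0, 0), "positive")
})
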