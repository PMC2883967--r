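# Run-length copy-number calling and recurrent-region detection.

cn_fixture <- function(values_by_sample, chromosome = "7") {
  n <- length(values_by_sample[[1]])
  ann <- snp_annotation(data.frame(
    snp_id = sprintf("s%03d", seq_len(n)), chromosome = chromosome,
    position = seq_len(n) * 1000))
  vals <- do.call(cbind, values_by_sample)
  rownames(vals) <- ann$snp_id
  list(cn = cn_matrix(vals, stats::setNames(rep("coh", ncol(vals)),
                                            colnames(vals))),
       ann = ann)
}

test_that("the four-consecutive-SNP rules call exactly the stated runs", {
  fx <- cn_fixture(list(
    t1 = c(2, 2, 1.0, 1.0, 1.0, 1.0, 2),      # loss run of 4: called
    t2 = c(2, 1.0, 1.0, 1.0, 2, 2, 2),        # run of 3: not called
    t3 = c(4.0, 3.6, 3.8, 3.9, 3.7, 2, 2)))   # gain run of 5: called
  calls <- call_cn_segments(fx$cn, fx$ann)
  expect_identical(nrow(calls), 2L)
  loss <- calls[calls$type == "loss", ]
  expect_identical(loss$sample, "t1")
  expect_identical(c(loss$start_index, loss$end_index), c(3L, 6L))
  expect_identical(loss$n_snps, 4L)
  gain <- calls[calls$type == "gain", ]
  expect_identical(gain$sample, "t3")
  expect_identical(c(gain$start_index, gain$end_index), c(1L, 5L))
  expect_equal(gain$mean_cn, mean(c(4.0, 3.6, 3.8, 3.9, 3.7)))
})

test_that("thresholds are strict and missing values break runs", {
  fx <- cn_fixture(list(
    t1 = c(1.6, 1.5, 1.5, 1.5, 1.5, 1.6, 2),   # 1.6 itself is not a loss
    t2 = c(1.0, 1.0, NA, 1.0, 1.0, 1.0, 1.0))) # NA splits 7 into 2 + 4
  calls <- call_cn_segments(fx$cn, fx$ann)
  t1 <- calls[calls$sample == "t1", ]
  expect_identical(c(t1$start_index, t1$end_index), c(2L, 5L))
  t2 <- calls[calls$sample == "t2", ]
  expect_identical(nrow(t2), 1L)
  expect_identical(c(t2$start_index, t2$end_index), c(4L, 7L))
})

test_that("calls are maximal and invariant to input row order", {
  set.seed(21)
  sim <- simulate_cn(simulation_config(snps_per_chromosome = 40), seed = 21)
  calls <- call_cn_segments(sim$cn, sim$annotation)
  v <- sim$cn$values[sim$annotation$snp_id, ]
  for (j in seq_len(nrow(calls))) {
    cl <- calls[j, ]
    inside <- v[cl$start_index:cl$end_index, cl$sample]
    if (cl$type == "loss") {
      expect_true(all(inside < 1.6))
      for (edge in c(cl$start_index - 1, cl$end_index + 1)) {
        same_chrom <- edge >= 1 && edge <= nrow(v) &&
          sim$annotation$chromosome[edge] == cl$chromosome
        if (same_chrom) expect_false(isTRUE(v[edge, cl$sample] < 1.6))
      }
    }
  }
  shuffled <- sim$cn
  perm <- sample(nrow(shuffled$values))
  shuffled$values <- shuffled$values[perm, ]
  expect_identical(call_cn_segments(shuffled, sim$annotation), calls)
})

test_that("unsorted annotation is rejected with advice", {
  fx <- cn_fixture(list(t1 = rep(2, 5)))
  bad <- fx$ann[c(2, 1, 3, 4, 5), ]
  expect_error(call_cn_segments(fx$cn, bad), "canonically sorted")
})

test_that("the 30% prevalence rule is strict in both directions", {
  n_snp <- 30
  ann <- snp_annotation(data.frame(snp_id = sprintf("s%03d", 1:n_snp),
                                   chromosome = "1",
                                   position = (1:n_snp) * 1000))
  shared <- data.frame(
    sample = c("a", "b"), chromosome = "1",
    start_index = 5L, end_index = 24L, start_pos = 5000, end_pos = 24000,
    type = "loss", n_snps = 20L, mean_cn = 1.0, stringsAsFactors = FALSE)
  # 2 of 6 samples: 0.333 > 0.30 -> CNA
  six <- cna_regions(shared, c("a", "b", paste0("m", 3:6)), ann)
  expect_identical(nrow(six), 1L)
  expect_identical(c(six$start_index, six$end_index), c(5L, 24L))
  expect_equal(six$prevalence_min, 1 / 3)
  # 2 of 8 samples: 0.25 -> nothing
  eight <- cna_regions(shared, c("a", "b", paste0("m", 3:8)), ann)
  expect_identical(nrow(eight), 0L)
  # empty inputs
  expect_identical(nrow(cna_regions(shared[0, ], c("a", "b", paste0("m", 3:6)), ann)), 0L)
  expect_error(cna_regions(shared, character(0), ann), "empty cohort")
})

test_that("short shared runs never become CNA regions", {
  ann <- snp_annotation(data.frame(snp_id = sprintf("s%03d", 1:20),
                                   chromosome = "2",
                                   position = (1:20) * 500))
  short <- data.frame(sample = c("a", "b", "c"), chromosome = "2",
                      start_index = 8L, end_index = 10L, start_pos = 4000,
                      end_pos = 5000, type = "gain", n_snps = 3L,
                      mean_cn = 4, stringsAsFactors = FALSE)
  expect_identical(nrow(cna_regions(short, letters[1:4], ann)), 0L)
})

test_that("cohort profiles separate the two simulated tumor classes", {
  sim <- simulate_cn(simulation_config(), seed = 23)
  calls <- call_cn_segments(sim$cn, sim$annotation)
  loss_chroms <- c("1", "2", "6", "10", "13", "17", "21")
  chr_m <- names(sim$cn$cohort)[sim$cn$cohort == "chRCC"]
  onc_m <- names(sim$cn$cohort)[sim$cn$cohort == "oncocytoma"]

  chr_reg <- cna_regions(calls, chr_m, sim$annotation)
  chr_prof <- cnv_cohort_profile(chr_reg, sim$annotation)
  hot <- chr_prof[chr_prof$type == "loss" &
                    chr_prof$chromosome %in% loss_chroms, ]
  expect_gte(min(hot$altered_fraction), 0.8)
  quiet <- chr_prof[chr_prof$type == "loss" &
                      !chr_prof$chromosome %in% loss_chroms, ]
  expect_lte(max(quiet$altered_fraction), 0.05)

  onc_reg <- cna_regions(calls, onc_m, sim$annotation)
  onc_prof <- cnv_cohort_profile(onc_reg, sim$annotation)
  one_p <- onc_prof[onc_prof$chromosome == "1" & onc_prof$type == "loss", ]
  expect_gt(one_p$altered_fraction, 0.1)   # distal 1p only
  expect_lt(one_p$altered_fraction, 0.25)
  other <- onc_prof[onc_prof$chromosome != "1" & onc_prof$type == "loss", ]
  expect_lte(max(other$altered_fraction), 0.05)

  empty_prof <- cnv_cohort_profile(chr_reg[0, ], sim$annotation)
  expect_true(all(empty_prof$altered_fraction == 0))
})
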