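test_that("a noise-free pool reproduces each sample's expected index pair", {
  sheet <- demo_sheet(4)
  reads <- simulate_pool(sheet, n_reads = 2000, p_swap_i7 = 0,
                         p_swap_i5 = 0, index_error_rate = 0, seed = 5)
  own <- match(reads$true_sample, sheet$sample_id)
  expect_identical(reads$i7_obs, sheet$i7[own])
  expect_identical(reads$i5_obs, sheet$i5[own])
  expect_identical(reads$i7_source, reads$true_sample)
  expect_identical(reads$i5_source, reads$true_sample)
})

test_that("swap event and detectable-swap fractions match the binomial closed form", {
  # two equal-abundance samples, p_i5 = 0.5: half of the swap draws land on
  # the read's own index, so detectable i5 swaps occur at ~ 0.25
  sheet <- demo_sheet(2)
  n <- 100000
  reads <- simulate_pool(sheet, n_reads = n, p_swap_i7 = 0, p_swap_i5 = 0.5,
                         index_error_rate = 0, swap_length_coeff = 0,
                         swap_gc_coeff = 0, seed = 9)
  own <- match(reads$true_sample, sheet$sample_id)
  event_frac <- mean(reads$i5_source != reads$true_sample)
  detect_frac <- mean(reads$i5_obs != sheet$i5[own])
  expect_lt(abs(event_frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_identical(detect_frac, event_frac)
  # i5 swap events (detectable, since replacement != self here) are half of
  # all swap draws; total draws ~ 0.5
  expect_lt(abs(event_frac / 0.5 - 0.5), 3 * sqrt(0.25 / (0.5 * n)) / 0.5)
  expect_identical(sum(reads$i7_source != reads$true_sample), 0L)
})

test_that("simulation is deterministic and conserves read counts", {
  sheet <- demo_sheet(4)
  a <- simulate_pool(sheet, n_reads = 5000, index_error_rate = 0.01, seed = 77)
  b <- simulate_pool(sheet, n_reads = 5000, index_error_rate = 0.01, seed = 77)
  expect_identical(a, b)
  expect_identical(nrow(a), 5000L)
  expect_identical(nrow(truth_table(a)), 5000L)
})

test_that("empirical per-end swap-event rates converge to the configured rates", {
  sheet <- demo_sheet(6)
  n <- 200000
  p7 <- 0.0131; p5 <- 0.0302
  reads <- simulate_pool(sheet, n_reads = n, p_swap_i7 = p7, p_swap_i5 = p5,
                         index_error_rate = 0, swap_length_coeff = 0,
                         swap_gc_coeff = 0, seed = 21)
  # events include self-replacement; recover them from source-sample truth
  # (detectable events) scaled by the self-draw weight
  S <- nrow(sheet)
  det7 <- mean(reads$i7_source != reads$true_sample)
  det5 <- mean(reads$i5_source != reads$true_sample)
  q7 <- p7 * (S - 1) / S
  q5 <- p5 * (S - 1) / S
  expect_lt(abs(det7 - q7), 3 * sqrt(q7 * (1 - q7) / n))
  expect_lt(abs(det5 - q5), 3 * sqrt(q5 * (1 - q5) / n))
})

test_that("the two ends swap independently when covariate effects are off", {
  sheet <- demo_sheet(6)
  reads <- simulate_pool(sheet, n_reads = 100000, p_swap_i7 = 0.05,
                         p_swap_i5 = 0.1, index_error_rate = 0,
                         swap_length_coeff = 0, swap_gc_coeff = 0, seed = 33)
  ev7 <- reads$i7_source != reads$true_sample
  ev5 <- reads$i5_source != reads$true_sample
  p <- suppressWarnings(stats::chisq.test(table(ev7, ev5)))$p.value
  expect_gt(p, 0.01)
})

test_that("negative covariate coefficients skew swaps toward short, AT-rich fragments", {
  sheet <- demo_sheet(6)
  reads <- simulate_pool(sheet, n_reads = 50000, p_swap_i7 = 0.02,
                         p_swap_i5 = 0.05, index_error_rate = 0,
                         swap_length_coeff = -1, swap_gc_coeff = -0.8,
                         seed = 41)
  ev <- reads$i7_source != reads$true_sample |
    reads$i5_source != reads$true_sample
  expect_lt(mean(reads$insert_len[ev]), mean(reads$insert_len[!ev]))
  expect_lt(mean(reads$gc[ev]), mean(reads$gc[!ev]))
})

test_that("mixture simulation demands exactly two organism labels", {
  sheet <- demo_sheet(4)
  three <- stats::setNames(c("a", "b", "c", "a"), sheet$sample_id)
  expect_error(simulate_mixture(sheet, three, n_reads = 10, seed = 1),
               class = "indexhop_error_config")
  one <- stats::setNames(rep("a", 4), sheet$sample_id)
  expect_error(simulate_mixture(sheet, one, n_reads = 10, seed = 1),
               class = "indexhop_error_config")
  two <- stats::setNames(c("a", "a", "b", "b"), sheet$sample_id)
  reads <- simulate_mixture(sheet, two, n_reads = 100, seed = 1)
  expect_identical(sort(unique(reads$organism)), c("a", "b"))
})

test_that("invalid simulation configs fail before any output", {
  sheet <- demo_sheet(4)
  expect_error(simulate_pool(sheet, 10, abundances = c(0.5, 0.5, 0.1, 0.1)),
               class = "indexhop_error_config")
  expect_error(simulate_pool(sheet, 10, p_swap_i7 = 1.2),
               class = "indexhop_error_config")
  redundant <- sheet
  redundant$i7[2] <- redundant$i7[1]
  expect_error(simulate_pool(redundant, 10, seed = 1),
               class = "indexhop_error_redundant_sheet")
})

test_that("index FASTQ pairs round-trip exactly", {
  sheet <- demo_sheet(4)
  reads <- simulate_pool(sheet, n_reads = 1000, index_error_rate = 0.05,
                         seed = 13)
  i1 <- withr::local_tempfile(fileext = ".fastq")
  i2 <- withr::local_tempfile(fileext = ".fastq")
  write_index_fastq(reads, i1, i2)

  # 4-line record structure
  lines <- readLines(i1)
  expect_identical(length(lines), 4000L)
  expect_identical(substr(lines[1], 1, 1), "@")
  expect_identical(substr(lines[3], 1, 1), "+")

  back <- read_index_fastq(i1, i2)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$i7_obs, reads$i7_obs)
  expect_identical(back$i5_obs, reads$i5_obs)
  expect_identical(back$i7_qual, reads$i7_qual)
  expect_identical(back$i5_qual, reads$i5_qual)
  expect_identical(back$surface, reads$surface)
  expect_identical(back$tile, reads$tile)
})

test_that("an empty read stream writes two empty, readable FASTQ files", {
  sheet <- demo_sheet(2)
  reads <- simulate_pool(sheet, n_reads = 0, seed = 1)
  i1 <- withr::local_tempfile(fileext = ".fastq")
  i2 <- withr::local_tempfile(fileext = ".fastq")
  write_index_fastq(reads, i1, i2)
  expect_true(file.exists(i1) && file.size(i1) == 0)
  back <- read_index_fastq(i1, i2)
  expect_identical(nrow(back), 0L)
})
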