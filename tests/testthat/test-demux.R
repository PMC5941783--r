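test_that("match_index resolves unique candidates and flags ties", {
  cands <- c("AAAATTTT", "CCCCGGGG", "ACACACAC")
  expect_identical(match_index("ACACACAC", cands, 0), 3L)
  expect_identical(match_index("AAAATTTA", cands, 1), 1L)
  expect_identical(match_index("GGGGGGGG", cands, 1), NA_integer_)
  # two candidates 1 mismatch apart: an observed read between them is ambiguous
  close <- c("AAAATTTT", "AAAATTTG")
  expect_identical(match_index("AAAATTTC", close, 1), 0L)
  expect_error(match_index("AAAA", cands, 1), class = "indexhop_error_length")
  expect_error(match_index("AAAATTTT", character(0), 1),
               class = "indexhop_error_insufficient_input")
})

test_that("match_index agrees with the exhaustive Hamming scan", {
  set.seed(601)
  cands <- design_index_set(8, index_constraints(min_hamming = 3),
                            seed = 601)$i7
  obs <- random_index(500)
  got <- match_index(obs, cands, 1)
  oracle <- vapply(obs, bf_match, integer(1),
                   candidates = cands, max_mismatch = 1)
  expect_identical(got, unname(oracle))
})

test_that("classification applies quality, matching and pair-consistency in order", {
  sheet <- demo_sheet(4)
  hi <- strrep("F", 8)   # Q37
  lo <- strrep("+", 8)   # Q10
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    i7_obs = c(sheet$i7[1], sheet$i7[1], sheet$i7[2], "ACGTACGT", sheet$i7[3]),
    i5_obs = c(sheet$i5[1], sheet$i5[2], sheet$i5[2], sheet$i5[1], sheet$i5[3]),
    i7_qual = c(hi, hi, hi, hi, lo),
    i5_qual = hi)
  got <- classify_reads(reads, sheet, max_mismatch = 0)
  expect_identical(as.character(got$class),
                   c("MATCHED", "SWAPPED", "MATCHED", "UNDETERMINED",
                     "LOW_QUALITY"))
  expect_identical(got$sample_id[1], sheet$sample_id[1])
  expect_identical(got$i7_owner[2], sheet$sample_id[1])
  expect_identical(got$i5_owner[2], sheet$sample_id[2])
  # the low-quality read matched sample 3 exactly, but quality wins
  expect_true(is.na(got$sample_id[5]))
})

test_that("foreign indexes never enter the swap matrix", {
  sheet <- demo_sheet(4)
  # construct an index provably > 1 mismatch from every pool index
  set.seed(605)
  repeat {
    foreign <- random_index(1)
    d <- vapply(c(sheet$i7, sheet$i5),
                function(cand) bf_hamming(foreign, cand), integer(1))
    if (min(d) > 1L) break
  }
  outside <- tibble::tibble(
    read_id = "x", i7_obs = foreign, i5_obs = foreign,
    i7_qual = strrep("F", 8), i5_qual = strrep("F", 8))
  got <- classify_reads(outside, sheet, max_mismatch = 1)
  expect_identical(as.character(got$class), "UNDETERMINED")
  tal <- tabulate_reads(got, sheet)
  expect_identical(sum(tal$counts), 0L)
  expect_identical(tal$undetermined, 1L)
})

test_that("tallies partition the read stream and match simulation truth", {
  sheet <- demo_sheet(6)
  reads <- simulate_pool(sheet, n_reads = 10000, p_swap_i7 = 0.05,
                         p_swap_i5 = 0.1, index_error_rate = 0.02,
                         quality_low = 2, seed = 55)
  cls <- classify_reads(reads, sheet)
  tal <- tabulate_reads(cls, sheet)
  expect_identical(sum(tal$counts) + tal$undetermined + tal$low_quality,
                   nrow(reads))
  expect_identical(tal$total, nrow(reads))

  # error-free, exact-match classification equals truth classification
  clean <- simulate_pool(sheet, n_reads = 10000, p_swap_i7 = 0.05,
                         p_swap_i5 = 0.1, index_error_rate = 0, seed = 56)
  cls0 <- classify_reads(clean, sheet, max_mismatch = 0)
  expect_identical(as.character(cls0$class), truth_classes(clean))
  expect_identical(cls0$i7_owner, clean$i7_source)
  expect_identical(cls0$i5_owner, clean$i5_source)

  # and the count matrix is exactly the truth cross-tabulation
  tal0 <- tabulate_reads(cls0, sheet)
  oracle <- table(factor(clean$i7_source, levels = sheet$sample_id),
                  factor(clean$i5_source, levels = sheet$sample_id))
  expect_identical(as.vector(tal0$counts), as.vector(as.integer(oracle)))
})

test_that("a 6-plex pool with heavy swapping populates all 36 combinations", {
  sheet <- demo_sheet(6)
  reads <- simulate_pool(sheet, n_reads = 30000, p_swap_i7 = 0.3,
                         p_swap_i5 = 0.3, index_error_rate = 0,
                         swap_length_coeff = 0, swap_gc_coeff = 0, seed = 58)
  tal <- tabulate_reads(classify_reads(reads, sheet), sheet)
  expect_identical(dim(tal$counts), c(6L, 6L))
  expect_true(all(tal$counts > 0))
  # diagonal = correct combinations, and dominates every off-diagonal cell
  expect_true(all(diag(tal$counts) > max(tal$counts - diag(6) * tal$counts)))
})

test_that("zero-swap tallies have an empty off-diagonal", {
  sheet <- demo_sheet(4)
  reads <- simulate_pool(sheet, n_reads = 5000, p_swap_i7 = 0, p_swap_i5 = 0,
                         index_error_rate = 0, seed = 59)
  tal <- tabulate_reads(classify_reads(reads, sheet), sheet)
  off <- tal$counts; diag(off) <- 0L
  expect_identical(sum(off), 0L)
  expect_identical(swap_rate(tal), 0)
})

test_that("swap_rate implements swapped over qualifying reads", {
  sheet <- demo_sheet(2)
  # worked example: the qualifying denominator excludes undetermined and
  # low-quality reads; 34,219,842 swapped of 842,853,260 qualifying
  matched <- 842853260 - 34219842
  tal <- structure(list(
    counts = matrix(c(matched, 34219842 / 2, 34219842 / 2, 0), 2, 2,
                    dimnames = list(i7_owner = sheet$sample_id,
                                    i5_owner = sheet$sample_id)),
    undetermined = 123, low_quality = 456,
    total = 842853260 + 579,
    tiles = tibble::tibble()), class = "swap_tally")
  expect_equal(round(swap_rate(tal), 4), 0.0406)

  empty <- tal
  empty$counts[] <- 0
  expect_error(swap_rate(empty), class = "indexhop_error_undefined_rate")
})

test_that("swap_rate is invariant under sample-sheet permutation", {
  sheet <- demo_sheet(5)
  reads <- simulate_pool(sheet, n_reads = 20000, p_swap_i7 = 0.05,
                         p_swap_i5 = 0.1, index_error_rate = 0, seed = 61)
  r1 <- swap_rate(tabulate_reads(classify_reads(reads, sheet), sheet))
  perm <- sheet[c(3, 5, 1, 2, 4), ]
  r2 <- swap_rate(tabulate_reads(classify_reads(reads, perm), perm))
  expect_identical(r1, r2)
})

test_that("demultiplexing works end to end from FASTQ files", {
  sheet <- demo_sheet(4)
  reads <- simulate_pool(sheet, n_reads = 2000, p_swap_i7 = 0.05,
                         p_swap_i5 = 0.1, index_error_rate = 0, seed = 63)
  i1 <- withr::local_tempfile(fileext = ".fastq.gz")
  i2 <- withr::local_tempfile(fileext = ".fastq.gz")
  write_index_fastq(reads, i1, i2)
  res <- demux_fastq(i1, i2, sheet)
  direct <- tabulate_reads(classify_reads(reads, sheet), sheet)
  expect_identical(res$tally$counts, direct$counts)
  expect_identical(res$tally$tiles, direct$tiles)
})
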