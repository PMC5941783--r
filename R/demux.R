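#' Match observed index sequences against a candidate list
#'
#' For every observed sequence, counts the candidates within
#' `max_mismatch` Hamming distance.  Exactly one qualifying candidate
#' gives a unique match; none gives `NA` (no match); two or more give
#' `0` (ambiguous -- a second candidate also qualifies, so the call is
#' not trusted).
#'
#' @param observed Character vector of observed index reads.
#' @param candidates Character vector of candidate index sequences, all
#'   the same length as the observed reads.
#' @param max_mismatch Maximum Hamming distance for a candidate to
#'   qualify.
#' @return Integer vector, one element per observed sequence: the
#'   1-based position of the unique qualifying candidate, `NA` for no
#'   match, `0L` for ambiguous.
#' @export
#' @examples
#' match_index(c("AAAATTTT", "AAAATTTA"), c("AAAATTTT", "CCCCGGGG"),
#'             max_mismatch = 1)
match_index <- function(observed, candidates, max_mismatch = 1L) {
  if (length(candidates) == 0L) {
    stop_indexhop("`candidates` must be nonempty.",
                  "indexhop_error_insufficient_input")
  }
  if (length(observed) == 0L) return(integer(0))
  if (length(unique(nchar(c(observed, candidates)))) != 1L) {
    stop_indexhop("Observed and candidate sequences must share one length.",
                  "indexhop_error_length")
  }
  u <- unique(observed)
  um <- seq_char_matrix(u)
  cm <- seq_char_matrix(candidates)
  n_qual <- integer(length(u))
  pos <- rep(NA_integer_, length(u))
  for (j in seq_along(candidates)) {
    qual_j <- colSums(um != cm[, j]) <= max_mismatch
    first <- qual_j & n_qual == 0L
    pos[first] <- j
    n_qual <- n_qual + qual_j
  }
  pos[n_qual > 1L] <- 0L
  pos[match(observed, u)]
}

#' Classify index-read pairs against a non-redundant sample sheet
#'
#' Applies, in order: (1) the quality filter -- a read whose i7 or i5
#' index read has mean Phred below `min_mean_q` is `LOW_QUALITY` and
#' never enters swap statistics; (2) index matching -- the observed i7 is
#' resolved against the sheet's i7 list and the observed i5 against the
#' i5 list with [match_index()]; (3) pair consistency -- both ends
#' resolving to the same sample is `MATCHED`, to different samples
#' `SWAPPED` (with the owning samples recorded per end), and any
#' unresolved or ambiguous end is `UNDETERMINED`.  Reads carrying indexes
#' from outside the pool therefore never contribute to swap counts.
#'
#' A double swap that lands on a valid expected pair is classified
#' `MATCHED`: by construction it is indistinguishable at demultiplexing
#' and is only recoverable through the mixture design
#' (see [classify_swap_end()]).
#'
#' @param reads Tibble with columns `i7_obs`, `i5_obs` and (for the
#'   quality filter) `i7_qual`, `i5_qual`; extra columns pass through.
#' @param samplesheet Non-redundant dual-index sample sheet.
#' @param max_mismatch Per-index mismatch tolerance (default 1, safe for
#'   sets with pairwise distance >= 3).
#' @param min_mean_q Minimum mean index-read Phred quality (default 30).
#' @return The input tibble with columns `class` (factor `MATCHED`,
#'   `SWAPPED`, `UNDETERMINED`, `LOW_QUALITY`), `sample_id` (the
#'   demultiplexed sample, `MATCHED` only), and `i7_owner`, `i5_owner`
#'   (the samples owning each resolved index, `MATCHED`/`SWAPPED` only).
#' @export
#' @examples
#' sheet <- design_index_set(4, seed = 1)
#' reads <- simulate_pool(sheet, n_reads = 200, seed = 2)
#' dplyr::count(classify_reads(reads, sheet), class)
classify_reads <- function(reads, samplesheet, max_mismatch = 1L,
                           min_mean_q = 30) {
  check_nonredundant(samplesheet)
  n <- nrow(reads)
  lowq <- rep(FALSE, n)
  if (all(c("i7_qual", "i5_qual") %in% names(reads)) && n > 0L) {
    lowq <- mean_phred(reads$i7_qual) < min_mean_q |
      mean_phred(reads$i5_qual) < min_mean_q
  }
  p7 <- match_index(reads$i7_obs, samplesheet$i7, max_mismatch)
  p5 <- match_index(reads$i5_obs, samplesheet$i5, max_mismatch)
  resolved <- !is.na(p7) & !is.na(p5) & p7 > 0L & p5 > 0L

  class <- rep("UNDETERMINED", n)
  class[resolved & p7 == p5] <- "MATCHED"
  class[resolved & p7 != p5] <- "SWAPPED"
  class[lowq] <- "LOW_QUALITY"

  keep <- class %in% c("MATCHED", "SWAPPED")
  # 0 (ambiguous) must not drop elements when used as an index
  p7[!is.na(p7) & p7 == 0L] <- NA_integer_
  p5[!is.na(p5) & p5 == 0L] <- NA_integer_
  own7 <- samplesheet$sample_id[p7]
  own5 <- samplesheet$sample_id[p5]
  out <- reads
  out$class <- factor(class, levels = read_class_levels)
  out$i7_owner <- if_else(keep, own7, NA_character_)
  out$i5_owner <- if_else(keep, own5, NA_character_)
  out$sample_id <- if_else(class == "MATCHED", own7, NA_character_)
  as_tibble(out)
}

read_class_levels <- c("MATCHED", "SWAPPED", "UNDETERMINED", "LOW_QUALITY")

#' Tabulate classified reads into a swap count table and tile grid
#'
#' Single-pass tallies over reads classified by [classify_reads()]:
#' every read increments exactly one cell of the (i7 owner x i5 owner)
#' combination matrix or one of the undetermined / low-quality tallies,
#' so the counts partition the input.  The matrix diagonal holds the
#' correctly demultiplexed (matched) reads; every off-diagonal cell is a
#' detectable swapped combination.  When reads carry tile coordinates a
#' per-tile grid of swapped and classified (matched + swapped) counts is
#' tabulated as well.
#'
#' @param classified Output of [classify_reads()].
#' @param samplesheet The sample sheet used for classification (fixes
#'   matrix row/column order).
#' @return An object of class `swap_tally`: `counts` (named
#'   sample-by-sample integer matrix, rows = i7 owner, columns = i5
#'   owner), `undetermined`, `low_quality`, `total`, and `tiles`, a
#'   tibble with per-tile `swapped` and `classified` counts (empty when
#'   no tile info).  [tidy()] returns the matrix in long form,
#'   [glance()] the class tallies plus [swap_rate()].
#' @export
tabulate_reads <- function(classified, samplesheet) {
  check_nonredundant(samplesheet)
  ids <- samplesheet$sample_id
  keep <- classified$class %in% c("MATCHED", "SWAPPED")
  counts <- table(
    factor(classified$i7_owner[keep], levels = ids),
    factor(classified$i5_owner[keep], levels = ids))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(i7_owner = ids, i5_owner = ids))

  has_tile <- all(c("surface", "swath", "tile") %in% names(classified))
  if (has_tile && anyNA(classified[keep, c("surface", "swath", "tile")])) {
    # tolerated: such reads count in the matrix but cannot be placed
    warn("Some classified reads lack tile coordinates; skipped in the tile grid.")
  }
  tiles <- if (has_tile) {
    classified |>
      filter(.data$class %in% c("MATCHED", "SWAPPED"),
             !is.na(.data$surface), !is.na(.data$swath), !is.na(.data$tile)) |>
      group_by(.data$surface, .data$swath, .data$tile) |>
      summarise(swapped = sum(.data$class == "SWAPPED"),
                classified = n(), .groups = "drop")
  } else {
    tibble(surface = integer(0), swath = integer(0), tile = integer(0),
           swapped = integer(0), classified = integer(0))
  }

  structure(
    list(counts = counts,
         undetermined = sum(classified$class == "UNDETERMINED"),
         low_quality = sum(classified$class == "LOW_QUALITY"),
         total = nrow(classified),
         tiles = tiles),
    class = "swap_tally")
}

#' @export
print.swap_tally <- function(x, ...) {
  d <- sum(diag(x$counts))
  s <- sum(x$counts) - d
  cat(sprintf("Swap tally over %d reads (%d samples, %d index combinations)\n",
              x$total, nrow(x$counts), length(x$counts)))
  cat(sprintf("  matched %d | swapped %d | undetermined %d | low quality %d\n",
              d, s, x$undetermined, x$low_quality))
  if (d + s > 0) {
    cat(sprintf("  swap rate (qualifying reads): %.4f\n", swap_rate(x)))
  }
  invisible(x)
}

#' @export
tidy.swap_tally <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "reads",
                                stringsAsFactors = FALSE)) |>
    mutate(matched = .data$i7_owner == .data$i5_owner)
}

#' @export
glance.swap_tally <- function(x, ...) {
  d <- sum(diag(x$counts))
  s <- sum(x$counts) - d
  tibble(total = x$total, matched = d, swapped = s,
         undetermined = x$undetermined, low_quality = x$low_quality,
         swap_rate = if (d + s > 0) swap_rate(x) else NA_real_)
}

#' Overall detectable swap rate of a tally
#'
#' Off-diagonal (swapped) reads divided by all qualifying reads: passing
#' filter reads whose high-quality index reads both match an index used
#' within the pool (matrix diagonal + off-diagonal).  Undetermined and
#' low-quality reads are excluded from the denominator.
#'
#' @param tally A `swap_tally` from [tabulate_reads()].
#' @return Fraction of qualifying reads that are detectably swapped.
#' @export
swap_rate <- function(tally) {
  stopifnot(inherits(tally, "swap_tally"))
  denom <- sum(tally$counts)
  if (denom == 0) {
    stop_indexhop("Swap rate undefined: no qualifying reads in the tally.",
                  "indexhop_error_undefined_rate")
  }
  (denom - sum(diag(tally$counts))) / denom
}

#' Demultiplex an index FASTQ pair end to end
#'
#' Convenience wrapper: reads an I1/I2 FASTQ pair, classifies, and
#' tabulates.
#'
#' @inheritParams read_index_fastq
#' @inheritParams classify_reads
#' @return A list with `classified` (per-read tibble) and `tally`
#'   (`swap_tally`).
#' @export
demux_fastq <- function(i1_path, i2_path, samplesheet, max_mismatch = 1L,
                        min_mean_q = 30) {
  reads <- read_index_fastq(i1_path, i2_path)
  classified <- classify_reads(reads, samplesheet, max_mismatch, min_mean_q)
  list(classified = classified,
       tally = tabulate_reads(classified, samplesheet))
}
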