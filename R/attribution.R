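swap_end_levels <- c("NON_SWAP", "UNDETERMINED_END", "I7_SWAP", "I5_SWAP",
                     "DOUBLE_SWAP")

#' Classify the swapped end of each read in a two-organism mixture
#'
#' In a pool mixing samples from exactly two organisms, the organism a
#' read maps to identifies which index stayed with the fragment: an
#' index owned by a sample of the *other* organism must have swapped
#' on, while an index owned by the read's own organism is assumed not to
#' have swapped.  With `R` the read's organism and `O7`, `O5` the
#' organisms owning the resolved i7 and i5:
#'
#' * `MATCHED` pair, `O7 == O5 == R` -> `NON_SWAP`;
#' * `MATCHED` pair but `O7 == O5 != R` -> `DOUBLE_SWAP` (a valid
#'   expected pair from the wrong organism: both ends swapped);
#' * `SWAPPED`, both owners from `R`'s organism -> `UNDETERMINED_END`
#'   (a within-organism swap: which end moved is unknowable);
#' * `SWAPPED`, `O7 != R`, `O5 == R` -> `I7_SWAP`;
#' * `SWAPPED`, `O5 != R`, `O7 == R` -> `I5_SWAP`;
#' * `SWAPPED`, both owners foreign -> `DOUBLE_SWAP`.
#'
#' Reads classified `UNDETERMINED` or `LOW_QUALITY` get `NA`.
#'
#' @param classified Output of [classify_reads()] carrying an `organism`
#'   column (the organism each read maps to; simulation truth or an
#'   external annotation).
#' @param organism_of Organism label per sample: named character vector
#'   or data frame (`sample_id`, `organism`); exactly two labels.
#' @return The input tibble with an `end_class` factor column
#'   (`NON_SWAP`, `UNDETERMINED_END`, `I7_SWAP`, `I5_SWAP`,
#'   `DOUBLE_SWAP`).
#' @export
classify_swap_end <- function(classified, organism_of) {
  if (!"organism" %in% names(classified)) {
    stop_indexhop(
      "Reads need an `organism` column (mapping organism per read).",
      "indexhop_error_config")
  }
  if (is.data.frame(organism_of)) {
    map <- stats::setNames(as.character(organism_of$organism),
                           organism_of$sample_id)
  } else {
    map <- organism_of
  }
  labels <- unique(unname(map))
  if (length(labels) != 2L) {
    stop_indexhop(
      sprintf("End attribution supports exactly two organisms, got %d.",
              length(labels)),
      "indexhop_error_unsupported_design")
  }
  if (!all(stats::na.omit(classified$organism) %in% labels)) {
    stop_indexhop("Read organism labels not covered by `organism_of`.",
                  "indexhop_error_config")
  }

  R <- classified$organism
  O7 <- unname(map[classified$i7_owner])
  O5 <- unname(map[classified$i5_owner])
  known <- !is.na(R) & !is.na(O7) & !is.na(O5)
  is_m <- classified$class == "MATCHED" & known
  is_s <- classified$class == "SWAPPED" & known

  end <- rep(NA_character_, nrow(classified))
  end[is_m & O7 == R] <- "NON_SWAP"
  end[is_m & O7 != R] <- "DOUBLE_SWAP"
  end[is_s & O7 == R & O5 == R] <- "UNDETERMINED_END"
  end[is_s & O7 != R & O5 == R] <- "I7_SWAP"
  end[is_s & O7 == R & O5 != R] <- "I5_SWAP"
  end[is_s & O7 != R & O5 != R] <- "DOUBLE_SWAP"

  out <- classified
  out$end_class <- factor(end, levels = swap_end_levels)
  as_tibble(out)
}

#' Estimate per-end swap probabilities from mixture swap counts
#'
#' The two-organism mixture estimator.  Cross-organism swaps identify the
#' swapped end directly; within-organism ("undetermined") swaps are
#' allocated to the two ends proportionally to the known-end counts; and
#' double swaps, having one event on each end, count toward both totals:
#'
#' \deqn{\hat{T}_{i7} = \frac{K_7}{K_7 + K_5} U + K_7 + D, \qquad
#'       \hat{T}_{i5} = \frac{K_5}{K_7 + K_5} U + K_5 + D}
#'
#' with per-end probabilities \eqn{\hat{T}/N'} over the qualifying-read
#' denominator \eqn{N' = \mathrm{non\_swapped} + U + K_7 + K_5 + D}.
#' The allocation conserves events exactly:
#' \eqn{\hat{T}_{i7} + \hat{T}_{i5} = U + K_7 + K_5 + 2D}.
#'
#' When an independently tallied total swapped read count and total
#' passing-filter count are supplied, the overall swap probability
#' `p_total` is computed from them; otherwise it is the component-based
#' \eqn{(U + K_7 + K_5 + D)/N'}.  Both versions are retained so a
#' discrepancy between an upstream tally and the component counts is
#' visible rather than silently resolved.
#'
#' @param non_swapped Reads whose pair is their own sample's.
#' @param undetermined Detected swaps whose two indexes belong to samples
#'   of the same organism (swapped end unknowable).
#' @param known_i7,known_i5 Cross-organism swaps attributed to the i7 /
#'   i5 end.
#' @param double_swaps Reads with both ends swapped across organisms.
#' @param total_pf,total_swapped Optional independently tallied totals
#'   for the overall swap probability.
#' @return Object of class `mixture_attribution`; see [tidy()] /
#'   [glance()] methods.  Probabilities are kept at full precision;
#'   printing rounds half-up to 4 decimals.
#' @export
#' @examples
#' estimate_attribution(non_swapped = 9500, undetermined = 200,
#'                      known_i7 = 90, known_i5 = 180, double_swaps = 30)
estimate_attribution <- function(non_swapped, undetermined, known_i7,
                                 known_i5, double_swaps,
                                 total_pf = NULL, total_swapped = NULL) {
  counts <- c(non_swapped = non_swapped, undetermined = undetermined,
              known_i7 = known_i7, known_i5 = known_i5,
              double_swaps = double_swaps)
  if (any(counts < 0) || anyNA(counts)) {
    stop_indexhop("Counts must be non-negative numbers.",
                  "indexhop_error_config")
  }
  if (undetermined > 0 && known_i7 + known_i5 == 0) {
    stop_indexhop(
      "Proportional allocation undefined: undetermined swaps present but no known-end swaps.",
      "indexhop_error_allocation_undefined")
  }
  alloc7 <- if (undetermined > 0) {
    known_i7 / (known_i7 + known_i5) * undetermined
  } else 0
  est_total_i7 <- alloc7 + known_i7 + double_swaps
  est_total_i5 <- (undetermined - alloc7) + known_i5 + double_swaps
  n_prime <- non_swapped + undetermined + known_i7 + known_i5 + double_swaps
  component_swapped <- undetermined + known_i7 + known_i5 + double_swaps

  p_total_components <- if (n_prime > 0) component_swapped / n_prime else NA_real_
  p_total <- if (!is.null(total_pf) && !is.null(total_swapped)) {
    total_swapped / total_pf
  } else {
    p_total_components
  }

  structure(
    list(non_swapped = non_swapped, undetermined = undetermined,
         known_i7 = known_i7, known_i5 = known_i5,
         double_swaps = double_swaps,
         est_total_i7 = est_total_i7, est_total_i5 = est_total_i5,
         n_prime = n_prime,
         p_i7 = if (n_prime > 0) est_total_i7 / n_prime else NA_real_,
         p_i5 = if (n_prime > 0) est_total_i5 / n_prime else NA_real_,
         p_total = p_total,
         p_total_components = p_total_components,
         total_pf = total_pf, total_swapped = total_swapped),
    class = "mixture_attribution")
}

#' Attribute swap ends over a classified read table
#'
#' Counts the end classes produced by [classify_swap_end()] and feeds
#' them to [estimate_attribution()].
#'
#' @param end_classified Output of [classify_swap_end()].
#' @return A `mixture_attribution` object.
#' @export
attribute_mixture <- function(end_classified) {
  if (!"end_class" %in% names(end_classified)) {
    stop_indexhop("Run classify_swap_end() first (no `end_class` column).",
                  "indexhop_error_config")
  }
  k <- table(end_classified$end_class)
  estimate_attribution(
    non_swapped = as.numeric(k[["NON_SWAP"]]),
    undetermined = as.numeric(k[["UNDETERMINED_END"]]),
    known_i7 = as.numeric(k[["I7_SWAP"]]),
    known_i5 = as.numeric(k[["I5_SWAP"]]),
    double_swaps = as.numeric(k[["DOUBLE_SWAP"]]))
}

#' @export
print.mixture_attribution <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("Two-organism mixture swap attribution\n")
  cat(sprintf("  Qualifying reads (N'):            %s\n", fmt(x$n_prime)))
  cat(sprintf("  Non-swapped reads:                %s\n", fmt(x$non_swapped)))
  cat(sprintf("  Undetermined i7-or-i5 swaps:      %s\n", fmt(x$undetermined)))
  cat(sprintf("  Known i7 swaps:                   %s\n", fmt(x$known_i7)))
  cat(sprintf("  Known i5 swaps:                   %s\n", fmt(x$known_i5)))
  cat(sprintf("  Known double swaps:               %s\n", fmt(x$double_swaps)))
  cat(sprintf("  Estimated total i7 swaps:         %s\n", fmt(round(x$est_total_i7))))
  cat(sprintf("  Estimated total i5 swaps:         %s\n", fmt(round(x$est_total_i5))))
  cat(sprintf("  p(i7 swap) = %.4f   p(i5 swap) = %.4f   p(total swap) = %.4f\n",
              round_half_up(x$p_i7), round_half_up(x$p_i5),
              round_half_up(x$p_total)))
  if (!is.null(x$total_swapped) &&
      !isTRUE(all.equal(x$total_swapped,
                        x$undetermined + x$known_i7 + x$known_i5 + x$double_swaps))) {
    cat(sprintf(
      "  Note: supplied total swapped (%s) differs from the component sum (%s);\n  p(total swap) uses the supplied total, component-based value = %.4f\n",
      fmt(x$total_swapped),
      fmt(x$undetermined + x$known_i7 + x$known_i5 + x$double_swaps),
      round_half_up(x$p_total_components)))
  }
  invisible(x)
}

#' @export
tidy.mixture_attribution <- function(x, ...) {
  tibble(
    quantity = c("Total non-swapped reads",
                 "Undetermined i7 or i5 swaps",
                 "Known i7 swaps", "Known i5 swaps",
                 "Known double i7 and i5 swaps",
                 "Estimated total i7 swaps", "Estimated total i5 swaps",
                 "p(i7 Swap)", "p(i5 Swap)", "p(Total Swap)"),
    value = c(x$non_swapped, x$undetermined, x$known_i7, x$known_i5,
              x$double_swaps, x$est_total_i7, x$est_total_i5,
              x$p_i7, x$p_i5, x$p_total))
}

#' @export
glance.mixture_attribution <- function(x, ...) {
  tibble(n_prime = x$n_prime, p_i7 = x$p_i7, p_i5 = x$p_i5,
         p_total = x$p_total,
         est_total_i7 = x$est_total_i7, est_total_i5 = x$est_total_i5)
}
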