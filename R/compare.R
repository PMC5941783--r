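#' Compare fragment metrics between swapped and non-swapped reads
#'
#' Splits classified reads into the detectably swapped (`SWAPPED`) and
#' correctly paired (`MATCHED`) populations and compares their fragment
#' covariates: insert-length mean and SD, percent chimerism, and the GC
#' spectrum.  GC is histogrammed in bins of width `gc_bin_width` over
#' the unit interval; each population's histogram is normalised to 1 and the
#' swapped spectrum is reported as a ratio to the non-swapped spectrum,
#' so a ratio below 1 in high-GC bins reads directly as "fewer high-GC
#' reads among swaps".
#'
#' @param classified Output of [classify_reads()] carrying `insert_len`,
#'   `gc` and `chimeric` columns (simulation truth or external
#'   annotation).
#' @param gc_bin_width GC bin width (default 0.05).
#' @return Object of class `population_comparison` with `summary` (one
#'   row per population: `n`, `mean_insert`, `sd_insert`,
#'   `pct_chimeric`; `NA` markers for an empty population) and
#'   `gc_ratio` (per-bin normalised frequencies and their ratio).
#' @export
compare_populations <- function(classified, gc_bin_width = 0.05) {
  need <- c("insert_len", "gc", "chimeric")
  if (!all(need %in% names(classified))) {
    stop_indexhop(
      sprintf("Missing annotation column(s): %s.",
              paste(setdiff(need, names(classified)), collapse = ", ")),
      "indexhop_error_config")
  }
  pops <- list(
    non_swapped = classified[classified$class == "MATCHED", , drop = FALSE],
    swapped = classified[classified$class == "SWAPPED", , drop = FALSE])

  summary <- bind_rows(lapply(names(pops), function(nm) {
    p <- pops[[nm]]
    if (nrow(p) == 0L) {
      return(tibble(population = nm, n = 0L, mean_insert = NA_real_,
                    sd_insert = NA_real_, pct_chimeric = NA_real_))
    }
    tibble(population = nm, n = nrow(p),
           mean_insert = mean(p$insert_len),
           sd_insert = sd(p$insert_len),
           pct_chimeric = 100 * mean(p$chimeric))
  }))

  breaks <- seq(0, 1, by = gc_bin_width)
  hist_frac <- function(p) {
    if (nrow(p) == 0L) return(rep(NA_real_, length(breaks) - 1L))
    h <- tabulate(findInterval(p$gc, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
    h / sum(h)
  }
  f_non <- hist_frac(pops$non_swapped)
  f_swp <- hist_frac(pops$swapped)
  gc_ratio <- tibble(
    gc_bin_low = breaks[-length(breaks)],
    gc_bin_high = breaks[-1],
    gc_bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    non_swapped_frac = f_non,
    swapped_frac = f_swp,
    ratio = if_else(!is.na(f_non) & f_non > 0, f_swp / f_non, NA_real_))

  structure(list(summary = summary, gc_ratio = gc_ratio),
            class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat("Swapped vs non-swapped population metrics\n")
  print(x$summary)
  occupied <- sum(!is.na(x$gc_ratio$ratio))
  cat(sprintf("GC spectrum ratio (swapped / non-swapped) over %d occupied bins\n",
              occupied))
  invisible(x)
}

#' @export
tidy.population_comparison <- function(x, ...) x$summary

#' Plot the GC spectrum ratio of swapped versus non-swapped reads
#'
#' @param object A `population_comparison`.
#' @param ... Unused.
#' @return A ggplot: per-GC-bin normalised read fraction ratio; points
#'   below the dashed unity line mark GC bins depleted among swapped
#'   reads.
#' @export
autoplot.population_comparison <- function(object, ...) {
  d <- object$gc_ratio[!is.na(object$gc_ratio$ratio), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc_bin_mid, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "GC fraction (bin midpoint)",
                  y = "Normalised read fraction ratio (swapped / non-swapped)",
                  title = "GC spectrum of swapped relative to non-swapped reads") +
    ggplot2::theme_minimal()
}
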