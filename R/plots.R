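#' Heatmap of the index combination count matrix
#'
#' The diagonal cells are the correct (expected) index combinations;
#' every off-diagonal cell is a detectable swapped combination.  Counts
#' are displayed on a log10 colour scale so the rare swapped cells stay
#' visible next to the matched diagonal.
#'
#' @param object A `swap_tally` from [tabulate_reads()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.swap_tally <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i5_owner, y = .data$i7_owner,
                                  fill = log10(.data$reads + 1))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(data = d[d$matched, , drop = FALSE], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "log10(reads + 1)") +
    ggplot2::labs(x = "i5 index owner", y = "i7 index owner",
                  title = "Read counts per index combination",
                  subtitle = "Outlined diagonal = expected pairs; off-diagonal = swaps") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Flow-cell tile map of per-tile swap rates
#'
#' One facet per surface; tiles along the x axis, swaths along the y
#' axis, filled by the per-tile detectable swap rate.
#'
#' @param tally A `swap_tally` with tile information.
#' @return A ggplot.
#' @export
plot_tile_rates <- function(tally) {
  d <- render_tile_heatmap_table(tally)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tile, y = factor(.data$swath),
                                  fill = .data$rate)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~surface, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "swap rate", na.value = "grey80") +
    ggplot2::labs(x = "tile", y = "swath",
                  title = "Detectable swap rate across the flow-cell lane") +
    ggplot2::theme_minimal()
}
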