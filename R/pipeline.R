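#' Run the full simulate / demultiplex / attribute pipeline
#'
#' Composes the package's stages end to end: simulate a pooled run
#' ([simulate_pool()] or, when `organism_of` is given,
#' [simulate_mixture()]), classify every read against the sample sheet
#' ([classify_reads()]), tabulate combination and per-tile counts
#' ([tabulate_reads()]), and -- for a two-organism design -- classify
#' swap ends and estimate per-end swap probabilities
#' ([attribute_mixture()]) plus the swapped-versus-non-swapped
#' population comparison ([compare_populations()]).  The result is a
#' single report object; identical arguments and `seed` give an
#' identical report (up to its timestamp).
#'
#' @inheritParams simulate_pool
#' @inheritParams classify_reads
#' @param ... Further simulation parameters passed to [simulate_pool()].
#' @param seed Integer seed driving every random draw.
#' @return Object of class `swap_report`: `tally` (`swap_tally`),
#'   `swap_rate`, `attribution` (`mixture_attribution` or `NULL`),
#'   `populations` (`population_comparison`), `tiles` (the long-format
#'   per-tile table from [render_tile_heatmap_table()]), `classified`
#'   (per-read tibble), and `provenance` (package version, seed,
#'   `n_reads`, timestamp).
#' @export
#' @examples
#' sheet <- design_index_set(4, seed = 1)
#' rep <- run_pipeline(sheet, n_reads = 500, seed = 42)
#' rep$swap_rate
run_pipeline <- function(samplesheet, n_reads, organism_of = NULL,
                         max_mismatch = 1L, min_mean_q = 30, ...,
                         seed) {
  reads <- if (is.null(organism_of)) {
    simulate_pool(samplesheet, n_reads, seed = seed, ...)
  } else {
    simulate_mixture(samplesheet, organism_of, n_reads, seed = seed, ...)
  }
  classified <- classify_reads(reads, samplesheet, max_mismatch, min_mean_q)
  tally <- tabulate_reads(classified, samplesheet)

  attribution <- NULL
  if (!is.null(organism_of)) {
    classified <- classify_swap_end(classified, organism_of)
    attribution <- attribute_mixture(classified)
  }

  structure(
    list(tally = tally,
         swap_rate = if (sum(tally$counts) > 0) swap_rate(tally) else NA_real_,
         attribution = attribution,
         populations = compare_populations(classified),
         tiles = if (nrow(tally$tiles)) render_tile_heatmap_table(tally) else
           tally$tiles,
         classified = classified,
         provenance = list(
           package = "indexhop",
           version = as.character(utils::packageVersion("indexhop")),
           seed = seed,
           n_reads = n_reads,
           n_samples = nrow(samplesheet),
           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "swap_report")
}

#' @export
print.swap_report <- function(x, ...) {
  cat(sprintf("indexhop pipeline report (seed %s, %s reads, %d samples)\n",
              x$provenance$seed,
              format(x$provenance$n_reads, big.mark = ","),
              x$provenance$n_samples))
  print(x$tally)
  if (!is.null(x$attribution)) print(x$attribution)
  invisible(x)
}

#' Long-format per-tile swap table
#'
#' Flattens the per-tile grid of a tally into the long-format table used
#' for flow-cell heatmaps: one row per (surface, swath, tile) with the
#' swapped and total classified read counts and the per-tile swap rate
#' (`NA`, rendered blank on write, where a tile holds no classified
#' reads).
#'
#' @param tally A `swap_tally` with a nonempty tile grid.
#' @return Tibble `surface`, `swath`, `tile`, `swapped`, `total`, `rate`.
#' @export
render_tile_heatmap_table <- function(tally) {
  stopifnot(inherits(tally, "swap_tally"))
  if (nrow(tally$tiles) == 0L) {
    stop_indexhop("The tally has no per-tile information.",
                  "indexhop_error_insufficient_input")
  }
  # complete the grid over the observed coordinate ranges so tiles with no
  # classified reads appear with a blank rate rather than vanishing
  grid <- tidyr::complete(
    tally$tiles,
    surface = seq_len(max(tally$tiles$surface)),
    swath = seq_len(max(tally$tiles$swath)),
    tile = seq_len(max(tally$tiles$tile)),
    fill = list(swapped = 0L, classified = 0L))
  grid |>
    mutate(total = .data$classified,
           rate = if_else(.data$total > 0, .data$swapped / .data$total,
                          NA_real_)) |>
    arrange(.data$surface, .data$swath, .data$tile) |>
    dplyr::select("surface", "swath", "tile", "swapped", "total", "rate")
}

report_summary_list <- function(report, include_timestamp = TRUE) {
  g <- glance(report$tally)
  out <- list(
    provenance = report$provenance,
    classes = list(matched = g$matched, swapped = g$swapped,
                   undetermined = g$undetermined,
                   low_quality = g$low_quality, total = g$total),
    swap_rate = report$swap_rate)
  if (!include_timestamp) out$provenance$created <- NULL
  if (!is.null(report$attribution)) {
    a <- report$attribution
    out$attribution <- list(
      "Total Non-swapped reads" = a$non_swapped,
      "Undetermined i7 or i5 swaps" = a$undetermined,
      "Known i7 swaps" = a$known_i7,
      "Known i5 swaps" = a$known_i5,
      "Known double i7 and i5 swaps" = a$double_swaps,
      "Estimated total i7 swaps" = a$est_total_i7,
      "Estimated total i5 swaps" = a$est_total_i5,
      "p(i7 Swap)" = a$p_i7,
      "p(i5 Swap)" = a$p_i5,
      "p(Total Swap)" = a$p_total)
  }
  if (!is.null(report$populations)) {
    out$populations <- report$populations$summary
  }
  out
}

#' Write a pipeline report to disk
#'
#' Writes `summary.json` (class tallies, swap rate, attribution,
#' population metrics, provenance), `matrix.tsv` (the sample-by-sample
#' combination count matrix with sample ids as header row and column),
#' and `tiles.tsv` (long-format per-tile table; empty rates blank).
#'
#' @param report A `swap_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_swap_report <- function(report, dir) {
  stopifnot(inherits(report, "swap_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(report_summary_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, json_path)

  mat_path <- file.path(dir, "matrix.tsv")
  m <- data.frame(sample_id = rownames(report$tally$counts),
                  as.data.frame.matrix(report$tally$counts),
                  check.names = FALSE)
  readr::write_tsv(m, mat_path)
  paths <- c(paths, mat_path)

  if (nrow(report$tiles)) {
    tile_path <- file.path(dir, "tiles.tsv")
    readr::write_tsv(report$tiles, tile_path, na = "")
    paths <- c(paths, tile_path)
  }
  invisible(paths)
}
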