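# per-base index sequencing error: substitute to one of the other three
# bases and drop the quality of the miscalled cycle to quality_low
apply_index_errors <- function(seqs, rate, quality_high, quality_low) {
  L <- nchar(seqs[1])
  n <- length(seqs)
  qual <- rep.int(phred_string(quality_high, L), n)
  if (rate <= 0 || n == 0L) {
    return(list(seq = seqs, qual = qual))
  }
  err <- matrix(runif(n * L) < rate, nrow = L)
  if (!any(err)) {
    return(list(seq = seqs, qual = qual))
  }
  m <- seq_char_matrix(seqs)
  base_idx <- match(intToUtf8(m[err], multiple = TRUE), DNA_BASES)
  # row b of alt_table lists the three substitution targets for base b
  alt_table <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  pick <- sample.int(3L, length(base_idx), replace = TRUE)
  m[err] <- utf8ToInt(paste(DNA_BASES, collapse = ""))[alt_table[cbind(base_idx, pick)]]
  qm <- matrix(rep.int(utf8ToInt(phred_string(quality_high, 1L)), n * L), nrow = L)
  qm[err] <- utf8ToInt(phred_string(quality_low, 1L))
  list(seq = collapse_char_matrix(m), qual = collapse_char_matrix(qm))
}

check_sim_args <- function(samplesheet, n_reads, abundances,
                           p_swap_i7, p_swap_i5, index_error_rate,
                           chimera_rate_base, chimera_rate_swapped, tiles) {
  check_nonredundant(samplesheet)
  if (!is.numeric(n_reads) || length(n_reads) != 1L || n_reads < 0) {
    stop_indexhop("`n_reads` must be a single non-negative number.",
                  "indexhop_error_config")
  }
  if (!is.null(abundances)) {
    if (length(abundances) != nrow(samplesheet) || any(abundances < 0)) {
      stop_indexhop("`abundances` must be non-negative, one value per sample.",
                    "indexhop_error_config")
    }
    if (abs(sum(abundances) - 1) > 1e-9) {
      stop_indexhop("`abundances` must sum to 1 (tolerance 1e-9).",
                    "indexhop_error_config")
    }
  }
  check_probability(p_swap_i7, "p_swap_i7")
  check_probability(p_swap_i5, "p_swap_i5")
  check_probability(index_error_rate, "index_error_rate")
  check_probability(chimera_rate_base, "chimera_rate_base")
  check_probability(chimera_rate_swapped, "chimera_rate_swapped")
  if (length(tiles) != 3L || any(tiles < 1)) {
    stop_indexhop("`tiles` must be three positive integers: surfaces, swaths, tiles.",
                  "indexhop_error_config")
  }
  invisible(TRUE)
}

as_organism_map <- function(organism_of, samplesheet) {
  if (is.data.frame(organism_of)) {
    if (!all(c("sample_id", "organism") %in% names(organism_of))) {
      stop_indexhop("`organism_of` needs columns `sample_id` and `organism`.",
                    "indexhop_error_config")
    }
    map <- stats::setNames(as.character(organism_of$organism),
                           organism_of$sample_id)
  } else {
    map <- organism_of
  }
  if (is.null(names(map)) || !all(samplesheet$sample_id %in% names(map))) {
    stop_indexhop("`organism_of` must label every sample in the sheet.",
                  "indexhop_error_config")
  }
  map[samplesheet$sample_id]
}

#' Simulate a pooled dual-indexed read population with index swapping
#'
#' Generates the two index reads (i7 and i5) of every cluster in a pooled
#' run, together with full per-read ground truth.  The generative model,
#' applied independently per read:
#'
#' 1. The true sample is drawn by pool `abundances`.
#' 2. An insert length (lognormal) and fragment GC (Beta) are drawn.
#' 3. Each end swaps independently with probability
#'    `plogis(qlogis(p_swap_end) + swap_length_coeff * z_len +
#'    swap_gc_coeff * z_gc)`, where `z_len`, `z_gc` standardise the
#'    covariates under their configured distributions.  Negative
#'    coefficients make short, AT-rich fragments swap more, matching the
#'    free-adapter amplification-efficiency mechanism.
#' 4. A swapping end's replacement index is drawn from the pool's indexes
#'    weighted by sample abundance (the free-adapter model); drawing the
#'    read's own index is allowed and produces no detectable swap.
#' 5. Per-base substitution error is applied to the observed index reads
#'    at `index_error_rate`; miscalled cycles carry `quality_low`, all
#'    others `quality_high`.
#' 6. The cluster is placed uniformly on the
#'    surfaces x swaths x tiles grid.
#' 7. The read is chimeric with probability `chimera_rate_swapped` if
#'    either end swapped, else `chimera_rate_base`.
#'
#' Output is byte-identical for identical arguments and `seed`.
#'
#' @param samplesheet Non-redundant dual-index sample sheet
#'   (`sample_id`, `i7`, `i5`).
#' @param n_reads Number of reads (clusters) to simulate.
#' @param abundances Per-sample pool fractions summing to 1; default equal.
#' @param p_swap_i7,p_swap_i5 Baseline per-end swap probabilities.
#'   Defaults mirror the roughly 1.3% (i7) and 3.0% (i5) rates estimated
#'   for a PCR-free two-organism pool; the i5 end swaps about twice as
#'   often as i7.
#' @param index_error_rate Per-base index-read substitution probability.
#' @param quality_high,quality_low Phred scores assigned to correct and
#'   miscalled index bases.
#' @param tiles Integer vector `c(surfaces, swaths, tiles)` describing the
#'   flow-cell lane grid; default `c(2, 2, 24)` (a HiSeqX-like lane).
#' @param organism_of Optional organism label per sample: named character
#'   vector or data frame (`sample_id`, `organism`).
#' @param insert_mean_log,insert_sd_log Lognormal parameters of insert
#'   length in bp.
#' @param gc_beta_a,gc_beta_b Beta parameters of fragment GC fraction.
#' @param swap_length_coeff,swap_gc_coeff Logistic-scale covariate effects
#'   on the per-end swap probability (0 disables the dependence).
#' @param chimera_rate_base,chimera_rate_swapped Chimerism probability for
#'   reads without / with a swap event.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return A tibble with one row per read: `read_id`, observed index
#'   reads `i7_obs`, `i5_obs` with qualities `i7_qual`, `i5_qual`, tile
#'   coordinates `surface`, `swath`, `tile`, and truth columns
#'   `true_sample`, `i7_source`, `i5_source` (the sample whose index each
#'   end carries, equal to `true_sample` unless that end swapped),
#'   optionally `organism`, and `insert_len`, `gc`, `chimeric`.
#' @seealso [simulate_mixture()], [truth_table()], [write_index_fastq()]
#' @export
#' @examples
#' sheet <- design_index_set(4, seed = 1)
#' reads <- simulate_pool(sheet, n_reads = 100, seed = 1)
#' dplyr::count(reads, true_sample)
simulate_pool <- function(samplesheet, n_reads,
                          abundances = NULL,
                          p_swap_i7 = 0.0131, p_swap_i5 = 0.0302,
                          index_error_rate = 0.001,
                          quality_high = 37L, quality_low = 11L,
                          tiles = c(2L, 2L, 24L),
                          organism_of = NULL,
                          insert_mean_log = log(350), insert_sd_log = 0.25,
                          gc_beta_a = 8, gc_beta_b = 11.5,
                          swap_length_coeff = -0.3, swap_gc_coeff = -0.2,
                          chimera_rate_base = 0.01,
                          chimera_rate_swapped = 0.05,
                          seed = NULL) {
  check_sim_args(samplesheet, n_reads, abundances, p_swap_i7, p_swap_i5,
                 index_error_rate, chimera_rate_base, chimera_rate_swapped,
                 tiles)
  n <- as.integer(n_reads)
  S <- nrow(samplesheet)
  if (is.null(abundances)) abundances <- rep(1 / S, S)
  org_map <- if (!is.null(organism_of)) as_organism_map(organism_of, samplesheet)

  run <- function() {
    true <- sample.int(S, n, replace = TRUE, prob = abundances)
    insert_len <- rlnorm(n, insert_mean_log, insert_sd_log)
    gc <- rbeta(n, gc_beta_a, gc_beta_b)

    z_len <- (log(insert_len) - insert_mean_log) / insert_sd_log
    gc_mu <- gc_beta_a / (gc_beta_a + gc_beta_b)
    gc_sd <- sqrt(gc_beta_a * gc_beta_b /
                    ((gc_beta_a + gc_beta_b)^2 * (gc_beta_a + gc_beta_b + 1)))
    z_gc <- (gc - gc_mu) / gc_sd

    p7 <- plogis(qlogis(p_swap_i7) + swap_length_coeff * z_len + swap_gc_coeff * z_gc)
    p5 <- plogis(qlogis(p_swap_i5) + swap_length_coeff * z_len + swap_gc_coeff * z_gc)

    ev7 <- runif(n) < p7
    ev5 <- runif(n) < p5
    i7_source <- true
    i5_source <- true
    if (any(ev7)) {
      i7_source[ev7] <- sample.int(S, sum(ev7), replace = TRUE, prob = abundances)
    }
    if (any(ev5)) {
      i5_source[ev5] <- sample.int(S, sum(ev5), replace = TRUE, prob = abundances)
    }

    obs7 <- apply_index_errors(samplesheet$i7[i7_source], index_error_rate,
                               quality_high, quality_low)
    obs5 <- apply_index_errors(samplesheet$i5[i5_source], index_error_rate,
                               quality_high, quality_low)

    surface <- sample.int(tiles[1], n, replace = TRUE)
    swath <- sample.int(tiles[2], n, replace = TRUE)
    tile <- sample.int(tiles[3], n, replace = TRUE)

    chim_p <- if_else(ev7 | ev5, chimera_rate_swapped, chimera_rate_base)
    chimeric <- runif(n) < chim_p

    reads <- tibble(
      read_id = sprintf("read_%08d", seq_len(n)),
      i7_obs = obs7$seq, i5_obs = obs5$seq,
      i7_qual = obs7$qual, i5_qual = obs5$qual,
      surface = surface, swath = swath, tile = tile,
      true_sample = samplesheet$sample_id[true],
      i7_source = samplesheet$sample_id[i7_source],
      i5_source = samplesheet$sample_id[i5_source],
      insert_len = pmax(1, round(insert_len)),
      gc = gc,
      chimeric = chimeric)
    if (!is.null(org_map)) {
      reads$organism <- unname(org_map[reads$true_sample])
      reads <- reads[, c("read_id", "i7_obs", "i5_obs", "i7_qual", "i5_qual",
                         "surface", "swath", "tile", "true_sample",
                         "i7_source", "i5_source", "organism",
                         "insert_len", "gc", "chimeric")]
    }
    reads
  }

  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a two-organism mixture pool
#'
#' Convenience wrapper around [simulate_pool()] for the two-organism
#' (e.g. human / E. coli) mixture design used to attribute swaps to the
#' i7 or i5 end: each sample carries one of exactly two organism labels,
#' and the label of each read's true sample is recorded so downstream
#' end-classification can treat it as the read's mapping organism.
#'
#' @inheritParams simulate_pool
#' @param organism_of Organism label per sample (named character vector or
#'   data frame `sample_id`, `organism`); must use exactly two distinct
#'   labels covering the whole sheet.
#' @param ... Passed to [simulate_pool()].
#' @return As [simulate_pool()], with an `organism` column.
#' @export
#' @examples
#' sheet <- design_index_set(4, seed = 1)
#' orgs <- setNames(rep(c("human", "ecoli"), each = 2), sheet$sample_id)
#' reads <- simulate_mixture(sheet, orgs, n_reads = 50, seed = 1)
simulate_mixture <- function(samplesheet, organism_of, n_reads, ...) {
  map <- as_organism_map(organism_of, samplesheet)
  if (length(unique(map)) != 2L) {
    stop_indexhop(
      sprintf("The mixture design requires exactly two organism labels, got %d.",
              length(unique(map))),
      "indexhop_error_config")
  }
  simulate_pool(samplesheet, n_reads, organism_of = map, ...)
}

#' Extract the per-read truth table from simulated reads
#'
#' @param reads Tibble from [simulate_pool()] or [simulate_mixture()].
#' @return Tibble of the truth columns keyed by `read_id`.
#' @export
truth_table <- function(reads) {
  cols <- intersect(
    c("read_id", "true_sample", "i7_source", "i5_source", "organism",
      "insert_len", "gc", "chimeric", "surface", "swath", "tile"),
    names(reads))
  as_tibble(reads[, cols])
}

#' Write or read a truth table as TSV
#'
#' @param reads Simulated reads (or a truth table).
#' @param path File path.
#' @export
write_truth_table <- function(reads, path) {
  readr::write_tsv(truth_table(reads), path)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}
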