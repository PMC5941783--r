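#' Hamming distance between equal-length index sequences
#'
#' Number of positions at which two sequences differ.  Vectorised over
#' pairs: `a` and `b` are recycled to a common length and compared
#' element-wise.
#'
#' @param a,b Character vectors of equal-length sequences.
#' @return Integer vector of distances, one per pair.
#' @export
#' @examples
#' hamming_distance("AAAAAAAA", "AAAAAAAT")
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop_indexhop("Sequences must have equal lengths for Hamming distance.",
                  "indexhop_error_length")
  }
  am <- seq_char_matrix(a)
  bm <- seq_char_matrix(b)
  as.integer(colSums(am != bm))
}

#' Minimum pairwise Hamming distance within a sequence set
#'
#' @param seqs Character vector of at least two equal-length sequences.
#' @return Single integer: the smallest Hamming distance over all
#'   unordered pairs.
#' @export
#' @examples
#' min_pairwise_distance(c("AAAAAAAA", "AAAATTTT", "TTTTTTTT"))
min_pairwise_distance <- function(seqs) {
  if (length(seqs) < 2L) {
    stop_indexhop("Need at least two sequences for a pairwise distance.",
                  "indexhop_error_insufficient_input")
  }
  m <- seq_char_matrix(seqs)
  k <- ncol(m)
  d <- nrow(m)
  for (i in seq_len(k - 1L)) {
    di <- colSums(m[, i] != m[, (i + 1L):k, drop = FALSE])
    d <- min(d, di)
  }
  as.integer(d)
}

# chemistry signal rules: a cycle's base composition must light both
# imaging channels.  Two-color instruments read G as dark (no dye), so a
# cycle needs at least one base in the red channel {A,C} and one in the
# green channel {A,T}.  Four-color instruments need both laser pairs
# {A,C} and {G,T} represented.
color_rules <- list(
  four_color = function(bases) {
    any(bases %in% c("A", "C")) && any(bases %in% c("G", "T"))
  },
  two_color = function(bases) {
    any(bases %in% c("A", "C")) && any(bases %in% c("A", "T"))
  }
)

#' Constraints for dual-index validation and design
#'
#' Bundles the sequence-quality rules an index set is held to: minimum
#' pairwise Hamming distance within each end's list, GC-content window,
#' maximum homopolymer run, and per-cycle color balance for the imaging
#' chemistry.
#'
#' @param min_hamming Minimum pairwise Hamming distance required within
#'   the i7 list and within the i5 list.  The default 3 permits confident
#'   single-mismatch correction on 8-mers.
#' @param gc_min,gc_max Allowed GC fraction per index, inclusive.
#' @param max_homopolymer Longest allowed single-base run.
#' @param chemistry `"four_color"` or `"two_color"`; selects the built-in
#'   per-cycle signal rule.  Ignored when `color_rule` is supplied.
#' @param require_color_balance Check per-cycle color balance at all?
#' @param color_rule Optional custom predicate `function(bases)` returning
#'   `TRUE` when the set of bases observed at one cycle carries enough
#'   signal; overrides `chemistry`.
#' @return An object of class `index_constraints`.
#' @export
#' @examples
#' index_constraints(min_hamming = 3, chemistry = "two_color")
index_constraints <- function(min_hamming = 3L,
                              gc_min = 0.25, gc_max = 0.75,
                              max_homopolymer = 2L,
                              chemistry = c("four_color", "two_color"),
                              require_color_balance = TRUE,
                              color_rule = NULL) {
  if (is.null(color_rule)) {
    chemistry <- match.arg(chemistry)
    color_rule <- color_rules[[chemistry]]
  } else {
    stopifnot(is.function(color_rule))
    chemistry <- "custom"
  }
  if (gc_min > gc_max) {
    stop_indexhop("`gc_min` must not exceed `gc_max`.", "indexhop_error_config")
  }
  stopifnot(min_hamming >= 0, max_homopolymer >= 1)
  structure(
    list(min_hamming = as.integer(min_hamming),
         gc_min = gc_min, gc_max = gc_max,
         max_homopolymer = as.integer(max_homopolymer),
         chemistry = chemistry,
         require_color_balance = isTRUE(require_color_balance),
         color_rule = color_rule),
    class = "index_constraints")
}

gc_fraction <- function(seqs) {
  stringr::str_count(seqs, "[GC]") / nchar(seqs)
}

max_homopolymer_run <- function(seqs) {
  vapply(strsplit(seqs, ""),
         function(x) max(rle(x)$lengths),
         integer(1))
}

check_samplesheet <- function(samplesheet, require_nonempty = TRUE) {
  if (!is.data.frame(samplesheet) ||
      !all(c("sample_id", "i7", "i5") %in% names(samplesheet))) {
    stop_indexhop(
      "A sample sheet needs columns `sample_id`, `i7`, `i5`.",
      "indexhop_error_samplesheet")
  }
  if (require_nonempty && nrow(samplesheet) == 0L) {
    stop_indexhop("The sample sheet is empty.",
                  "indexhop_error_insufficient_input")
  }
  if (anyDuplicated(samplesheet$sample_id)) {
    stop_indexhop("`sample_id` values must be unique.",
                  "indexhop_error_samplesheet")
  }
  check_index_alphabet(samplesheet$i7, "i7")
  check_index_alphabet(samplesheet$i5, "i5")
  if (length(unique(nchar(c(samplesheet$i7, samplesheet$i5)))) > 1L) {
    stop_indexhop("All index sequences must share one length.",
                  "indexhop_error_length")
  }
  invisible(samplesheet)
}

# non-redundancy only: every i7 and every i5 used by exactly one sample
check_nonredundant <- function(samplesheet) {
  check_samplesheet(samplesheet)
  if (anyDuplicated(samplesheet$i7) || anyDuplicated(samplesheet$i5)) {
    stop_indexhop(
      "The sample sheet is not non-redundant: an i7 or i5 sequence is shared by two samples.",
      "indexhop_error_redundant_sheet")
  }
  invisible(samplesheet)
}

dup_violations <- function(samplesheet, end) {
  seqs <- samplesheet[[end]]
  dup_seqs <- unique(seqs[duplicated(seqs)])
  vapply(dup_seqs, function(s) {
    sprintf("%s %s shared by samples %s", end, s,
            paste(samplesheet$sample_id[seqs == s], collapse = ", "))
  }, character(1))
}

distance_violations <- function(samplesheet, end, min_hamming) {
  seqs <- samplesheet[[end]]
  if (length(seqs) < 2L || min_hamming <= 0L) return(character(0))
  m <- seq_char_matrix(seqs)
  out <- character(0)
  for (i in seq_len(ncol(m) - 1L)) {
    d <- colSums(m[, i] != m[, (i + 1L):ncol(m), drop = FALSE])
    bad <- which(d < min_hamming)
    for (j in bad) {
      out <- c(out, sprintf(
        "%s distance %d < %d between samples %s and %s",
        end, d[j], min_hamming,
        samplesheet$sample_id[i], samplesheet$sample_id[i + j]))
    }
  }
  out
}

balance_violations <- function(samplesheet, end, rule) {
  m <- matrix(intToUtf8(seq_char_matrix(samplesheet[[end]]), multiple = TRUE),
              nrow = nchar(samplesheet[[end]][1]))
  bad <- which(!vapply(seq_len(nrow(m)),
                       function(i) isTRUE(rule(unique(m[i, ]))),
                       logical(1)))
  vapply(bad, function(i) {
    sprintf("%s cycle %d has unbalanced base composition {%s}",
            end, i, paste(sort(unique(m[i, ])), collapse = ","))
  }, character(1))
}

#' Validate a dual-index sample sheet against design constraints
#'
#' Runs, in order: (1) i7 uniqueness across samples; (2) i5 uniqueness;
#' (3) minimum pairwise Hamming distance within the i7 list and within the
#' i5 list (the two ends are checked separately, since swapping is a
#' within-end phenomenon); (4) GC window per index; (5) homopolymer run
#' limit; (6) per-cycle color balance for the configured chemistry.
#'
#' @param samplesheet Data frame with columns `sample_id`, `i7`, `i5`.
#' @param constraints An [index_constraints()] object.
#' @return An object of class `index_set_report` with elements `passed`
#'   (TRUE iff no violations), `min_pairwise_distance_i7`,
#'   `min_pairwise_distance_i5`, and `violations`, a tibble with columns
#'   `constraint` and `detail`.  [tidy()] returns the violations tibble.
#' @export
#' @examples
#' sheet <- tibble::tibble(sample_id = c("A", "B"),
#'                         i7 = c("ACACGGTT", "TGTGCCAA"),
#'                         i5 = c("CCAAGGTT", "GGTTAACC"))
#' validate_dual_index_set(sheet, index_constraints(min_hamming = 3))
validate_dual_index_set <- function(samplesheet,
                                    constraints = index_constraints()) {
  check_samplesheet(samplesheet)
  v <- list()
  add <- function(constraint, details) {
    if (length(details)) {
      v[[length(v) + 1L]] <<- tibble(constraint = constraint, detail = details)
    }
  }

  add("i7_uniqueness", dup_violations(samplesheet, "i7"))
  add("i5_uniqueness", dup_violations(samplesheet, "i5"))
  add("min_hamming", distance_violations(samplesheet, "i7", constraints$min_hamming))
  add("min_hamming", distance_violations(samplesheet, "i5", constraints$min_hamming))

  for (end in c("i7", "i5")) {
    seqs <- samplesheet[[end]]
    gc <- gc_fraction(seqs)
    bad <- which(gc < constraints$gc_min | gc > constraints$gc_max)
    add("gc_content", sprintf(
      "%s of sample %s has GC %.3f outside [%.2f, %.2f]",
      end, samplesheet$sample_id[bad], gc[bad],
      constraints$gc_min, constraints$gc_max))

    runs <- max_homopolymer_run(seqs)
    bad <- which(runs > constraints$max_homopolymer)
    add("homopolymer", sprintf(
      "%s of sample %s has a homopolymer run of %d (max %d)",
      end, samplesheet$sample_id[bad], runs[bad], constraints$max_homopolymer))
  }

  if (constraints$require_color_balance) {
    add("color_balance", balance_violations(samplesheet, "i7", constraints$color_rule))
    add("color_balance", balance_violations(samplesheet, "i5", constraints$color_rule))
  }

  violations <- if (length(v)) bind_rows(v) else
    tibble(constraint = character(0), detail = character(0))

  mind <- function(seqs) {
    if (length(seqs) >= 2L) min_pairwise_distance(seqs) else NA_integer_
  }
  structure(
    list(passed = nrow(violations) == 0L,
         min_pairwise_distance_i7 = mind(samplesheet$i7),
         min_pairwise_distance_i5 = mind(samplesheet$i5),
         n_samples = nrow(samplesheet),
         violations = violations,
         constraints = constraints),
    class = "index_set_report")
}

#' @export
print.index_set_report <- function(x, ...) {
  cat(sprintf("Dual-index set report: %s (%d samples)\n",
              if (x$passed) "PASSED" else "FAILED", x$n_samples))
  cat(sprintf("  min pairwise Hamming distance: i7 = %s, i5 = %s\n",
              x$min_pairwise_distance_i7, x$min_pairwise_distance_i5))
  if (!x$passed) {
    cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
    print(x$violations, n = 20)
  }
  invisible(x)
}

#' @export
tidy.index_set_report <- function(x, ...) x$violations

#' @export
glance.index_set_report <- function(x, ...) {
  tibble(passed = x$passed,
         n_samples = x$n_samples,
         min_pairwise_distance_i7 = x$min_pairwise_distance_i7,
         min_pairwise_distance_i5 = x$min_pairwise_distance_i5,
         n_violations = nrow(x$violations))
}

propose_index <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

passes_single <- function(seq, constraints) {
  gc <- gc_fraction(seq)
  gc >= constraints$gc_min && gc <= constraints$gc_max &&
    max_homopolymer_run(seq) <= constraints$max_homopolymer
}

count_unbalanced_cycles <- function(seqs, rule) {
  m <- matrix(intToUtf8(seq_char_matrix(seqs), multiple = TRUE),
              nrow = nchar(seqs[1]))
  sum(!vapply(seq_len(nrow(m)),
              function(i) isTRUE(rule(unique(m[i, ]))),
              logical(1)))
}

# color balance is a set-level property invisible to the greedy accumulator;
# repair by single-sequence replacement, accepting only strict improvements
repair_color_balance <- function(accepted, constraints, length, attempt_budget) {
  attempts <- 0L
  repeat {
    bad <- count_unbalanced_cycles(accepted, constraints$color_rule)
    if (bad == 0L) return(accepted)
    attempts <- attempts + 1L
    if (attempts > attempt_budget) {
      stop_indexhop(
        sprintf("Index search failed: color-balance repair exhausted %d attempts.",
                attempt_budget),
        "indexhop_error_search_failure", attempts = attempts)
    }
    cand <- propose_index(length)
    if (!passes_single(cand, constraints)) next
    pos <- sample.int(length(accepted), 1L)
    trial <- accepted
    trial[pos] <- cand
    others <- trial[-pos]
    if (length(others) &&
        min(hamming_distance(rep(cand, length(others)), others)) <
        constraints$min_hamming) next
    if (count_unbalanced_cycles(trial, constraints$color_rule) < bad) {
      accepted <- trial
    }
  }
}

design_end_list <- function(n, constraints, length, attempt_budget) {
  accepted <- character(0)
  total_attempts <- 0L
  for (slot in seq_len(n)) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      total_attempts <- total_attempts + 1L
      if (attempts > attempt_budget) {
        stop_indexhop(
          sprintf("Index search failed: slot %d exhausted %d attempts (%d total).",
                  slot, attempt_budget, total_attempts),
          "indexhop_error_search_failure",
          attempts = total_attempts)
      }
      cand <- propose_index(length)
      if (!passes_single(cand, constraints)) next
      if (length(accepted) &&
          min(hamming_distance(rep(cand, length(accepted)), accepted)) <
          constraints$min_hamming) next
      accepted <- c(accepted, cand)
      break
    }
  }
  if (constraints$require_color_balance) {
    accepted <- repair_color_balance(accepted, constraints, length,
                                     attempt_budget)
  }
  accepted
}

#' Design a non-redundant dual-index set by seeded rejection sampling
#'
#' Greedily accumulates random index sequences for each end (i7 and i5
#' lists are built and distance-checked separately), accepting a proposal
#' only if it satisfies the per-sequence constraints and the pairwise
#' distance against every already-accepted sequence.  The finished set is
#' re-validated with [validate_dual_index_set()]; if a set-level
#' constraint such as color balance fails, the search restarts from the
#' continuing random stream.  Deterministic given `seed`.
#'
#' @param n Number of samples (index pairs) to design.
#' @param constraints An [index_constraints()] object.
#' @param seed Integer seed; the same `(n, constraints, seed)` always
#'   returns the same set.
#' @param length Index length in bases.
#' @param attempt_budget Proposal budget per slot before the search aborts.
#' @param max_restarts Full-set rebuilds allowed when set-level validation
#'   (e.g. color balance) fails.
#' @return A sample-sheet tibble (`sample_id`, `i7`, `i5`) that passes
#'   [validate_dual_index_set()] under the same constraints.
#' @export
#' @examples
#' sheet <- design_index_set(8, index_constraints(min_hamming = 3), seed = 7)
#' validate_dual_index_set(sheet, index_constraints(min_hamming = 3))$passed
design_index_set <- function(n, constraints = index_constraints(), seed,
                             length = 8L, attempt_budget = 10000L,
                             max_restarts = 25L) {
  stopifnot(n >= 1L, length >= 1L)
  withr::with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      sheet <- tibble(
        sample_id = sprintf("S%02d", seq_len(n)),
        i7 = design_end_list(n, constraints, length, attempt_budget),
        i5 = design_end_list(n, constraints, length, attempt_budget))
      report <- validate_dual_index_set(sheet, constraints)
      if (report$passed) return(sheet)
    }
    stop_indexhop(
      sprintf("Index search failed set-level validation %d times.", max_restarts),
      "indexhop_error_search_failure", attempts = max_restarts)
  })
}

#' Read or write a dual-index sample sheet
#'
#' The sample sheet is a CSV with header `sample_id,i7,i5`, one row per
#' sample, sequences uppercase.
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns a validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!identical(names(sheet)[1:3], c("sample_id", "i7", "i5"))) {
    stop_indexhop(
      sprintf("Expected header `sample_id,i7,i5` in %s.", path),
      "indexhop_error_samplesheet")
  }
  sheet$i7 <- toupper(sheet$i7)
  sheet$i5 <- toupper(sheet$i5)
  check_samplesheet(sheet)
  sheet
}

#' @param samplesheet Data frame with columns `sample_id`, `i7`, `i5`.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(samplesheet, path) {
  check_samplesheet(samplesheet)
  readr::write_csv(samplesheet[, c("sample_id", "i7", "i5")], path)
  invisible(path)
}
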