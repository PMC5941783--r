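# Fixtures and independent oracles shared across the suite.

# small designed sheet for demux unit tests (pairwise distance >= 3)
demo_sheet <- function(n = 4, seed = 11) {
  design_index_set(n, index_constraints(min_hamming = 3), seed = seed)
}

# the 12 + 12 two-organism mixture design
mixture_sheet <- function() {
  design_index_set(24, index_constraints(min_hamming = 3), seed = 104729)
}

mixture_organisms <- function(sheet) {
  stats::setNames(rep(c("human", "ecoli"), each = nrow(sheet) / 2),
                  sheet$sample_id)
}

random_index <- function(n, length = 8) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), length, TRUE),
                           collapse = ""),
         character(1))
}

# character-loop Hamming oracle, independent of the vectorised code path
bf_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  d <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) d <- d + 1L
  d
}

# exhaustive scan oracle for index matching
bf_match <- function(obs, candidates, max_mismatch) {
  d <- vapply(candidates, function(cand) bf_hamming(obs, cand), integer(1))
  hits <- which(d <= max_mismatch)
  if (length(hits) == 0L) return(NA_integer_)
  if (length(hits) > 1L) return(0L)
  hits
}

# truth-derived read classification: detectable class follows directly from
# which sample's index each end carries
truth_classes <- function(reads) {
  ifelse(reads$i7_source == reads$i5_source, "MATCHED", "SWAPPED")
}
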