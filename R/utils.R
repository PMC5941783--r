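DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
stop_indexhop <- function(message, class, ...) {
  abort(message, class = c(class, "indexhop_error"), ...)
}

# L x n matrix of integer character codes; all strings must share one length
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop_indexhop("All sequences must have the same length.",
                  "indexhop_error_length")
  }
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = lens)
}

check_index_alphabet <- function(seqs, what = "index") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop_indexhop(
      sprintf("%s sequences must be uppercase strings over {A,C,G,T}; offending: %s",
              what, paste(utils::head(seqs[bad], 5L), collapse = ", ")),
      "indexhop_error_alphabet")
  }
  invisible(seqs)
}

#' Mean Phred quality of fixed-length quality strings
#'
#' Decodes Phred+33 quality strings and returns the per-read mean quality.
#' All strings must have the same length (index reads of one run do).
#'
#' @param qual Character vector of Phred+33-encoded quality strings.
#' @return Numeric vector of per-read mean Phred scores.
#' @export
#' @examples
#' mean_phred(c("FFFFFFFF", "FF,,FFFF"))
mean_phred <- function(qual) {
  if (length(qual) == 0L) return(numeric(0))
  m <- seq_char_matrix(qual) - 33L
  colMeans(m)
}

# round-half-up, used only for display alongside printed reference tables;
# base round() half-to-even would differ on exact .XXXX5 boundaries
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

phred_string <- function(q, length) {
  strrep(intToUtf8(q + 33L), length)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_indexhop(sprintf("`%s` must be a single probability in [0, 1].", name),
                  "indexhop_error_config")
  }
  x
}

# collapse an L x n character-code matrix back to n strings
collapse_char_matrix <- function(m) {
  if (ncol(m) == 0L) return(character(0))
  ch <- matrix(intToUtf8(m, multiple = TRUE), nrow = nrow(m))
  do.call(paste0, lapply(seq_len(nrow(m)), function(i) ch[i, ]))
}
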