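#' Write index reads as an I1/I2 FASTQ file pair
#'
#' Writes the observed i7 index reads to `i1_path` (I1) and the observed
#' i5 index reads to `i2_path` (I2) as standard 4-line FASTQ with
#' Phred+33 qualities.  The read identifier is identical in both files
#' and carries the tile coordinates as `surface:swath:tile` in the
#' comment field, so tile information survives the round trip.
#'
#' @param reads Tibble with columns `read_id`, `i7_obs`, `i5_obs`,
#'   `i7_qual`, `i5_qual` and optionally `surface`, `swath`, `tile`
#'   (as produced by [simulate_pool()]).
#' @param i1_path,i2_path Output paths (`.gz` suffix compresses).
#' @return Invisibly, `c(i1_path, i2_path)`.
#' @seealso [read_index_fastq()]
#' @export
write_index_fastq <- function(reads, i1_path, i2_path) {
  ids <- reads$read_id
  if (all(c("surface", "swath", "tile") %in% names(reads)) && nrow(reads) > 0L) {
    ids <- paste0(ids, " ", reads$surface, ":", reads$swath, ":", reads$tile)
  }
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(reads$i7_obs, reads$i7_qual, i1_path)
  write_one(reads$i5_obs, reads$i5_qual, i2_path)
  invisible(c(i1_path, i2_path))
}

#' Read an I1/I2 index FASTQ pair into a read tibble
#'
#' Parses the two index FASTQ files written by [write_index_fastq()] (or
#' produced by a sequencer pipeline) and pairs them record by record.
#' A `surface:swath:tile` comment, when present, is decoded back into
#' tile columns.
#'
#' @param i1_path,i2_path Paths to the I1 (i7) and I2 (i5) FASTQ files.
#' @return Tibble with `read_id`, `i7_obs`, `i5_obs`, `i7_qual`,
#'   `i5_qual`, and tile columns when encoded in the headers.
#' @export
read_index_fastq <- function(i1_path, i2_path) {
  # the reader notes that it drops metadata columns; nothing we use
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(i1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(i2_path))
  ids1 <- names(r1) %||% character(0)
  ids2 <- names(r2) %||% character(0)
  id1 <- sub(" .*$", "", ids1)
  id2 <- sub(" .*$", "", ids2)
  if (!identical(id1, id2)) {
    stop_indexhop(
      sprintf("I1 (%s) and I2 (%s) are not in the same read order.",
              i1_path, i2_path),
      "indexhop_error_fastq_pairing")
  }
  out <- tibble(
    read_id = id1,
    i7_obs = unname(as.character(r1)), i5_obs = unname(as.character(r2)),
    i7_qual = unname(as.character(Biostrings::quality(r1))),
    i5_qual = unname(as.character(Biostrings::quality(r2))))
  comment <- ifelse(grepl(" ", ids1), sub("^[^ ]+ ", "", ids1), NA_character_)
  if (length(comment) && all(grepl("^\\d+:\\d+:\\d+$", comment))) {
    parts <- matrix(as.integer(unlist(strsplit(comment, ":"))),
                    ncol = 3L, byrow = TRUE)
    out$surface <- parts[, 1]
    out$swath <- parts[, 2]
    out$tile <- parts[, 3]
  }
  out
}
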