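DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T}: %s",
                  what, paste(head(which(bad), 3), collapse = ", ")))
  }
  invisible(x)
}

# expand one user-facing seed into independent per-stage seeds
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Read and write FASTQ files
#'
#' Reads are represented as a tibble with `read_id`, `sequence` and `quality`
#' columns throughout the package. IO goes through Biostrings; gzip input is
#' handled transparently on read.
#'
#' @param path File path.
#' @param reads Tibble with at least `read_id` and `sequence`; a missing
#'   `quality` column is filled with the constant placeholder `"I"`.
#' @return `read_fastq()` returns a tibble; `write_fastq()` returns `path`
#'   invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality %||% NULL
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qs <- Biostrings::PhredQuality(qual)
  xq <- Biostrings::QualityScaledDNAStringSet(x, qs)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}
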