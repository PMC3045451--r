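# Sequence-format I/O, delegated to Biostrings.

# Reverse complement of plain character strings (vectorized).
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(unname(reads))
  names(dss) <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(dss), names(dss))
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- stats::setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
  out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-separated: name, description, members...).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
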