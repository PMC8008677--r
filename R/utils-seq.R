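# Sequence plumbing shared across modules. Sequences travel as plain
# uppercase character strings; Biostrings handles file formats and
# reverse-complementation, integer codes feed the C++ kernels.

DNA_BASES4 <- c("A", "C", "G", "T")

# amino-acid alphabet, fixed column order for all profile matrices
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.dna_lookup <- local({
  x <- integer(256)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x
})

.aa_lookup <- local({
  x <- integer(256)
  x[vapply(AA20, utf8ToInt, 0L)] <- seq_along(AA20)
  x
})

#' Encode a DNA string as integers
#'
#' A, C, G, T map to 1..4; anything else (including N) maps to 0, which the
#' matching kernels treat as never matching.
#' @param s a single DNA string
#' @return integer vector, one element per base
#' @keywords internal
dna_to_int <- function(s) {
  .dna_lookup[as.integer(charToRaw(s))]
}

#' @keywords internal
aa_to_int <- function(s) {
  .aa_lookup[as.integer(charToRaw(s))]
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings
#' @return character vector of the same length
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA
#'
#' Uniform base composition by default; `gc` tunes the G+C fraction.
#' @param n sequence length in bp
#' @param gc G+C fraction in \[0, 1\]
#' @return a single DNA string
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

#' Read and write FASTA as named character vectors
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ (constant quality, synthetic reads carry no
#' base-quality information)
#' @param reads named character vector of DNA reads
#' @param path output file
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), ""))
  qs <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

# all k-mers of a string as a character vector (positions 1..n-k+1)
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# interval union length on integers, intervals as matrix [start, end) 0-based
.union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > ce) { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
    else ce <- max(ce, ends[i])
  }
  tot + (ce - cs)
}
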