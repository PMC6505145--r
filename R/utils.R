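#' Random DNA sequence
#'
#' Draws a uniform random sequence over A, C, G, T using the current RNG
#' state.
#'
#' @param n Sequence length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq Character string over ACGTN (case preserved as upper case).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  vapply(seq, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# Run an expression under a private RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards. All stochastic operations
# in the package flow through this helper, so nothing perturbs (or is
# perturbed by) global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 0-based half-open -> 1-based inclusive (reporting convention)
to1based <- function(x) as.integer(x) + 1L

check_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    stop("non-ACGTN characters in ", what,
         " (first offender: ", names(seq)[bad][1], ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' Thin wrapper over [Biostrings::writeXStringSet()].
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read sequences from FASTA/FASTQ
#'
#' @param path Input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return Named character vector of sequences.
#' @export
read_seqs <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(x), names(x))
}
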