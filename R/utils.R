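#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors on both ends.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## 0-based half-open genomic extraction; returns NA if off-chromosome.
## `strand == "-"` returns the reverse complement, so the result always reads
## 5'->3' on the transcribed strand.
extract_genome <- function(genome, chrom, start0, end0, strand = "+") {
  if (!chrom %in% names(genome)) return(NA_character_)
  L <- length(genome[[chrom]])
  if (start0 < 0 || end0 > L || start0 >= end0) return(NA_character_)
  s <- as.character(subseq(genome[[chrom]], start = start0 + 1L, end = end0))
  if (strand == "-") revcomp(s) else s
}

## seeded RNG scope that never leaks into the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

## stable integer sub-seed derived from a master seed (keeps within 32-bit)
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}
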