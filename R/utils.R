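## Internal sequence utilities. Hot paths work on integer-encoded bases
## (A=1, C=2, G=3, T=4); complement(b) == 5L - b.

.BASES <- c("A", "C", "G", "T")
## order matches the internal level index (b1 - 1) * 4 + b2
.DINUCS <- paste0(rep(.BASES, each = 4L), rep(.BASES, times = 4L))

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' works on plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revComp(c("ACGT", "AAAC"))
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## n x len integer matrix, one row per sequence
.encodeSeqs <- function(seqs) {
  n <- length(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("all sequences must have the same length")
  b <- match(unlist(strsplit(seqs, "", fixed = TRUE)), .BASES)
  if (anyNA(b))
    stop("sequences contain characters outside {A,C,G,T}")
  matrix(b, nrow = n, ncol = len, byrow = TRUE)
}

.decodeSeq <- function(ints) paste(.BASES[ints], collapse = "")

.checkDNA <- function(x, what = "sequence") {
  if (any(grepl("[^ACGT]", x)))
    stop(what, " contains characters outside {A,C,G,T}")
  invisible(x)
}

## Rolling polynomial hash of a character scalar, for config fingerprints
## in output headers. Pure R; speed is irrelevant at this call frequency.
.strHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
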