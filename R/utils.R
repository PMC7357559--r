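# Small shared helpers: alphabet normalisation, reverse complement, checks.

#' Normalise a nucleotide sequence for comparison
#'
#' Uppercases and maps U to T so that RNA reference sequences and DNA genome
#' slices compare equal. All sequence comparison in the package happens in
#' this normalised alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector in the \{A,C,G,T,N\} alphabet.
#' @export
norm_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Convert a DNA-alphabet sequence to RNA (T to U)
#' @param x character vector of sequences.
#' @return character vector with T replaced by U.
#' @export
to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

#' Reverse complement
#'
#' @param x character vector of DNA/RNA sequences (U handled as T, restored
#'   as T in the output).
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(norm_seq(x))))
}

.assert_alphabet <- function(x, extra = "N", what = "sequence") {
  bad <- grepl(sprintf("[^ACGTU%s]", extra), toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the A/C/G/T/U/%s alphabet",
                 what, extra), call. = FALSE)
  }
  invisible(TRUE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# split a string into single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
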