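#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character vectors, IUPAC-aware.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAN"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Single strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Pairwise sequence identity
#'
#' Identity between two sequences defined as matches over alignment columns
#' of a global (Needleman-Wunsch) alignment, the definition used for the
#' <98 % retention rule on terminus candidates and for nontarget
#' classification.  A full global alignment is used rather than an
#' end-gap-free one because the sequences compared here are co-extensive
#' (identical-length reads, or barcode cores of one amplicon); free end
#' gaps would let a short spurious overlap between two unrelated sequences
#' report a deceptively high identity.
#'
#' @param a,b Single DNA strings.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' seq_identity("ACGTACGTAC", "ACGTTCGTAC")
seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

# nucleotide set of an IUPAC code, as a character vector of A/C/G/T
iupac_set <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) return(character(0))
  strsplit(map[[code]], "")[[1]]
}

#' Decode a Phred+33 quality string
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors of Phred scores (ASCII - 33).
#' @export
#' @examples
#' phred_scores("#F")[[1]]  # c(2, 37)
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# data.table is used via :: only; declare awareness so its `[` dispatch works
.datatable.aware <- TRUE
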