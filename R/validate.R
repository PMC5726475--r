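# Post-assembly QC: reading-frame checks under the invertebrate
# mitochondrial code, column-wise comparison against Sanger references
# with IUPAC-ambiguity handling, and classification of retained secondary
# assemblies into cross-contamination / NUMT-or-error / putative nontarget.

#' Strip primers from a full-length barcode
#'
#' @param seq Assembled barcode(s) including primers.
#' @param fwd_primer,rev_primer Primer sequences whose lengths are removed
#'   from the two ends (defaults: the Folmer pair).
#' @return The primer-free barcode core (658 bp for a standard amplicon).
#' @export
barcode_core <- function(seq, fwd_primer = folmer_primers()[["fwd"]],
                         rev_primer = folmer_primers()[["rev"]]) {
  substr(seq, nchar(fwd_primer) + 1L, nchar(seq) - nchar(rev_primer))
}

#' Reading-frame / stop-codon check
#'
#' Translates a primer-stripped barcode under the invertebrate
#' mitochondrial genetic code (translation table 5) and reports internal
#' stop codons.  Genuine COI fragments translate without stops; in-frame
#' stops flag NUMT pseudogenes, chimeric assemblies, or frameshifted
#' errors.
#'
#' @param seq Primer-stripped barcode sequence.
#' @param code Genetic code id for [Biostrings::getGeneticCode()]
#'   (default `"5"`, invertebrate mitochondrial).
#' @param frame_offset 0-based offset of codon position 1 relative to the
#'   barcode start.  The standard Folmer fragment begins at codon position
#'   3, so its reading frame starts at the second base (offset 1).
#' @return List with `ok` (TRUE iff zero internal stops), `n_stops`
#'   (internal stop count) and `n_ambiguous` (codons skipped for
#'   containing N).
#' @export
translation_check <- function(seq, code = "5", frame_offset = 1L) {
  gc_tab <- Biostrings::getGeneticCode(code)
  s <- substring(seq, frame_offset + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return(list(ok = TRUE, n_stops = 0L, n_ambiguous = 0L))
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  has_n <- grepl("[^ACGT]", codons)
  aa <- rep(NA_character_, n_codon)
  aa[!has_n] <- gc_tab[codons[!has_n]]
  internal <- seq_len(max(n_codon - 1L, 0L))
  n_stops <- sum(aa[internal] == "*", na.rm = TRUE)
  list(ok = n_stops == 0L, n_stops = as.integer(n_stops),
       n_ambiguous = as.integer(sum(has_n)))
}

#' Compare an assembled barcode to a reference sequence
#'
#' Column-wise classification against a (possibly IUPAC-ambiguous) Sanger
#' reference.  Equal-length sequences are compared directly; otherwise a
#' global alignment introduces gap columns, which are flagged as indels and
#' excluded from the mismatch count.  A reference ambiguity code whose set
#' contains the assembled base counts as `ambiguous_resolved` — the
#' assembly has identified the degenerate Sanger call to a specific
#' nucleotide — not as a mismatch.
#'
#' @param assembled Assembled barcode (A/C/G/T), pre-trimmed to the common
#'   interval.
#' @param reference Reference sequence, IUPAC codes allowed.
#' @return List with `n_match`, `n_mismatch` (both bases unambiguous and
#'   different), `ambiguous_resolved`, `ambiguous_conflict`, `n_indel`,
#'   `n_columns` (sum of the former five) and `identity` = (matches +
#'   resolved ambiguities) / non-indel columns.
#' @export
compare_to_reference <- function(assembled, reference) {
  if (nchar(assembled) == nchar(reference)) {
    a <- strsplit(assembled, "")[[1]]
    r <- strsplit(reference, "")[[1]]
  } else {
    aln <- Biostrings::pairwiseAlignment(assembled, reference, type = "global")
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    r <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  }
  indel <- a == "-" | r == "-"
  plain <- r %in% c("A", "C", "G", "T")
  match <- !indel & a == r
  mismatch <- !indel & plain & a != r
  amb <- !indel & !plain
  resolved <- logical(length(a))
  if (any(amb)) {
    resolved[amb] <- mapply(function(ab, rb) ab %in% iupac_set(rb),
                            a[amb], r[amb])
  }
  conflict <- amb & !resolved
  n_cols <- length(a)
  non_indel <- n_cols - sum(indel)
  list(n_match = sum(match),
       n_mismatch = sum(mismatch),
       ambiguous_resolved = sum(resolved),
       ambiguous_conflict = sum(conflict),
       n_indel = sum(indel),
       n_columns = n_cols,
       identity = if (non_indel > 0)
         (sum(match) + sum(resolved)) / non_indel else NA_real_)
}

#' Classify retained secondary assemblies
#'
#' Secondary barcodes (assembled from secondary anchors that passed the
#' 1/10-abundance, <98%-identity retention rule) are classified by
#' comparing their primer-stripped cores against the plate's primary
#' barcodes:
#' \itemize{
#'   \item `cross_contamination`: at least 98% identical to the primary
#'     barcode of a *different* well (the same-haplotype threshold used
#'     throughout the pipeline);
#'   \item `putative_numt_or_error`: the translation check fails (in-frame
#'     stops) or identity to the well's own primary is at least 90%;
#'   \item `putative_nontarget`: everything else (Wolbachia-like,
#'     fungal or other co-amplicons; exported for external identity
#'     search).
#' }
#'
#' @param secondaries List of secondary barcode records (from
#'   [assemble_plate()]).
#' @param records Named list of the plate's primary barcode records.
#' @return Data frame with `sample_id`, `seq`, `abundance_ratio`,
#'   `identity_to_primary` (own well), `category`.
#' @export
classify_nontarget <- function(secondaries, records) {
  out <- data.frame(sample_id = character(0), seq = character(0),
                    abundance_ratio = numeric(0),
                    identity_to_primary = numeric(0),
                    category = character(0), stringsAsFactors = FALSE)
  if (length(secondaries) == 0L) return(out)
  prim_cores <- vapply(records, function(r) barcode_core(r$seq), character(1))
  for (sec in secondaries) {
    core <- barcode_core(sec$seq)
    own <- prim_cores[names(prim_cores) == sec$sample_id]
    others <- prim_cores[names(prim_cores) != sec$sample_id]
    id_own <- if (length(own)) seq_identity(core, own[[1]]) else NA_real_
    id_others <- if (length(others))
      vapply(others, seq_identity, numeric(1), a = core) else numeric(0)
    category <- if (length(id_others) && max(id_others) >= 0.98) {
      "cross_contamination"
    } else if (!isTRUE(sec$translation_ok) ||
               (!is.na(id_own) && id_own >= 0.90)) {
      "putative_numt_or_error"
    } else {
      "putative_nontarget"
    }
    out <- rbind(out, data.frame(
      sample_id = sec$sample_id, seq = sec$seq,
      abundance_ratio = sec$abundance_ratio %||% NA_real_,
      identity_to_primary = id_own,
      category = category, stringsAsFactors = FALSE))
  }
  out
}
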