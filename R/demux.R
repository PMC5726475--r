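# Read assignment: inline 5-bp tag + primer matching at read starts.
#
# Tags are matched exactly (the plate design guarantees >=2 substitutions
# between any two tags at the same end, so one sequencing error can never
# convert a read to another well); primers tolerate a small number of
# substitutions.

# Vectorized terminus matching over read sequences.  Returns a data.frame
# with one row per read: sample_id (NA if none), end, orientation, and
# n_hits (number of distinct (well, end) matches found; >1 means ambiguous
# and sample_id is NA).
.match_termini <- function(seqs, plate, max_primer_mismatch = 2L) {
  n <- length(seqs)
  out <- data.frame(sample_id = rep(NA_character_, n),
                    end = rep(NA_character_, n),
                    orientation = rep(NA_character_, n),
                    n_hits = rep(0L, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  orientations <- list(forward = seqs, revcomp = revcomp(seqs))
  ends <- list(five_prime = list(tag = plate$fwd_tag, primer = plate$fwd_primer),
               three_prime = list(tag = plate$rev_tag, primer = plate$rev_primer))
  for (ori in names(orientations)) {
    s <- orientations[[ori]]
    p5 <- substr(s, 1L, 5L)
    for (end in names(ends)) {
      widx <- match(p5, ends[[end]]$tag)
      cand <- which(!is.na(widx))
      if (!length(cand)) next
      for (primer in unique(ends[[end]]$primer[widx[cand]])) {
        sub <- cand[ends[[end]]$primer[widx[cand]] == primer]
        mm <- mismatch_at(s[sub], primer, 6L)
        ok <- sub[!is.na(mm) & mm <= max_primer_mismatch]
        if (!length(ok)) next
        first <- out$n_hits[ok] == 0L
        out$sample_id[ok[first]] <- plate$sample_id[widx[ok[first]]]
        out$end[ok[first]] <- end
        out$orientation[ok[first]] <- ori
        out$n_hits[ok] <- out$n_hits[ok] + 1L
      }
    }
  }
  amb <- out$n_hits > 1L
  out$sample_id[amb] <- NA_character_
  out$end[amb] <- NA_character_
  out$orientation[amb] <- NA_character_
  out
}

#' Match a read to a well terminus
#'
#' Tests whether a read (or its reverse complement) begins with the exact
#' 5-bp tag of some well immediately followed by the corresponding primer
#' within `max_primer_mismatch` substitutions.  A match to the forward
#' tag + forward primer identifies the 5' terminus; reverse tag + reverse
#' primer the 3' terminus.
#'
#' @param read_seq A single read sequence.
#' @param plate Plate data frame (see [read_plate_sheet()]).
#' @param max_primer_mismatch Allowed primer substitutions (default 2).
#' @return A list with `sample_id`, `end` (`"five_prime"`/`"three_prime"`)
#'   and `orientation` (`"forward"`/`"revcomp"`), or `NULL` when no well
#'   matches or more than one does (ambiguous).
#' @export
match_terminus <- function(read_seq, plate, max_primer_mismatch = 2L) {
  hit <- .match_termini(read_seq, plate, max_primer_mismatch)
  if (is.na(hit$sample_id[1])) return(NULL)
  list(sample_id = hit$sample_id[1], end = hit$end[1],
       orientation = hit$orientation[1])
}

# Vectorized artifact detection per mate: an amplification artifact shorter
# than one read shows both a forward-primer and a reverse-primer match on a
# single mate (either strand), or a tag+primer prefix at both ends of the
# mate.
.artifact_mate <- function(seqs, plate, max_primer_mismatch = 2L) {
  n <- length(seqs)
  if (n == 0L) return(logical(0))
  fwd_hit <- rep(FALSE, n); rev_hit <- rep(FALSE, n)
  for (p in unique(plate$fwd_primer)) {
    fwd_hit <- fwd_hit | contains_pattern(seqs, p, max_primer_mismatch) |
      contains_pattern(seqs, revcomp(p), max_primer_mismatch)
  }
  for (p in unique(plate$rev_primer)) {
    rev_hit <- rev_hit | contains_pattern(seqs, p, max_primer_mismatch) |
      contains_pattern(seqs, revcomp(p), max_primer_mismatch)
  }
  both_primers <- fwd_hit & rev_hit
  # tag+primer prefix at both ends of one mate (prefix of the read and
  # prefix of its reverse complement, i.e. its far end)
  both_ends <- .prefix_hit(seqs, plate, max_primer_mismatch) &
    .prefix_hit(revcomp(seqs), plate, max_primer_mismatch)
  both_primers | both_ends
}

# TRUE when the sequence *as given* starts with some plate tag followed by
# the corresponding primer (no reverse-complement search)
.prefix_hit <- function(seqs, plate, max_primer_mismatch = 2L) {
  n <- length(seqs)
  hit <- rep(FALSE, n)
  if (n == 0L) return(hit)
  p5 <- substr(seqs, 1L, 5L)
  ends <- list(list(tag = plate$fwd_tag, primer = plate$fwd_primer),
               list(tag = plate$rev_tag, primer = plate$rev_primer))
  for (e in ends) {
    widx <- match(p5, e$tag)
    cand <- which(!is.na(widx))
    if (!length(cand)) next
    for (primer in unique(e$primer[widx[cand]])) {
      sub <- cand[e$primer[widx[cand]] == primer]
      mm <- mismatch_at(seqs[sub], primer, 6L)
      hit[sub[!is.na(mm) & mm <= max_primer_mismatch]] <- TRUE
    }
  }
  hit
}

#' Classify a read pair as amplification artifact or normal
#'
#' Primer dimers and short PCR chimeras are shorter than a single read, so
#' one mate shows both primers (in either orientation) or tag+primer
#' prefixes at both of its ends.
#'
#' @param pair List or one-row data frame with `seq1` and `seq2`.
#' @param plate Plate data frame.
#' @param max_primer_mismatch Allowed primer substitutions (default 2).
#' @return `"primer_dimer_or_chimera"` or `"normal"`.
#' @export
classify_artifact <- function(pair, plate, max_primer_mismatch = 2L) {
  df <- as.data.frame(pair, stringsAsFactors = FALSE)
  bad <- .artifact_mate(df$seq1[1], plate, max_primer_mismatch) ||
    .artifact_mate(df$seq2[1], plate, max_primer_mismatch)
  if (bad) "primer_dimer_or_chimera" else "normal"
}

.reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Route clean reads to terminus pools, intermediate pool, or artifacts
#'
#' Partitions every clean read into exactly one of three classes: terminus
#' reads (tag+primer identified; routed with their mates to the per-well,
#' per-end pools used for anchor building), intermediate reads (untagged
#' mid-amplicon fragments feeding the shared k-mer graph), or artifacts
#' (primer dimers / short chimeras, excluded from both pools).
#'
#' @param pairs Clean read-pair data frame (post [filter_read_pairs()]).
#' @param plate Plate data frame.
#' @param max_primer_mismatch Allowed primer substitutions (default 2).
#' @return List with:
#'   \describe{
#'     \item{terminus}{data frame of hits: `sample_id`, `end`, `read_id`,
#'       `orientation`, `hit_seq`/`hit_qual` (oriented tag-first) and
#'       `mate_seq`/`mate_qual` (mate transformed into the same anchor
#'       orientation, ready for overlap merging).}
#'     \item{intermediate}{character vector of mid-amplicon read sequences.}
#'     \item{report}{named integer vector: `n_clean_reads`, `n_terminus`,
#'       `n_intermediate`, `n_artifact`, `n_ambiguous`; the first is always
#'       the sum of the middle three.  A terminus read's mate counts as a
#'       terminus read (it is an end-region read used for merging, never
#'       added to the intermediate pool).}
#'     \item{per_well}{data frame of per-(well, end) hit counts.}
#'   }
#' @export
route_reads <- function(pairs, plate, max_primer_mismatch = 2L) {
  n <- nrow(pairs)
  empty_hits <- data.frame(sample_id = character(0), end = character(0),
                           read_id = character(0), orientation = character(0),
                           hit_seq = character(0), hit_qual = character(0),
                           mate_seq = character(0), mate_qual = character(0),
                           stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(terminus = empty_hits, intermediate = character(0),
                report = c(n_clean_reads = 0L, n_terminus = 0L,
                           n_intermediate = 0L, n_artifact = 0L,
                           n_ambiguous = 0L),
                per_well = data.frame(sample_id = character(0),
                                      end = character(0), n = integer(0))))
  }
  art <- .artifact_mate(pairs$seq1, plate, max_primer_mismatch) |
    .artifact_mate(pairs$seq2, plate, max_primer_mismatch)
  ok <- which(!art)
  m1 <- .match_termini(pairs$seq1[ok], plate, max_primer_mismatch)
  m2 <- .match_termini(pairs$seq2[ok], plate, max_primer_mismatch)
  n_ambiguous <- sum(m1$n_hits > 1L) + sum(m2$n_hits > 1L)

  orient_hit <- function(idx, m, seq, qual, mate_seq, mate_qual) {
    if (!length(idx)) return(empty_hits)
    fwd <- m$orientation[idx] == "forward"
    data.frame(
      sample_id = m$sample_id[idx],
      end = m$end[idx],
      read_id = pairs$read_id[ok][idx],
      orientation = m$orientation[idx],
      hit_seq = ifelse(fwd, seq[idx], revcomp(seq[idx])),
      hit_qual = ifelse(fwd, qual[idx], .reverse_string(qual[idx])),
      mate_seq = ifelse(fwd, revcomp(mate_seq[idx]), mate_seq[idx]),
      mate_qual = ifelse(fwd, .reverse_string(mate_qual[idx]), mate_qual[idx]),
      stringsAsFactors = FALSE)
  }
  hit1 <- !is.na(m1$sample_id)
  hit2 <- !is.na(m2$sample_id)
  terminus <- rbind(
    orient_hit(which(hit1), m1, pairs$seq1[ok], pairs$qual1[ok],
               pairs$seq2[ok], pairs$qual2[ok]),
    orient_hit(which(hit2), m2, pairs$seq2[ok], pairs$qual2[ok],
               pairs$seq1[ok], pairs$qual1[ok]))

  inter_pair <- !hit1 & !hit2
  intermediate <- c(pairs$seq1[ok][inter_pair], pairs$seq2[ok][inter_pair])

  n_terminus_reads <- 2L * sum(hit1 | hit2)  # hit reads plus their mates
  report <- c(n_clean_reads = 2L * n,
              n_terminus = n_terminus_reads,
              n_intermediate = length(intermediate),
              n_artifact = 2L * sum(art),
              n_ambiguous = n_ambiguous)
  if (nrow(terminus)) {
    per_well <- as.data.frame(table(sample_id = terminus$sample_id,
                                    end = terminus$end),
                              stringsAsFactors = FALSE)
    names(per_well)[3] <- "n"
  } else {
    per_well <- data.frame(sample_id = character(0), end = character(0),
                           n = integer(0))
  }
  list(terminus = terminus, intermediate = intermediate,
       report = report, per_well = per_well)
}
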