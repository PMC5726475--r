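# Per-(well, end) anchor construction: 100%-identity read clustering,
# abundance-based candidate selection, paired-end overlap merging, and a
# coverage-trimmed majority consensus anchored at the tag.

#' Paired-end overlap parameters
#'
#' @param min_identity Minimum identity over the overlapped region for a
#'   merge to be accepted (default 0.95).
#' @param min_overlap Minimum overlap length in bp (default 10).
#' @return List of class `overlap_params`.
#' @export
overlap_params <- function(min_identity = 0.95, min_overlap = 10L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_overlap >= 1)
  structure(list(min_identity = min_identity,
                 min_overlap = as.integer(min_overlap)),
            class = "overlap_params")
}

#' Cluster identical reads
#'
#' Groups exactly identical sequences (100% clustering) and returns unique
#' sequences with abundances, deterministically sorted by abundance
#' descending, then lexicographically by sequence.
#'
#' @param reads Character vector of same-orientation read sequences.
#' @return Data frame with columns `seq` and `abundance`.
#' @export
#' @examples
#' cluster_identical(c("AAA", "AAA", "AAT"))
cluster_identical <- function(reads) {
  if (length(reads) == 0L)
    return(data.frame(seq = character(0), abundance = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(reads)
  df <- data.frame(seq = names(tab), abundance = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$abundance, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select terminus candidates from unique-read clusters
#'
#' The most abundant unique sequence is the primary candidate (abundance
#' ties broken lexicographically by the deterministic sort of
#' [cluster_identical()]).  Any further unique sequence is retained as a
#' secondary candidate when its abundance is at least 1/10 of the primary's
#' AND its identity to the primary is below 98% — i.e. it looks like a
#' distinct co-amplified template (heteroplasmic haplotype, parasite,
#' Wolbachia, gut content) rather than PCR/sequencing noise on the primary.
#'
#' @param clusters Data frame from [cluster_identical()] (sorted).
#' @param min_abundance_frac Secondary retention threshold relative to the
#'   primary abundance (default 0.1).
#' @param max_identity Secondaries at or above this identity to the primary
#'   are discarded as same-haplotype noise (default 0.98).
#' @return List with `primary` (one-row data frame) and `secondaries`
#'   (data frame, possibly empty).
#' @export
select_candidates <- function(clusters, min_abundance_frac = 0.1,
                              max_identity = 0.98) {
  if (nrow(clusters) == 0L) stop("no clusters: empty terminus pool")
  primary <- clusters[1L, , drop = FALSE]
  rest <- clusters[-1L, , drop = FALSE]
  keep <- rest$abundance >= min_abundance_frac * primary$abundance
  rest <- rest[keep, , drop = FALSE]
  if (nrow(rest)) {
    ident <- vapply(rest$seq, seq_identity, numeric(1), b = primary$seq,
                    USE.NAMES = FALSE)
    rest <- rest[ident < max_identity, , drop = FALSE]
  }
  rownames(rest) <- NULL
  list(primary = primary, secondaries = rest)
}

#' Merge one oriented read pair by overlap
#'
#' Finds, among all overlap offsets of length at least `min_overlap` whose
#' identity reaches `min_identity`, the one maximizing the number of
#' matching bases (ties go to the longer overlap), and concatenates the
#' pair into a single fragment.  Disagreeing overlap positions take the
#' higher-quality base; equal qualities yield `N`.
#'
#' @param hit_seq Terminus read, tag-first orientation.
#' @param mate_seq Mate already reverse-complemented into the same
#'   orientation (so a suffix of `hit_seq` overlaps a prefix of
#'   `mate_seq`).
#' @param params An [overlap_params()] object.
#' @param hit_qual,mate_qual Optional Phred+33 strings (equal qualities are
#'   assumed when absent).
#' @return Merged sequence, or `NULL` when no offset qualifies.
#' @export
merge_pair <- function(hit_seq, mate_seq, params = overlap_params(),
                       hit_qual = NULL, mate_qual = NULL) {
  out <- merge_read_pairs(hit_seq, mate_seq, hit_qual, mate_qual, params)
  if (is.na(out[1])) NULL else out[1]
}

#' @rdname merge_pair
#' @param hit_seqs,mate_seqs,hit_quals,mate_quals Vectorized equivalents.
#' @return `merge_read_pairs()`: character vector with `NA` for pairs that
#'   failed to merge.
#' @export
merge_read_pairs <- function(hit_seqs, mate_seqs, hit_quals = NULL,
                             mate_quals = NULL, params = overlap_params()) {
  if (is.null(hit_quals)) hit_quals <- strrep("!", nchar(hit_seqs))
  if (is.null(mate_quals)) mate_quals <- strrep("!", nchar(mate_seqs))
  merge_pairs_cpp(hit_seqs, mate_seqs, hit_quals, mate_quals,
                  params$min_overlap, params$min_identity)
}

#' Build a coverage-trimmed majority consensus
#'
#' Fragments share the tag-anchored start (all aligned at position 1) and
#' vary in length with insert size; the consensus takes the per-position
#' majority base over all fragments covering that position and trims the
#' distal end while coverage is below `min_cov`.  Because every fragment
#' starts at position 1, coverage is non-increasing and distal trimming is
#' sufficient.  Ties are broken by the base of the earliest fragment
#' carrying a tied base; `N` never out-votes a concrete base.
#'
#' @param merged_frags Character vector of merged fragments.
#' @param min_cov Minimum per-position read coverage retained (default 5).
#' @return List of class `terminus_consensus` with `seq` and integer
#'   `coverage` (empty `seq` when no position reaches `min_cov`).
#' @export
build_consensus <- function(merged_frags, min_cov = 5L) {
  frags <- merged_frags[!is.na(merged_frags) & nchar(merged_frags) > 0L]
  empty <- structure(list(seq = "", coverage = integer(0)),
                     class = "terminus_consensus")
  if (length(frags) == 0L) return(empty)
  lens <- nchar(frags)
  maxlen <- max(lens)
  cov <- rev(cumsum(rev(tabulate(lens, nbins = maxlen))))
  keep <- which(cov >= min_cov)
  if (length(keep) == 0L) return(empty)
  L <- max(keep)
  cov <- cov[seq_len(L)]
  mat <- matrix(NA_character_, nrow = length(frags), ncol = L)
  for (i in seq_along(frags)) {
    li <- min(lens[i], L)
    mat[i, seq_len(li)] <- strsplit(substr(frags[i], 1L, li), "")[[1]]
  }
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b, na.rm = TRUE),
                   numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, bases))
  top <- max.col(counts, ties.method = "first")
  cons <- bases[top]
  mx <- counts[cbind(seq_len(L), top)]
  cons[mx == 0] <- "N"
  # tie-break by earliest-observed base among tied maxima
  ties <- which(mx > 0 & rowSums(counts == mx) > 1L)
  for (p in ties) {
    tied <- bases[counts[p, ] == mx[p]]
    col <- mat[, p]
    cons[p] <- col[which(col %in% tied)[1]]
  }
  structure(list(seq = paste(cons, collapse = ""), coverage = as.integer(cov)),
            class = "terminus_consensus")
}

# Build the anchor set (primary + secondary consensus anchors) for one
# (well, end) subset of the terminus pool.  The inline tag is retained
# while merging (fragments are tag-anchored) and stripped from the reported
# anchor, which therefore begins at the primer's first base.
.anchor_set <- function(hits, overlap = overlap_params(), min_cov = 5L,
                        min_abundance_frac = 0.1, max_identity = 0.98,
                        tag_len = 5L) {
  if (nrow(hits) == 0L) return(NULL)
  clusters <- cluster_identical(hits$hit_seq)
  cand <- select_candidates(clusters, min_abundance_frac, max_identity)
  build_one <- function(seq, abundance) {
    idx <- which(hits$hit_seq == seq)
    merged <- merge_read_pairs(hits$hit_seq[idx], hits$mate_seq[idx],
                               hits$hit_qual[idx], hits$mate_qual[idx],
                               overlap)
    cons <- build_consensus(merged, min_cov)
    if (nchar(cons$seq) <= tag_len) return(NULL)
    list(seq = substring(cons$seq, tag_len + 1L),
         coverage = cons$coverage[-seq_len(tag_len)],
         abundance = abundance,
         n_merged = sum(!is.na(merged)))
  }
  primary <- build_one(cand$primary$seq, cand$primary$abundance)
  secondaries <- list()
  for (i in seq_len(nrow(cand$secondaries))) {
    s <- build_one(cand$secondaries$seq[i], cand$secondaries$abundance[i])
    if (!is.null(s)) secondaries[[length(secondaries) + 1L]] <- s
  }
  if (is.null(primary)) return(NULL)
  list(primary = primary, secondaries = secondaries)
}

#' Build consensus anchors for every well and end
#'
#' Runs the full terminus stage (identical clustering, candidate selection,
#' pair merging, coverage-trimmed consensus) on the routed terminus pool.
#'
#' @param terminus Terminus-hit data frame from [route_reads()].
#' @param plate Plate data frame.
#' @param overlap An [overlap_params()] object.
#' @param min_cov Consensus coverage floor (default 5).
#' @param min_abundance_frac,max_identity Secondary retention rule
#'   (defaults 0.1 and 0.98; see [select_candidates()]).
#' @return Named list (by `sample_id`) of lists with elements `five_prime`
#'   and `three_prime`, each an anchor set (`primary` plus `secondaries`,
#'   every anchor holding `seq`, `coverage`, `abundance`, `n_merged`) or
#'   `NULL` when the end failed.
#' @export
plate_anchors <- function(terminus, plate, overlap = overlap_params(),
                          min_cov = 5L, min_abundance_frac = 0.1,
                          max_identity = 0.98) {
  out <- list()
  for (sid in plate$sample_id) {
    sub <- terminus[terminus$sample_id == sid, , drop = FALSE]
    out[[sid]] <- list(
      five_prime = .anchor_set(sub[sub$end == "five_prime", , drop = FALSE],
                               overlap, min_cov, min_abundance_frac,
                               max_identity),
      three_prime = .anchor_set(sub[sub$end == "three_prime", , drop = FALSE],
                                overlap, min_cov, min_abundance_frac,
                                max_identity))
  }
  out
}
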