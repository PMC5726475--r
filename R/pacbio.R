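# Companion single-molecule route: circular consensus (CCS) reads are pass
# filtered, demultiplexed by their terminal indices with a 1-bp terminal
# deletion tolerance, length filtered around the standard barcode length,
# and clustered identically to pick one barcode per well.

#' CCS route parameters
#'
#' @param min_passes Minimum polymerase pass count for a CCS read to be
#'   used (default 15; at this depth residual platform error is largely
#'   corrected).
#' @param target_len Expected primer-stripped barcode length (658).
#' @param len_tol Tolerated deviation from `target_len` (6, i.e. 658 ± 6).
#' @param max_index_end_deletions Maximum deletions tolerated at the outer
#'   terminus of each index (1: the 5' end of the forward index or the 3'
#'   end of the reverse index may lose one base).
#' @return List of class `ccs_params`.
#' @export
ccs_params <- function(min_passes = 15L, target_len = 658L, len_tol = 6L,
                       max_index_end_deletions = 1L) {
  stopifnot(min_passes >= 0, target_len >= 0, len_tol >= 0,
            max_index_end_deletions >= 0)
  structure(list(min_passes = as.integer(min_passes),
                 target_len = as.integer(target_len),
                 len_tol = as.integer(len_tol),
                 max_index_end_deletions = as.integer(max_index_end_deletions)),
            class = "ccs_params")
}

#' Filter CCS reads by pass count
#'
#' @param ccs Data frame from [read_ccs()] (`read_id`, `seq`, `passes`).
#' @param params A [ccs_params()] object.
#' @return The subset with `passes >= min_passes` (NA passes dropped).
#' @export
pass_filter <- function(ccs, params = ccs_params()) {
  keep <- !is.na(ccs$passes) & ccs$passes >= params$min_passes
  ccs[keep, , drop = FALSE]
}

# match a 5-bp index at a sequence terminus allowing up to `max_del`
# missing bases at the index's outer end.  Returns the number of index
# bases found (5 or 4) or 0 for no match.
.index_at_start <- function(s, tag, max_del) {
  if (substr(s, 1L, 5L) == tag) return(5L)
  if (max_del >= 1L && substr(s, 1L, 4L) == substr(tag, 2L, 5L)) return(4L)
  0L
}

#' Demultiplex one CCS read
#'
#' Matches the forward index (well tag) at the 5' terminus and the reverse
#' index at the 3' terminus, checking both strands.  Each index may be
#' found in full or with a single base missing at its outer end (a common
#' CCS deletion mode); both indices must point to the same well.  On
#' success the indices and primers are stripped and the insert returned.
#'
#' @param read One-row data frame or list with `seq` (and optionally
#'   `read_id`).
#' @param plate Plate data frame.
#' @param params A [ccs_params()] object.
#' @return List with `sample_id` and `insert` (primer-stripped, barcode
#'   orientation), or `NULL` when unassignable (no match at either end, or
#'   conflicting wells).
#' @export
demux_ccs <- function(read, plate, params = ccs_params()) {
  md <- params$max_index_end_deletions
  for (s in c(read$seq, revcomp(read$seq))) {
    L <- nchar(s)
    fwd_len <- vapply(plate$fwd_tag, .index_at_start, integer(1), s = s,
                      max_del = md)
    # reverse index sits reverse-complemented at the 3' terminus; a
    # deletion at its 3' end removes the first base of its complement
    send <- revcomp(s)
    rev_len <- vapply(plate$rev_tag, .index_at_start, integer(1), s = send,
                      max_del = md)
    fwd_wells <- which(fwd_len > 0L)
    rev_wells <- which(rev_len > 0L)
    hit <- intersect(fwd_wells, rev_wells)
    if (length(hit) == 0L) next
    if (length(unique(plate$sample_id[hit])) > 1L) return(NULL)  # conflict
    w <- hit[1]
    lead <- fwd_len[w] + nchar(plate$fwd_primer[w])
    trail <- rev_len[w] + nchar(plate$rev_primer[w])
    if (lead + trail >= L) return(NULL)
    return(list(sample_id = plate$sample_id[w],
                insert = substr(s, lead + 1L, L - trail)))
  }
  NULL
}

#' Pick one barcode per well from CCS inserts
#'
#' Inserts outside `target_len ± len_tol` are removed; the remainder are
#' clustered at 100% identity, clusters are ranked by member count with
#' ties broken by the summed pass numbers (then lexicographically), and
#' the winning cluster's sequence is returned.
#'
#' @param inserts Data frame with columns `seq` and `passes` for one well.
#' @param params A [ccs_params()] object.
#' @return The winning barcode sequence, or `NULL` when no insert
#'   survives the length filter.
#' @export
pick_barcode <- function(inserts, params = ccs_params()) {
  len <- nchar(inserts$seq)
  ok <- abs(len - params$target_len) <= params$len_tol
  inserts <- inserts[ok, , drop = FALSE]
  if (nrow(inserts) == 0L) return(NULL)
  agg <- stats::aggregate(inserts$passes, by = list(seq = inserts$seq),
                          FUN = function(p) c(n = length(p), passes = sum(p)))
  df <- data.frame(seq = agg$seq, n = agg$x[, "n"], passes = agg$x[, "passes"],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, -df$passes, df$seq), , drop = FALSE]
  df$seq[1]
}

#' Run the whole CCS route on a plate
#'
#' @param ccs Data frame from [read_ccs()].
#' @param plate Plate data frame.
#' @param params A [ccs_params()] object.
#' @return List with `barcodes` (named character vector of per-well
#'   barcode cores), and `report` (named integer vector: `n_ccs`,
#'   `n_pass_filtered`, `n_assigned`, `n_conflict`, `n_wells_recovered`).
#' @export
pacbio_barcodes <- function(ccs, plate, params = ccs_params()) {
  kept <- pass_filter(ccs, params)
  assigns <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    assigns[[i]] <- demux_ccs(kept[i, , drop = FALSE], plate, params)
  }
  ok <- !vapply(assigns, is.null, logical(1))
  sid <- vapply(assigns[ok], `[[`, character(1), "sample_id")
  ins <- vapply(assigns[ok], `[[`, character(1), "insert")
  passes <- kept$passes[ok]
  barcodes <- character(0)
  for (w in unique(sid)) {
    sub <- data.frame(seq = ins[sid == w], passes = passes[sid == w],
                      stringsAsFactors = FALSE)
    b <- pick_barcode(sub, params)
    if (!is.null(b)) barcodes[w] <- b
  }
  list(barcodes = barcodes,
       report = c(n_ccs = nrow(ccs), n_pass_filtered = nrow(kept),
                  n_assigned = sum(ok),
                  n_wells_recovered = length(barcodes)))
}
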