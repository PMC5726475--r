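#' Read-filtering parameters
#'
#' Thresholds for removing bad-quality read pairs before demultiplexing.
#' Defaults follow the rules the assembler was designed around: a pair is
#' dropped when either mate (i) carries adapter contamination, defined as
#' an ungapped local alignment to an adapter of length >= 15 with <= 3
#' mismatches; (ii) has more than 10 N calls; or (iii) has more than 50
#' bases at Phred quality <= 2 (ASCII 35, Phred+33).
#'
#' @param adapter_seqs Character vector of adapter sequences (may be empty;
#'   reverse complements are scanned as well).
#' @param min_adapter_align Minimum ungapped alignment length (default 15).
#' @param max_adapter_mismatch Maximum mismatches in that alignment (3).
#' @param max_n Maximum tolerated N count per mate (10).
#' @param low_q_phred Phred score at or below which a base counts as low
#'   quality (2).
#' @param max_low_q Maximum tolerated low-quality bases per mate (50).
#' @return List of class `filter_params`.
#' @export
filter_params <- function(adapter_seqs = character(0),
                          min_adapter_align = 15L,
                          max_adapter_mismatch = 3L,
                          max_n = 10L,
                          low_q_phred = 2L,
                          max_low_q = 50L) {
  stopifnot(min_adapter_align >= 0, max_adapter_mismatch >= 0,
            max_n >= 0, low_q_phred >= 0, max_low_q >= 0)
  structure(list(adapter_seqs = toupper(adapter_seqs),
                 min_adapter_align = as.integer(min_adapter_align),
                 max_adapter_mismatch = as.integer(max_adapter_mismatch),
                 max_n = as.integer(max_n),
                 low_q_phred = as.integer(low_q_phred),
                 max_low_q = as.integer(max_low_q)),
            class = "filter_params")
}

#' Adapter contamination test
#'
#' TRUE when some adapter (or its reverse complement) aligns to the read
#' with an ungapped local alignment of length >= `min_adapter_align`
#' containing <= `max_adapter_mismatch` mismatches.
#'
#' @param seq Character vector of read sequences.
#' @param params A [filter_params()] object.
#' @return Logical vector.
#' @export
has_adapter <- function(seq, params = filter_params()) {
  if (length(params$adapter_seqs) == 0L) return(rep(FALSE, length(seq)))
  pats <- unique(c(params$adapter_seqs, revcomp(params$adapter_seqs)))
  adapter_scan(seq, pats, params$min_adapter_align, params$max_adapter_mismatch)
}

#' Filter one read pair
#'
#' Applies the pair-level drop rules; the reason reported is the first rule
#' triggered in the order adapter, many Ns, low quality.  Both mates are
#' examined and the pair is dropped when either fails, because downstream
#' terminus merging needs both mates.
#'
#' @param pair List or one-row data frame with `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param params A [filter_params()] object.
#' @return List with `keep` (logical) and `reason` (one of `"adapter"`,
#'   `"many_n"`, `"low_quality"`, `"clean"`).
#' @export
filter_pair <- function(pair, params = filter_params()) {
  df <- as.data.frame(pair, stringsAsFactors = FALSE)
  res <- filter_read_pairs(df, params)
  list(keep = res$keep[1], reason = res$reason[1])
}

#' Filter a table of read pairs
#'
#' Vectorized form of [filter_pair()] over a pairs data frame.
#'
#' @param pairs Data frame from [read_fastq_pairs()].
#' @param params A [filter_params()] object.
#' @return List with `keep` (logical vector), `reason` (character vector),
#'   `clean` (the retained subset of `pairs`) and `report`, a named integer
#'   vector `n_input`, `n_adapter`, `n_many_n`, `n_low_quality`, `n_clean`
#'   that always sums correctly (`n_input` = dropped + clean).
#' @export
filter_read_pairs <- function(pairs, params = filter_params()) {
  n <- nrow(pairs)
  if (n == 0L) {
    rep0 <- c(n_input = 0L, n_adapter = 0L, n_many_n = 0L,
              n_low_quality = 0L, n_clean = 0L)
    return(list(keep = logical(0), reason = character(0),
                clean = pairs, report = rep0))
  }
  adapter <- has_adapter(pairs$seq1, params) | has_adapter(pairs$seq2, params)
  many_n <- count_char_eq(pairs$seq1, "N") > params$max_n |
    count_char_eq(pairs$seq2, "N") > params$max_n
  qmax <- 33L + params$low_q_phred
  low_q <- count_char_le(pairs$qual1, qmax) > params$max_low_q |
    count_char_le(pairs$qual2, qmax) > params$max_low_q
  reason <- rep("clean", n)
  reason[low_q] <- "low_quality"
  reason[many_n] <- "many_n"
  reason[adapter] <- "adapter"
  keep <- reason == "clean"
  report <- c(n_input = n,
              n_adapter = sum(reason == "adapter"),
              n_many_n = sum(reason == "many_n"),
              n_low_quality = sum(reason == "low_quality"),
              n_clean = sum(keep))
  list(keep = keep, reason = reason,
       clean = pairs[keep, , drop = FALSE], report = report)
}
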