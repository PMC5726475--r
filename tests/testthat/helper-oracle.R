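# Independent oracles implemented from first principles, kept separate
# from the package's own code paths.

# Exhaustive recursive enumeration of gap-walk paths with the same pruning
# arithmetic: (i) at out-degree > 1, drop successors with abundance below
# min_kmer_frac x mean path abundance since the last bifurcation; (ii) if
# more than one survives, drop those with common-read support below
# min_commonread_frac x mean across survivors (vs the k-mer at the previous
# bifurcation, initially the start k-mer); (iii) abandon paths at max_len.
oracle_walk <- function(graph, start, end, min_kmer_frac = 0.1,
                        min_commonread_frac = 0.1, max_len = 709L) {
  k <- graph$k
  ab_map <- setNames(graph$counts$abundance, graph$counts$kmer)
  reads_map <- split(graph$reads$read, graph$reads$kmer)
  out <- character(0)
  recurse <- function(path, seg, bif) {
    last <- substr(path, nchar(path) - k + 1L, nchar(path))
    if (last == end) { out <<- c(out, path); return(invisible()) }
    if (nchar(path) >= max_len) return(invisible())
    succ <- paste0(substr(last, 2L, k), BASES)
    ab <- unname(ab_map[succ]); ab[is.na(ab)] <- 0
    pres <- which(ab > 0)
    if (length(pres) == 0L) return(invisible())
    if (length(pres) == 1L) {
      recurse(paste0(path, BASES[pres]), c(seg, ab[pres]), bif)
      return(invisible())
    }
    keep <- pres[ab[pres] >= min_kmer_frac * mean(seg)]
    if (length(keep) == 0L) return(invisible())
    if (length(keep) > 1L) {
      common <- vapply(keep, function(i)
        length(intersect(reads_map[[succ[i]]], reads_map[[bif]])), numeric(1))
      keep <- keep[common >= min_commonread_frac * mean(common)]
      if (length(keep) == 0L) return(invisible())
    }
    for (i in keep) recurse(paste0(path, BASES[i]), ab[i], last)
    invisible()
  }
  recurse(start, unname(ab_map[start]), start)
  sort(out)
}

# naive sliding-window k-mer counter over both strands
oracle_kmer_counts <- function(reads, k) {
  counts <- list()
  for (s in c(reads, revcomp(reads))) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      counts[[km]] <- (counts[[km]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive-offset overlap merge oracle (sequence choice only; ties and
# quality resolution are not reproduced -- used to check offset selection)
oracle_best_overlap <- function(s1, s2, min_overlap, min_identity) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  best <- NULL
  for (o in seq.int(min_overlap, min(l1, l2))) {
    a <- substring(s1, l1 - o + 1L, l1)
    b <- substring(s2, 1L, o)
    m <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    if (m / o >= min_identity &&
        (is.null(best) || m > best$m || (m == best$m && o > best$o)))
      best <- list(o = o, m = m)
  }
  best
}

# naive ungapped adapter window scan
oracle_has_adapter <- function(seq, adapter, min_len, max_mm) {
  las <- c(adapter, revcomp(adapter))
  sv <- strsplit(seq, "")[[1]]
  for (ad in las) {
    av <- strsplit(ad, "")[[1]]
    for (d in seq.int(-(length(av) - min_len), length(sv) - min_len)) {
      j0 <- max(1L, 1L - d); j1 <- min(length(av), length(sv) - d)
      if (j1 - j0 + 1L < min_len) next
      for (st in seq.int(j0, j1 - min_len + 1L)) {
        win <- st:(st + min_len - 1L)
        if (sum(av[win] != sv[win + d]) <= max_mm) return(TRUE)
      }
    }
  }
  FALSE
}
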