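# Targeted gap filling: a de Bruijn graph over the shared intermediate-read
# pool is walked base by base from each well's 5' anchor to its 3' anchor.
# Because intermediate reads are untagged, per-well specificity comes
# entirely from the anchors; the walk prunes branches by local k-mer
# abundance and by read support across bifurcations.

#' Gap-walk parameters
#'
#' @param min_kmer_frac At a bifurcation, successor k-mers with abundance
#'   below this fraction of the mean path k-mer abundance since the last
#'   bifurcation are removed (default 0.10).
#' @param min_commonread_frac When more than one successor survives,
#'   successors whose common-read count with the k-mer at the previous
#'   bifurcation falls below this fraction of the mean common-read count
#'   across survivors are removed (default 0.10).
#' @param max_len Preset length bound: the standard COI barcode (658 bp)
#'   plus both Folmer primers, 709 bp.  Walks extending beyond it without
#'   reaching the end point are abandoned.
#' @return List of class `walk_params`.
#' @export
walk_params <- function(min_kmer_frac = 0.1, min_commonread_frac = 0.1,
                        max_len = unname(barcode_lengths()["with_primers"])) {
  stopifnot(min_kmer_frac > 0, min_kmer_frac < 1,
            min_commonread_frac > 0, min_commonread_frac < 1)
  structure(list(min_kmer_frac = min_kmer_frac,
                 min_commonread_frac = min_commonread_frac,
                 max_len = as.integer(max_len)),
            class = "walk_params")
}

#' Build a k-mer graph from intermediate reads
#'
#' Every read contributes the k-mers of both strands (reverse-complement
#' closure); windows containing non-A/C/G/T characters are skipped.
#' Abundance is the number of read positions (over both strands) producing
#' the k-mer; the supporting read ids of each k-mer are retained for the
#' common-read pruning strategy.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer size.  The pipeline default is `min(127, read length - 1)`:
#'   amplicon pools are deep, so a large k minimizes spurious joins.
#' @return Object of class `kmer_graph` with elements `k`, `counts`
#'   (data.table keyed by k-mer with `abundance`) and `reads` (data.table
#'   keyed by k-mer with supporting read indices).
#' @export
build_graph <- function(reads, k) {
  k <- as.integer(k)
  if (length(reads) == 0L) stop("cannot build a k-mer graph from zero reads")
  if (k < 2L) stop("k must be at least 2")
  if (k > max(nchar(reads))) stop("k exceeds the maximum read length")
  km <- enum_kmers(reads, k)
  dt <- data.table::data.table(kmer = km$kmer, read = km$read)
  counts <- dt[, list(abundance = .N), by = "kmer"]
  rdt <- unique(dt)
  data.table::setkey(counts, kmer)
  data.table::setkey(rdt, kmer)
  structure(list(k = k, counts = counts, reads = rdt), class = "kmer_graph")
}

#' @rdname build_graph
#' @param graph A `kmer_graph`.
#' @param kmers Character vector of k-mers to look up.
#' @return `graph_abundance()`: integer abundances (0 for absent k-mers).
#' @export
graph_abundance <- function(graph, kmers) {
  .query <- kmers
  ab <- graph$counts[list(.query), on = "kmer"]$abundance
  ab[is.na(ab)] <- 0L
  ab
}

#' @rdname build_graph
#' @param kmer A single k-mer.
#' @return `graph_reads()`: integer vector of supporting read indices.
#' @export
graph_reads <- function(graph, kmer) {
  .query <- kmer
  graph$reads[list(.query), on = "kmer", nomatch = NULL]$read
}

.anchor_seq <- function(x) {
  if (inherits(x, "terminus_consensus") || (is.list(x) && !is.null(x$seq)))
    x$seq
  else as.character(x)
}

#' Walk the k-mer graph between two anchors
#'
#' Depth-first, base-by-base extension from the terminal k-mer of the 5'
#' anchor toward the entry k-mer of the reverse-complemented 3' anchor.
#' At a bifurcation (more than one successor k-mer present in the graph)
#' three pruning strategies apply: (i) successors with abundance below
#' `min_kmer_frac` times the mean abundance of the path k-mers accumulated
#' since the last bifurcation are removed; (ii) if more than one successor
#' survives, reads shared between each survivor and the k-mer at the
#' previous bifurcation (the anchor's terminal k-mer before any) are
#' counted, and survivors below `min_commonread_frac` times the mean
#' common-read count are removed; (iii) paths exceeding `max_len` (or
#' `max_path_len`) without reaching the end point are abandoned.  All
#' surviving branches are explored and every path reaching the end k-mer is
#' returned.
#'
#' A sole successor is never pruned: strategy (i) arbitrates between
#' competing out-edges, and applying it to an unbranched extension would
#' abort assemblies at any local coverage dip.
#'
#' @param graph A `kmer_graph` from [build_graph()].
#' @param anchor5 5' consensus anchor (a `terminus_consensus` or a string).
#' @param anchor3 3' consensus anchor, in its own (tag-first) orientation;
#'   it is reverse-complemented internally.
#' @param params A [walk_params()] object.
#' @param max_path_len Optional override of the path-length bound (used by
#'   [assemble_well()] to account for anchor lengths so the assembled
#'   barcode respects `max_len`).
#' @return Character vector of successful paths, each beginning with the
#'   start k-mer and ending with the end k-mer (possibly empty).
#' @export
walk_graph <- function(graph, anchor5, anchor3, params = walk_params(),
                       max_path_len = params$max_len) {
  k <- graph$k
  a5 <- .anchor_seq(anchor5)
  a3rc <- revcomp(.anchor_seq(anchor3))
  if (nchar(a5) < k || nchar(a3rc) < k)
    stop("anchors shorter than k")
  start <- substr(a5, nchar(a5) - k + 1L, nchar(a5))
  end_kmer <- substr(a3rc, 1L, k)
  if (graph_abundance(graph, start) == 0L)
    stop("terminal k-mer of the 5' anchor is absent from the graph")
  if (graph_abundance(graph, end_kmer) == 0L)
    stop("entry k-mer of the 3' anchor is absent from the graph")
  bases <- c("A", "C", "G", "T")
  done <- character(0)
  stack <- list(list(path = start,
                     seg = as.numeric(graph_abundance(graph, start)),
                     bif = start))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    path <- st$path; seg <- st$seg; bif <- st$bif
    repeat {
      L <- nchar(path)
      if (substr(path, L - k + 1L, L) == end_kmer) {
        done <- c(done, path)
        break
      }
      if (L >= max_path_len) break  # (iii)
      suffix <- substr(path, L - k + 2L, L)
      succ <- paste0(suffix, bases)
      ab <- graph_abundance(graph, succ)
      present <- which(ab > 0L)
      if (length(present) == 0L) break  # dead end
      if (length(present) == 1L) {
        i <- present
        path <- paste0(path, bases[i])
        seg <- c(seg, ab[i])
        next
      }
      # bifurcation: (i) abundance pruning against the current segment mean
      thr <- params$min_kmer_frac * mean(seg)
      surv <- present[ab[present] >= thr]
      if (length(surv) == 0L) break
      if (length(surv) > 1L) {
        # (ii) read support across the previous bifurcation
        bif_reads <- graph_reads(graph, bif)
        common <- vapply(surv, function(i) {
          length(intersect(graph_reads(graph, succ[i]), bif_reads))
        }, numeric(1))
        cthr <- params$min_commonread_frac * mean(common)
        surv <- surv[common >= cthr]
        if (length(surv) == 0L) break
      }
      cur <- substr(path, L - k + 1L, L)
      if (length(surv) == 1L) {
        i <- surv
        path <- paste0(path, bases[i])
        seg <- ab[i]
        bif <- cur
        next
      }
      for (i in surv) {
        stack[[length(stack) + 1L]] <-
          list(path = paste0(path, bases[i]), seg = ab[i], bif = cur)
      }
      break
    }
  }
  done
}

# mean graph abundance of the k-mers along a path
.path_mean_abundance <- function(graph, path) {
  k <- graph$k
  n <- nchar(path) - k + 1L
  kms <- substring(path, seq_len(n), seq_len(n) + k - 1L)
  mean(graph_abundance(graph, kms))
}

# Try to assemble one anchor combination.  Returns list(seq, n_paths,
# alt_seqs) or a character failure stage.
.assemble_combo <- function(a5, a3, graph, params) {
  k <- graph$k
  a5s <- .anchor_seq(a5)
  a3rc <- revcomp(.anchor_seq(a3))
  if (nchar(a5s) < k) return("anchor5_short")
  if (nchar(a3rc) < k) return("anchor3_short")
  end_kmer <- substr(a3rc, 1L, k)
  # degenerate short amplicon: the 3' anchor's entry k-mer already lies
  # inside the 5' anchor -> direct overlap merge, no walk
  hit <- gregexpr(end_kmer, a5s, fixed = TRUE)[[1]]
  if (hit[1] != -1L) {
    p <- hit[length(hit)]
    o <- nchar(a5s) - p + 1L  # overlap length
    if (o <= nchar(a3rc)) {
      ident <- mean(utf8ToInt(substr(a5s, p, nchar(a5s))) ==
                      utf8ToInt(substr(a3rc, 1L, o)))
      merged <- paste0(substr(a5s, 1L, p - 1L), a3rc)
      if (ident >= 0.95 && nchar(merged) <= params$max_len)
        return(list(seq = merged, n_paths = 1L, alt_seqs = character(0)))
    }
  }
  budget <- params$max_len - (nchar(a5s) - k) - (nchar(a3rc) - k)
  if (budget < k) return("anchors_exceed_max_len")
  paths <- tryCatch(
    walk_graph(graph, a5s, .anchor_seq(a3), params,
               max_path_len = budget),
    error = function(e) e)
  if (inherits(paths, "error")) return("anchor_kmer_missing")
  if (length(paths) == 0L) return("no_path")
  seqs <- paste0(a5s, substring(paths, k + 1L))
  seqs <- paste0(seqs, substring(a3rc, k + 1L))
  keep <- nchar(seqs) <= params$max_len
  paths <- paths[keep]; seqs <- seqs[keep]
  if (length(seqs) == 0L) return("no_path")
  if (length(seqs) > 1L) {
    score <- vapply(paths, .path_mean_abundance, numeric(1), graph = graph)
    ord <- order(-score, seqs)
    seqs <- seqs[ord]
  }
  list(seq = seqs[1], n_paths = length(seqs), alt_seqs = seqs[-1])
}

#' Assemble one well's full-length barcode
#'
#' Stitches the well's 5' anchor, the gap-filling walk, and the
#' reverse-complemented 3' anchor into a full-length barcode (primers
#' included).  The primary x primary anchor combination is tried first,
#' then combinations involving secondary anchors; retained secondary
#' anchor pairs are additionally assembled into secondary records for the
#' nontarget screen.  When several full paths survive pruning, all are
#' kept and the path with the highest mean k-mer abundance becomes the
#' reported barcode.
#'
#' @param anchors One well's anchor list (element of [plate_anchors()]):
#'   `five_prime` and `three_prime` anchor sets.
#' @param graph Shared intermediate-pool `kmer_graph`.
#' @param sample_id Well identifier carried into the records.
#' @param params A [walk_params()] object.
#' @param frame_offset Reading-frame offset passed to the translation
#'   check (see [translation_check()]).
#' @return List with `record` (the well's barcode record, or `NULL`),
#'   `failure` (failure stage string when `record` is `NULL`),
#'   `secondaries` (list of secondary barcode records) and `alt_seqs`.
#'   Each record holds `sample_id`, `seq`, `n_paths_found`,
#'   `anchor5_abundance`, `anchor3_abundance`, `abundance_ratio`,
#'   `translation_ok` and `source = "illumina"`.
#' @export
assemble_well <- function(anchors, graph, sample_id = "well",
                          params = walk_params(), frame_offset = 1L) {
  a5set <- anchors$five_prime; a3set <- anchors$three_prime
  if (is.null(a5set)) return(list(record = NULL, failure = "no_anchor5",
                                  secondaries = list(), alt_seqs = character(0)))
  if (is.null(a3set)) return(list(record = NULL, failure = "no_anchor3",
                                  secondaries = list(), alt_seqs = character(0)))
  mk_record <- function(res, a5, a3, ratio) {
    core <- barcode_core(res$seq)
    tr <- translation_check(core, frame_offset = frame_offset)
    list(sample_id = sample_id, seq = res$seq,
         n_paths_found = res$n_paths,
         anchor5_abundance = a5$abundance,
         anchor3_abundance = a3$abundance,
         abundance_ratio = ratio,
         translation_ok = tr$ok, source = "illumina")
  }
  # ordered combinations for the well's own barcode
  combos <- list(list(a5 = a5set$primary, a3 = a3set$primary))
  for (s3 in a3set$secondaries)
    combos[[length(combos) + 1L]] <- list(a5 = a5set$primary, a3 = s3)
  for (s5 in a5set$secondaries)
    combos[[length(combos) + 1L]] <- list(a5 = s5, a3 = a3set$primary)
  record <- NULL; failure <- "no_path"; alt <- character(0)
  for (cb in combos) {
    res <- .assemble_combo(cb$a5, cb$a3, graph, params)
    if (is.list(res)) {
      record <- mk_record(res, cb$a5, cb$a3, 1)
      alt <- res$alt_seqs
      break
    } else failure <- res
  }
  # secondary anchor pairs -> secondary records (nontarget candidates)
  secondaries <- list()
  for (s5 in a5set$secondaries) {
    partners <- c(a3set$secondaries, list(a3set$primary))
    for (a3 in partners) {
      res <- .assemble_combo(s5, a3, graph, params)
      if (is.list(res)) {
        ratio <- s5$abundance / a5set$primary$abundance
        rec <- mk_record(res, s5, a3, ratio)
        # skip if it reproduces the well's own primary assembly
        if (is.null(record) || rec$seq != record$seq)
          secondaries[[length(secondaries) + 1L]] <- rec
        break
      }
    }
  }
  list(record = record, failure = if (is.null(record)) failure else NA_character_,
       secondaries = secondaries, alt_seqs = alt)
}

#' Assemble every well on a plate
#'
#' @param anchors_all Output of [plate_anchors()].
#' @param graph Shared `kmer_graph` built from the intermediate pool.
#' @param params A [walk_params()] object.
#' @param frame_offset Reading-frame offset for translation checks.
#' @return List with `records` (successful barcode records, named by
#'   sample), `failures` (named character vector of failure stages), and
#'   `secondaries` (flat list of secondary records).
#' @export
assemble_plate <- function(anchors_all, graph, params = walk_params(),
                           frame_offset = 1L) {
  records <- list(); failures <- character(0); secondaries <- list()
  for (sid in names(anchors_all)) {
    res <- assemble_well(anchors_all[[sid]], graph, sid, params, frame_offset)
    if (!is.null(res$record)) records[[sid]] <- res$record
    else failures[sid] <- res$failure
    secondaries <- c(secondaries, res$secondaries)
  }
  list(records = records, failures = failures, secondaries = secondaries)
}
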