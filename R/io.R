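#' Read a paired-end FASTQ library
#'
#' Reads two FASTQ files (Phred+33) holding the two mates of a paired-end
#' library in matched record order and returns them as one data frame of
#' read pairs.
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A `data.frame` with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.  `read_id` is the header up to the first whitespace, with a
#'   trailing `/1` or `/2` mate suffix removed.
#' @details Record counts must agree between the two files; a mismatch is a
#'   hard error naming the first pair index lacking a mate.  Qualities are
#'   kept as Phred+33 strings; decode with [phred_scores()].
#' @export
read_fastq_pairs <- function(path1, path2) {
  f1 <- .read_fastq(path1)
  f2 <- .read_fastq(path2)
  n1 <- nrow(f1); n2 <- nrow(f2)
  if (n1 != n2) {
    stop(sprintf("mate files differ in record count (%d vs %d): pair %d has no mate",
                 n1, n2, min(n1, n2) + 1L))
  }
  id1 <- .strip_mate_suffix(f1$read_id)
  id2 <- .strip_mate_suffix(f2$read_id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop(sprintf("read ids disagree at pair %d: '%s' vs '%s'",
                 bad[1], id1[bad[1]], id2[bad[1]]))
  }
  data.frame(read_id = id1, seq1 = f1$seq, qual1 = f1$qual,
             seq2 = f2$seq, qual2 = f2$qual, stringsAsFactors = FALSE)
}

.read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

.strip_mate_suffix <- function(id) sub("/[12]$", "", id)

#' Write a paired-end FASTQ library
#'
#' @param pairs Data frame as returned by [read_fastq_pairs()].
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2.
#' @return Invisibly, the number of pairs written.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  .write_fastq(pairs$read_id, pairs$seq1, pairs$qual1, path1)
  .write_fastq(pairs$read_id, pairs$seq2, pairs$qual2, path2)
  invisible(nrow(pairs))
}

.write_fastq <- function(id, seq, qual, path) {
  if (length(id) == 0L) { file.create(path); return(invisible(0L)) }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con, sep = "\n")
  invisible(length(id))
}

#' Read the plate tag/primer sheet
#'
#' Parses the tab-separated sheet describing one amplification plate: one
#' row per well with its sample id, 5-bp forward/reverse inline tags and the
#' primer pair, and validates the plate-wide tag design.
#'
#' @param path Path to a TSV with columns `sample_id`, `fwd_tag`, `rev_tag`,
#'   `fwd_primer`, `rev_primer`.
#' @return A validated `data.frame` of well specifications.
#' @details Validation enforces the tag design the demultiplexer relies on:
#'   tags are exactly 5 bp over A/C/G/T, at most 96 wells per plate, unique
#'   sample ids, and every pair of distinct tags at the same end differs by
#'   at least 2 substitutions (so a single sequencing error can never turn
#'   one well's tag into another's).
#' @export
read_plate_sheet <- function(path) {
  if (!file.exists(path)) stop("no such plate sheet: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_plate(df)
}

#' @rdname read_plate_sheet
#' @param plate Data frame with the plate sheet columns, validated in place.
#' @export
validate_plate <- function(plate) {
  need <- c("sample_id", "fwd_tag", "rev_tag", "fwd_primer", "rev_primer")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate sheet missing columns: ", paste(miss, collapse = ", "))
  if (nrow(plate) == 0L) stop("empty plate sheet: no wells defined")
  if (nrow(plate) > 96L) stop("more than 96 wells on one plate")
  if (anyDuplicated(plate$sample_id))
    stop("duplicated sample_id: ",
         plate$sample_id[duplicated(plate$sample_id)][1])
  for (col in c("fwd_tag", "rev_tag")) {
    bad <- !grepl("^[ACGT]{5}$", plate[[col]])
    if (any(bad))
      stop(sprintf("%s of well %s is not a 5-bp A/C/G/T tag",
                   col, plate$sample_id[which(bad)[1]]))
    .check_tag_distances(plate[[col]], plate$sample_id, col)
  }
  plate
}

.check_tag_distances <- function(tags, ids, label) {
  n <- length(tags)
  if (n < 2L) return(invisible())
  m <- do.call(rbind, strsplit(tags, ""))
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, 5L, byrow = TRUE))
    close_idx <- which(d < 2L & tags[(i + 1L):n] != tags[i])
    same_idx <- which(tags[(i + 1L):n] == tags[i])
    # identical tags at the same end are also a design violation: the well
    # could not be demultiplexed
    if (length(same_idx))
      stop(sprintf("wells %s and %s share %s %s",
                   ids[i], ids[i + same_idx[1]], label, tags[i]))
    if (length(close_idx))
      stop(sprintf("%s of wells %s (%s) and %s (%s) differ by <2 substitutions",
                   label, ids[i], tags[i],
                   ids[i + close_idx[1]], tags[i + close_idx[1]]))
  }
  invisible()
}

#' Write a plate tag/primer sheet
#'
#' @param plate Plate data frame (see [read_plate_sheet()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_plate_sheet <- function(plate, path) {
  write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings FASTA IO working on named character
#' vectors.  `write_fasta()` refuses duplicate record ids; an empty input
#' produces an empty file with a warning.
#'
#' @param records Named character vector of sequences; names are headers
#'   (they may carry `key=value` provenance tokens after the id).
#' @param path File path.
#' @return `read_fasta()`: named character vector.  `write_fasta()`:
#'   invisibly, the number of records written.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) {
    warning("writing empty FASTA: ", path)
    file.create(path)
    return(invisible(0L))
  }
  ids <- sub("\\s.*$", "", names(records))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  x <- Biostrings::DNAStringSet(unname(records))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path)
  invisible(length(records))
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read circular-consensus (CCS) reads with pass counts
#'
#' Reads PacBio CCS records from FASTQ or FASTA.  The per-molecule pass
#' count is parsed from a `passes=N` or `np=N` token in the record header
#' (also accepting the `np:i:N` tag form); records without a token get
#' `NA` passes.
#'
#' @param path FASTQ or FASTA file of CCS reads.
#' @return `data.frame` with columns `read_id`, `seq`, `passes`.
#' @export
read_ccs <- function(path) {
  if (!file.exists(path)) stop("no such CCS file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    x <- Biostrings::readDNAStringSet(path)
  }
  hdr <- names(x)
  m <- regmatches(hdr, regexpr("(passes=|np=|np:i:)[0-9]+", hdr))
  passes <- rep(NA_integer_, length(hdr))
  hit <- regexpr("(passes=|np=|np:i:)[0-9]+", hdr) > 0
  passes[hit] <- as.integer(sub("^(passes=|np=|np:i:)", "", m))
  data.frame(read_id = sub("\\s.*$", "", hdr),
             seq = as.character(x), passes = passes,
             stringsAsFactors = FALSE)
}
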