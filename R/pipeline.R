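#' Run the full short-read assembly pipeline
#'
#' Orchestrates filtering, tag/primer demultiplexing, terminus consensus
#' building, de Bruijn gap filling and post-assembly validation, writing
#' barcode FASTAs and a run report.  All stage thresholds default to the
#' pipeline's canonical values (adapter 15 bp / 3 mismatches, >10 Ns,
#' >50 bases at Q2, exact tags with <=2 primer mismatches, 1/10 abundance
#' and <98% identity retention, 95% overlap identity, coverage-5 trimming,
#' 10% pruning fractions, 709-bp length bound) and are exposed as
#' arguments.
#'
#' @param fastq1,fastq2 Paired FASTQ paths.
#' @param plate_sheet Plate sheet TSV path (see [read_plate_sheet()]).
#' @param outdir Output directory for FASTAs and reports (created).
#' @param filter A [filter_params()] object.
#' @param overlap An [overlap_params()] object.
#' @param walk A [walk_params()] object.
#' @param max_primer_mismatch Primer substitutions tolerated in
#'   demultiplexing (2).
#' @param min_cov Consensus coverage floor (5).
#' @param min_abundance_frac,max_identity Secondary-candidate retention
#'   rule (0.1, 0.98).
#' @param k K-mer size; `NULL` picks `min(127, shortest read - 1)`.
#' @param frame_offset Reading-frame offset for translation checks (1).
#' @return List of class `run_report` with per-stage counts (`reads`),
#'   assembled `records`, `failures`, `secondaries`, `nontarget` calls and
#'   output `paths`.
#' @export
run_pipeline <- function(fastq1, fastq2, plate_sheet, outdir,
                         filter = filter_params(),
                         overlap = overlap_params(),
                         walk = walk_params(),
                         max_primer_mismatch = 2L, min_cov = 5L,
                         min_abundance_frac = 0.1, max_identity = 0.98,
                         k = NULL, frame_offset = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  plate <- read_plate_sheet(plate_sheet)
  pairs <- read_fastq_pairs(fastq1, fastq2)
  message(sprintf("read %d pairs", nrow(pairs)))

  flt <- filter_read_pairs(pairs, filter)
  message(sprintf("filter: %d/%d pairs clean", flt$report[["n_clean"]],
                  flt$report[["n_input"]]))

  routed <- route_reads(flt$clean, plate, max_primer_mismatch)
  message(sprintf("demux: %d terminus / %d intermediate / %d artifact reads",
                  routed$report[["n_terminus"]],
                  routed$report[["n_intermediate"]],
                  routed$report[["n_artifact"]]))

  anchors <- plate_anchors(routed$terminus, plate, overlap, min_cov,
                           min_abundance_frac, max_identity)

  inter <- routed$intermediate
  records <- list(); failures <- character(0); secondaries <- list()
  if (length(inter)) {
    if (is.null(k)) k <- min(127L, min(nchar(inter)) - 1L)
    graph <- build_graph(inter, k)
    asm <- assemble_plate(anchors, graph, walk, frame_offset)
    records <- asm$records
    failures <- asm$failures
    secondaries <- asm$secondaries
  } else {
    failures <- setNames(rep("no_intermediate_reads", nrow(plate)),
                         plate$sample_id)
  }
  message(sprintf("assembled %d/%d wells", length(records), nrow(plate)))

  nontarget <- classify_nontarget(secondaries, records)

  paths <- list(barcodes = file.path(outdir, "barcodes.fasta"),
                secondaries = file.path(outdir, "secondary_barcodes.fasta"),
                report = file.path(outdir, "run_report.tsv"))
  if (length(records)) {
    fa <- vapply(records, `[[`, character(1), "seq")
    names(fa) <- sprintf("%s length=%d n_paths=%d translation_ok=%s",
                         names(records), nchar(fa),
                         vapply(records, function(r)
                           as.integer(r$n_paths_found), integer(1)),
                         vapply(records, `[[`, logical(1), "translation_ok"))
    write_fasta(fa, paths$barcodes)
  } else file.create(paths$barcodes)
  if (length(secondaries)) {
    fa2 <- vapply(secondaries, `[[`, character(1), "seq")
    names(fa2) <- sprintf("%s_sec%d abundance_ratio=%.3f",
                          vapply(secondaries, `[[`, character(1), "sample_id"),
                          seq_along(secondaries),
                          vapply(secondaries, `[[`, numeric(1),
                                 "abundance_ratio"))
    write_fasta(fa2, paths$secondaries)
  } else file.create(paths$secondaries)

  reads <- c(raw_pairs = nrow(pairs),
             clean_pairs = unname(flt$report[["n_clean"]]),
             flt$report[-1],
             routed$report)
  well_status <- data.frame(
    sample_id = plate$sample_id,
    status = ifelse(plate$sample_id %in% names(records), "assembled",
                    "failed"),
    failure_stage = failures[plate$sample_id],
    stringsAsFactors = FALSE)
  full_len <- barcode_lengths()[["with_primers"]]
  n_full <- sum(vapply(records, function(r) nchar(r$seq), integer(1)) ==
                  full_len)
  report_df <- data.frame(metric = c(names(reads), "n_wells", "n_assembled",
                                     "n_full_length"),
                          value = c(unname(reads), nrow(plate),
                                    length(records), n_full))
  write.table(report_df, paths$report, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(list(reads = reads, records = records, failures = failures,
                 secondaries = secondaries, nontarget = nontarget,
                 anchors = anchors, well_status = well_status,
                 n_full_length = n_full, paths = paths),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pooled amplicon assembly run\n")
  cat(sprintf("  pairs: %d raw, %d clean\n", x$reads[["raw_pairs"]],
              x$reads[["clean_pairs"]]))
  cat(sprintf("  reads: %d terminus, %d intermediate, %d artifact\n",
              x$reads[["n_terminus"]], x$reads[["n_intermediate"]],
              x$reads[["n_artifact"]]))
  cat(sprintf("  wells assembled: %d (%d full length)\n",
              length(x$records), x$n_full_length))
  if (nrow(x$nontarget))
    cat(sprintf("  nontarget calls: %d\n", nrow(x$nontarget)))
  invisible(x)
}
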