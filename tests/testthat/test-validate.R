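test_that("translation check flags frameshifts and in-frame stops", {
  cfg <- sim_config(n_wells = 2L, depth_per_well = 0L, ccs_depth = 0L,
                    rng_seed = 61L)
  sim <- simulate_plate(cfg, withr::local_tempdir())
  core <- sim$truth[[1]]$primary  # generated stop-free by construction
  expect_true(translation_check(core)$ok)
  # a 1-bp deletion shifts the frame; scan against an all-frames oracle
  del <- paste0(substr(core, 1L, 99L), substring(core, 101L))
  gc5 <- Biostrings::getGeneticCode("5")
  frame_stops <- function(s, off) {
    n <- (nchar(s) - off) %/% 3L
    codons <- substring(s, off + 1L + 3L * (seq_len(n) - 1L),
                        off + 3L * seq_len(n))
    sum(gc5[codons[seq_len(n - 1L)]] == "*", na.rm = TRUE)
  }
  expect_equal(translation_check(del)$n_stops, frame_stops(del, 1L))
  expect_false(translation_check(del)$ok)
  # TAA inserted in frame
  stopin <- paste0(substr(core, 1L, 301L), "TAA", substring(core, 305L))
  expect_gte(translation_check(stopin)$n_stops, 1L)
  # codons containing N are skipped and counted separately
  nseq <- core
  substr(nseq, 50L, 50L) <- "N"
  tr <- translation_check(nseq)
  expect_true(tr$ok)
  expect_equal(tr$n_ambiguous, 1L)
})

test_that("reference comparison resolves IUPAC ambiguities without mismatches", {
  set.seed(62)
  asm <- rand_dna(1L, 658L)
  # identical sequences
  res <- compare_to_reference(asm, asm)
  expect_equal(res$n_mismatch, 0L)
  expect_equal(res$identity, 1)
  expect_equal(res$n_columns, 658L)
  # reference R at a position where the assembly has A: resolved, not mismatch
  ref <- asm
  a_pos <- which(strsplit(asm, "")[[1]] == "A")[10]
  substr(ref, a_pos, a_pos) <- "R"
  res2 <- compare_to_reference(asm, ref)
  expect_equal(res2$ambiguous_resolved, 1L)
  expect_equal(res2$n_mismatch, 0L)
  expect_equal(res2$identity, 1)
  # one true substitution
  ref3 <- asm
  substr(ref3, 300L, 300L) <- setdiff(BASES, substr(asm, 300L, 300L))[1]
  res3 <- compare_to_reference(asm, ref3)
  expect_equal(res3$n_mismatch, 1L)
  # column accounting always closes
  for (r in list(res, res2, res3)) {
    expect_equal(r$n_match + r$n_mismatch + r$ambiguous_resolved +
                   r$ambiguous_conflict + r$n_indel, r$n_columns)
  }
  # an internal indel is flagged and excluded from mismatches
  gap <- paste0(substr(asm, 1L, 329L), substring(asm, 331L))
  res4 <- compare_to_reference(gap, asm)
  expect_gte(res4$n_indel, 1L)
  expect_equal(res4$n_mismatch, 0L)
})

test_that("secondary assemblies are classified by origin", {
  cfg <- sim_config(n_wells = 3L, depth_per_well = 0L, ccs_depth = 0L,
                    rng_seed = 63L)
  sim <- simulate_plate(cfg, withr::local_tempdir())
  p <- folmer_primers()
  wrap <- function(core) paste0(p[["fwd"]], core, revcomp(p[["rev"]]))
  rec <- function(sid, core, ok = TRUE, ratio = 0.2) {
    list(sample_id = sid, seq = wrap(core), translation_ok = ok,
         abundance_ratio = ratio)
  }
  records <- list(A = rec("A", sim$truth[[1]]$primary),
                  B = rec("B", sim$truth[[2]]$primary),
                  C = rec("C", sim$truth[[3]]$primary))
  # identical to a neighboring well's primary
  cross <- rec("A", sim$truth[[2]]$primary)
  # stops + 93%-identical to own primary: NUMT-like
  numt_core <- coiassembler:::.mutate_stop_free(sim$truth[[1]]$primary, 45L)
  numt_core <- paste0(substr(numt_core, 1L, 200L), "TAA",
                      substring(numt_core, 204L))
  numt <- rec("A", numt_core, ok = FALSE)
  # deeply divergent, clean translation: putative nontarget
  far_core <- coiassembler:::.mutate_stop_free(sim$truth[[1]]$primary, 200L)
  far <- rec("A", far_core)
  calls <- classify_nontarget(list(cross, numt, far), records)
  expect_equal(calls$category,
               c("cross_contamination", "putative_numt_or_error",
                 "putative_nontarget"))
  # a well's own primary is never relabeled
  expect_false(any(calls$seq == records$A$seq))
})
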