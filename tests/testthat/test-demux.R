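test_that("terminus matching identifies wells by exact tag + primer", {
  set.seed(21)
  plate <- toy_plate(3L)
  core <- rand_dna(1L, 120L)
  # 5' read of well 1, forward orientation
  r5 <- paste0(plate$fwd_tag[1], plate$fwd_primer[1], core)
  hit <- match_terminus(r5, plate)
  expect_equal(hit[c("sample_id", "end", "orientation")],
               list(sample_id = "W1", end = "five_prime",
                    orientation = "forward"))
  # 3' read of well 2 seen on the reverse strand
  r3 <- revcomp(paste0(plate$rev_tag[2], plate$rev_primer[2], core))
  hit <- match_terminus(r3, plate)
  expect_equal(hit[c("sample_id", "end", "orientation")],
               list(sample_id = "W2", end = "three_prime",
                    orientation = "revcomp"))
  # primer mismatches within tolerance still match
  r5mm <- r5
  substr(r5mm, 8L, 8L) <- setdiff(BASES, substr(r5, 8L, 8L))[1]
  expect_equal(match_terminus(r5mm, plate)$sample_id, "W1")
  # brute force over all tag+primer prefixes agrees on a read set
  reads <- c(r5, r3, rand_dna(5L, 150L))
  prefixes <- c(paste0(plate$fwd_tag, plate$fwd_primer),
                paste0(plate$rev_tag, plate$rev_primer))
  brute <- vapply(reads, function(s) {
    any(vapply(prefixes, function(p)
      startsWith(s, p) || startsWith(revcomp(s), p), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  got <- vapply(reads, function(s) !is.null(match_terminus(s, plate, 0L)),
                logical(1), USE.NAMES = FALSE)
  expect_identical(got, brute)
})

test_that("tags are matched exactly: one substitution voids assignment", {
  set.seed(22)
  plate <- toy_plate(3L)
  core <- rand_dna(1L, 120L)
  r5 <- paste0(plate$fwd_tag[1], plate$fwd_primer[1], core)
  mut <- r5
  substr(mut, 2L, 2L) <- setdiff(BASES, substr(r5, 2L, 2L))[1]
  # the mutated leading 5-mer is Hamming-1 from well 1's tag and (by the
  # >=2 design) at least Hamming-1 from every other tag
  lead <- substr(mut, 1L, 5L)
  expect_true(all(vapply(plate$fwd_tag, hamming, numeric(1), a = lead) >= 1))
  expect_null(match_terminus(mut, plate))
})

test_that("primer dimers and short chimeras are flagged as artifacts", {
  set.seed(23)
  plate <- toy_plate(2L)
  w <- plate[1, , drop = FALSE]
  dimer <- paste0(w$fwd_tag, w$fwd_primer, rand_dna(1L, 30L),
                  revcomp(w$rev_primer), revcomp(w$rev_tag))
  pair_art <- make_pairs(dimer, revcomp(dimer))
  expect_equal(classify_artifact(pair_art, plate), "primer_dimer_or_chimera")
  # an ordinary terminus read (one primer) and a mid-amplicon read are normal
  term <- paste0(w$fwd_tag, w$fwd_primer, rand_dna(1L, 120L))
  expect_equal(classify_artifact(make_pairs(term, rand_dna(1L, 150L)), plate),
               "normal")
  expect_equal(classify_artifact(make_pairs(rand_dna(1L, 150L),
                                            rand_dna(1L, 150L)), plate),
               "normal")
})

test_that("routing partitions clean reads and is exact on error-free data", {
  cfg <- sim_config(n_wells = 6L, depth_per_well = 400L,
                    pcr_error_rate = 0, seq_error_rate = 0,
                    low_quality_pair_frac = 0, many_n_pair_frac = 0,
                    ccs_depth = 0L, rng_seed = 33L)
  sim <- cached_sim("errorfree6", cfg)
  pairs <- read_fastq_pairs(sim$paths$fastq1, sim$paths$fastq2)
  routed <- route_reads(pairs, sim$plate)
  rep <- routed$report
  expect_equal(rep[["n_clean_reads"]],
               rep[["n_terminus"]] + rep[["n_intermediate"]] +
                 rep[["n_artifact"]])
  # error-free: every assignment matches the well encoded in the read id
  hit_well <- routed$terminus$sample_id
  true_well <- sub(":.*$", "", routed$terminus$read_id)
  expect_true(all(hit_well == true_well))
  # recall: every read starting with its well's tag+primer is either in the
  # terminus pool or part of an artifact pair
  prefixes <- c(paste0(sim$plate$fwd_tag, sim$plate$fwd_primer),
                paste0(sim$plate$rev_tag, sim$plate$rev_primer))
  is_term_read <- function(s) any(startsWith(s, prefixes)) ||
    any(startsWith(revcomp(s), prefixes))
  spanning <- sum(vapply(pairs$seq1, is_term_read, logical(1)),
                  vapply(pairs$seq2, is_term_read, logical(1)))
  expect_equal(nrow(routed$terminus) + rep[["n_artifact"]], spanning)
})

test_that("all-artifact input yields empty pools", {
  set.seed(24)
  plate <- toy_plate(2L)
  w <- plate[2, , drop = FALSE]
  dimer <- paste0(w$fwd_tag, w$fwd_primer, rand_dna(1L, 20L),
                  revcomp(w$rev_primer), revcomp(w$rev_tag))
  pairs <- make_pairs(rep(dimer, 4L), rep(revcomp(dimer), 4L))
  routed <- route_reads(pairs, plate)
  expect_equal(nrow(routed$terminus), 0L)
  expect_length(routed$intermediate, 0L)
  expect_equal(routed$report[["n_artifact"]], 8L)
})
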