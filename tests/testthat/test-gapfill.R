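test_that("k-mer graphs match a sliding-window oracle", {
  set.seed(41)
  # single read, k = len - 1: two k-mers per strand
  g1 <- build_graph("ACGTT", 4L)
  expect_setequal(g1$counts$kmer,
                  unique(c("ACGT", "CGTT", revcomp(c("ACGT", "CGTT")))))
  # ACGT arises once per strand (forward, and from revcomp AACGT)
  expect_equal(graph_abundance(g1, c("ACGT", "CGTT", "AACG")), c(2L, 1L, 1L))
  # 10 copies of one read: every k-mer at abundance 10 per strand
  g2 <- build_graph(rep("ACGTTGCA", 10L), 5L)
  expect_true(all(g2$counts$abundance == 10L))
  # random read set vs brute-force enumeration (including N skipping)
  reads <- rand_dna(12L, 20L)
  substr(reads[1], 7L, 7L) <- "N"
  g <- build_graph(reads, 6L)
  want <- oracle_kmer_counts(reads, 6L)
  expect_equal(length(g$counts$kmer), length(want))
  expect_equal(graph_abundance(g, names(want)), unname(as.integer(want)))
  # read support: every k-mer's reads really contain it (either strand)
  for (km in sample(g$counts$kmer, 10L)) {
    rs <- graph_reads(g, km)
    expect_true(all(grepl(km, reads[rs], fixed = TRUE) |
                      grepl(km, revcomp(reads[rs]), fixed = TRUE)))
  }
  expect_error(build_graph(reads, 30L), "read length")
})

test_that("a linear graph walks to exactly one true path", {
  set.seed(42)
  seqlen <- 160L
  truth <- rand_dna(1L, seqlen)
  reads <- substring(truth, 1:(seqlen - 40L + 1L),
                     40:(seqlen))  # tiling 40-mers
  g <- build_graph(reads, 21L)
  a5 <- substr(truth, 1L, 30L)
  a3 <- revcomp(substring(truth, seqlen - 29L))
  paths <- walk_graph(g, a5, a3, walk_params(max_len = 300L))
  expect_length(paths, 1L)
  # reconstruction: anchor5 + path extension + anchor3 equals the truth
  rec <- paste0(a5, substring(paths[1], 22L))
  rec <- paste0(rec, substring(revcomp(a3), 22L))
  expect_equal(rec, truth)
  # every path k-mer is present in the graph
  n <- nchar(paths[1]) - 21L + 1L
  kms <- substring(paths[1], 1:n, 21:(n + 20L))
  expect_true(all(graph_abundance(g, kms) > 0L))
})

test_that("low-abundance bubble branches are pruned by the 10% rule", {
  set.seed(43)
  truth <- rand_dna(1L, 120L)
  alt <- truth
  substr(alt, 60L, 60L) <- setdiff(BASES, substr(truth, 60L, 60L))[1]
  reads <- c(rep(substring(truth, 1:91, 30:120), each = 20L),
             substring(alt, 31:61, 60:90))  # bubble at 5% abundance
  g <- build_graph(reads, 15L)
  paths <- walk_graph(g, substr(truth, 1L, 20L),
                      revcomp(substring(truth, 101L)),
                      walk_params(max_len = 200L))
  expect_length(paths, 1L)
  expect_false(grepl(substr(alt, 46L, 74L), paths[1], fixed = TRUE))
})

test_that("cycles are abandoned at the preset length bound", {
  # a rolling-circle repeat with no end point inside the cycle
  unit <- "ACGGTCATTGCAGGATCGTTACCGGTAT"  # 28 bp, k=10 keeps it cyclic
  circ <- strrep(unit, 6L)
  reads <- substring(circ, 1:(nchar(circ) - 24L), 25:nchar(circ))
  g <- build_graph(reads, 10L)
  a5 <- substr(circ, 1L, 15L)
  # the end point is a reverse-strand k-mer: present in the graph (strand
  # closure) but never reached by forward extension around the cycle
  paths <- walk_graph(g, a5, substr(circ, 40L, 54L),
                      walk_params(max_len = 120L))
  expect_length(paths, 0L)
})

test_that("walks equal exhaustive DFS enumeration on random graphs", {
  set.seed(44)
  par <- walk_params(max_len = 70L)
  for (i in 1:25) {
    reads <- rand_dna(sample(6:14, 1L), sample(15:22, 1L))
    k <- 7L
    g <- build_graph(reads, k)
    start <- substr(reads[1], 1L, k)
    r <- sample(seq_along(reads), 1L)
    end <- substring(reads[r], nchar(reads[r]) - k + 1L)
    got <- sort(walk_graph(g, start, revcomp(end), par))
    want <- oracle_walk(g, start, end, max_len = 70L)
    expect_identical(got, want)
  }
})

test_that("well assembly recovers the truth and handles degenerate inputs", {
  cfg <- sim_config(n_wells = 6L, depth_per_well = 400L,
                    pcr_error_rate = 0, seq_error_rate = 0,
                    low_quality_pair_frac = 0, many_n_pair_frac = 0,
                    ccs_depth = 0L, rng_seed = 33L)
  sim <- cached_sim("errorfree6", cfg)
  pairs <- read_fastq_pairs(sim$paths$fastq1, sim$paths$fastq2)
  routed <- route_reads(pairs, sim$plate)
  anchors <- plate_anchors(routed$terminus, sim$plate)
  g <- build_graph(routed$intermediate, 127L)
  for (sid in sim$plate$sample_id[1:3]) {
    res <- assemble_well(anchors[[sid]], g, sid)
    expect_false(is.null(res$record))
    expect_equal(res$record$seq, sim$truth[[sid]]$primary_with_primers)
    expect_true(res$record$translation_ok)
    expect_equal(nchar(res$record$seq), 709L)
  }
  # anchors that already overlap skip the walk entirely (the unrelated tiny
  # graph is never consulted)
  set.seed(45)
  tiny_g <- build_graph(rand_dna(1L, 40L), 12L)
  short <- rand_dna(1L, 180L)
  a5 <- list(primary = list(seq = substr(short, 1L, 120L), abundance = 50L),
             secondaries = list())
  a3 <- list(primary = list(seq = revcomp(substring(short, 61L)),
                            abundance = 40L),
             secondaries = list())
  res <- assemble_well(list(five_prime = a5, three_prime = a3), tiny_g, "short")
  expect_equal(res$record$seq, short)
  # a pool lacking the well's k-mers fails with a diagnostic
  sid <- sim$plate$sample_id[1]
  res2 <- assemble_well(anchors[[sid]],
                        build_graph(rand_dna(5L, 150L), 127L), sid)
  expect_null(res2$record)
  expect_true(res2$failure %in% c("anchor_kmer_missing", "no_path"))
})
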