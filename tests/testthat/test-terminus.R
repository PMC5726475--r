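test_that("identical clustering matches a counting oracle and sorts deterministically", {
  expect_equal(cluster_identical(c("AAA", "AAA", "AAT")),
               data.frame(seq = c("AAA", "AAT"), abundance = c(2L, 1L),
                          stringsAsFactors = FALSE))
  one <- cluster_identical(rep("ACGT", 1000L))
  expect_equal(one$abundance, 1000L)
  set.seed(31)
  reads <- sample(rand_dna(20L, 30L), 300L, replace = TRUE)
  cl <- cluster_identical(reads)
  tab <- table(reads)
  expect_equal(sum(cl$abundance), 300L)
  expect_equal(setNames(cl$abundance, cl$seq)[names(tab)],
               setNames(as.integer(tab), names(tab)))
  expect_true(all(diff(cl$abundance) <= 0))
  expect_equal(nrow(cluster_identical(character(0))), 0L)
})

test_that("candidate selection applies the 1/10 abundance and <98% identity rules", {
  set.seed(32)
  base <- rand_dna(1L, 150L)
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), n)
    for (p in pos) ch[p] <- setdiff(BASES, ch[p])[1]
    paste(ch, collapse = "")
  }
  clusters <- function(ab2, seq2) {
    data.frame(seq = c(base, seq2), abundance = c(100L, ab2),
               stringsAsFactors = FALSE)
  }
  far <- mut(base, 25L)    # ~83% identity
  near <- mut(base, 2L)    # ~98.7% identity
  # 9 < 100/10: dropped regardless of identity
  expect_equal(nrow(select_candidates(clusters(9L, far))$secondaries), 0L)
  # abundant but nearly identical: same-haplotype noise
  expect_equal(nrow(select_candidates(clusters(20L, near))$secondaries), 0L)
  # abundant and divergent: retained as a nontarget candidate
  sel <- select_candidates(clusters(20L, far))
  expect_equal(sel$secondaries$seq, far)
  # scale invariance
  scaled <- clusters(20L, far); scaled$abundance <- scaled$abundance * 7L
  expect_equal(select_candidates(scaled)$secondaries$seq, far)
})

test_that("pair merging picks the exhaustive-oracle offset at the 95% cutoff", {
  set.seed(33)
  frag <- rand_dna(1L, 250L)
  s1 <- substr(frag, 1L, 150L)
  s2 <- substring(frag, 101L)  # 50-bp true overlap
  expect_equal(merge_pair(s1, s2), frag)
  # 3 mismatches in a 50-bp overlap is 94% identity: rejected
  s2bad <- s2
  for (p in c(5L, 15L, 25L))
    substr(s2bad, p, p) <- setdiff(BASES, substr(s2, p, p))[1]
  expect_null(merge_pair(s1, s2bad))
  # 2 mismatches (96%) merge, disagreements resolved toward higher quality
  s2ok <- s2
  for (p in c(5L, 15L))
    substr(s2ok, p, p) <- setdiff(BASES, substr(s2, p, p))[1]
  merged <- merge_pair(s1, s2ok, hit_qual = strrep("I", 150L),
                       mate_qual = strrep("#", 150L))
  expect_equal(merged, frag)  # hit read wins both conflicts
  # equal qualities give N at conflicting positions
  mergedN <- merge_pair(s1, s2ok)
  expect_equal(nchar(gsub("[^N]", "", mergedN)), 2L)
  # random pairs: chosen offset equals the exhaustive-offset oracle
  for (i in 1:20) {
    f <- rand_dna(1L, sample(180:280, 1L))
    a <- substr(f, 1L, 150L)
    b <- substring(f, nchar(f) - 149L)
    got <- merge_pair(a, b)
    want <- oracle_best_overlap(a, b, 10L, 0.95)
    expect_equal(nchar(got), 300L - want$o)
  }
})

test_that("consensus takes per-column majority and trims coverage < 5", {
  frags <- rep(strrep("ACGT", 25L), 10L)
  cons <- build_consensus(frags)
  expect_equal(cons$seq, strrep("ACGT", 25L))
  expect_equal(cons$coverage, rep(10L, 100L))
  # coverage profile 10,...,10,4,4 -> last 2 positions trimmed
  frags2 <- c(rep(paste0(strrep("A", 8L)), 6L), rep(strrep("A", 10L), 4L))
  cons2 <- build_consensus(frags2)
  expect_equal(nchar(cons2$seq), 8L)
  expect_true(all(cons2$coverage >= 5L))
  # a 1-bp variant at 1/10 depth loses the column vote
  v <- strrep("ACGT", 25L)
  substr(v, 13L, 13L) <- "A"
  cons3 <- build_consensus(c(rep(strrep("ACGT", 25L), 9L), v))
  expect_equal(cons3$seq, strrep("ACGT", 25L))
  # column-count oracle on a random pile
  set.seed(34)
  pile <- substring(rand_dna(8L, 40L), 1L, sample(20:40, 8L, replace = TRUE))
  cons4 <- build_consensus(pile, min_cov = 3L)
  for (p in seq_len(nchar(cons4$seq))) {
    col <- substr(pile, p, p)
    col <- col[col != ""]
    tab <- table(col)
    expect_true(substr(cons4$seq, p, p) %in%
                  names(tab)[tab == max(tab)])
    expect_equal(cons4$coverage[p], length(col))
  }
})

test_that("single-haplotype simulated wells give the exact true anchor", {
  cfg <- sim_config(n_wells = 6L, depth_per_well = 400L,
                    pcr_error_rate = 0, seq_error_rate = 0,
                    low_quality_pair_frac = 0, many_n_pair_frac = 0,
                    ccs_depth = 0L, rng_seed = 33L)
  sim <- cached_sim("errorfree6", cfg)
  pairs <- read_fastq_pairs(sim$paths$fastq1, sim$paths$fastq2)
  routed <- route_reads(pairs, sim$plate)
  anchors <- plate_anchors(routed$terminus, sim$plate)
  for (w in seq_len(3L)) {
    sid <- sim$plate$sample_id[w]
    truth <- sim$truth[[sid]]$primary_with_primers
    a5 <- anchors[[sid]]$five_prime$primary
    expect_false(is.null(a5))
    expect_equal(a5$seq, substr(truth, 1L, nchar(a5$seq)))
    expect_true(all(a5$coverage >= 5L))
    a3 <- anchors[[sid]]$three_prime$primary
    a3bc <- revcomp(a3$seq)
    expect_equal(a3bc, substring(truth, nchar(truth) - nchar(a3bc) + 1L))
  }
})
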