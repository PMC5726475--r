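test_that("adapter detection honors the 15-bp / 3-mismatch boundary", {
  set.seed(11)
  adapter <- "AGATCGGAAGAGCACACGTC"  # 20 bp
  par <- filter_params(adapter_seqs = adapter)
  host <- rand_dna(1L, 150L)

  embed <- function(sub) paste0(substr(host, 1, 40), sub,
                                substr(host, 41 + nchar(sub), 150))
  # verbatim 20-bp adapter: 0 mismatches over >=15 bp
  expect_true(has_adapter(embed(adapter), par))
  # a 15-bp adapter window carrying exactly 3 vs 4 mismatches
  win <- substr(adapter, 1, 15)
  mism <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) ch[p * 3L] <- setdiff(BASES, ch[p * 3L])[1]
    paste(ch, collapse = "")
  }
  expect_true(has_adapter(embed(mism(win, 3L)), par))
  expect_false(has_adapter(embed(mism(win, 4L)), par))

  # random reads vs an unrelated adapter, against the exhaustive window oracle
  reads <- rand_dna(40L, 150L)
  got <- has_adapter(reads, par)
  want <- vapply(reads, oracle_has_adapter, logical(1), adapter = adapter,
                 min_len = 15L, max_mm = 3L, USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("pair dropping applies N and low-quality boundaries exactly", {
  par <- filter_params()
  mk <- function(n_N = 0L, n_q2 = 0L, mate = 2L) {
    seqs <- c(rand_dna(1L, 150L), rand_dna(1L, 150L))
    quals <- rep(strrep("F", 150L), 2L)
    if (n_N > 0L) {
      s <- strsplit(seqs[mate], "")[[1]]; s[seq_len(n_N)] <- "N"
      seqs[mate] <- paste(s, collapse = "")
    }
    if (n_q2 > 0L)
      quals[mate] <- paste0(strrep("#", n_q2), strrep("F", 150L - n_q2))
    make_pairs(seqs[1], seqs[2], quals[1], quals[2])
  }
  set.seed(12)
  expect_equal(filter_pair(mk(), par), list(keep = TRUE, reason = "clean"))
  expect_equal(filter_pair(mk(n_N = 10L), par)$reason, "clean")
  expect_equal(filter_pair(mk(n_N = 11L), par),
               list(keep = FALSE, reason = "many_n"))
  expect_equal(filter_pair(mk(n_q2 = 50L), par)$reason, "clean")
  expect_equal(filter_pair(mk(n_q2 = 51L, mate = 1L), par),
               list(keep = FALSE, reason = "low_quality"))
})

test_that("filter report conserves counts and is mate-symmetric", {
  set.seed(13)
  n <- 60L
  pairs <- make_pairs(rand_dna(n, 150L), rand_dna(n, 150L))
  # salt in failures of each kind
  pairs$seq2[1:5] <- paste0(strrep("N", 12L), substr(pairs$seq2[1:5], 13, 150))
  pairs$qual1[6:10] <- paste0(strrep("#", 60L), strrep("F", 90L))
  res <- filter_read_pairs(pairs)
  rep <- res$report
  expect_equal(rep[["n_input"]],
               rep[["n_adapter"]] + rep[["n_many_n"]] +
                 rep[["n_low_quality"]] + rep[["n_clean"]])
  expect_equal(rep[["n_many_n"]], 5L)
  expect_equal(rep[["n_low_quality"]], 5L)
  # swapping mates changes nothing
  swapped <- make_pairs(pairs$seq2, pairs$seq1, pairs$qual2, pairs$qual1)
  expect_equal(filter_read_pairs(swapped)$report, rep)
  # loosening a threshold never decreases n_clean
  looser <- filter_read_pairs(pairs, filter_params(max_n = 20L,
                                                   max_low_q = 80L))
  expect_gte(looser$report[["n_clean"]], rep[["n_clean"]])
})
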