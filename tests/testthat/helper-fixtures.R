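# Shared fixtures, built in code.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

# a small valid plate with well-separated tags
toy_plate <- function(n = 3L) {
  tags <- c("AACCA", "GGTTG", "CATGC", "TGCAT", "ACACA", "GTGTG",
            "AAGGT", "CCTTA", "TTAAC", "GGCCG", "ATTGA", "CGGAC")
  p <- folmer_primers()
  data.frame(sample_id = paste0("W", seq_len(n)),
             fwd_tag = tags[seq_len(n)],
             rev_tag = tags[6L + seq_len(n)],
             fwd_primer = p[["fwd"]], rev_primer = p[["rev"]],
             stringsAsFactors = FALSE)
}

# assemble a full amplicon (tags + primers + core) for a plate row
toy_amplicon <- function(plate_row, core) {
  paste0(plate_row$fwd_tag, plate_row$fwd_primer, core,
         revcomp(plate_row$rev_primer), revcomp(plate_row$rev_tag))
}

# one clean read-pair data frame
make_pairs <- function(seq1, seq2, qual1 = strrep("F", nchar(seq1)),
                       qual2 = strrep("F", nchar(seq2)),
                       read_id = sprintf("r%03d", seq_along(seq1))) {
  data.frame(read_id = read_id, seq1 = seq1, qual1 = qual1,
             seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
}

# memoized simulations shared across test files (built once per run)
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (!exists(key, envir = .sim_cache)) {
    dir <- file.path(tempdir(), paste0("sim_", key))
    assign(key, simulate_plate(cfg, dir), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_run <- function(key, sim, ...) {
  rkey <- paste0(key, "_run")
  if (!exists(rkey, envir = .sim_cache)) {
    out <- run_pipeline(sim$paths$fastq1, sim$paths$fastq2, sim$paths$sheet,
                        file.path(tempdir(), paste0("out_", key)), ...)
    assign(rkey, out, envir = .sim_cache)
  }
  get(rkey, envir = .sim_cache)
}

# the main study-condition plate: 48 wells, 2000 pairs/well, 0.3% sequencing
# error, with duplicated species, near haplotypes (1-3 nt) and a joint CCS
# library; shared by the end-to-end tests
study_sim <- function() {
  cfg <- sim_config(
    n_wells = 48L, depth_per_well = 2000L, seq_error_rate = 0.003,
    duplicate_species_well_pairs = list(c(1L, 7L), c(2L, 13L)),
    near_haplotype_pairs = list(c(3L, 9L), c(4L, 21L), c(5L, 30L)),
    near_haplotype_ndiff = c(1L, 2L, 3L),
    ccs_depth = 50L, rng_seed = 101L)
  cached_sim("study48", cfg)
}

study_run <- function() cached_run("study48", study_sim())

truth_with_primers <- function(sim) {
  vapply(sim$truth, `[[`, character(1), "primary_with_primers")
}
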