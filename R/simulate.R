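# Deterministic plate simulator: tagged amplicon libraries with ground
# truth, emitting Illumina 150 PE FASTQ, PacBio-style CCS FASTQ, a plate
# sheet and truth manifests, so every pipeline stage is testable offline.

#' Simulation configuration
#'
#' Describes one synthetic amplification plate.  Defaults mirror the
#' library design the assembler targets: a 96-well plate of 658-bp COI
#' barcodes amplified with tagged Folmer primers, fragmented to ~250-bp
#' inserts and sequenced at 150 PE, with a fifth of read pairs coming from
#' primer dimers / short chimeras, plus a companion CCS library.
#'
#' @param n_wells Number of wells (<= 96).
#' @param barcode_len Barcode core length; must be `1 + 3m` so the
#'   standard reading frame (offset 1) closes (default 658).
#' @param read_len Read length (150).
#' @param insert_mean,insert_sd Fragment-size model, bp (250, 25).
#' @param depth_per_well Read pairs per well (2000).
#' @param pcr_error_rate Per-base substitution rate applied per molecule
#'   before fragmentation (2e-4).
#' @param seq_error_rate Per-base sequencing substitution rate (0.001).
#' @param terminal_frac Fraction of non-artifact pairs drawn from terminal
#'   fragments, split evenly between the two ends (0.5); the rest start
#'   uniformly inside the amplicon.
#' @param dimer_chimera_frac Fraction of pairs from primer dimers or short
#'   chimeras (0.2).
#' @param low_quality_pair_frac Fraction of pairs given a long Phred-2
#'   tail on one mate, to be removed by filtering (0.02).
#' @param many_n_pair_frac Fraction of pairs given >10 N calls (0.01).
#' @param heteroplasmy_wells Integer well indices carrying a minor
#'   mitochondrial haplotype.
#' @param minor_allele_frac Molecule fraction of the minor haplotype
#'   (0.15).
#' @param minor_divergence Fraction of barcode positions at which the
#'   minor haplotype differs (default 0.005, a few sites, as typical for
#'   heteroplasmy).
#' @param duplicate_species_well_pairs List of index pairs `c(i, j)` given
#'   identical barcodes (same species in two wells).
#' @param near_haplotype_pairs List of index pairs whose barcodes differ
#'   by `near_haplotype_ndiff` substitutions.
#' @param near_haplotype_ndiff Number of differing sites for near pairs
#'   (1-3, default 2; recycled over the pairs when given as a vector).
#'   Variant sites are placed in the terminus-covered
#'   region (the outer 200 bp of the core): the gap interior is assembled
#'   from an untagged shared pool, so only anchor-visible variation is
#'   attributable to a well by design.
#' @param nontarget_spikeins Data frame with columns `well` (index),
#'   `divergence` (fraction of positions mutated relative to the host
#'   barcode) and `abundance` (molecule ratio relative to the host
#'   template).
#' @param ccs_depth CCS reads per well (50; 0 disables the CCS library).
#' @param ccs_error_rate,ccs_indel_rate CCS substitution and 1-bp indel
#'   rates (0.002, 5e-4).
#' @param ccs_pass_mu,ccs_pass_size Negative-binomial pass-count model
#'   (mean 26, straddling the pass filter at 15).
#' @param ccs_terminal_del_frac Fraction of CCS reads losing one terminal
#'   base at either molecule end (0.05), exercising the tolerant index
#'   matching.
#' @param fwd_primer,rev_primer Primer pair (Folmer defaults).
#' @param rng_seed Mandatory integer seed; all outputs are byte-identical
#'   under the same seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_wells = 96L, barcode_len = 658L, read_len = 150L,
                       insert_mean = 250, insert_sd = 25,
                       depth_per_well = 2000L,
                       pcr_error_rate = 2e-4, seq_error_rate = 0.001,
                       terminal_frac = 0.5, dimer_chimera_frac = 0.2,
                       low_quality_pair_frac = 0.02,
                       many_n_pair_frac = 0.01,
                       heteroplasmy_wells = integer(0),
                       minor_allele_frac = 0.15, minor_divergence = 0.005,
                       duplicate_species_well_pairs = list(),
                       near_haplotype_pairs = list(),
                       near_haplotype_ndiff = 2L,
                       nontarget_spikeins = NULL,
                       ccs_depth = 50L, ccs_error_rate = 0.002,
                       ccs_indel_rate = 5e-4,
                       ccs_pass_mu = 26, ccs_pass_size = 8,
                       ccs_terminal_del_frac = 0.05,
                       fwd_primer = folmer_primers()[["fwd"]],
                       rev_primer = folmer_primers()[["rev"]],
                       rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for reproducibility")
  if (n_wells < 1L || n_wells > 96L) stop("n_wells must be in 1..96")
  if ((barcode_len - 1L) %% 3L != 0L)
    stop("barcode_len must be 1 + 3m so the reading frame closes")
  if (read_len > insert_mean)
    stop("read_len exceeds insert_mean: inconsistent library design")
  rates <- c(pcr_error_rate, seq_error_rate, terminal_frac,
             dimer_chimera_frac, low_quality_pair_frac, many_n_pair_frac,
             minor_allele_frac, minor_divergence,
             ccs_error_rate, ccs_indel_rate, ccs_terminal_del_frac)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  cfg <- mget(names(formals(sys.function())), envir = environment())
  structure(cfg, class = "sim_config")
}

# 5-bp tag codebook with pairwise Hamming distance >= 2: the 256 words of
# the length-5 parity code over {A,C,G,T} (last base = sum of the first
# four mod 4).
.tag_codebook <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(i1 = 0:3, i2 = 0:3, i3 = 0:3, i4 = 0:3)
  chk <- (g$i1 + g$i2 + g$i3 + g$i4) %% 4
  paste0(b[g$i1 + 1], b[g$i2 + 1], b[g$i3 + 1], b[g$i4 + 1], b[chk + 1])
}

.BASES <- c("A", "C", "G", "T")

# random stop-free barcode: one leading base plus (len-1)/3 codons drawn
# from the 62 non-stop codons of the invertebrate mitochondrial code
.rand_barcode <- function(len) {
  gc_tab <- Biostrings::getGeneticCode("5")
  good <- names(gc_tab)[gc_tab != "*"]
  m <- (len - 1L) %/% 3L
  paste0(sample(.BASES, 1L),
         paste(sample(good, m, replace = TRUE), collapse = ""))
}

# mutate `npos` distinct positions (within `region` if given) keeping the
# frame-offset-1 translation stop free
.mutate_stop_free <- function(seq, npos, region = NULL) {
  len <- nchar(seq)
  if (is.null(region)) region <- seq_len(len)
  npos <- min(npos, length(region))
  pos <- sample(region, npos)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  out <- paste(chars, collapse = "")
  # repair any stop codon introduced (frame offset 1)
  gc_tab <- Biostrings::getGeneticCode("5")
  good <- names(gc_tab)[gc_tab != "*"]
  repeat {
    tr <- translation_check(out, frame_offset = 1L)
    if (tr$ok) return(out)
    starts <- 2L + 3L * (seq_len((len - 1L) %/% 3L) - 1L)
    codons <- substring(out, starts, starts + 2L)
    bad <- which(gc_tab[codons] == "*")
    for (b in bad) {
      repl <- sample(good, 1L)
      substr(out, starts[b], starts[b] + 2L) <- repl
    }
  }
}

# substitution errors on a character vector of sequences at a per-base
# rate; substituted bases always differ from the original
.add_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  if (!length(hit)) return(seqs)
  idx <- rep(hit, nerr[hit])
  pos <- unlist(lapply(hit, function(i) sample.int(lens[i], nerr[i])))
  orig <- substring(seqs[idx], pos, pos)
  pick <- function(o) sample(setdiff(.BASES, o), 1L)
  repl <- vapply(orig, pick, character(1), USE.NAMES = FALSE)
  apply_substitutions(seqs, idx, pos, repl)
}

# random 1-bp indels at a per-base rate (for CCS reads)
.add_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nind <- rbinom(length(seqs), lens, rate)
  for (i in which(nind > 0L)) {
    s <- seqs[i]
    for (j in seq_len(nind[i])) {
      p <- sample.int(nchar(s), 1L)
      if (runif(1) < 0.5) {
        s <- paste0(substr(s, 1L, p - 1L), substring(s, p + 1L))  # deletion
      } else {
        s <- paste0(substr(s, 1L, p), sample(.BASES, 1L), substring(s, p + 1L))
      }
    }
    seqs[i] <- s
  }
  seqs
}

#' Simulate a tagged amplicon plate
#'
#' Generates per-well stop-free COI-like barcodes (with the configured
#' duplicated species, near haplotypes, heteroplasmy and nontarget
#' spike-ins), builds tag+primer amplicons, applies per-molecule PCR
#' substitutions, fragments molecules with a Gaussian insert-size model,
#' and emits paired 150-bp reads with sequencing errors, plus primer
#' dimer / short chimera artifacts, a CCS library with pass counts, the
#' plate sheet, and ground-truth manifests.
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory (created if missing).
#' @return List with `plate` (data frame), `truth` (per-well list of
#'   `primary`, `primary_with_primers`, optional `minor`, `spikes`), and
#'   `paths` (named list: `sheet`, `fastq1`, `fastq2`, `ccs`,
#'   `truth_fasta`, `manifest`).
#' @export
simulate_plate <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  cfg <- config
  n <- cfg$n_wells

  # plate sheet
  ids <- paste0(rep(LETTERS[1:8], times = 12), sprintf("%02d", rep(1:12, each = 8)))
  book <- sample(.tag_codebook())
  plate <- data.frame(sample_id = ids[seq_len(n)],
                      fwd_tag = book[seq_len(n)],
                      rev_tag = book[n + seq_len(n)],
                      fwd_primer = cfg$fwd_primer,
                      rev_primer = cfg$rev_primer,
                      stringsAsFactors = FALSE)

  # per-well barcode cores
  cores <- vapply(seq_len(n), function(i) .rand_barcode(cfg$barcode_len),
                  character(1))
  for (p in cfg$duplicate_species_well_pairs) cores[p[2]] <- cores[p[1]]
  anchored <- c(seq_len(min(200L, cfg$barcode_len)),
                seq.int(max(1L, cfg$barcode_len - 199L), cfg$barcode_len))
  ndiffs <- rep_len(cfg$near_haplotype_ndiff,
                    max(1L, length(cfg$near_haplotype_pairs)))
  for (ip in seq_along(cfg$near_haplotype_pairs)) {
    p <- cfg$near_haplotype_pairs[[ip]]
    cores[p[2]] <- .mutate_stop_free(cores[p[1]], ndiffs[ip], unique(anchored))
  }

  truth <- list()
  molecules <- list()  # per well: data.frame(seq_core, weight, kind)
  spikes_df <- cfg$nontarget_spikeins
  for (w in seq_len(n)) {
    mols <- data.frame(core = cores[w], weight = 1, kind = "primary",
                       stringsAsFactors = FALSE)
    tw <- list(primary = cores[w])
    if (w %in% cfg$heteroplasmy_wells) {
      minor <- .mutate_stop_free(cores[w],
                                 round(cfg$minor_divergence * cfg$barcode_len))
      mols$weight[1] <- 1 - cfg$minor_allele_frac
      mols <- rbind(mols, data.frame(core = minor,
                                     weight = cfg$minor_allele_frac,
                                     kind = "minor", stringsAsFactors = FALSE))
      tw$minor <- minor
    }
    if (!is.null(spikes_df)) {
      for (k in which(spikes_df$well == w)) {
        sp <- .mutate_stop_free(cores[w],
                                round(spikes_df$divergence[k] * cfg$barcode_len))
        mols <- rbind(mols, data.frame(core = sp,
                                       weight = spikes_df$abundance[k] *
                                         sum(mols$weight[mols$kind == "primary"]),
                                       kind = "spike", stringsAsFactors = FALSE))
        tw$spikes <- c(tw$spikes, sp)
      }
    }
    amp5 <- paste0(plate$fwd_tag[w], cfg$fwd_primer)
    amp3 <- paste0(revcomp(cfg$rev_primer), revcomp(plate$rev_tag[w]))
    mols$amp <- paste0(amp5, mols$core, amp3)
    tw$primary_with_primers <- paste0(cfg$fwd_primer, cores[w],
                                      revcomp(cfg$rev_primer))
    truth[[plate$sample_id[w]]] <- tw
    molecules[[w]] <- mols
  }

  # Illumina paired-end library
  AS1 <- AS2 <- AQ1 <- AQ2 <- allid <- character(0)
  rl <- cfg$read_len
  for (w in seq_len(n)) {
    mols <- molecules[[w]]
    nd <- cfg$depth_per_well
    if (nd == 0L) next
    n_art <- rbinom(1L, nd, cfg$dimer_chimera_frac)
    n_norm <- nd - n_art
    pair_seqs <- character(0)

    if (n_norm > 0L) {
      hap <- sample.int(nrow(mols), n_norm, replace = TRUE, prob = mols$weight)
      amp <- mols$amp[hap]
      amp <- .add_substitutions(amp, cfg$pcr_error_rate)
      alen <- nchar(amp)
      l <- pmax(rl, pmin(alen, round(rnorm(n_norm, cfg$insert_mean,
                                           cfg$insert_sd))))
      u <- runif(n_norm)
      t2 <- cfg$terminal_frac / 2
      s <- integer(n_norm)
      s[u < t2] <- 0L
      i3 <- u >= t2 & u < cfg$terminal_frac
      s[i3] <- alen[i3] - l[i3]
      ii <- u >= cfg$terminal_frac
      smax <- pmax(alen[ii] - l[ii] - 1L, 1L)
      s[ii] <- vapply(smax, function(m) sample.int(m, 1L), integer(1))
      insert <- substring(amp, s + 1L, s + l)
    } else insert <- character(0)

    if (n_art > 0L) {
      x <- sample(5:60, n_art, replace = TRUE)
      mid <- vapply(x, function(m)
        paste(sample(.BASES, m, replace = TRUE), collapse = ""), character(1))
      art <- paste0(plate$fwd_tag[w], cfg$fwd_primer, mid,
                    revcomp(cfg$rev_primer), revcomp(plate$rev_tag[w]))
      insert <- c(insert, art)
    }
    np <- length(insert)
    il <- nchar(insert)
    rle_ <- pmin(rl, il)
    r_left <- substr(insert, 1L, rle_)
    r_right <- revcomp(substring(insert, il - rle_ + 1L, il))
    swap <- runif(np) < 0.5
    s1 <- ifelse(swap, r_right, r_left)
    s2 <- ifelse(swap, r_left, r_right)
    s1 <- .add_substitutions(s1, cfg$seq_error_rate)
    s2 <- .add_substitutions(s2, cfg$seq_error_rate)
    # pairs destined to fail quality filtering
    nlow <- rbinom(1L, np, cfg$low_quality_pair_frac)
    nn <- rbinom(1L, np, cfg$many_n_pair_frac)
    ntarget <- sample.int(np, min(np, nn))
    for (i in ntarget) {
      pos <- sample.int(nchar(s2[i]), min(12L, nchar(s2[i])))
      s2[i] <- {
        ch <- strsplit(s2[i], "")[[1]]; ch[pos] <- "N"
        paste(ch, collapse = "")
      }
    }
    q1 <- strrep("F", nchar(s1))
    q2 <- strrep("F", nchar(s2))
    lowtarget <- sample.int(np, min(np, nlow))
    for (i in lowtarget) {
      L2 <- nchar(q2[i])
      nlq <- min(60L, L2)
      q2[i] <- paste0(substr(q2[i], 1L, L2 - nlq), strrep("#", nlq))
    }
    allid <- c(allid, sprintf("%s:%06d", plate$sample_id[w], seq_len(np)))
    AS1 <- c(AS1, s1); AQ1 <- c(AQ1, q1)
    AS2 <- c(AS2, s2); AQ2 <- c(AQ2, q2)
  }
  pairs <- data.frame(read_id = allid, seq1 = AS1, qual1 = AQ1,
                      seq2 = AS2, qual2 = AQ2, stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    ord <- sample.int(nrow(pairs))  # shuffle wells together as in a pool
    pairs <- pairs[ord, , drop = FALSE]
  }

  paths <- list(sheet = file.path(outdir, "plate.tsv"),
                fastq1 = file.path(outdir, "reads_1.fastq"),
                fastq2 = file.path(outdir, "reads_2.fastq"),
                ccs = file.path(outdir, "ccs.fastq"),
                truth_fasta = file.path(outdir, "truth.fasta"),
                manifest = file.path(outdir, "truth.tsv"))
  write_plate_sheet(plate, paths$sheet)
  write_fastq_pairs(pairs, paths$fastq1, paths$fastq2)

  # CCS library
  ccs_id <- character(0); ccs_seq <- character(0); ccs_pass <- integer(0)
  if (cfg$ccs_depth > 0L) {
    for (w in seq_len(n)) {
      mols <- molecules[[w]]
      hap <- sample.int(nrow(mols), cfg$ccs_depth, replace = TRUE,
                        prob = mols$weight)
      s <- mols$amp[hap]
      s <- .add_substitutions(s, cfg$ccs_error_rate)
      s <- .add_indels(s, cfg$ccs_indel_rate)
      del5 <- runif(cfg$ccs_depth) < cfg$ccs_terminal_del_frac
      del3 <- runif(cfg$ccs_depth) < cfg$ccs_terminal_del_frac
      s[del5] <- substring(s[del5], 2L)
      s[del3] <- substr(s[del3], 1L, nchar(s[del3]) - 1L)
      flip <- runif(cfg$ccs_depth) < 0.5
      s[flip] <- revcomp(s[flip])
      ccs_seq <- c(ccs_seq, s)
      ccs_pass <- c(ccs_pass, rnbinom(cfg$ccs_depth, size = cfg$ccs_pass_size,
                                      mu = cfg$ccs_pass_mu))
      ccs_id <- c(ccs_id, sprintf("%s/ccs/%04d", plate$sample_id[w],
                                  seq_len(cfg$ccs_depth)))
    }
  }
  con <- file(paths$ccs, "w")
  if (length(ccs_id)) {
    writeLines(paste0("@", ccs_id, " passes=", ccs_pass, "\n", ccs_seq,
                      "\n+\n", strrep("F", nchar(ccs_seq))), con)
  }
  close(con)

  # ground truth
  fa <- character(0)
  man <- data.frame(sample_id = character(0), kind = character(0),
                    seq_id = character(0), length = integer(0),
                    stringsAsFactors = FALSE)
  for (w in seq_len(n)) {
    sid <- plate$sample_id[w]
    tw <- truth[[sid]]
    fa[paste0(sid, " kind=primary_with_primers")] <- tw$primary_with_primers
    man <- rbind(man, data.frame(sample_id = sid, kind = "primary",
                                 seq_id = sid,
                                 length = nchar(tw$primary_with_primers),
                                 stringsAsFactors = FALSE))
    if (!is.null(tw$minor)) {
      fa[paste0(sid, "_minor kind=minor_haplotype")] <- tw$minor
      man <- rbind(man, data.frame(sample_id = sid, kind = "minor",
                                   seq_id = paste0(sid, "_minor"),
                                   length = nchar(tw$minor),
                                   stringsAsFactors = FALSE))
    }
    for (k in seq_along(tw$spikes)) {
      fa[paste0(sid, "_spike", k, " kind=nontarget")] <- tw$spikes[k]
      man <- rbind(man, data.frame(sample_id = sid, kind = "spike",
                                   seq_id = paste0(sid, "_spike", k),
                                   length = nchar(tw$spikes[k]),
                                   stringsAsFactors = FALSE))
    }
  }
  if (length(fa)) write_fasta(fa, paths$truth_fasta) else file.create(paths$truth_fasta)
  write.table(man, paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)

  list(plate = plate, truth = truth, paths = paths)
}
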