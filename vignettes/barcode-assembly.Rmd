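---
title: "Assembling full-length COI barcodes from pooled tagged amplicons"
author: "coiassembler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling full-length COI barcodes from pooled tagged amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Reference DNA barcoding of animals rests on the 658-bp "Folmer" fragment of
mitochondrial COI, amplified with the LCO1490/HCO2198 primer pair (709 bp
including primers).  Sequencing one specimen per Sanger reaction is the
accuracy gold standard but dominates the cost of building reference
libraries.  The alternative this package implements: amplify each specimen
of a 96-well plate with primers carrying well-specific 5-bp inline tags at
both ends, pool all amplicons into a single fragmented short-read library
(~250-bp inserts, 150 PE), and reconstruct each well's full-length barcode
informatically.

The difficulty is that a 150-bp read is far shorter than the amplicon, and
after sonication only fragments containing an amplicon terminus still carry
a tag.  Reads therefore fall into three classes:

* **terminus reads** — begin with an exact 5-bp tag followed by the
  corresponding primer; attributable to a well and an end;
* **intermediate reads** — untagged mid-amplicon fragments; attributable to
  no well, pooled plate-wide;
* **artifacts** — primer dimers and short PCR chimeras, recognizable
  because both primers (or tag+primer blocks at both extremities) fit
  inside a single read.

## The assembly model

Per well and end, terminus reads are clustered at 100% identity.  The most
abundant unique sequence is the well's candidate terminus; additional unique
sequences are retained as *secondary* candidates when their abundance is at
least 1/10 of the primary's **and** their identity to the primary is below
98% — the signature of a genuinely distinct template (heteroplasmic
haplotype, Wolbachia, NUMT, contaminating well) rather than PCR or
sequencing noise.  Candidate reads are merged with their mates (exhaustive
overlap search, ≥95% identity over ≥10 bp, conflicts resolved toward the
higher base quality, `N` on ties), and the merged fragments — all anchored
at the tag — are collapsed into a majority-vote consensus whose distal end
is trimmed while coverage is below 5.  Because every fragment starts at
position 1, coverage is non-increasing, so distal-only trimming is
sufficient.  The tag is stripped from the reported anchor, which therefore
starts at the primer's first base; assembled barcodes include the primers
(709 bp), matching how full-length reference barcodes are deposited.

The gap between a well's 5′ and 3′ anchors is filled on a de Bruijn graph
built from the intermediate pool, both strands, default
`k = min(127, read length − 1)`: amplicon pools are extremely deep, and a
large k is the main defence against chimeric joins.  The walk extends base
by base from the terminal k-mer of the 5′ anchor toward the entry k-mer of
the reverse-complemented 3′ anchor, pruning at each bifurcation:

1. successors with abundance below 10% of the mean path abundance since the
   last bifurcation are removed;
2. if more than one survives, successors sharing fewer reads with the k-mer
   at the previous bifurcation than 10% of the survivors' mean common-read
   count are removed;
3. paths exceeding the preset bound (standard barcode plus primers, 709 bp,
   corrected for the anchors already in hand) are abandoned.

All surviving branches are explored; every path reaching the end k-mer is
reported, and the path with the highest mean k-mer abundance becomes the
barcode.  Three interpretation decisions deserve note, because the pruning
rules can be read several ways:

* **A sole successor is never pruned.** Rule 1 arbitrates between competing
  out-edges.  Applied to an unbranched extension it would abort the walk at
  any local coverage dip, and rule 2's phrasing ("if more than 1 out degree
  remains after step 1") confirms the branch-resolution reading.
* **The abundance window resets at bifurcations.** "Mean path abundance
  since the last bifurcation" is the most local reading and tracks coverage
  trends across the amplicon.
* **Rule 2's reference k-mer** is the branching k-mer of the *previous*
  bifurcation (the anchor's terminal k-mer before any).  When all survivors
  share zero reads with it — unavoidable once bifurcations are farther
  apart than a read length — the mean is zero and nothing is pruned.

A degenerate case is handled before walking: if the 3′ anchor's entry k-mer
already lies inside the 5′ anchor (a short amplicon), the anchors are merged
directly over their overlap and the graph is not consulted.

**The intermediate pool is shared plate-wide.**  Per-well specificity comes
only from the anchors.  A consequence worth stating prominently: if two
wells carry haplotypes differing at a *single* site located in the
anchor-uncovered interior of the barcode, no tag-based method can attribute
the two alleles to wells — the walk sees a bifurcation supported by both
wells' reads and both paths reach the end anchor (wrong-allele paths die
only when a variant falls inside the end k-mer or the anchors).  In
practice anchors cover roughly 250 bp from each end, i.e. the outer ~75% of
the barcode, and conspecific haplotypes differing only mid-gap are rare;
the simulator accordingly places near-haplotype variant sites in the
anchor-covered outer 200 bp of the core, which is also the regime in which
the method's per-well guarantees hold.

### Identity definition

All "<98% similarity" style rules use `seq_identity()`: matches over
alignment columns of a full global (Needleman–Wunsch) alignment.  An
end-gap-free alignment was considered and rejected: between two divergent
sequences its optimum can collapse to a short spurious overlap reporting
deceptively high (or undefined) identity, which would corrupt the retention
rule and nontarget classification.  The sequences compared by the pipeline
are co-extensive (equal-length unique reads, or barcode cores), so free end
gaps would add nothing.

## The CCS companion route

Circular-consensus reads provide an independent single-molecule check.
Reads with fewer than 15 passes are discarded (below that depth residual
platform error is substantial); survivors are demultiplexed by their
terminal indices, tolerating one missing base at the outer terminus of
either index — the characteristic CCS deletion mode — with both indices
required to agree on the well.  Primer-stripped inserts outside 658 ± 6 bp
are removed, identical sequences are clustered, and the largest cluster
(ties: higher summed passes, then lexicographic order) yields the well's
barcode.  Cluster size is the primary criterion and passes only break ties;
the alternative reading (pass-dominated ranking) would let a single
high-pass erroneous molecule outvote several concordant ones.

## Validation layer

* `translation_check()` translates the primer-stripped core under the
  invertebrate mitochondrial code (table 5).  The Folmer fragment's reading
  frame starts at its second base (offset 1, configurable per primer set);
  internal stops flag NUMTs, chimeras, or frameshifts.  Codons containing
  `N` are skipped and counted separately.
* `compare_to_reference()` classifies alignment columns against a Sanger
  reference as match / mismatch / ambiguity-resolved (reference IUPAC code
  whose set contains the assembled base) / ambiguity-conflict, with indel
  columns flagged and excluded from the mismatch count.
* `classify_nontarget()` sorts retained secondary assemblies into
  cross-contamination (≥98% identical to another well's primary — the
  pipeline's own same-haplotype threshold), NUMT-or-error (failed
  translation, or ≥90% identity to the well's own primary), and putative
  nontarget (exported for external identity search, which is deliberately
  out of scope).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| adapter alignment / mismatches | 15 bp / 3 | drop rule (i) |
| max `N` per mate | 10 | drop rule (ii) |
| low-quality definition / budget | Phred ≤ 2 / 50 bp | drop rule (iii) |
| tag matching | exact | plate design guarantees ≥2 substitutions |
| primer mismatches | 2 | demultiplexing tolerance |
| secondary retention | ≥1/10 abundance, <98% identity | candidate rule |
| overlap merge | ≥95% identity, ≥10 bp | paired-end merging |
| consensus floor | coverage 5 | distal trimming |
| `k` | min(127, read−1) | de Bruijn graph order |
| pruning fractions | 10% / 10% | walk rules 1–2 |
| length bound | 709 bp | walk rule 3 |
| CCS | ≥15 passes, 658 ± 6 bp, 1-bp terminal index deletion | companion route |

The low-quality floor is Q2 (ASCII 35 under Phred+33), the Illumina
"read segment quality control indicator"; counting is per mate and a pair
is dropped when either mate fails any rule, since downstream merging needs
both mates.

## What the simulator emulates — and what it does not

`simulate_plate()` generates per-well stop-free COI-like cores (one leading
base plus 219 codons drawn from the 62 non-stop codons of table 5),
tag+primer amplicons, per-molecule PCR substitutions, Gaussian fragment
sizes (250 ± 25 bp; half of non-artifact pairs terminal, half uniformly
interior — uniform interior starts approximate sonication and guarantee
junction coverage), 150-bp paired reads with substitution errors, primer
dimer/short chimera artifacts sized to fit inside one read, pairs destined
to fail the N and quality filters, and a CCS library with
negative-binomial pass counts (mean 26), low-rate substitutions, rare 1-bp
indels and occasional terminal index deletions.  Defaults mirror the
library design the assembler targets: 96 wells, 2000 pairs/well desk-scale
depth, ~20% artifact pairs, which lands the clean-read split near 40%
terminus / 40% intermediate / 20% artifact.

Not modeled: indel sequencing errors on the short-read side (substitution
error dominates that platform), adapter run-through on short inserts,
position-dependent quality decay, PCR chimera formation beyond simple short
joins, and template-specific amplification bias.  Passing tests therefore
demonstrate the pipeline's logic and its behavior under realistic depth,
error, artifact and co-amplification regimes — not robustness to indel-rich
or quality-degraded real libraries.

## Numerical choices and degenerate inputs

Abundance ties for the primary candidate break lexicographically;
consensus column ties take the earliest-observed base among the tied ones
and `N` never outvotes a concrete base; merge conflicts at equal quality
emit `N`; multiple surviving walk paths are all reported with the
max-mean-abundance path as primary (ties broken lexicographically for
determinism).  Empty inputs (zero-depth wells, empty FASTQ, all-artifact
pools) return empty-but-well-formed results rather than errors; a missing
anchor or graph k-mer fails the well with a stage-of-failure diagnostic.
There is no randomness anywhere in assembly — identical inputs give
identical outputs.

## Validation scale

The package validates itself on simulated plates: a 48-well plate at 2000
pairs/well and 0.3% sequencing error (with duplicated species, 1–3-nt
near haplotypes and a joint CCS library) for end-to-end recovery, 4-well
plates for heteroplasmy (85:15) and nontarget spike-in (70% identity at
20% and 5% abundance) behavior, and 50 random ≤200-k-mer graphs checked
against an exhaustive DFS enumeration of the pruned walk.  These sizes
were chosen as the smallest at which every phenomenon of interest appears
at realistic depth.

## Known limitations

* Mid-gap singleton variants between wells are unattributable by design
  (shared intermediate pool); see above.
* Exact-tag matching discards terminus reads with an error inside the tag
  (~1.5% at 0.3% error) rather than attempting correction; the plate
  design makes correction safe only up to 1 substitution and the paired
  anchor abundance makes the loss immaterial.
* "PCR error" versus "pseudogene" cannot be distinguished among secondary
  assemblies without external references; both map to one category.
* The CCS route polishes nothing: near-identical CCS reads fall into
  separate 100%-identity clusters by design and the ranking tolerates it,
  but a well represented only by singleton erroneous reads returns an
  erroneous barcode rather than none.
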