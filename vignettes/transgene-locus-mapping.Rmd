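---
title: "Mapping a transgene integration locus from long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a transgene integration locus from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgmap)
```

## The problem

Microinjected transgenes integrate at essentially random genomic
positions, usually as a tandem array of many construct copies, sometimes
with internal inversions, co-integrated fragments of cloning-host
(*E. coli*) DNA, and a deletion of host sequence at the insertion point.
Knowing the integration site matters: it tells you whether an endogenous
gene was disrupted, and it enables allele-specific genotyping that
distinguishes heterozygous from homozygous carriers.

Whole-genome long-read (nanopore-style) sequencing solves this with a
single cheap experiment, even at very low genome coverage, because a
single read can span from unique host sequence across the junction into
the array. `tgmap` implements the complete analysis: read screening and
run statistics, strand-aware alignment of reads against a small target
registry, junction/boundary calling, array-internal inversion and
contaminant detection, a minimal-tiling-path copy bound, depth-based
copy-number estimation, gene-integrity verification, and relative
quantification of copy number from qPCR Ct tables. A synthetic-locus
and read simulator with full ground truth makes every step testable
without any external data.

## The target registry and the aligner

Reads are aligned not against a whole genome but against a small
registry of targets with roles:

* **host** — the reference contig around the candidate integration site;
* **transgene** — one copy of the construct (the array monomer);
* **marker** — the screened subsequence of the unit (an EGFP-like CDS)
  used for copy counting;
* **contaminant** — optionally, a cloning-host genome.

The internal aligner is a conventional seed-and-chain local aligner:
canonical k-mers (default `k = 15`) are matched against an index of the
registry, co-linear seed chains are built per read/target/strand by
dynamic programming with a penalty proportional to diagonal drift (ties
broken toward the leftmost read start), chain ends are extended by an
*ungapped* X-drop scan, and each chain is scored by a banded global
alignment of its substrings, giving matching bases `n_match` and the
alignment span `block_len`. Segments shorter than 200 bp or below 60%
identity are dropped; these defaults suit reads with 10–15% error.
Ungapped end extension is a deliberate choice: it keeps the read/target
correspondence at segment ends exactly diagonal, which the breakpoint
refinement below depends on. External alignments can be substituted at
any point via `read_paf()`; `write_paf()` round-trips the segment table.

## Boundary calling and breakpoint refinement

A read carrying host sequence directly abutting transgene sequence (gap
on the read at most 100 bp) is junction evidence. The host-side endpoint
of the host segment gives a boundary candidate; candidates within 50 bp
are merged by median. Boundaries are reported in the 1-based
retained-base convention: `left_boundary` is the last host base kept
left of the array, `right_boundary` the first base kept right of it, so
`deletion_len = right_boundary - left_boundary - 1`. This is the only
convention under which a boundary pair at 124,115,870 / 124,116,557
yields a 686 bp deletion.

Raw alignment endpoints systematically overshoot a junction: local
alignment extension will happily consume a few coincidentally matching
bases of transgene sequence, and the same coincidences recur in every
read because the sequences are shared. `call_junctions()` therefore
refines each candidate with a two-sided changepoint scan when read
sequences are available. Around the junction estimate, each read
position is scored `z = [matches host diagonal] - [matches transgene]`
(sign-flipped when the host flank lies right of the junction) and the
breakpoint is placed at the prefix-sum argmax over ±40 bp. Matching
*both* references — the signature of junction microhomology — scores
zero, producing a flat plateau over the genuinely ambiguous bases; the
plateau is resolved toward the host side, matching the retained-base
convention. The host side uses the pure segment diagonal while it is
intact and falls back to a gapped alignment path when a read indel
breaks it; the transgene side uses a local alignment against a window
clipped at the estimated attachment point, so no transgene sequence is
available to extend across the junction. On error-free simulated reads
this recovers boundaries exactly; at 10% read error the support-median
lands within a few bp.

## Inversions and contaminating DNA

Adjacent transgene segments of opposite strand on one read are an
inversion event; the flip position is the midpoint of the inter-segment
gap. Evidence is kept per read. Contaminant-role segments are merged per
read; the observed length is a lower bound unless host/transgene
segments flank the foreign DNA on both sides of some read — a read that
terminates inside foreign DNA cannot see its far end.

## Copy number three ways

**Depth.** Each marker match is one array copy sampled at the local
coverage, so `copies ≈ total_matches / fold_coverage`, with Poisson
dispersion `sqrt(total_matches)/coverage`. A "match" is a marker-role
segment covering at least half the marker (robust to reads truncated
mid-marker; two hits on one read are distinct only if their read
intervals overlap by less than half). With the 50% threshold the
expected number of qualifying reads per copy equals the fold-coverage
exactly, making the estimator unbiased. No zygosity correction is
applied: dividing by whole-genome coverage treats the transgene allele
as present once per haploid genome equivalent, which is the convention
of the arithmetic this reproduces; users of diploid samples should
interpret the result accordingly.

**Tiling.** `minimal_tiling_path()` lays marker-bearing reads out by
read-vs-read overlap alignment, anchored on a junction-bearing read, and
greedily picks the furthest-reaching chain. An exact tandem repeat makes
this genuinely ill-posed: two reads can overlap equally well at any
multiple of the unit length. Three safeguards keep the resulting copy
bound *sound* (never above the true copy number): placements must be
proper dovetails (the overlap alignment must run to the facing read
ends, excluding alignments that merely share an internal repeat copy);
among placements the most identical, then most-matching one is used,
which is the true placement whenever a landmark — junction, inversion
flip, foreign-DNA edge, or inter-copy divergence — falls inside the
overlap, and an inward repeat-shifted one otherwise (never outward); and
marker projections are clipped to array bounds pinned by the host flanks
of chimeric path reads, with the copy count capped by the pinned span.
The bound equals the truth when reads are long enough to bridge adjacent
landmarks; at shorter read lengths it is deliberately conservative.

**qPCR.** `delta_delta_ct()` implements comparative Ct: per sample,
`dCt = mean(Ct_marker) - mean(Ct_housekeeping)`; against the calibrator,
`RQ = efficiency^-(dCt_test - dCt_cal)` with efficiency fixed at 2
(100%, configurable). A jackknife over the test sample's marker
replicates yields the dispersion. `copies_per_allele()` converts RQ via
the calibrator's copies per genome and the test animal's transgene
allele count (1 heterozygous, 2 homozygous). Because reference animals'
zygosity is often unstated, the calibrator convention (default: 1
marker copy per diploid genome) is an explicit parameter; both
conventions can be reported side by side.

## Gene integrity

A gene is *encompassed* when one single read's merged host-aligned span
contains its whole CDS span — the evidentiary standard of one molecule
covering the entire coding sequence. *Uncovered* intervals use the union
of all reads; the two criteria are deliberately distinct and both
reported. Host alignments of a read merge across internal gaps up to
1 kb (long-read alignments fragment); a gene overlapping a called
integration interval is flagged disrupted. Remaining gaps, extended by a
configurable flank and merged, are emitted as the intervals a follow-up
PCR assay must span. Only CDS intervals are checked, not UTRs.

## Dot plots

`dot_matches()` reproduces the classic windowed nucleotide dot plot
(window 15, step 1 by default): a forward match where two windows are
equal, a reverse match where one equals the reverse complement of the
other. Exact matching is the default — window hashing gives expected
linear time — with an optional mismatch budget taking the quadratic
all-pairs path. `segment_diagonals()` collapses matches into maximal
constant-orientation diagonal runs; an inversion appears as an
orientation change between adjacent runs.

## The simulator and what passing tests mean

`make_locus()` builds a random host contig and an integrated haplotype:
`copy_number` tandem unit copies (reverse-complemented at the inverted
indices), an optional foreign segment spliced at a bp offset, replacing
`deletion_len` host bases right of `integration_pos`. The truth record
carries every coordinate, and the length identity
`haplotype = host - deletion + copies x unit + contaminant` is enforced.
`simulate_reads()` draws log-normal read lengths (N50
`exp(meanlog + sdlog^2)`; defaults tuned to a 3 kb N50, a desk-scale
stand-in for the tens-of-kb N50 of a real run), injects i.i.d.
substitution/insertion/deletion errors (defaults 5% / 2.5% / 3.5%,
nanopore-like), and can anchor reads across stated intervals — how the
simulated studies guarantee junction-spanning evidence. All randomness
flows from one integer seed through a private RNG stream.

The simulator emulates the *structure* of a real locus, not everything
about real data: bases are uniform random (no genomic repeat families,
so host alignment ambiguity is understated), array copies are exact
duplicates (overstating tiling ambiguity — real arrays diverge), errors
are i.i.d. (no homopolymer bias), and quality scores are constant.
Passing the simulation studies therefore demonstrates correctness of the
inference machinery under the stated error model, not performance on any
particular real genome.

## Reference study conditions and experiment design

The packaged experiments (`experiment_*()`) fix the study conditions:
host 50–200 kb, 3 kb unit with a 720 bp marker, copy numbers
{6, 18, 26}, one internal inversion, a 686 bp deletion, a 6.2 kb foreign
segment on alternate seeds, background coverage 2x plus three anchored
reads per junction (and one across the foreign segment, whose full
length is otherwise rarely spanned at this scale). The noisy arm uses
10% total error (5/2.5/2.5).

Two experiment parameters were set by power analysis rather than taken
from the reference conditions:

* *Depth-estimator mode* (`experiment_copy_number`): the rounded
  estimate carries Poisson noise `sd = sqrt(C/coverage)` copies. For its
  empirical mode over 20 loci to concentrate on the true value, the
  sampling noise must sit below the 0.5-copy rounding resolution; at
  2–3x that is unattainable for C = 26 (peak probability ≈ 0.15), so the
  mode experiment runs at 100x on a compact locus (10 kb host), aligning
  against the marker alone — the only target the estimator uses. Mean
  recovery (within 20%) is verified separately in the 1.5–3x regime.
* *qPCR recovery* (`experiment_qpcr`): 6 replicates with 0.1-cycle
  per-well noise, the precision of a careful SYBR assay; the ddCt noise
  is `2*sd/sqrt(n) ≈ 0.08` cycles, comfortably inside the 15% recovery
  band (log2(1.15) ≈ 0.20 cycles).
* *Fully tiled arrays* (`experiment_tiling`): reads follow a
  concentrated 12 kb-N50 law because an overlap across an exact tandem
  repeat is only provably placeable when a landmark falls inside it;
  landmarks (junctions, the mid-array flip) sit three units apart, so
  reads must bridge that spacing plus the minimum overlap.

Problem sizes throughout (20 loci per arm, 20 seeds per copy setting,
200 qPCR batches) were chosen so the full simulation studies run in a
few minutes on one core.

## Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open; conversion to the
1-based inclusive reporting convention happens only at the boundary of
the package. Ties in seed chaining go to the leftmost read start; the
breakpoint plateau resolves toward the host side; boundary clusters
merge by median. Degenerate inputs fail loudly: empty registries,
out-of-range integration coordinates, zero-length haplotypes, error
rates above 20%, Ct values outside (0, 40), missing assays (named), and
non-ACGTN sequence are all rejected; k-mers containing N are skipped
rather than matched.

## Known limitations

Micro-inversions shorter than the minimum segment length are invisible
by design. The junction caller assumes the two boundary junctions are
the dominant host/transgene adjacencies; a second integration site
appears as separate boundary clusters but is not jointly phased. The
tiling bound degrades (conservatively) for exact arrays sequenced with
reads short relative to landmark spacing. Depth-based copy number
inherits whatever mappability and sampling bias the input reads carry —
no GC or mappability correction is attempted. The qPCR module consumes
Ct values; amplification-curve fitting is out of scope.
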