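---
title: "Closing repeat-associated gaps in draft genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing repeat-associated gaps in draft genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A draft genome assembled from short reads is a set of scaffolds in which
unresolved sequence appears as runs of `N`. Each such run is a *gap*,
delimited by breakpoints `b1` and `b2` on the scaffold, with the run
length `d = b2 − b1` serving as the length estimate. The majority of gaps
in real drafts coincide with repeats, and that is no accident: contig
extension stops where reads cannot be placed uniquely. The consequence
for gap closing is central to this package's design: the reads that
actually originate inside a repeat-associated gap are usually *not*
missing from the alignment — they are present, but mapped to other copies
of the same repeat, either as discordant mates or as multi-mapped records
with mapping quality 0. A gap closer that only looks at unmapped reads
near the gap never sees them.

## Read recruitment

All reads are aligned to the draft with BWA-MEM once per library. For a
library with insert-size mean `m`, insert-size standard deviation `v` and
read length `l`, four classes of reads are recruited per gap:

1. **Anchored unmapped mates (type i).** A mapped read whose leftmost
   position is within `m + 3v + l` of a breakpoint, on the gap-facing
   side, anchors its unmapped mate into the gap. All anchors are used
   regardless of mapping quality; mates of mapq-60 anchors form the
   *high-quality* subset used later in merging, and anchors above mapq 30
   mark their mates as confident.
2. **Repeat-associated reads (type ii).** Every mapq-0 read `B` whose
   mate lies inside `[b1 − m − 3v − l, b2 + m + 3v + l]` while `B` lies
   outside it, plus — because a repeat-associated gap benefits from all
   reads of the repeat neighbourhood when coverage is thin — every mapq-0
   read within `[p − d/2, p + d/2]` of each recruited `B` at position
   `p`. The neighbourhood is applied once per recruited `B` and the union
   de-duplicated.
3. **Breakpoint-clipped reads (type iii).** Reads whose soft-clip
   boundary falls within 20 bp (configurable) of a breakpoint with at
   least 10 clipped bases pointing into the gap. These pin the assembled
   sequence onto the flanks.
4. **Doubly-unmapped pairs (type iv).** Pairs with both mates unmapped
   are pooled globally; after the first assembly pass they are aligned to
   the per-gap contigs (exact-substring fast path, then BWA-MEM) and each
   hit assigns the read *and its mate* to that gap. Gaps already fully
   closed after pass 1 are excluded.

A read satisfying several gaps' windows is used for all of them. Pair
concordance is defined against `[m − 3v, m + 3v]` with forward–reverse
orientation; insert size is measured outer-edge to outer-edge.

Two points where the method description admits alternatives, and what
this package does: the type-i window uses the operational `m + 3v + l`
(not the narrative `m + 3v`); and only anchors oriented *into* the gap
(forward-strand left of `b1`, reverse-strand right of `b2`) recruit
mates. The orientation filter is not part of the original description; it
follows from paired-end geometry, halves false recruitment, and can be
switched off (`require_orientation = FALSE`).

## Two-stage local assembly

**Stage 1 — de Bruijn contigs.** Each gap's recruited reads are
k-merized canonically (a k-mer is represented by the lexicographic
minimum of itself and its reverse complement), counted, and filtered at
`min_kmer_count = 2` (1 when a gap has fewer than 50 reads, where every
observation counts). The graph is simplified by clipping dead-end paths
shorter than `2k` and popping simple bubbles whose branches are ≥ 90%
identical (the better-covered branch survives); maximal unbranched paths
of at least 100 bp become contigs. This is run independently for
k ∈ {31, 41, 51} and the contigs pooled: small k bridges low-coverage
stretches, large k separates repeat variants. The graph is traversed in
sorted k-mer order and contains no randomness, so assembly is
deterministic. The pipeline performs exactly two assembly passes: pass 1
on types i–iii, pass 2 on types i–iv for gaps still open.

**Stage 2 — prefix–suffix merging.** Assembled contigs are typically
fragments of the gap sequence broken at errors or repeat-variant sites,
overlapping each other without having been joined. The merger repeatedly
merges the pair with the *longest qualifying overlap* — suffix of one
against prefix of the other, at least 20 bp, at most 2% mismatches,
searched over all four relative orientations of the pair — until no pair
qualifies. Sequences contained in another (within the same mismatch rate)
are absorbed without extension, which also collapses a contig with its
own reverse complement. Ties are broken toward more constituents, then
the lexicographically smaller merged sequence, keeping the procedure
deterministic. Within an overlap, disputed bases come from the longer
constituent (higher expected coverage). High-quality recruited reads that
cannot be aligned to any contig (neither contained nor sharing an
end-overlap of half the read length) join the merge as mini-contigs; this
is the mechanism that bridges thin-coverage stretches.

The overlap scan is exact but pruned: candidate overlap lengths whose
base-composition L1 distance already exceeds twice the mismatch budget
are skipped (composition distance / 2 is a lower bound on mismatches, so
no qualifying overlap can be lost). Pairwise overlaps are cached across
greedy iterations.

## Finishing

The gap's flanks (300 bp by default; when two gaps lie closer than
300 bp the whole inter-gap segment is the shared flank) are aligned
semi-globally to each merged candidate in both orientations. A qualifying
hit needs ≥ 95% identity over ≥ 30 bp, the flank's gap-proximal end
within 15 bp of an interior candidate position, and the distal end either
fully aligned or running off the candidate. If the left flank hits one
side and the right flank the other, in the same orientation, the
candidate has FULL geometry and the inter-flank sequence is the gap
sequence; among several FULL candidates the longest is chosen.
Otherwise "covers the gap the most" is operationalised as total extension
length capped at `d`; one candidate per side may contribute when no
single candidate covers both, and extensions under 10 bp are treated as
noise. Patching replaces the N-run for FULL gaps and shrinks it to
`max(d − covered, 1)` for EXTENDED ones; sequence outside gap intervals
is never touched.

## Assessment

*Reference-based.* Flanks are aligned to the reference (BWA-MEM); a gap's
truth is usable only if both flanks map with mapq 60, at most 15 bp
soft-clip, in the same orientation, on one reference sequence, left
before right. The spanned interval is the "true" gap sequence, and a
closure is CORRECT if it aligns to it with at most 15 bp clip on each of
its own ends and ≥ 95% identity (identity threshold is this package's
choice; the printed rule only fixes the 15 bp slack). Extended closures
are scored on each extension.

*Reference-free.* Each closure is rebuilt as `flank + closure + flank`
(150 bp flanks), all reads are re-aligned, and validation requires at
least 10 reads spanning each joint with a 20 bp unclipped margin and
≥ 95% of non-N construct bases at ≥ 10×. "Fully mapped at the joint" is
operationalised as the aligned span covering joint ± 20 bp, which places
any soft-clip outside that window.

## The synthetic world

The fixture generator states one fixed world and the test-suite numbers
are read against it:

* **Genome**: 100 kb i.i.d. background, 10 dispersed repeat families of
  6 copies × 600 bp at 0.5% divergence from the family consensus (~36%
  repeat content). The divergence value is the load-bearing choice: at
  0.5%, 100 bp reads frequently match several intact copies equally well
  and receive mapping quality 0, which is the defining property of the
  repeat class this method targets (young SINE/LINE subfamilies). An
  early draft of this package used 2% divergence and few copies; BWA then
  resolved almost every read uniquely, no mapq-0 reads existed, and
  repeat gaps were unclosable by *any* recruitment rule — that world
  contradicts the phenomenon the generator exists to emulate, so it was
  corrected before the defaults were frozen.
* **Gaps**: 20 non-overlapping intervals of 200–800 bp, at least 600 bp
  apart, half planted inside repeat copies with at most one gapped copy
  per family (so each family keeps intact copies to attract the gap
  copy's reads), half in repeat-free background.
* **Reads**: PE 300 ± 30 at 40× and MP 3000 ± 300 at 10×, 100 bp reads,
  0.5% uniform substitution error, no indels. Fragment lengths are
  Normal(m, v) truncated below at `2l`. Both libraries are generated in
  forward–reverse orientation — i.e. the MP library is modelled as
  already orientation-normalised, so the classifier's per-library
  normalisation step is a no-op on these fixtures.

What a green test does establish: the recruitment windows, the two-stage
assembly and the finishing logic reconstruct planted gap sequences,
including repeat-internal ones, from realistic read geometry, and the
type-ii (repeat-read) channel is what closes the repeat gaps. What it
does not establish: behaviour under indel errors, chimeric fragments,
diverged haplotypes, scaffolder-misestimated gap lengths (the N-run
length is trusted as `d`), or genome-scale repeat families with
thousands of copies.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; SAM positions are
  converted at I/O boundaries. Secondary and supplementary records are
  dropped; duplicate (name, mate) records collapse to the first.
* Gaps flagged `NO_FLANK` (empty flank at a scaffold edge or abutting
  another gap) are excluded from closure and reported as such.
* Empty read sets, failed assemblies and empty candidate lists all
  degrade to UNFILLED, never to an error; a per-gap failure is isolated
  as status ERROR without aborting the run.
* Ambiguity codes other than N are kept as literal characters; the draft
  is uppercased at ingest.
* `min_gap_len` defaults to 1 for closing; evaluation-style reports
  conventionally use 100, mirroring how very small gaps are excluded
  from benchmarking.
* recruit_unmapped accepts hits at ≥ 90% identity over ≥ 80% of the read
  length; the exact-substring fast path short-circuits BWA for the
  error-free majority.

## Known limitations

* The merger's greedy longest-overlap-first rule is a stated design
  choice standing in for an unpublished procedure; on adversarial
  overlap structures greedy merging can differ from the optimum, though
  the test suite checks agreement with exhaustive search on random
  fragment sets of up to six pieces.
* Extensions from different candidates are combined one-per-side only;
  candidates are never chained across the unassembled middle.
* Validation requires both joints to be spanned, so single-sided
  EXTENDED closures cannot validate by construction.
* Per-gap processing is sequential in this implementation; gaps are
  independent, so external parallelisation is safe.
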