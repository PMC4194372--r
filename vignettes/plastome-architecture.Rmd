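---
title: "Comparative chloroplast genome architecture with plastarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative chloroplast genome architecture with plastarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastarch)
```

## The problem

Chloroplast genomes of green algae are small circular molecules
(roughly 60–200 kb) carrying a largely shared repertoire of ~85–130
conserved genes. Lineages differ strikingly in *architecture*: overall
size and A+T content, how tightly genes are packed, whether a large
inverted repeat (IR) containing the rRNA operon divides the circle into
the classic quadripartite layout (IRa/IRb plus a large and a small
single-copy region), how thoroughly gene order has been scrambled by
inversions, and which genes have been lost. plastarch implements the
comparative toolkit for this kind of study: per-genome architecture
metrics, IR/quadripartite detection, signed gene-order comparison
(adjacency pairs, ancestral-pair selection, colinear synteny blocks),
presence/absence repertoire comparison with Dollo loss mapping on a
fixed species tree, and a seeded simulator that generates
chloroplast-like genomes evolving along a tree so that every stage can
be validated against planted truth.

## Data model and coordinates

A genome is a `ChloroGenome`: an id, a length, an optional sequence and
a feature table with one row per gene *occurrence* (IR-duplicated genes
appear twice). Coordinates are 0-based half-open on the circle;
a feature wrapping the origin is stored as two spans. GenBank 1-based
closed locations are converted on read; the unambiguous interval
arithmetic on circles is worth the one-off conversion.

Gene names are normalized against a shipped conserved-gene catalog
(`conservedCatalog()`): tRNAs as `trn<AA>-<anticodon>` (the anticodon
suffix keeps, say, `trnL-uaa` and `trnL-uag` distinct, as repertoire
comparisons require), rRNAs as `rrs`/`rrl`/`rrf`, and a synonym table
for legacy spellings (`ycf9` → `psbZ`, `rrn16` → `rrs`, ...).
Unknown names pass through lowercased and are flagged non-conserved.
The catalog is the package's own curation: it unites the core gene set
shared by all compared prasinophyte genomes with the genes reported in
only some lineages (the six Prasinococcales-specific genes `ndhJ`,
`rbcR`, `rpl21`, `rps15`, `rps16`, `ycf66`; `ftsI`/`ftsW`; the full
`ndh` family; the `chl` family; rarer tRNAs such as `trnV-gac`) and the
standard plastid families. Records annotated with gene symbols outside
this set still parse; the unknown genes simply do not enter conserved
counts.

Two conventions matter for the headline numbers and are therefore fixed
and documented here rather than left implicit:

* **Gene counts** count unique conserved base names once: IR duplicates,
  duplicated tRNAs and the parts of fragmented genes (`ycf3a`/`ycf3b`,
  stored as separate order elements sharing a base name) collapse.
  Occurrences are reported separately.
* **Free-standing ORFs** (`orfNNN`) are parsed but never conserved; they
  are excluded from gene counts, pair/block analysis and the genic cover.
  Large unassigned ORFs are how IR-expanded genomes reach intergenic
  fractions above 40 percent, so treating them as genic would make the
  intergenic metric incomparable across genomes.

## Architecture metrics

`atContent()` is `100·(A+T)/(A+C+G+T)` with `N` excluded from the
denominator. `intergenicFraction()` is the percentage of the circle not
covered by conserved-gene features; merged features cover exons *and*
introns, so introns count as genic, and overlapping features count
once. Whether published intergenic percentages treat introns as genic
and ORFs as intergenic is usually inferable only indirectly; this
package fixes the convention above and exposes it, rather than trying
to reverse-engineer per-study choices. All percentages are rounded to
one decimal, half away from zero, the convention of printed summary
tables.

### Inverted-repeat detection

`detectInvertedRepeat()` finds the maximal-length pair of *disjoint
exact* reverse-complement segments of the circular sequence, by
seed-and-extend on k-mer anchors: every circular k-mer of the sequence
is matched against the k-mers of its reverse complement, seed hits are
merged along diagonals into maximal matches, overlapping arc pairs are
trimmed to their largest disjoint prefix/suffix pair, and ties are
broken by the smallest IRa start. Exactness (mismatch tolerance 0) is
deliberate: a single integer "IR length" per genome is only well
defined for an exact repeat, and chloroplast IR copies are homogenized
by gene conversion in practice. The two gaps between the copies become
the single-copy regions, LSC the longer. When the caller supplies the
genome's rRNA features (`requireRrn`), only candidates whose two copies
each contain the full rRNA gene set qualify — this selects the
biological IR over incidental long repeats — and the operon orientation
(`toward_ssc` vs `toward_lsc`, probing the first base past the IR copy
in the direction of rrs transcription) is reported, since transcription
of the operon toward the small single-copy region is the ancestral
state. A quadratic diagonal-scan oracle verifies the detector in the
test suite.

`repeatFraction()` reproduces the classic repeat-content protocol: find
all bases covered by an exact repeated segment of ≥ 30 bp in forward or
reverse-complement (palindromic) orientation and report the masked
percentage. The implementation masks every position covered by a
repeated 30-mer, which is exactly equivalent to masking all maximal
repeats ≥ 30 bp (every such repeat is tiled by repeated 30-mers, and
every repeated 30-mer is such a repeat). One full IR copy is removed
before scanning when a quadripartite structure is supplied, so the IR
itself never counts as repeat content. Where protocols differ on how
overlapping maximal repeats are reported, the masking *union* is used —
it is insensitive to that ambiguity.

## Signed gene-order comparison

The `SignedGeneOrder` of a genome lists its conserved gene occurrences
by ascending feature midpoint on the circle (midpoints are wrap-aware),
signed by coding strand. Adjacency pairs are the circular neighbours
`((a,sa),(b,sb))`, canonicalized so that reading the circle backwards
with flipped signs yields the same key — the orientation of the whole
molecule is arbitrary.

`selectAncestralPairs()` classifies pairs across a set of ingroup
genomes (each assigned to a lineage) and outgroups by two rules:
(A) present in at least two ingroup genomes from distinct lineages and
in an outgroup — conservation across deep splits plus outgroup support;
(B) when a member gene has itself been lost from two or more ingroup
lineages or from both outgroups, presence in a single ingroup lineage
suffices, because pair absence caused by gene loss says nothing about
rearrangement. Absence cells are classified accordingly
(`absent_gene_loss` vs `absent_rearranged`).

`colinearBlocks()` reduces both circular orders to the genes occurring
exactly once in each (IR second copies and duplicated tRNAs cannot be
aligned unambiguously and are excluded; collapsing one IR copy before
extraction, the default in `runStudy()`, re-admits IR-resident genes as
single-copy) and reports the maximal runs of genes consecutive in both
reduced circles, in identical or globally reversed-and-sign-flipped
orientation. Blocks may wrap the origin. `minLen = 2` by default — a
single shared gene is not evidence of synteny, the gene *pair* is the
baseline unit. A `maxGap` option admits up to that many displaced genes
between consecutive members, since unpublished block definitions
sometimes tolerate small insertions; 0 (strict colinearity) is the
default and the setting used everywhere in the tests. The decomposition
is verified against a brute-force enumeration of all common circular
substrings, exhaustively for up to six genes and on 1000 seeded random
permutations of 7–12.

Percentages in `syntenyStats()` use unique conserved gene names as
denominators, matching the gene-count convention above; they are
rounded to integers as such statistics are conventionally printed.

## Repertoire evolution under Dollo parsimony

`buildPresenceMatrix()` reduces genomes to presence/pseudogene/absence
of conserved base names. Pseudogenes count as absent for parsimony —
a pseudogene is a loss in progress as far as functional gene content is
concerned — but stay distinct in reports; `pseudoAsPresent = TRUE`
flips the convention.

`dolloMap()` reconstructs a binary character under Dollo parsimony:
a single gain, losses only. The gain sits either at the root
(appropriate for characters known to be ancestral, e.g. present in
outgroups — `dolloLossTable()` chooses root exactly when an outgroup
carries the character) or at the last common ancestor of the present
leaves. Given the gain, the minimum loss set is the set of maximal
all-absent subtrees under the gain node; the implementation computes it
in one postorder/preorder pass, and the test suite checks it against a
brute-force minimal-subset oracle, exhaustively over all 945 rooted
six-leaf binary trees and all presence patterns. On polytomies each
lost child subtree counts as its own loss: events live on edges, not
nodes. `irLossEvents()` is the same machinery applied to IR presence
with the gain fixed at the root, the IR being ancestral for green
plants.

The shipped species tree (`prasinophyteTree()`) encodes the backbone
topology of the twelve compared prasinophyte chloroplast genomes plus
the two streptophyte outgroups, with the Prasinococcales as the
earliest chlorophyte branch; `reportedPresencePatterns()` carries the
published presence patterns of the six Prasinococcales-specific genes
and of the IR. Mapping those patterns on that tree yields two losses
for `ndhJ` (one after the Prasinococcales diverged, one on the MBIC
10622 branch), a single loss for each of the other five genes, and four
independent IR losses — computed by the parsimony engine at run time,
not transcribed.

## The simulator

`simulateAncestor()` builds a chloroplast-like circular genome:
`nGenes` conserved genes drawn from the catalog, random strands,
category-typical lengths (tRNAs 72–90 bp, rRNAs at their canonical
sizes, protein genes scaled so the intergenic target is met), spacers
split by a stars-and-bars draw, an i.i.d. sequence at the configured
A+T percentage, and optionally an exact IR of the requested length
containing the rRNA operon in the ancestral layout (LSC–IRa–SSC–IRb,
operon transcribed toward the SSC). The bases flanking the two IR
copies are forced to mismatch so the planted IR is *exactly* the
maximal reverse-complement pair — otherwise chance one-base extensions
would blur planted-truth tests. Defaults (110 genes, 100 kb, A+T 62%,
intergenic 20%) sit mid-range of the architectures observed across
sequenced prasinophyte chloroplast genomes: sizes of roughly 64–200 kb,
86–128 genes, A+T 58–68%, intergenic fractions of 9–46%.

`evolveClade()` walks a rooted tree applying, per branch: `nLosses`
gene losses (uniform over current single-copy conserved genes; rRNA
genes and IR residents are exempt so the IR and the operon stay
coherent), IR loss with probability `pIrLoss` (deletion of one copy,
the copy-correction view — the genes survive once, the repeat is gone),
and `nInversions` segment reversals with sign flips whose breakpoints
never split a feature or an IR copy, mirroring the resolution at which
real rearrangements are analysed. Every event is logged with exact
coordinates; `replayEvents()` re-applies the log and must reproduce
each leaf byte for byte, which is the simulator's own consistency
invariant and the anchor for planted-truth tests (presence-matrix
recovery, ≤ 2k breakpoints after k inversions).

What the simulator does *not* emulate: nucleotide substitution (the
pipeline never aligns or translates sequence, only exact repeats
matter), intron gain/loss, IR boundary expansion/contraction, gene
duplication beyond the IR, and horizontal transfer. Passing tests
therefore validate the combinatorial machinery — order comparison,
repertoire mapping, IR detection on exact repeats — not robustness to
sequence-level noise or near-identical repeats.

## Numerical choices and degenerate inputs

* Rounding: one decimal, half away from zero, for percent metrics;
  integers for synteny percentages.
* IR detection k-mer seed: `min(minLen, 24)`; every position of a true
  match contributes a seed, so merging contiguous seeds recovers the
  maximal match exactly, with no heuristic extension step.
* Tie-breaks: equal-length IR candidates by smallest IRa start; equal
  synteny blocks by position in the first genome. Deterministic output
  everywhere; `runStudy()` reports are reproducible byte for byte.
* Degenerate inputs: empty sequence errors (`"sequence absent"`);
  records with no gene features parse to an empty genome; an
  all-absent character under the LCA gain policy errors
  (`"character never present"`); orders without conserved features
  error; a reference partition sharing no genes yields `NA` conformity.

## Problem sizes used in validation

The suite runs entirely from generated data: exhaustive gene-order
comparison to n = 6 plus 1000 random cases at n = 7–12; all 945 rooted
six-leaf trees with all presence patterns for the Dollo engine; 120
planted IR/repeat recoveries on 10–40 kb sequences; simulated clades of
2–12 leaves with genomes of 8–50 kb. These sizes were chosen to make
the exhaustive checks exhaustive and the planted checks numerous while
keeping the whole suite comfortably fast on one core; the operations
themselves are routinely used on full-size (60–200 kb) genomes, as in
the worked example in the README.

## Known limitations

* IR detection is exact-match only; genomes whose IR copies have
  diverged by even one substitution will report the longest exact core
  instead. Near-identical IR handling is out of scope.
* Block detection is pairwise; no multi-genome (≥ 3-way) blocks.
* No rearrangement distances (inversion distance, DCJ) — the block and
  breakpoint statistics are descriptive.
* Dollo mapping does not search for multiple gains; a character whose
  distribution demands regain is still explained by losses under the
  single-gain model.
* GenBank parsing covers the feature syntax found in organelle records
  (join/complement, origin wrap, pseudo flags); it is not a general
  GenBank implementation.
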