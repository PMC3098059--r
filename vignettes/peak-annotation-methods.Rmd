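---
title: "Methods: peak annotation, overlap significance and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak annotation, overlap significance and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakannot)
```

## Scope and data model

`peakannot` annotates enriched genomic regions ("peaks") against
user-supplied feature sets and quantifies agreement between peak lists.
Every region is a row in a tibble with columns `name`, `chrom`, `start`,
`end`, `strand`, `score`. Coordinates are **1-based and closed** on both
ends, the GFF convention; BED input (0-based, half-open) is converted at
the boundary (`start = chromStart + 1`, `end = chromEnd`) and converted
back on output, so round trips are byte-stable. This choice keeps the
internal arithmetic identical to the coordinates a biologist reads in a
genome browser or a GFF file. Strand tokens `+`, `-`, `.`, `*`, `1`,
`-1` are accepted on input and canonicalized to `+`, `-`, `*`;
chromosome names are compared by exact string equality — silent
`chr1`/`1` aliasing hides input errors, so none is applied.

Region names key every join in the package; duplicates within one set
are rejected rather than repaired, and missing names are filled
deterministically (`peak_<k>` in file order).

## Nearest-TSS annotation

For a stranded feature the transcription start site is the 5' boundary:
`start` on `+`, `end` on `-`. The signed distance from a peak to a
feature is measured **from the peak start** to the TSS in the feature's
orientation:

* `+` strand: *d* = peak_start − TSS
* `-` strand: *d* = TSS − peak_start

so negative *d* always means the peak starts on the gene's upstream
side. The peak start (not the midpoint) is the anchor; a midpoint option
was considered and deliberately left out of the core definition so that
the reported distances stay directly comparable with the conventional
output columns users know. Peaks themselves are treated as unstranded
throughout: peak strand is carried as annotation but plays no role in
any comparison.

`annotate_peaks()` supports three outputs. `nearest` selects, per peak,
the feature minimizing |*d*|. `overlapping` selects features within
`maxgap` bases; with `multiple = FALSE` only the closest is kept.
`both` is the union of the nearest rows and those overlapping rows
whose feature is *not* the peak's nearest feature, so a feature never
appears twice for the same peak. Ties — possible when two TSSs are
equidistant — break by smallest |*d*|, then upstream (negative *d*)
before downstream, then lexicographic feature name. The rule is
arbitrary but total, which makes every run reproducible; nothing in the
underlying definition dictates a particular tie order.

The nearest search runs per chromosome by binary search
(`findInterval`) over the sorted distinct TSS positions: the minimizing
TSS is always one of the two values flanking the peak start, and all
features at those two positions enter the tie-break. This is a
different algorithm from the O(n·m) scan used as the oracle in the test
suite, which is the point: the two routes must agree.

Relative position is classified strand-aware into six mutually
exclusive, exhaustive classes: `upstream` and `downstream` (no
intersection, on the 5'/3' side respectively), `includeFeature` (peak
covers the feature), `overlapStart`/`overlapEnd` (peak covers exactly
the 5'/3' boundary), `inside` (intersects, covers neither boundary).
Exhaustiveness and exclusivity are verified by enumeration over all
interval pairs on a small coordinate range on both strands.

Distance histograms use half-open bins `[e_i, e_{i+1})`; values outside
the break range are reported in separate underflow/overflow rows so
counts always sum to the number of rows binned. Relative-position
counts apply the precedence rule that an `Overlapping` row beats a
`NearestStart` row for the same peak, matching the conventional pie
chart of peak positions.

## Overlap, merged peaks and significance

Two closed intervals have gap = number of bases strictly between them
(0 when they intersect **or abut**, infinite across chromosomes), and
"overlap under `maxgap = g`" means gap ≤ g. Abutting-counts-at-zero is
a documented convention choice: the alternative (requiring a shared
base at `maxgap = 0`) creates an off-by-one discontinuity between
`maxgap = 0` and `maxgap = 1`.

Merged peaks are the connected components of the overlap graph over all
regions of all sets; overlap is transitive through chains, so two
regions that never touch can share a component. On one chromosome these
components are exactly the clusters produced by interval reduction with
`min.gapwidth = maxgap + 1`, which is how they are computed (via
IRanges); the test suite checks the result against a union-find over
the full pairwise gap matrix.

For the Venn report, a component counts **once** per membership
pattern, regardless of how many regions from each set it contains: the
cells of a Venn diagram partition merged regions, and component
counting is the only choice under which the cells are disjoint and
exhaustive. Counting first-set peaks instead is available as
`count_mode = "set1"` for users who want per-peak bookkeeping. Pairwise
significance recomputes n₁, n₂ and k **on the two sets alone**, so a
3-set report and its 2-set projections always agree.

The significance model is the exact hypergeometric upper tail
P(X ≥ k), X ~ Hypergeometric(totalTest, n₁, n₂), computed with
`phyper` (log-space, exact). `totalTest` — the number of potential peak
locations — is a required user input, never estimated from the data:
it encodes a genome-biological judgement (how many places could have
been called a peak) that the peak lists themselves cannot supply. The
p-value is non-increasing in k and non-increasing in `totalTest`: a
larger universe makes any fixed overlap rarer.

## Sequence extraction

`get_peak_sequences()` fetches the forward-strand genome substring over
`[start − upstream, end + downstream]`, silently clipped to
`[1, chromosome length]` with the clipped peak names reported as a
message. Clipping (rather than erroring) was chosen because flanks
commonly run off chromosome ends in small genomes and the truncated
sequence is still the correct motif-discovery input; the fetched
coordinates are always returned so nothing is hidden. Output FASTA
wraps at a configurable width (default 50) and re-parses with
`load_genome()` byte-for-byte. No reverse complementing is applied in
this version — peaks are unstranded — and repeat masking is out of
scope.

## GO enrichment

The universe per aspect (BP/MF/CC) is every gene with at least one
annotation in that aspect — a genome-wide background. The sample is the
deduplicated set of feature genes from an annotation run: a gene hit by
several peaks counts once, since the test's unit is the gene, not the
peak. Sample genes absent from an aspect's universe are dropped from
*n* (and reported), because a gene the annotation source does not know
cannot contribute to either tail.

Terms annotating fewer than `min_go_term` universe genes (default 10,
a conventional floor below which the tail is dominated by single-gene
noise) are removed **before** adjustment — the filter changes the
number of tests m, and applying it afterwards would make the reported
FDRs depend on tests that were never meant to be run.
Benjamini–Hochberg runs within each aspect separately, matching the
per-category reporting convention; `max_p` (default 0.01) applies to
the adjusted value when adjustment is requested, else to the raw
p-value. Ancestor propagation over user-supplied is-a edges is opt-in:
default behaviour uses direct annotations only, so results are a pure
function of the two input tables rather than of a bundled ontology
snapshot.

## The synthetic-data generator

The simulator emulates exactly the structure the methods consume:
uniform-composition genomes; non-overlapping single-interval gene
models with configurable length range, strand probability and minimum
spacing; peak sets in three placement modes; and random gene→term maps.
One global seed drives everything, with per-generator substreams so
adding a generator never shifts another's output; identical inputs give
byte-identical files.

* `uniform` places peaks on a slot grid of stride `max(width) + 1` (one
  spacer base, so peaks in distinct slots never overlap nor abut).
  Sampling slots without replacement makes the overlap count between
  two independent sets *exactly* hypergeometric with
  `totalTest = n_slots()`, which is what the null-calibration tests
  exploit.
* `planted_offset(d)` starts each peak exactly *d* bases 5' of a random
  gene's TSS, so nearest annotation must recover
  `distancetoFeature = −d` for every peak; with gene spacing above 2·d
  the planted gene is provably the nearest.
* `planted_overlap(f, S)` makes a fixed fraction f of peaks intersect
  the partner set and places the rest disjointly by rejection sampling.

What the simulator does **not** emulate: realistic base composition or
repeats, multi-exon gene structure, peak-width and spacing
distributions of real peak callers, or correlated replicate noise.
Passing tests therefore demonstrate algebraic and distributional
correctness of the methods — coordinate conversions, tie-breaks, exact
tails, calibration under the stated null — not robustness to the messiness
of real ChIP data.

## Problem sizes and numerical choices

The test suite checks the closed-interval gap relation and the
six-class classification by exhaustive enumeration on small coordinate
ranges; annotation, merging and sequence extraction against independent
brute-force implementations on several hundred random instances
(≤ 30 regions per set); hypergeometric tails against closed-form
`choose()` sums for every parameterization with N ≤ 25; BH against the
hand-computed step-up rule; null calibration on 2000 simulated set
pairs of 30 peaks in a 300-slot universe (the acceptance script uses
1000); and planted-offset recovery at d ∈ {0, 1, 50, 500} with gene
spacing 1200. These sizes give exhaustive or tightly concentrated
checks while keeping a full run in the order of minutes on one core.

Degenerate inputs are handled explicitly: empty region sets read and
write as header-only files; empty feature sets are an error for
annotation (there is nothing to annotate against); peaks with no
qualifying feature yield a row with `NA` feature fields rather than
disappearing; `P(X ≥ 0) = 1` exactly; a single tested term adjusts to
its own raw p-value.

## Known limitations

Venn reports support 2–3 sets (the display convention the cell-pattern
table mirrors); features are single intervals, so exon-level or UTR
annotation must be supplied as separate feature sets; `totalTest` is
the user's responsibility; the overlap null assumes exchangeable peak
locations and does not model GC or mappability bias; and no
permutation/genome-shuffling alternative to the hypergeometric test is
provided.
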