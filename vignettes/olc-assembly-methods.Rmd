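---
title: "Overlap-layout-consensus assembly: model, parameters and design notes"
author: "olcassembler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-layout-consensus assembly: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`olcassembler` reconstructs a genome sequence de novo from paired-end
short-read libraries (reads around 100 bp, inserts of a few hundred bp)
using the overlap-layout-consensus (OLC) strategy. Whole reads are kept as
graph vertices: every read and its reverse complement form a *double
vertex*, and a directed arc u → v records a verified inexact suffix–prefix
overlap in which v extends u rightward by `shift` bases. Keeping whole
reads preserves read continuity through short repeats — the property that
distinguishes OLC from k-mer decomposition (de Bruijn) assembly — at the
price of computing pairwise alignments.

The pipeline has three stages: overlap-graph construction, state-voting
traversal into contigs, and paired-end contig correction, followed by a
contig-trimming pass that prepares the output for external scaffolders.

## Overlap graph construction

All-versus-all alignment of n reads is quadratic and infeasible, so
candidate pairs are preselected by four heuristics and only candidates are
aligned:

1. **k-mer characteristics.** Each oriented read is fingerprinted by its
   multiset of k-mers (k = 16 by default; at most l − k + 1 entries for a
   read of length l), duplicates collapsed with a counter, entries ordered
   by decreasing count then lexicographically. Sorting all fingerprints
   like dictionary words places reads that overlap on at least about half
   their length close together; every pair within a neighborhood `window`
   (default 8) of the sorted list becomes *promising*.
2. **Partial characteristics** repeat the procedure on the begin/center/end
   thirds of the read, catching pairs that overlap only near an end. Equal
   thirds are used; the region boundaries are the simplest reading of
   "beginning, center, end".
3. **Smallest lexicographical descriptors.** For each half of a read, the
   lexicographically smallest substring of length d (default 14, within
   the customary 12–20 range); reads sharing a descriptor value are
   promising.
4. **Propagation.** If A overlaps B, the mates A′ and B′ may overlap too
   (on the flipped strand), and if A overlaps both B and C, then (B, C) is
   promising. Successor propagation is iterated (default 3 rounds or until
   closure) because each round roughly doubles the overlap distance covered
   along a chain.

Every promising pair is verified by a semi-global (free end gaps)
Needleman–Wunsch alignment, implemented in C++ and shared by all stages.
Scoring is match +1, mismatch −1, gap −2; *errors* are mismatches plus gap
columns inside the overlapped span. A pair becomes an arc when
`overlap_length >= min_overlap` (40 bp) and
`errors <= ceiling(max_error_rate * overlap_length)` (3 %). Accepted arcs
are mirrored onto the reverse complements arithmetically
(`shift' = len_b − overlap`), without re-alignment. Containment overlaps
(the target does not extend past the source) are stored but flagged and
skipped during traversal, which needs strict extension.

Tie-breaking in the aligner is fully specified so results are reproducible:
among equally scoring end cells the last column is scanned top-to-bottom,
then the last row left-to-right, and the first maximum wins; traceback
prefers diagonal over vertical over horizontal moves. Identical sequences
from distinct read pairs stay distinct vertices.

## Traversal: the voting state

Contigs grow from random start points (a permutation drawn from the run
seed), rightward from the seed vertex and rightward from its mirror vertex
— the double-vertex symmetry makes a separate leftward code path
unnecessary. Instead of trusting a single vertex, the walk keeps a *state*:
the most recently added vertices whose sequence span still overlaps the
newest vertex by at least `min_state_overlap` (default = `min_overlap`).
Every state member votes for its successors; a candidate's score is the sum
of the overlap lengths of its supporting arcs, so candidates backed by many
recent vertices beat any single over-attractive arc. The best candidate is
appended (ties to the smallest vertex id), the state is pruned from the old
end, and the walk repeats until no candidate remains or a repeat fork is
confirmed.

Each read is consumed by at most one contig (both strands count as one
use); vertices released by a fork cut return to the pool so the opposite
branch can still seed its own contig. Contigs assembled from leftover
reads of an already-covered region — exact either-strand substrings of a
longer contig — are dropped at the end, keeping the duplication ratio near
one.

The consensus is a per-column majority vote over the layout implied by the
arc shifts, ties broken alphabetically; a zero-coverage column would mean
inconsistent shifts and raises an error instead of emitting a gap.

## Fork detection and classification

Forks in a DNA overlap graph come from sequencing errors, SNPs (in diploid
or mixed samples) and genomic repeats. Only the last kind may stop the
walk: following either branch of a repeat fork beyond the repeat produces a
chimera.

A **forward fork** is suspected when a whole group of candidates loses its
support at once — the state has moved entirely onto one branch and the
other branch's candidate front is dropped. The drop count must reach a
dynamic threshold `max(base_drop_threshold, round(coverage_scale × local /
median))` (defaults 2 and 3), where the local coverage of a region and the
data-set-wide distribution are estimated from vertex degrees (a vertex's
overlap partners are, on locally uniform data, proportional to the read
depth of its neighborhood). The **countercheck** then requires that no
dropped vertex has an arc into the state: such an arc means the graph is
merely missing transitive arcs and the "fork" is a jump over skipped
vertices. By default the countercheck targets the newest state member only.
The alternative (`countercheck_scope = "any"`) is stricter about jumps but
has a blind spot at repeat exits: branch-specific reads with only a couple
of flank bases keep sub-budget arcs into older, still-ambiguous state
members, so the fork is vetoed exactly where it matters most; the newest
member is already branch-specific when the drop happens, which is why
"newest" is the default.

A **backward fork** (two paths merging) is the mirror situation: candidates
appear that are supported only by the newest vertex and carry incoming arcs
from vertices outside the current path — the other branch's tail. It is
confirmed symmetrically (outside-supported count reaching the threshold, no
reverse arcs from the added group into the state).

Confirmed forks are classified before any cut:

* **error** — the alternative branch dies out within `dead_end_limit`
  (5) vertices: a tip of erroneous reads; ignored.
* **snp** — the branches rejoin within `bubble_window` (10) vertices, or
  their candidate fronts are similar (Jaccard ≥ `candidate_similarity_tau`,
  0.5): a bubble; the supported branch is followed and the other branch's
  vertices remain available. Reconvergence is tested by expanding *both*
  branch fronts breadth-first in lockstep, our own front first, and
  comparing reads (either strand): a branch running a few vertices ahead —
  the typical signature of arcs missed during graph construction on
  erroneous data — is then caught at the same depth instead of chasing the
  other front forever. A backward fork with an empty remaining candidate
  front has nothing to corroborate an alternative context against and is
  treated as a bubble.
* **repeat** — neither: the walk stops and the path is cut directly before
  the state (forward) or at the merge vertex (backward).

The cut leaves at most a state-span's worth (< 65 bp at defaults: the state
spans at most `read_length − min_state_overlap` bases) of
cross-branch residue on the contig end, which is below the evaluation
module's minimum alignment block and therefore never scored as a
relocation.

## Paired-end contig correction

Traversal sees only local overlap context. The correction stage maps reads
back to contigs (layout reads at their layout offsets, the rest by exact
31-bp seed and verified full-length match on either strand; ambiguous reads
stay unmapped) and scans the pair geometry for two anomaly types:

1. **Continuity breaks** — maximal intervals spanned by zero properly
   oriented, in-range pairs, at least `min_break_width` (default: mean
   insert) wide. End margins of `insert_max` are exempt, since no pair can
   span a contig end.
2. **Mismapped density** — sliding windows (width = read length) counting
   reads whose mate sits on another contig or more than `insert_max` away;
   windows at or above `mismap_count_threshold` (default `max(3, pair
   coverage / 4)`) merge into anomalies.

A greedy hyper-heuristic arbitrates: each iteration both detectors propose
their most severe anomaly; severities are normalised per kind (break width
over `min_break_width`; peak count over the threshold) and weighted by the
detector's learned utility; the winner's cut is applied (break midpoint, or
density peak center), and the utility is rewarded (×1.2, cap 4) when the
cut removes at least one anomaly on re-evaluation, else penalised (×0.8,
floor 0.25). Multiplicative weights are the simplest update consistent with
a greedy hyper-heuristic; the normalisation makes the two severity scales
commensurable, a choice this package makes rather than one inherited from
the method description. Pieces shorter than 250 bp (the evaluation floor)
are discarded. The accepted insert range defaults to the mean ± 3 standard
deviations.

## Contig trimming

OLC contigs duplicate sequence near their ends (the exact fork position
inside a consensus cannot be pinpointed), which scaffolders do not expect.
Terminal windows of every contig pair are aligned (same-strand tail–head
and the strand-crossing combinations); duplications of at least
`min_dup_length` (default = `min_overlap`) are trimmed from the longer
contig — unless that contig would drop below `min_keep` (250 bp), in which
case the shorter partner is tried, and if both are too short the pair is
left untouched. Trimming the longer contig first minimises relative
information loss; the guard exists precisely because nearby forks can make
naive trimming destroy short contigs and with them genome fraction.

## Evaluation metrics

For synthetic references the package re-implements the handful of metrics
needed to judge itself: NG(X) (the length c such that contigs ≥ c cover X %
of the genome), genome fraction, duplication ratio, largest alignment and
misassembled-contig detection. Contigs are aligned by exact 31-bp anchors
every 50 bp, grouped by diagonal and strand, extended by exact matching,
greedily tiled, and checked for breakpoints: consecutive blocks on
different strands, out of order, or displaced by more than
`misassembly_tolerance` (1000 bp, the usual relocation threshold) flag the
contig as misassembled. Blocks under 65 bp are ignored. Contigs under
250 bp are excluded from reports, matching the common evaluation floor.
This is a test oracle for synthetic, error-free or low-error data — not a
general aligner: anchor seeding assumes long exact stretches, which
substitution-only simulated reads guarantee but real indel-rich data would
not.

Library depth of coverage uses the standard arithmetic
`floor(2 · n_pairs · read_length / genome_length)`; flooring reproduces the
published depths of the three reference libraries this package's defaults
are modelled on (113, 66, and 26 on a ~90 Mb effective length).

## The synthetic-data generator

`simulate_genome()` draws a uniform random sequence, plants exact repeat
copies at requested positions and optionally a second haplotype with i.i.d.
SNPs. `simulate_paired_reads()` emulates the structure of the real
libraries the method targets: ~100 bp reads, Gaussian insert sizes
(defaults mean 300, sd 30 — inside the published 159–312 bp insert range,
with the sd chosen at 10 % of the mean as is typical for small-insert
libraries), forward–reverse mate orientation with random pair strand,
substitution-only errors (Illumina's dominant error mode; indels are
exercised directly at the aligner level instead), and a complete per-read
ground truth table.

What the generator does **not** emulate: position-dependent quality decay,
GC bias, coverage dips, adapter contamination, indel sequencing errors, and
long-range repeat families. Passing tests therefore demonstrate
algorithmic correctness under the stated model, not production robustness
on arbitrary real libraries.

Problem sizes used in the tests and in `scripts/acceptance.R` are
desk-scale study conditions chosen once: 10–20 kb genomes at coverage
10–30, 500 bp planted repeats with 300 bp inserts (repeat longer than the
read + insert span, the regime where paired ends cannot bridge and fork
detection alone must protect correctness), and chimera junctions joining
loci ≥ 5 kb apart.

## Numerical and degenerate-input choices

* Alignment tie-breaks: see above; both the C++ engine and the independent
  R reference implementation in the test suite pin them down, and 1000
  random pairs are compared exactly.
* All string sorting uses byte (radix) order, never locale collation.
* Empty overlaps (score 0, length 0) are representable but can never pass
  `accept_arc`, whose thresholds are strictly positive.
* `ngx()` returns `NA` when total contig length is below X % of the genome
  — undefined rather than zero, as on low-coverage assemblies.
* The quality filter keeps the longest substring whose every full sliding
  window passes; reads shorter than the window are rejected; trimming (not
  whole-read discarding) is the default, with `action = "discard"`
  available since the underlying rule admits both readings.
* Reads containing `N` are removed at parse time (`keep_n = FALSE`),
  mirroring standard preprocessing; the mate of a removed read stays,
  unpaired.
* A cut or trim never happens when it would leave a piece under 250 bp
  (correction discards such pieces; trimming refuses the trim).

## Known limitations

* The traversal engine is O(steps × state × degree) in R; graphs beyond a
  few hundred thousand arcs will be slow. The aligner and anchor matcher
  are the only compiled components.
* Fork classification inspects candidate fronts only up to
  `bubble_window`; nested repeats longer than the window but shorter than a
  read are resolved by read continuity, but repeat structures with
  interleaved copies may fragment contigs more than necessary (they are cut
  safely rather than resolved).
* Correction cut placement is anomaly-midpoint / peak-center; the true
  junction is localised only to within roughly one insert size.
* Scaffolding is out of scope: trimmed contigs are written for external
  scaffolders.
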