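---
title: "Methods: homology-based assembly correction, scaffolding, patching and merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based assembly correction, scaffolding, patching and merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafkit)
```

scafkit improves draft genome assemblies using pairwise whole-genome
homology. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical and design choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real data.

## Alignment filtering and macro-synteny blocks

All tools consume pairwise alignments (PAF or MUMmer delta) in a single
tabular form with 0-based half-open coordinates and query-forward query
intervals. Two filters precede everything else:

* **Unique-anchor filtering** (`filter_unique_anchor()`): repetitive
  alignments are removed per query by processing alignments in decreasing
  aligned-length order and keeping one only if it contributes at least
  `min_unique_anchor` bp (default 10,000 bp, the canonical anchor length
  for this style of filtering) of query territory not already claimed.
  The processing order is a design choice: the strongest alignment claims
  territory first, which makes the filter deterministic and biased toward
  the alignments a scaffolder should trust.
* **Mapping quality** (`filter_mapq()`): applied only when a score exists;
  delta records and PAF mapq 255 ("missing") always pass.

Filtered alignments are merged into blocks (`merge_blocks()`): per query,
sorted by reference position, consecutive alignments on the same reference
sequence and strand merge when their reference separation is at most `d`
(default 100,000 bp), taking minimum/maximum coordinates as the new
extent. Two numerical choices are deliberate and tested:

* separation is the *gap* between reference intervals (overlap counts as
  0), and the bound is **inclusive** — 100,000 bp merges, 100,001 does
  not;
* after merging, blocks contained within other blocks on the query axis
  are removed; for byte-identical intervals the block with more aligned bp
  survives, then the lexicographically smaller identity. The tie-break is
  not forced by the method, it is fixed for reproducibility.

## Misassembly correction

A query with two or more merged blocks is a correction candidate. The
break coordinate between consecutive blocks is not pinned by the method
description, so scafkit uses the **midpoint of the inter-block query
interval** (the shared coordinate when blocks abut) — the least-committed
choice given that the true junction lies somewhere in the unaligned
interval. Candidates are suppressed when:

* within `terminus_margin` (default 5,000 bp) of either sequence end;
* inside a user-provided feature interval (never break inside a gene);
* the flanking blocks' reference assignments do not match the requested
  mode (`intra` = same reference sequence only, `inter` = different only);
* read coverage looks normal: with `min_cov`/`max_cov` set, a break
  survives only if some base within `coverage_window` (default 10,000 bp)
  of the breakpoint is below `min_cov` or above `max_cov`. The window is
  **closed** (`[pos − v, pos + v]`) and clamped at sequence ends. Coverage
  validation is opt-in: without read evidence all candidates stay applied.

Breaking (`apply_breaks()`) conserves every base; fragments are named
`<id>:<start>-<end>` and an AGP maps them back to original coordinates.

## Reference-guided scaffolding

Confidence scores measure how unambiguously a query maps. The upstream
method defers their exact formulas to an earlier tool without restating
them, so scafkit adopts and documents these alignment-mass ratios:

* **grouping** — aligned bp on the best reference sequence ÷ total aligned
  bp;
* **orientation** — aligned bp on the majority strand within the best
  reference ÷ aligned bp on the best reference;
* **location** — aligned bp of best-reference blocks overlapping the
  primary block's reference interval (including itself) ÷ aligned bp on
  the best reference.

All three are scale-invariant and equal 1 for a single-block query.
Default thresholds are permissive (`min_grouping` 0.2, the others 0) and
exposed; they gate placement, not scoring.

Each placed query's **primary** alignment is its longest merged block
(most aligned bp; ties by larger reference span, then smaller start).
Primaries contained within other primaries on reference coordinates demote
their queries to unplaced. Order is by primary reference start (ties:
longer primary, then query id); orientation is the primary's strand.

### Gap sizing

Between adjacent placements the default is a fixed 100-bp "unknown" AGP
gap (`U` row, evidence `align_genus`). With `gap_policy = "inferred"` the
gap is computed from the flanking primary alignments:

```
gapsize() = (aln2_rs − aln2_qs) − (aln1_re + len(seq1) − aln1_qe)
```

For `-`-oriented placements the query coordinates are flipped to scaffold
orientation before the formula applies (the formula presumes
orientation-adjusted coordinates); this also answers whether inference
applies across mixed-orientation neighbours — it does, via the
normalisation. Every inferred size must be at least 1 bp, so the retention
band is `[max(min_gap, 1), max_gap]` with `min_gap = 1` and
`max_gap = 100,000` by default; sizes outside it become the 100-bp unknown
placeholder. The 100 bp figure is the placeholder size only — it is not
the lower retention bound, and the package's acceptance checks probe
exactly this boundary (sizes 3, 2, 1 retained; 0 and −5 replaced).
Known inferred gaps are written as `N` rows, unknown as `U` rows, both
with evidence `align_genus`.

## The scaffold graph and its solver

Patching and merging share one structure: two nodes per sequence (begin
and end termini), weighted edges between termini of distinct sequences,
and an implicit intra-sequence pairing that is never matched. "Maximal
weight matching" is implemented as **maximum-weight matching** — a global
optimum, found exactly. No installed R package offers general
(non-bipartite) maximum-weight matching, so the solver is implemented
in-package: edges are partitioned into connected components and each
component is solved by a memoised include/exclude search over edges in
breadth-first order, which keeps the live frontier small on the sparse,
chain-like components scaffold graphs produce. The suite verifies the
solver against a brute-force enumeration oracle on hundreds of random
graphs.

Determinism: equal-weight optima are resolved toward the
lexicographically smallest sorted edge-key set; weights are compared
exactly when integral and with a 1e-9 relative tolerance otherwise.
Overlaying the matching on the intra-sequence pairings yields disjoint
paths and cycles; each cycle is broken by removing its **lowest-weight
matched edge** (ties: smallest edge key) — the least-supported adjacency
is the one discarded, since the method only states that cycles are broken.
Chains are walked from their free termini: entering a sequence at its
begin terminus emits `+`, at its end terminus `-`.

## Patching

The target is split at N runs into seqlets; the graph is initialised with
the original gap adjacencies, whose edges carry a weight far above any
query-derived weight. This is a deliberate ranking: a gap adjacency is
asserted by the input assembly itself and should never lose to conflicting
alignment evidence; queries can *fill* such a gap (the gap metadata is
replaced by the query filler when the same adjacency is supported) but not
rewire across it.

Merged query-vs-seqlet blocks are kept only if at least `min_block_len`
(default 50,000 bp) long and within `terminus_distance` of a seqlet
terminus. The terminus distance default is not stated by the upstream
method; 10,000 bp is chosen — comfortably above alignment end jitter,
well below typical contig scale — and exposed (`-i`). Blocks implying the
target is contained in the query while large target portions fail to align
are discarded. An adjacency supported by more than one alignment pair is
deleted entirely, including its gap provenance: ambiguous evidence is
worse than none.

Joining is gapless: the inter-block query interval is inserted
(reverse-complemented when the chain traverses the edge against its stored
direction). A **negative** interval means the seqlets overlap in the
query; the overlap is trimmed from the start of the downstream (oriented)
seqlet and the sequences joined directly — the non-overlapping case is the
only one the upstream method describes, and trimming the downstream side
keeps the upstream coordinate frame stable. An optional `max_filler_len`
caps inserted sequence as a guard against misassembled queries; no
automatic misassembly detection is claimed. Chains that reproduce one
original target object exactly keep its name, which makes patching with no
evidence a strict identity (tested).

## Merging scaffolding solutions

Each input AGP must order and orient the same component set (violations
are reported with the offending component ids). Every adjacent component
pair votes for a terminus-pair edge with the AGP's weight (default 1);
components below `min_component_len` (default 100,000 bp) are unmergeable
singletons. With Hi-C evidence the vote weights are **replaced** (not
blended) by

```
h(t1, t2) = linking contacts(win(t1), win(t2)) / max(sites(win(t1)) + sites(win(t2)), 1)
```

where `win()` is the terminal window — `min(component_length / 2,
terminal_window)` bp, default cap 1 Mbp — and `sites()` counts
restriction-motif matches (overlaps allowed, forward strand, degenerate
`[...]` classes supported; the Arima two-enzyme motif set is the default).
The normalisation form and window size are design choices documented here
because the upstream description names the weighting scheme without its
formula; restriction-site normalisation corrects for the contact-density
bias of enzyme-digested libraries, and the half-length cap keeps the two
windows of a short component disjoint. Whether gap-derived edges should be
re-weighted differently does not arise: the merge graph contains only
AGP-vote edges.

Merged chains become AGP objects with 100-bp unknown gaps (evidence
`proximity_ligation` when Hi-C-weighted, otherwise `align_genus`); input
gap sizes are not propagated because a merged adjacency has no single size
evidence. The merge is conservative by construction — every output
adjacency was proposed by at least one input — so merged contiguity can be
lower than the best single input wherever inputs disagree. Practical
advice: feed the merge the minimal set of informative solutions.

## Contig screening and patch evaluation

`screen_contigs()` is a pure classifier over per-database covered
fractions: rDNA first (fraction > 0.10 ⇒ rDNA, always kept), then removal
when bacterial > 0.10, or mitochondrial > 0.20 on a contig under 1 Mbp,
or chloroplast > 0.20 on a contig under 0.5 Mbp. The rDNA exemption gates
*all three* removal rules, following the order in which the rules are
stated; running the alignments that produce the fractions is out of scope.
`patch_distance()` is the Euclidean metric over patch coordinate tuples
(start/end of the two joined sequences and of the filler).

## The synthetic-data generators

`simulate_genome()` draws uniform-composition chromosomes (optionally
implanting a duplicated repeat unit to stress unique-anchor filtering);
`fragment_assembly()` cuts them into contigs with lengths jittered
uniformly in 0.6–1.4 × `target_n50` — so no degenerate slivers arise,
matching real contig size distributions — and can consume sequence into
truth-logged gaps, reverse-complement contigs, and splice inter-chromosome
chimeras. `cross_alignments()` and `truth_alignments()` emit the *exact*
alignments implied by the truth AGPs, and `simulate_hic_pairs()` draws
contacts with exponentially decaying genomic separation. All generators
are deterministic under a fixed seed.

What the generators emulate: fragmentation, unknown gap sizes, orientation
loss, chimeric joins, contact-frequency decay. What they do not: alignment
noise and endpoint jitter, indels and divergence between genotypes,
repeat-induced mapping ambiguity (unless repeats are requested), read
errors, and biological contact-matrix structure beyond distance decay.
Passing the exact-regime suites therefore demonstrates the *logic* of the
pipelines — coordinate arithmetic, graph construction, solver optimality,
format round-trips — not robustness to noisy alignments, which depends on
the upstream aligner and the filtering thresholds.

## Problem sizes and numerical conventions

The test and acceptance suites run, per check, on: two-chromosome genomes
of 0.2–5 Mbp; fragmented assemblies of ~10–50 contigs; 200 random graphs
of up to 8 sequences against the exhaustive matching oracle; 3,000
simulated Hi-C pairs. These sizes make every property exercise the same
code paths as chromosome-scale runs while each suite completes in seconds
to tens of seconds.

Conventions: all internal coordinates are 0-based half-open; AGP I/O
converts to the format's 1-based inclusive convention at the boundary
only. Query coordinates are always query-forward. Sequence case is
preserved on output and ignored in comparisons (masking is metadata).
Degenerate inputs are defined: empty alignment sets, empty graphs, and
empty queries yield empty or identity results rather than errors.

## Known limitations

* The solver's exact search is designed for the sparse components real
  scaffold graphs produce; pathological dense components with many
  equal-weight edges could be slow (they do not arise from AGP votes,
  whose degree is bounded by the number of input solutions).
* Coverage profiles and Hi-C contacts are consumed as simple tables;
  BAM-level adapters are intentionally out of scope.
* `-`/`-` overlap trimming at patched joins assumes the overlap estimate
  from exactly-placed blocks; with noisy alignments a polishing pass over
  join junctions is advisable and is not performed here.
* Reference-free scaffolding and map-based (optical/linkage) scaffolding
  are out of scope; external maps enter only as AGP solutions through the
  merge.
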