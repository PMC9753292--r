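# scafkit

Homology-based improvement of draft genome assemblies in R: misassembly
**correction**, reference-guided **scaffolding**, gapless **patching**, and
**reconciliation (merge)** of competing scaffolding solutions, plus readers,
writers and validators for the formats these workflows live on (PAF, MUMmer
delta, AGP v2.1, FASTA, GFF3 intervals) and assembly contiguity (nX)
statistics.

## Who this is for

Genome assembly practitioners who have a draft assembly and one or more
sources of ordering evidence — a related reference genome, a second assembly
of the same sample, several candidate scaffolding solutions, Hi-C contacts —
and want to combine them into a better assembly with auditable, tabular
intermediates. Every user-facing function takes and returns plain data
frames (tibbles), so pipelines compose with the pipe and results drop
straight into dplyr/ggplot2.

## The model

All four tools start from pairwise whole-genome alignments between a query
and a reference/target assembly. Alignments are cleaned by *unique-anchor
filtering* (an alignment is kept only if it claims enough query territory
not already covered by stronger alignments) and then merged into
macro-synteny blocks: consecutive same-strand alignments within `d` bp on
the reference (default 100 kbp) merge, taking the minimum coordinate as the
new start and the maximum as the new end; blocks contained within other
blocks on the query are removed.

* **correct** breaks query sequences at merged-alignment boundaries —
  evidence of chimeric joins — unless the boundary is within `b` = 5 kbp of
  a terminus, falls inside an annotated feature, or read coverage within
  `v` = 10 kbp of the breakpoint looks normal (no depth below `--min-cov`
  or above `--max-cov`), in which case the boundary is attributed to true
  structural variation.
* **scaffold** assigns each query to the reference sequence holding most of
  its aligned bases, scores the assignment with grouping / location /
  orientation confidences, orders queries by the reference position of
  their longest ("primary") block, and orients them by its strand. Gaps
  between neighbours are 100-bp "unknown" AGP rows by default, or inferred
  from the flanking primary alignments:

  ```
  gapsize() = (aln2_rs − aln2_qs) − (aln1_re + len(seq1) − aln1_qe)
  ```

  Inferred sizes must be at least 1 bp; sizes below `-g` (or 1) or above
  `-m` (default 100 kbp) are replaced by the 100-bp unknown placeholder.
* **patch** splits a target assembly at its N runs, aligns a second
  assembly to the resulting seqlets, and solves a directed *scaffold graph*
  (two terminus nodes per seqlet; edges are original gap adjacencies plus
  query-supported adjacencies carrying the filler interval) by
  maximum-weight matching with cycle breaking. Joins supported by query
  sequence are made gaplessly; unreplaced gap edges re-emit their original
  N run.
* **merge** turns each input AGP's component adjacencies into weighted
  votes on the same scaffold graph (weight of the source AGP, 1 by
  default), optionally *replaces* the vote weights with Hi-C scores
  h(t1, t2) = linking contacts in the two terminal windows ÷ restriction
  sites in those windows, solves the graph, and emits one merged AGP.
  Unmerged components pass through unchanged, so the merge never invents an
  adjacency that no input proposed.

A deterministic synthetic-data module (`simulate_genome()`,
`fragment_assembly()`, `simulate_hic_pairs()`, `cross_alignments()`)
generates truth-tracked genomes, fragmented assemblies, and exact
alignments so the whole toolkit is testable without external data, and the
contamination-screening classifier (`screen_contigs()`) and patch-accuracy
metric (`patch_distance()`) support assembly curation workflows.

## Worked example

```r
library(scafkit)

genome <- simulate_genome(seed = 101, n_chrom = 2, chrom_len = 1e6)
asm    <- fragment_assembly(genome, seed = 102, target_n50 = 1e5,
                            gap_rate = 1, flip_prob = 0.3)
asm
#> <truth_assembly> 19 contigs over 2 chromosomes, 17 events

res <- run_scaffold(asm$contigs, truth_alignments(asm),
                    scaffold_config(gap_policy = "inferred"))
glance(res)
#> # A tibble: 1 × 4
#>   n_placed n_unplaced n_objects output_n50
#>      <int>      <int>     <int>      <dbl>
#> 1       19          0         2    1000000

head(tidy(res)[, c("query_id", "ref_id", "order_index", "orientation")], 3)
#> # A tibble: 3 × 4
#>   query_id ref_id order_index orientation
#> 1 tig0001  chr1             0 +
#> 2 tig0002  chr1             1 +
#> 3 tig0003  chr1             2 +

nx_statistics(nchar(asm$contigs), 50)   # contig N50:   103174
nx_statistics(nchar(res$seqs), 50)      # scaffold N50: 1000000
```

The 19 contigs (contig N50 103.2 kbp) are placed into two chromosome-scale
scaffolds whose N50 equals the 1-Mbp chromosome length; with exact
alignments every truth adjacency, orientation, and inter-contig gap size is
recovered, which the test suite asserts. `write_agp()` / `write_fasta()`
emit the results, and `inst/cli/scafkit` exposes the same pipelines as
shell subcommands (`agpcheck`, `stats`, `agp2fa`, `scaffold`, `patch`,
`merge`, `sim-genome`, `sim-fragment`).

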