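# olcassembler

An overlap-layout-consensus (OLC) de novo assembler for paired-end short
reads, written as a desk-scale R package. It is aimed at people who want a
complete, inspectable OLC pipeline — overlap-graph construction with
heuristic pair preselection, state-voting graph traversal with repeat-aware
fork detection, paired-end misassembly correction, and contig trimming —
together with a paired-end read simulator and reference-based evaluation
metrics, so every stage can be exercised on synthetic data with known
ground truth.

## The method in brief

Every read r and its reverse complement form a *double vertex*; a directed
arc u → v records a verified inexact overlap in which v extends u rightward
by `shift` bp. Candidate pairs are preselected by four heuristics (sorted
k-mer characteristic fingerprints, partial fingerprints of read thirds,
smallest lexicographical descriptors of each read half, and
paired-end/successor propagation) and verified with a semi-global
Needleman–Wunsch alignment (match +1, mismatch −1, gap −2, free end gaps);
an arc is accepted when

    overlap_length >= min_overlap   and
    errors <= ceiling(max_error_rate * overlap_length).

Traversal grows contigs from random seeds. A sliding *state*
S = s₁, …, s_r of recently added vertices votes for candidate successors,
score(c) = Σᵢ overlap(sᵢ → c); the best candidate is appended and s₁ is
pruned once its overlap with the newest vertex drops below
`min_state_overlap`. Forward forks (a dropped candidate group after the
state settles on one branch) and backward forks (candidates appearing with
predecessors outside the path) are counterchecked against missing-arc
artifacts, then classified as sequencing-error tips (ignored), SNP bubbles
(ignored), or repeats (the path is cut directly before the state). A
greedy hyper-heuristic then cuts contigs where paired-end geometry shows
anomalies — continuity breaks and mismapped-mate density peaks — and
overlapping contig ends are trimmed for scaffolder compatibility, with a
guard that never shortens a contig below 250 bp.

Evaluation against a known (synthetic) reference reports NG(X), genome
fraction, duplication ratio and misassembled contigs, plus the library
arithmetic `depth = floor(2 · n_pairs · read_length / genome_length)`.

## Worked example

```r
library(olcassembler)

genome <- simulate_genome(20000, seed = 11)
sim    <- simulate_paired_reads(genome, n_pairs = 3000, read_length = 100,
                                insert_mean = 300, insert_sd = 30, seed = 12)
res    <- assemble_reads(sim$reads, assembly_params(), seed = 13)
print(res$graph)
#> overlap_graph: 6000 reads / 12000 vertices, 220224 arcs ( 1800 containments )
evaluate(res$contigs, genome)
#> assembly_report: 1 contigs
#>   genome fraction    : 99.93 %
#>   duplication ratio  : 1.000
#>   NG50 / NG75        : 19986 / 19986 bp
#>   largest alignment  : 19986 bp
#>   total aligned      : 19986 bp
#>   misassembled       : 0 contigs (0 bp)
```

At coverage 30 the 20 kb genome assembles into a single contig covering
99.9 % of the reference with no misassembly. With a planted 500 bp repeat
at two loci (longer than read + insert, so pairs cannot bridge it), fork
detection cuts the walk at the repeat boundaries instead of guessing:
contigs stay misassembly-free and the repeat region is emitted as its own
contig.

A thin command line lives in `inst/scripts/olc_pipeline.R`:

```sh
Rscript inst/scripts/olc_pipeline.R simulate --genome-length 20000 \
    --n-pairs 3000 --out-dir sim
Rscript inst/scripts/olc_pipeline.R all --fastq1 sim/sim_1.fastq \
    --fastq2 sim/sim_2.fastq --reference sim/sim_ref.fasta --out-dir out
```

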