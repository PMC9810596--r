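# mitostall

Codon-resolution analysis of mitochondrial ribosome profiling, built to
detect mitoribosome stalling at the non-canonical stop codons of the human
mitochondrial genome.

Human mitochondria translate 13 proteins under a genetic code in which UGA
encodes tryptophan, AUA/AUU act as start codons, and AGA/AGG — found only
at the ends of the *COX1* and *ND6* open reading frames — have no cognate
tRNAs and serve as non-canonical stop codons. Termination there requires a
dedicated release factor (mtRF1); when it is missing, mitoribosomes stall
on the AGA/AGG codon and trailing ribosomes queue about one footprint
length (a 35-nt footprint ≈ 12 codons) upstream. `mitostall` is for
researchers who want to quantify that phenotype from ribosome-protected
fragment (RPF) libraries, or to validate such a pipeline end to end
without sequencing data.

## What the package computes

Raw single-end FASTQ reads are turned into per-sample **codon count
tables** — A-site counts indexed by `(gene, codon index)` — via

1. 3' adapter trimming (`TGGAATTCTCGGGTGCCAAGG`, mismatch-tolerant,
   trimmed to a fixpoint),
2. footprint length filtering (25–35 nt),
3. exhaustive mapping of every circular offset on both strands of the
   mitochondrial genome (small C++ scan; ties are reported as `MULTI`,
   never broken silently), and
4. A-site assignment at a fixed 5' offset of 14 nt, strand-aware and
   modular across the circular origin, with bicistronic overlaps counted
   toward both frames.

On top of the count table:

* **relative transcript occupancy** — each gene's share of all footprints;
* **size factors** — mean gene total over each gene's total, equalizing
  transcript-level coverage;
* **terminal-window occupancy** — the share of a gene's scaled counts in
  its last 15 codons (stop codon included by default), the stall statistic;
* **stall fold change** versus a reference sample, with Haldane
  pseudocount stabilization;
* **codon-identity profiles** and their fold changes (AGA/AGG enrichment);
* **queued-ribosome scan** for the secondary peak 10–16 codons upstream of
  a stall.

A **synthetic footprint generator** emits FASTQ with the statistical
structure of a mitoribosome profiling library (footprint length
distribution, 3' adapter, programmed stall and queue peaks, strand-aware
circular footprints) plus a per-read ground-truth table, and a bundled
synthetic genome reproduces the human mtDNA coding layout (13 ORFs, ND6 on
the minus strand, COX1→AGA, ND6→AGG, a single CGG codon, bicistronic
overlaps, polyA-completed stops) at desk scale. Small helpers cover the
arithmetic of in vitro peptide-release assays (release fraction,
background correction, active-ribosome fraction, replicate summaries).

## Worked example

Simulate a wildtype-like and a knockout-like library on the bundled
synthetic genome, run the full pipeline on both, and quantify stalling:

```r
library(mitostall)

fx <- synthetic_mito_genome()
wt_sim <- simulate_reads(fx$genome, fx$orfs,
                         wt_like_config(fx$orfs, n_reads = 20000, seed = 1))
ko_sim <- simulate_reads(fx$genome, fx$orfs,
                         ko_like_config(fx$orfs, n_reads = 20000, seed = 2))

count_sample <- function(sim, id) {
  res <- process_reads(fx$genome, sim$reads)   # trim, filter, map
  asg <- assign_alignments(fx$genome, fx$orfs, res$alignments)
  build_count_table(asg, fx$orfs, fx$genome, id)
}
wt <- count_sample(wt_sim, "WT")
ko <- count_sample(ko_sim, "KO")

occ <- merge(relative_transcript_occupancy(wt),
             relative_transcript_occupancy(ko),
             by = "gene", suffixes = c("_wt", "_ko"))
subset(occ, gene %in% c("COX1", "ND6"), c(gene, fraction_wt, fraction_ko))
#>    gene fraction_wt fraction_ko
#> 3  COX1  0.19569154  0.09386036
#> 13  ND6  0.02004371  0.03940276

fc <- stall_fold_change(terminal_window_occupancy(ko, fx$orfs),
                        terminal_window_occupancy(wt, fx$orfs))
subset(fc, gene %in% c("COX1", "ND6"))
#>    gene occupancy_sample occupancy_reference fold_change stabilized
#> 3  COX1        0.4316832           0.1065731    4.050584      FALSE
#> 12  ND6        0.5880503           0.2647975    2.220755      FALSE

upstream_queue_scan(ko, fx$orfs[fx$orfs$gene == "COX1", ])
#>   gene offset count median_count     fold called
#> 1 COX1     12    95            6 15.83333   TRUE
```

Reading the output: in the knockout-like sample *COX1* drops from ~20% to
~9% of all footprints while *ND6* roughly doubles; the last 15 codons of
*COX1* carry 43% of its footprints versus 11% in the wildtype-like sample
(a ~4-fold terminal enrichment, ~2.2-fold for *ND6*); and the queued
trailing ribosome is detected 12 codons upstream of the *COX1* stop, a
15.8-fold peak over the gene's median codon count. The generator planted
these effects with magnitudes derived from the terminal fold changes and
occupancies reported for mtRF1-deficient cells, and the pipeline recovers
them from raw reads.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "mitostall-cli.R", package = "mitostall")` with
`simulate`, `process`, `count`, `stall` and `release` subcommands.

To analyze real data, point `read_genome_fasta()` and `read_orf_table()`
(or `read_orf_gff3()`) at the human mitochondrial reference (RefSeq
NC_012920) and its CDS annotation and feed the same pipeline with real
FASTQ; reproducing published occupancy numbers from deposited sequencing
runs is an integration experiment, not part of the test suite.

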