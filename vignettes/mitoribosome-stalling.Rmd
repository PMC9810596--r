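---
title: "Codon-resolution detection of mitoribosome stalling at non-canonical stop codons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolution detection of mitoribosome stalling at non-canonical stop codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostall)
```

## The biological question

Human mitochondria translate 13 proteins from a 16.6 kb circular genome
under a genetic code that deviates from the universal one: UGA encodes
tryptophan, AUA/AUU serve as start codons, and the codons AGA and AGG have
no cognate tRNAs at all. AGA and AGG sit at the very ends of the *COX1* and
*ND6* open reading frames, where they act as non-canonical stop codons. The
canonical stops UAA/UAG are recognized by the release factor mtRF1a; the
non-canonical ones require a second release factor, mtRF1. When mtRF1 is
lost, mitoribosomes that reach an AGA or AGG codon cannot release their
peptide and stall, and trailing ribosomes queue up one footprint length
(about 12 codons) behind them.

`mitostall` implements the computational side of detecting this phenotype
from mitoribosome profiling data at single-codon resolution, together with
a synthetic footprint generator that makes every stage of the pipeline
verifiable without any sequencing data, and small helpers for the
arithmetic of in vitro peptide-release assays.

## The analysis model

### From raw reads to A-site codon counts

Ribosome-protected fragments (RPFs) are sequenced as single-end reads that
run through the footprint into the 3' ligation adapter
(`TGGAATTCTCGGGTGCCAAGG`). Processing proceeds in four steps.

1. **Adapter trimming** (`trim_adapter`). For each read we locate the
   5'-most position at which a prefix of the adapter (at least
   `min_overlap = 3` nt) matches the read suffix with at most a 10%
   mismatch fraction, and truncate there. The scan is iterated to a
   fixpoint so that a trimmed read never retains a qualifying adapter
   prefix at its 3' end; this makes trimming idempotent. The fixpoint can
   occasionally remove a few genuine 3' insert bases that happen to
   resemble the adapter start, but the 5' end — the only coordinate used
   for A-site assignment — is never affected.
2. **Length filtering** (`length_filter`). Footprints of 25–35 nt are
   retained, the range over which the single fixed A-site offset is valid.
   Untrimmed reads are discarded by default: with 50-cycle raw reads and
   footprints under 41 nt the adapter must be present.
3. **Mapping** (`map_reads`). Because the reference is a few kb of circular
   DNA, the package maps by *exhaustive scanning*: every circular offset on
   both strands is evaluated (a small C++ loop over the doubled genome
   string) and candidate loci are ranked by mismatch count, with
   `max_mismatches = 1` by default. A read is `UNIQUE` only when a single
   locus attains the minimal mismatch count; ties are never broken
   silently, they yield `MULTI`, and `MULTI` reads are excluded from
   counting because codon-level attribution requires a unique locus. This
   removes any aligner dependency, is exactly reproducible, and is cheap at
   this genome size (tens of thousands of reads in seconds). A minimal SAM
   writer preserves interoperability with samtools.
4. **A-site assignment** (`assign_alignments`). The A-site codon's first
   base sits a fixed `offset = 14` nt downstream of the footprint's 5' end
   for all retained lengths; on the minus strand this means 14 nt in the
   direction of decreasing genomic coordinate. The genomic A-site position
   is converted to a codon index in every same-strand ORF that contains it.

Counts are accumulated into the central object of the analysis, the
**codon count table**: per sample, the A-site count at every
`(gene, codon index)` cell of the annotation.

### Coordinates, circularity, and special cases

All coordinates are 0-based, half-open, on the forward genome axis; strand
only changes reading direction, and every position is interpreted modulo
the genome length, so annotations and footprints may wrap the origin.
Three mitochondria-specific features get explicit treatment:

* **PolyA-completed stops.** Several mitochondrial mRNAs end in `U` or
  `UA` genomically and are completed to a `UAA` stop by polyadenylation.
  The completion count (0–2) is an annotation field, not something inferred
  from sequence. Genomic A-site positions inside the completed terminal
  codon can only fall on its 1–3 genomically encoded bases, which caps the
  sensitivity for terminal-codon occupancy; the same geometric rule is
  applied at every codon.
* **Bicistronic overlaps.** ATP8/ATP6 and ND4L/ND4 overlap in shifted
  reading frames. An A-site in an overlap is counted toward *both* ORFs,
  and the number of double-counted reads is reported alongside the table.
  How the original analyses attributed such reads is not documented
  anywhere we could verify, so the package makes its policy explicit
  rather than guessing.
* **Off-ORF A-sites** are tallied in a diagnostics counter, never silently
  dropped.

### Stall statistics

All statistics consume the codon count table and keep exact integer counts
until the final division.

* **Relative transcript occupancy** (`relative_transcript_occupancy`):
  each gene's share of the grand total; sums to 1.
* **Size factors** (`size_factors`): `sf_g = mean(gene totals) / total_g`,
  the arithmetic mean over genes, so that scaling equalizes every gene's
  total. (Whether the original normalization used an arithmetic or a
  weighted mean is unstated; the arithmetic mean is assumed.)
* **Terminal-window occupancy** (`terminal_window_occupancy`): the share
  of a gene's (size-factor-scaled) counts falling in its last 15 codons.
  Two window conventions circulate — the stop codon plus 14 upstream sense
  codons, or the 15 sense codons before the stop — and descriptions of the
  analysis conflict between them. The default here *includes* the stop
  (`include_stop = TRUE`), because stalling at the stop codon itself is
  part of the end-of-transcript signal; both variants are supported and
  the choice is recorded as an attribute of the report. The size factor
  cancels inside a single gene's ratio; it is applied nevertheless so
  window counts remain comparable across genes and samples.
* **Stall fold change** (`stall_fold_change`): ratio of terminal-window
  occupancies, sample over reference. When either window count is zero a
  Haldane-style pseudocount of 0.5 is added to both window counts and the
  gene is flagged; no p-values are attached, matching the descriptive
  character of a 13-gene comparison.
* **Codon-identity profile** (`codon_identity_profile`): counts summed by
  the identity of the decoded codon. The exact normalization used in
  published codon-occupancy panels is ambiguous, so both supported modes
  are labelled explicitly: `"total"` (share of the grand total, default
  for fold changes) and `"per_occurrence"` (additionally divided by the
  codon's occurrence count in the coding mtDNA). Both presentation
  orderings (mtDNA codon frequency, sequencing coverage) are carried in
  the output.
* **Queued-ribosome scan** (`upstream_queue_scan`): a 35-nt footprint
  spans `round(35/3) = 12` codons, so a ribosome queued behind a stalled
  one pauses ~12–13 codons upstream. The scan searches offsets 10–16
  codons upstream of the stall for the maximal secondary peak and reports
  its fold over the gene's median codon count, calling a queue only above
  `min_fold = 2`.

## The synthetic data generator

`simulate_reads` draws, for each read: a gene (probability proportional to
transcript weight times total per-codon density), an A-site codon
(proportional to the gene's density profile), and a footprint length; it
then emits the strand-aware genomic sequence whose 5' end lies 14 nt
upstream of the A-site first base, appends the adapter, truncates to the
50-nt raw read length, and records the ground truth per read. Identical
seeds give byte-identical FASTQ output.

Default settings define the emulated library:

* **Length distribution**: triangular over 25–40 nt peaking at 33–35 nt —
  gel slices of 30–40 nt are excised during library preparation and
  mitoribosome footprints usually comprise 35 nt. Lengths above 35 exist
  deliberately so the `max_length` filter is exercised.
* **Transcript weights**: the wildtype preset (`wt_like_config`) assigns
  weights so expected read shares match wildtype relative occupancies,
  with *COX1* at 20% of footprints; the knockout preset halves *COX1* to
  10% and doubles *ND6*.
* **Stalls**: the knockout preset places a terminal stall at *COX1*'s AGA
  and *ND6*'s AGG whose total excess weight is derived analytically from
  the reported terminal fold changes (4.5 and 2.5) by inverting the
  closed-form window-occupancy expectation (`stall_mass_for_fold_change`),
  with one sixth of the excess placed on a queued peak 12 codons upstream.
  The pipeline then has to *recover* these effect sizes from raw reads.
* **No sequencing errors** by default, so the processing round trip is
  exact; an optional per-base substitution rate exercises
  mismatch-tolerant mapping. Quality strings are constant; quality
  modeling is out of scope.
* Footprints whose 5' end precedes the ORF start simply extend into
  upstream genomic sequence, mirroring the near-absence of 5' UTRs on
  mitochondrial mRNAs.

What the generator does **not** model — and what passing tests therefore
do not show about real data: ligation and PCR biases, duplicate reads,
RNase digestion variability, and in particular the shorter footprints
produced by stalled ribosomes with an empty A-site, which real analyses
exclude and which would otherwise add mass below 25 nt. Footprints are cut
from the genome, so reads over a polyA-completed stop carry downstream
genomic bases rather than the mRNA's non-templated A's; at footprint
lengths of 25–35 this affects at most the last few bases of a minority of
terminal reads and no coordinate used in counting.

### The bundled synthetic genome

`synthetic_mito_genome()` deterministically constructs a ~3.6 kb circular
genome reproducing the *layout* of the human mitochondrial coding region
while keeping exhaustive analyses fast: 13 ORFs in human gene order with
scaled-down lengths (~1.1 kb of codons), ND6 on the minus strand, COX1
ending AGA, ND6 ending AGG with the genome's single in-frame CGG
immediately upstream, the ATP8/ATP6 (46 nt) and ND4L/ND4 (7 nt) overlaps
in shifted frames, alternative ATA/ATT starts, and five polyA-completed
UAA stops. It is a synthetic stand-in — not the human reference sequence
(RefSeq NC_012920) — and the file names and documentation label it as
such. The loaders (`read_genome_fasta`, `read_orf_table`, `read_orf_gff3`)
accept a real genome and annotation unchanged, so the identical pipeline
runs on real mitoribosome profiling data; reproducing published occupancy
numbers from deposited sequencing runs is an integration experiment
outside the test suite.

## Numerical and testing choices

* Problem sizes: unit tests use 200–20,000 simulated reads; the
  end-to-end checks use 50,000 reads per sample, where the whole pipeline
  (trim, filter, exhaustive map, assign) runs in a few seconds per sample.
* Stochastic checks compare statistics against closed-form expectations
  from the density vectors (`expected_terminal_fold_change`) within three
  standard errors, with standard errors taken from binomial/multinomial
  sampling theory on the raw counts, or against exact multinomial draws
  (`rmultinom`) as an independent oracle.
* The mapper is verified read-for-read against a naive doubled-genome scan
  written independently in R, over random toy genomes including
  origin-spanning, reverse-complement, mismatched and unmappable reads.
* Degenerate inputs fail loudly: empty reads, all-zero count tables,
  windows longer than a gene, mismatched window definitions or
  normalization modes between compared samples.

## Release-assay arithmetic

The in vitro counterpart of the profiling phenotype is a co-sedimentation
release assay: radiolabelled peptide released by a factor stays in the
supernatant, ribosome-bound peptide pellets. `release_fraction` is
supernatant counts over total counts; `background_corrected_activity`
subtracts the factor-free spontaneous release (typically 10–15%), clamped
at zero, with the rescaled form `(sample - bg)/(1 - bg)` available behind
a flag since published percentages do not state which convention they use;
`summarize_release` adds replicate means, SDs and unpaired two-tailed
t-tests against the background condition. `active_ribosome_fraction`
(peptide per ribosome, ~30% for isolated mitoribosomes) completes the set.

## Known limitations

* A single fixed A-site offset is applied to all footprint lengths; a
  per-length offset map is accepted in configuration but no calibration
  routine is provided.
* Exhaustive mapping is only sensible for references up to a few tens of
  kb; this is by design for mitochondrial work.
* No nuclear-genome screening of contaminating cytosolic footprints is
  performed; the experimental workflow isolates mitochondrial monosome
  fractions upstream.
* Fold changes are descriptive; no replicate-level inferential statistics
  are attached to the profiling side.
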