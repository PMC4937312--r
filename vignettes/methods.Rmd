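---
title: "Quantifying transgene-induced trans-silencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transgene-induced trans-silencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnascope)
```

## The biological system and what the package measures

In *Paramecium* and other ciliates, a truncated transgene that cannot
produce intact mRNA triggers RNAi against the homologous endogenous gene.
The injected construct is transcribed bidirectionally; both spliced and
un-spliced transcripts accumulate and are converted into ~23 nt siRNAs.
These **primary siRNAs** map to the sequence shared between transgene and
endogenous locus. Silencing then spreads: the endogenous locus itself starts
producing **secondary siRNAs** in regions that are *absent* from the
transgene — direct evidence of transitivity via RNA-dependent RNA polymerase
(RDR) activity on target transcripts. The silenced locus acquires repressive
chromatin marks (H3K27me3) and loses active ones (H3K9ac, H3K4me3),
measurable by ChIP-qPCR.

`sirnascope` implements the quantitative backbone of such a study as
reusable, tested components:

* **genemodels** — gene/transgene representation and the induced
  primary/secondary region partition;
* **synthetic_data** — a seeded generator that emulates the study system
  and labels every read with its truth;
* **smallrna** — exact-match small-RNA mapping and region/strand/length/
  junction classification;
* **normalization** — knockdown-aware total-count scaling and fold
  changes;
* **splicing** — isoform-guided long-read alignment, per-intron splice
  rates, antisense-intron detection, strand coverage;
* **chipquant** — ChIP-qPCR percent-input arithmetic with reference-locus
  and H3 normalization;
* **pipeline** — `run_pipeline()` composing all stages into a
  deterministic report bundle. The exported functions are the interface;
  every artifact is a plain-text standard format (FASTA/FASTQ, GFF3, BED,
  SAM, bedGraph, TSV, JSON, YAML), so any stage can be fed real data.

## Region partition

A `GeneModel` stores exons on a reference contig (0-based half-open
internally; BED export stays 0-based, GFF3 and SAM are 1-based, as their
dialects require). A `TransgeneSpec` lists deletions and foreign
replacements in gene-relative coordinates; `build_transgene()` splices the
parent sequence accordingly and keeps an invertible coordinate map, from
which `derive_regions()` computes:

* `primary_capable` regions — parent intervals present in the transgene;
* `secondary_only` regions — parent intervals absent from it (named
  `endo_1`, `endo_2`, ... in genomic order);
* `foreign` regions — replacement inserts, on the transgene itself;
* a `five_prime` sub-region from the transcription start to the first
  intron, where siRNAs show a sense rather than antisense bias.

The default construct removes an internal 5' fragment at gene-relative
173–529 and truncates the gene from position 1250 of a 1600 nt span,
yielding two secondary-only regions; an optional foreign replacement at
625–1010 yields a third plus a foreign region. Only the 173–529 boundary is
fixed by the system being emulated; the remaining boundaries are generator
parameters chosen once as realistic and kept in the packaged default
configuration.

## The synthetic-data generator

The generator (`inst/extdata/default_sim_config.yaml`) defines the study
conditions; its defaults are not tuning knobs.

* **Composition is allocated, positions are sampled.** Per class, the
  (sub-region x strand x length) composition is fixed by deterministic
  largest-remainder quotas, so truth-table class counts equal configured
  counts exactly and composition fractions are exact rather than binomial;
  only read positions (and per-read intron retention, which must be
  Bernoulli) consume randomness. Each stage draws from its own RNG stream
  derived from the master seed, so adding a stage never perturbs earlier
  output, and identical seeds give byte-identical files.
* **Sequence composition** is 72% AT, emulating the AT-rich macronuclear
  genome and keeping accidental multi-mapping negligible at 17–25 nt.
  Sense introns carry canonical GT...AG boundaries; one antisense-strand
  GT...AG intron is planted inside an exon.
* **Small RNAs.** Lengths follow a 17–25 nt distribution with 55% of the
  mass at 23 nt. Antisense fractions default to 0.90 in the transgene
  body, 0.40 in the 5' sub-region, 0.95 for secondary siRNAs. A cohort
  sample holds 6,000 primary reads, 400 exon-exon junction reads drawn
  from the spliced mRNA with at least 4 nt on each side of a junction,
  150,000 background reads from elsewhere in the genome surrogate (so that
  transgene siRNAs are a small share of the library, as in real data),
  plus contaminant, structural-RNA, feeding-vector and knockdown-induced
  reads. Secondary abundance is parameterized as a fraction (defaults 0.05
  and 0.01) of the **measured** quantity — the transgene-covered region's
  mean per-base 23 nt antisense coverage at baseline composition — so the
  recovered coverage ratio estimates the configured fraction directly and
  knockdown response is carried by the class multipliers alone.
* **Long reads** are parameterized by a fixed-width (100 nt) genomic
  window with a uniform start; the emitted read is the transcript-coherent
  subsequence inside the window, so a read across a spliced intron is
  shorter by the intron length. This choice equalizes candidate
  ascertainment between spliced and un-spliced isoforms: sampling
  fixed-length reads in transcript space instead would under-ascertain
  un-spliced candidates (a read must span the whole intron to prove
  retention) and bias the measured splice rate upward by roughly
  (L-1)/(L-1-len_intron) on the un-spliced side — about +2.3 percentage
  points at L = 100 and 25 nt introns. With window parameterization the
  measured rate estimates 1 - retention without any correction. Each read
  comes from its own transcript copy in which every intron is retained
  independently with the configured probability (default 0.10). A
  configurable fraction (default 0.10) of reads is antisense: sense
  introns retained, the planted antisense intron spliced with probability
  0.9.
* **What the generator does not emulate:** sequencing errors, adapters,
  quality variation, polyA-selection bias, multi-gene loci, and genuine
  biological replicate variability. Passing tests therefore demonstrate
  correctness of the analysis arithmetic and classification rules under
  the stated statistical structure, not robustness to real-data noise.

## Small-RNA mapping and classification

Reads are filtered to 17–25 nt (inclusive), then aligned by **exact
matching** of the read or its reverse complement, in two rounds: reads
hitting a contaminant reference are removed first; the rest are matched
against the target set (genome surrogate contigs, the spliced mRNA — the
analogue of mapping against the coding-sequence annotation — the
transgene and feeding vectors). Every zero-mismatch occurrence is
reported and multi-mapped reads carry their hit count instead of an
arbitrary best hit. Matching uses Biostrings PDict machinery; the test
suite holds it against an independent naive sliding-window scan.

Region counting credits an alignment to **every** region it overlaps by at
least 1 nt (the overlap rule is a stated package decision) and accumulates
both read counts and overlapped bases, so per-base coverage is
`bases / region length`. Sense/antisense is always resolved against the
annotated coding strand of the target gene. The antisense ratio is
`antisense / (sense + antisense)`, `NA` at zero depth, and invariant under
count scaling.

A **junction read** matches the spliced mRNA across an exon-exon boundary
with at least 4 nt on each side *and* has no exact genomic match (the
genomic exclusion prevents double-assignment near intron boundaries); an
**intron read** matches the genome overlapping an intron by at least 1 nt.
The two classes are disjoint by construction. Junction-mapping antisense
siRNAs are the diagnostic of RDR activity on spliced transcripts.

## Knockdown-aware normalization

Libraries differ in depth, and knockdown libraries are flooded with siRNAs
against the knockdown gene, which would bias a plain total-count factor.
For each sample, `T` counts genome-mapped reads after removing
structural-RNA and feeding-vector reads, and `K` counts the reads within
`T` that map to the knockdown gene, so `T - K` is the count of reads
mapping to the rest of the genome. With `M` the cohort maximum of
`T - K` (computed once per invocation over all supplied samples):

$$\hat R = R \cdot \frac{M}{T - K}$$

Exactly one sample keeps its raw counts; all factors are >= 1; the formula
is linear in `R` and invariant to duplicating a library. Fold changes are
ratios of normalized counts (reported with log2), `NA` when the control
count is zero — no pseudocount is fabricated by default (`pseudocount`
exists but is off).

## Long-read splice analysis

With at most 8 annotated introns, all retain/splice isoform combinations
are enumerated and reads are matched against every isoform on both strands
(one mismatch allowed; fewest mismatches, then fewest gaps, then leftmost,
then forward strand). This model-guided design reflects that splice calls
are only ever made against annotated introns; de-novo discovery is limited
to the antisense-intron scan. Per intron, a read is

* **spliced** — alignment gaps exactly at the intron with at least one
  aligned base on each flank;
* **un-spliced** — covers both flanks and aligns to more than 4 bp of the
  intron (a 5 bp incursion triggers the call, 1–4 bp does not);
* otherwise **not a candidate** (including reads touching only one
  flank).

Requiring both flanks for both classes keeps the two candidate windows
identical under the generator's window parameterization, so
`splice_rate = n_spliced / (n_spliced + n_unspliced)` estimates
`1 - retention` per intron; the summary reports per-intron rates and their
unweighted mean. Splice rates are computed on sense-strand alignments by
default because antisense reads of a bidirectionally transcribed locus
retain sense introns and would be miscounted as un-spliced. The length
filter for long reads is strictly "longer than 60 nt".

The antisense-intron scan aligns reads on the antisense strand allowing a
single novel gap of 18–35 nt whose boundaries read GT...AG on the read's
strand (the "typical intron boundary" window and motif are package
decisions) and which does not equal any annotated sense intron; each
candidate reports its supporting reads and whether they retain overlapped
sense introns — the signature separating bidirectional transcription from
RDR copying of spliced mRNA.

## ChIP-qPCR arithmetic

No qPCR mathematics is inherited from the emulated study; the chain is the
standard reconstruction of its description, with amplification efficiency
fixed at 2: percent input is `100 * 2^(Ct_input - log2(1/f) - Ct_IP)` for
input fraction `f` (default 0.10); enrichments are normalized to a
reference locus (a native promoter) per antibody, and modifications
additionally to H3 occupancy at the same locus. Technical PCR replicates
are averaged on the Ct scale (geometric mean of quantities); biological
replicates are summarized as mean and SD on the enrichment scale. The
whole chain is invariant to adding a constant to all Ct values. The Ct
simulator plants a silencing signature (H3 occupancy gain, active-mark
loss, a 4-fold H3-corrected H3K27me3 gain at the target 3' CDS) with small
technical (0.02 cycles) and biological (0.01 log2) noise — deliberately
modest, since its purpose is validating the arithmetic chain, not
emulating assay variability.

## Numerical and design choices

* Coordinates: 0-based half-open internally; 1-based only in GFF3/SAM
  output and printed reports.
* Ties: alignment reports are sorted by (reference, start, strand, read
  id); quota allocation breaks remainder ties by index order; isoform
  alignment ties prefer fewer gaps, then leftmost, then the forward
  strand.
* Degenerate inputs: `T <= K` libraries, empty target reference sets,
  regions shorter than a read, out-of-range edits and overlapping edits
  raise errors; zero-depth ratios and zero-control fold changes are `NA`.
* Reported problem sizes: the validation studies use 20,000 long reads on
  a compact five-intron gene (about 2,200 candidates per intron), cohorts
  of about 176,000 small reads per sample, and 5,000 long reads for the
  default locus — sizes at which binomial uncertainty on every recovered
  quantity is well inside its acceptance band.
* `K` is counted within `T`: `T - K` is then exactly "reads mapping to
  the rest of the genome", which is the quantity the scaling divides by,
  and `T > K` stays meaningful.
* Knockdown-gene membership for `K` uses exact-match assignment to the
  gene's reference sequence (CDS-centric); feeding-introduced reads are
  removed by membership in the feeding-vector reference, not by sequence
  heuristics.

## Known limitations

* The exact matcher is deliberate about zero mismatches; small-RNA data
  with sequencing errors would need error-tolerant mapping upstream.
* Isoform enumeration is exponential in intron count and capped at 8
  introns — ample for *Paramecium*-like genes with few tiny introns, wrong
  for vertebrate-scale transcripts.
* The ChIP module models perfect doubling; efficiency estimation from
  dilution series is out of scope.
* Fold changes are descriptive ratios; no differential-expression
  inference is attempted, and median-of-ratios normalization is
  intentionally not offered because it presumes a locus annotation that
  small-RNA data here does not have.

## A minimal run

```{r, eval = FALSE}
cfg <- read_sim_config()          # packaged default study conditions
res <- run_pipeline(cfg, "out")   # writes the full report bundle
res$manifest$samples              # per-sample T, K and scaling factors
```
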