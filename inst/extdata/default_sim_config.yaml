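# Default synthetic-cohort configuration.
#
# The geometry emulates the study system: a five-intron target gene with
# ~25 nt introns, a double-truncated transgene (5' internal deletion at
# 173-529 gene-relative, 3' truncation from 1250), secondary-siRNA regions
# at a few percent of the primary per-base coverage, 23 nt modal siRNA
# length and a strong antisense bias outside the 5' sub-region.
seed: 20160416
at_content: 0.72
region_prefix: endo

gene:
  gene_id: target_gene
  reference_id: target_locus
  exon_lengths: [120, 260, 300, 280, 255, 260]
  intron_lengths: [25, 25, 25, 25, 25]
  flank: 100

transgene:
  # gene-relative 0-based half-open edit intervals
  deletions:
    - [173, 529]
    - [1250, 1600]
  linearization_offset: 200
  insert:
    enabled: false          # enable for the foreign-replacement construct
    interval: [625, 1010]
    length: 395
    name: toxin_insert

feeding:
  knockdown_gene:
    id: rdr2
    length: 1600
    insert: [500, 1100]     # dsRNA feeding-vector fragment
  control_gene:
    id: ctrl_gene
    length: 1200
    insert: [300, 900]

contigs:
  background_length: 60000
  structural_length: 3000
  contaminant_length: 5000

smallrna:
  counts:
    primary: 6000
    junction: 400
    background: 150000
    contaminant: 3000
    structural: 4000
    feeding_vector: 8000
    feeding_induced: 4000
  length_probs:
    "17": 0.02
    "18": 0.02
    "19": 0.03
    "20": 0.04
    "21": 0.06
    "22": 0.12
    "23": 0.55
    "24": 0.10
    "25": 0.06
  antisense:
    body: 0.90
    five_prime: 0.40
    secondary: 0.95
    junction: 0.90
    background: 0.50
    other: 0.50
  # per secondary-only region in genomic order, as a fraction of the
  # transgene-covered region's 23 nt antisense per-base coverage
  secondary_fractions: [0.05, 0.01]

longrna:
  n_reads: 5000
  window: 100
  retention: 0.10
  antisense_fraction: 0.10
  antisense_intron: [850, 878]   # gene-relative; GT...AG on the antisense strand
  antisense_intron_splice_prob: 0.90

samples:
  - id: control
    role: control
    feeding: ctrl_gene
  - id: knockdown
    role: knockdown
    feeding: rdr2
    multipliers:
      primary: {sense: 1.0, antisense: 0.2}
      secondary: {sense: 1.0, antisense: 0.2}
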