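test_that("transgene with no edits reproduces the parent span", {
  gene <- make_test_gene(1L)
  tg <- build_transgene(gene, transgene_spec("g1"))
  sp <- gene_span(gene)
  expect_identical(tg$sequence, substr(gene$sequence, sp[1] + 1, sp[2]))
  expect_length(tg$junctions, 0)
})

test_that("internal deletion yields the documented length and junction", {
  gene <- make_test_gene(2L, exon_lengths = c(200, 300, 300, 200),
                         intron_lengths = c(25, 25, 25), flank = 0L)
  expect_equal(diff(gene_span(gene)), 1075)
  # 1000-like case: deletion [173, 529) removes 356 nt, junction at 173
  spec <- transgene_spec("g1", deletions = list(c(173L, 529L)),
                         linearization_offset = 40L)
  tg <- build_transgene(gene, spec)
  expect_equal(nchar(tg$sequence), 1075 - 356 + 40)
  expect_identical(tg$junctions, 173L)
})

test_that("random edits match the string-splice oracle", {
  for (seed in 1:8) {
    gene <- make_test_gene(seed, exon_lengths = c(150, 200, 150),
                           intron_lengths = c(25, 25))
    sp <- gene_span(gene)
    parent <- substr(gene$sequence, sp[1] + 1, sp[2])
    set.seed(seed + 100)
    a1 <- sample(30:100, 1); b1 <- a1 + sample(20:60, 1)
    a2 <- b1 + sample(20:60, 1); b2 <- a2 + sample(20:60, 1)
    repl <- list(interval = c(a2, b2), seq = paste(
      sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
      name = "ins")
    spec <- transgene_spec("g1", deletions = list(c(a1, b1)),
                           replacements = list(repl))
    tg <- build_transgene(gene, spec)
    expect_identical(tg$sequence,
                     splice_oracle(parent, list(c(a1, b1)), list(repl)))
    # length arithmetic
    expect_equal(nchar(tg$sequence),
                 nchar(parent) - (b1 - a1) - (b2 - a2) + 50)
  }
})

test_that("coordinate map round-trips on parent-derived intervals", {
  gene <- make_test_gene(5L, exon_lengths = c(200, 300, 200),
                         intron_lengths = c(25, 25))
  spec <- transgene_spec("g1", deletions = list(c(100L, 250L)),
                         linearization_offset = 30L)
  tg <- build_transgene(gene, spec)
  glen <- diff(gene_span(gene))
  parent_pos <- setdiff(0:(glen - 1L), 100:249)
  tpos <- parent_to_transgene(tg, parent_pos)
  expect_false(anyNA(tpos))
  expect_identical(transgene_to_parent(tg, tpos), as.integer(parent_pos))
  # deleted positions have no transgene image
  expect_true(all(is.na(parent_to_transgene(tg, 100:249))))
  # filler maps to NA
  expect_true(is.na(transgene_to_parent(tg, nchar(tg$sequence) - 1L)))
})

test_that("overlapping or out-of-range edits are rejected", {
  gene <- make_test_gene(6L)
  expect_error(transgene_spec("g1", deletions = list(c(10L, 50L), c(40L, 80L))),
               "overlapping")
  spec <- transgene_spec("g1", deletions = list(c(10L, 10000L)))
  expect_error(build_transgene(gene, spec), "out of parent range")
})

test_that("derive_regions partitions the locus into primary and secondary", {
  gene <- make_test_gene(7L, exon_lengths = c(120, 260, 300, 280, 255, 260),
                         intron_lengths = rep(25, 5), flank = 50L)
  glen <- diff(gene_span(gene))      # 1600
  spec <- transgene_spec("g1", deletions = list(c(173L, 529L), c(1250L, glen)))
  tg <- build_transgene(gene, spec)
  reg <- derive_regions(gene, tg)
  sec <- reg[reg$role == "secondary_only", ]
  expect_equal(nrow(sec), 2L)
  prim <- reg[reg$role == "primary_capable" & !reg$subregion, ]
  # partition: primary + secondary tile the span exactly, no overlap
  parts <- rbind(sec[, c("start", "end")], prim[, c("start", "end")])
  parts <- parts[order(parts$start), ]
  expect_equal(parts$start[1], gene_span(gene)[1])
  expect_equal(parts$end[nrow(parts)], gene_span(gene)[2])
  expect_true(all(parts$start[-1] == parts$end[-nrow(parts)]))
  # 5' sub-region runs from transcription start to the first intron
  five <- reg[reg$subregion, ]
  expect_equal(unname(unlist(five[, c("start", "end")])),
               unname(c(gene_span(gene)[1], gene_introns(gene)[1, "start"])))
})

test_that("a no-edit transgene induces no secondary regions", {
  gene <- make_test_gene(8L)
  tg <- build_transgene(gene, transgene_spec("g1"))
  reg <- derive_regions(gene, tg)
  expect_equal(sum(reg$role == "secondary_only"), 0L)
})

test_that("a foreign replacement adds a third secondary and a foreign region", {
  gene <- make_test_gene(9L, exon_lengths = c(120, 260, 300, 280, 255, 260),
                         intron_lengths = rep(25, 5), flank = 50L)
  glen <- diff(gene_span(gene))
  spec <- transgene_spec(
    "g1", deletions = list(c(173L, 529L), c(1250L, glen)),
    replacements = list(list(interval = c(625L, 1010L),
                             seq = strrep("ACGT", 99), name = "k_insert")))
  tg <- build_transgene(gene, spec)
  reg <- derive_regions(gene, tg)
  expect_equal(sum(reg$role == "secondary_only"), 3L)
  expect_equal(sum(reg$role == "foreign"), 1L)
  expect_identical(reg$name[reg$role == "foreign"], "k_insert")
  expect_identical(reg$reference_id[reg$role == "foreign"], tg$transgene_id)
})

test_that("spliced_sequence concatenates exons and places junctions", {
  # single exon: mRNA equals the genomic span, no junctions
  g1 <- make_test_gene(10L, exon_lengths = 120, intron_lengths = integer(0))
  ss1 <- spliced_sequence(g1)
  sp <- gene_span(g1)
  expect_identical(ss1$seq, substr(g1$sequence, sp[1] + 1, sp[2]))
  expect_length(ss1$junctions, 0)

  # five introns give five junctions
  g5 <- make_test_gene(11L, exon_lengths = rep(100, 6),
                       intron_lengths = rep(25, 5))
  expect_length(spliced_sequence(g5)$junctions, 5)

  # random model equals the direct exon-substring concatenation oracle
  for (seed in 1:5) {
    g <- make_test_gene(seed + 20L)
    ss <- spliced_sequence(g)
    oracle <- paste(vapply(seq_len(nrow(g$exons)), function(i)
      substr(g$sequence, g$exons[i, "start"] + 1, g$exons[i, "end"]),
      character(1)), collapse = "")
    expect_identical(ss$seq, oracle)
    # mRNA -> genomic mapping is consistent with the oracle
    pos <- c(0L, ss$junctions, nchar(ss$seq) - 1L)
    for (p in pos) {
      gpos <- mrna_to_genomic(g, p)
      expect_identical(substr(g$sequence, gpos + 1, gpos + 1),
                       substr(ss$seq, p + 1, p + 1))
    }
  }
})

test_that("gene model and regions survive GFF3/BED/YAML round trips", {
  gene <- make_test_gene(30L)
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "g.gff3"); fa <- file.path(dir, "g.fa")
  write_gene_gff3(gene, gff)
  write_fasta(c(chr1 = gene$sequence), fa)
  back <- read_gene_gff3(gff, fa)
  expect_identical(back$exons, gene$exons)
  expect_identical(back$sequence, gene$sequence)
  expect_identical(back$coding_strand, gene$coding_strand)

  spec <- transgene_spec("g1", deletions = list(c(10L, 50L)),
                         replacements = list(list(interval = c(60L, 80L),
                                                  seq = "ACGTACGT",
                                                  name = "ins")),
                         linearization_offset = 12L)
  yml <- file.path(dir, "spec.yaml")
  write_transgene_spec(spec, yml)
  back_spec <- read_transgene_spec(yml)
  expect_equal(back_spec$deletions, spec$deletions)
  expect_equal(back_spec$replacements[[1]]$seq, "ACGTACGT")
  expect_equal(back_spec$linearization_offset, 12L)

  tg <- build_transgene(gene, transgene_spec("g1", deletions = list(c(30L, 60L))))
  reg <- derive_regions(gene, tg)
  bed <- file.path(dir, "r.bed")
  write_regions_bed(reg, bed)
  lines <- readLines(bed)
  expect_equal(length(lines), nrow(reg))
  f <- strsplit(lines[1], "\t")[[1]]
  expect_identical(as.integer(f[2:3]), c(reg$start[1], reg$end[1]))
})
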