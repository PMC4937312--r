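test_that("long-read length filter is strictly greater-than", {
  r <- data.frame(read_id = c("a", "b", "c"),
                  seq = c(strrep("A", 60), strrep("C", 61), strrep("G", 100)),
                  stringsAsFactors = FALSE)
  kept <- filter_long_reads(r)
  expect_identical(kept$read_id, c("b", "c"))
  expect_equal(nrow(filter_long_reads(r[0, ])), 0L)
  all100 <- r[rep(3, 5), ]
  expect_identical(filter_long_reads(all100), all100)
})

test_that("reads from the spliced mRNA gap exactly at overlapped introns", {
  gene <- make_test_gene(50L, exon_lengths = c(80, 90, 80),
                         intron_lengths = c(25, 25))
  ss <- spliced_sequence(gene)
  # 100-mer over junction 1 only
  j <- ss$junctions[1]
  r1 <- substr(ss$seq, j - 49, j + 50)
  al <- align_long(data.frame(read_id = "r1", seq = r1), gene)
  expect_true(al$aligned)
  expect_identical(al$strand, "+")
  expect_equal(al$gap_mask, 1L)
  expect_equal(al$n_gaps, 1L)
  bl <- alignment_blocks(al, gene)[[1]]
  intr <- gene_introns(gene)
  sp <- gene_span(gene)
  expect_equal(unname(bl$gaps[1, ]), unname(intr[1, ] - sp[1]))

  # one substituted base: same projection, one mismatch
  r2 <- r1
  substr(r2, 25, 25) <- ifelse(substr(r2, 25, 25) == "A", "G", "A")
  al2 <- align_long(data.frame(read_id = "r2", seq = r2), gene)
  expect_true(al2$aligned)
  expect_equal(al2$mismatches, 1L)
  expect_equal(al2$span_start, al$span_start)
  expect_equal(al2$gap_mask, al$gap_mask)

  # two substitutions: no alignment within one mismatch
  r3 <- r2
  substr(r3, 60, 60) <- ifelse(substr(r3, 60, 60) == "C", "T", "C")
  al3 <- align_long(data.frame(read_id = "r3", seq = r3), gene)
  expect_false(al3$aligned)
})

test_that("align_long agrees with the exhaustive isoform/offset oracle", {
  gene <- make_test_gene(51L, exon_lengths = c(120, 150, 120),
                         intron_lengths = c(25, 25), flank = 10L)
  sp <- gene_span(gene)
  pre <- substr(gene$sequence, sp[1] + 1, sp[2])
  ss <- spliced_sequence(gene)
  set.seed(99)
  reads <- character(0)
  # genomic fragments, spliced fragments (plain and reverse-complemented),
  # and mutated copies
  for (i in 1:8) {
    a <- sample(1:(nchar(pre) - 80), 1)
    reads <- c(reads, substr(pre, a, a + 79))
    b <- sample(1:(nchar(ss$seq) - 80), 1)
    reads <- c(reads, substr(ss$seq, b, b + 79))
  }
  reads <- c(reads, rc_chr(reads[1:6]))
  mut <- vapply(reads[1:6], function(s) {
    p <- sample(10:70, 1)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, p, p))[sample(3, 1)]
    s
  }, character(1), USE.NAMES = FALSE)
  reads <- c(reads, mut)
  al <- align_long(data.frame(read_id = sprintf("o%02d", seq_along(reads)),
                              seq = reads), gene)
  for (i in seq_along(reads)) {
    want <- brute_align(reads[i], gene)
    expect_equal(al$mismatches[i], want$mm, info = paste("read", i))
    expect_equal(al$n_gaps[i], want$gaps, info = paste("read", i))
    expect_equal(al$span_start[i], want$start, info = paste("read", i))
    expect_identical(al$strand[i], want$strand, info = paste("read", i))
  }
})

test_that("splice classification follows the 4-bp rule", {
  gene <- make_test_gene(52L, exon_lengths = c(80, 90, 80),
                         intron_lengths = c(25, 25))
  sp <- gene_span(gene)
  intr <- gene_introns(gene)
  a <- intr[1, "start"] - sp[1]; b <- intr[1, "end"] - sp[1]
  mk <- function(span_start, span_end, gap_mask) {
    data.frame(read_id = "x", aligned = TRUE, strand = "+",
               span_start = span_start, span_end = span_end,
               gap_mask = gap_mask, n_gaps = 0L, mismatches = 0L,
               length = 50L, seq = "A", stringsAsFactors = FALSE)
  }
  # gap exactly at the intron with both flanks: spliced
  expect_identical(classify_splice(mk(a - 20L, b + 20L, 1L), gene, 1), "spliced")
  # contiguous read through the intron (25 bp > 4 bp): unspliced
  expect_identical(classify_splice(mk(a - 20L, b + 20L, 0L), gene, 1), "unspliced")
  # 5 bp incursion touching one flank only: not a candidate
  expect_identical(classify_splice(mk(a - 20L, a + 5L, 0L), gene, 1),
                   "not_candidate")
  # 4 bp incursion without a gap: not a candidate either
  expect_identical(classify_splice(mk(a - 20L, a + 4L, 0L), gene, 1),
                   "not_candidate")
  # read away from the intron: not a candidate
  expect_identical(classify_splice(mk(b + 5L, b + 60L, 0L), gene, 1),
                   "not_candidate")
  expect_error(classify_splice(mk(0L, 10L, 0L), gene, 7), "intron not in gene")

  # partition: every intron-overlapping read lands in exactly one class
  set.seed(5)
  spans <- data.frame(s = sample(0:(b + 30), 50, replace = TRUE))
  spans$e <- spans$s + sample(30:80, 50, replace = TRUE)
  alns <- do.call(rbind, lapply(seq_len(50), function(i)
    mk(spans$s[i], spans$e[i], sample(0:1, 1))))
  cls <- classify_splice(alns, gene, 1)
  expect_true(all(cls %in% c("spliced", "unspliced", "not_candidate")))
})

test_that("splice rates summarize candidate counts per intron", {
  gene <- make_test_gene(53L, exon_lengths = c(80, 90, 80),
                         intron_lengths = c(25, 25))
  sp <- gene_span(gene)
  intr <- gene_introns(gene)
  a <- intr[1, "start"] - sp[1]; b <- intr[1, "end"] - sp[1]
  rows <- lapply(1:10, function(i) data.frame(
    read_id = sprintf("r%d", i), aligned = TRUE, strand = "+",
    span_start = a - 10L, span_end = b + 10L,
    gap_mask = if (i <= 9) 1L else 0L, n_gaps = 0L, mismatches = 0L,
    length = 45L, seq = "A", stringsAsFactors = FALSE))
  al <- do.call(rbind, rows)
  sr <- splice_rates(al, gene)
  expect_equal(sr$splice_rate[1], 0.9)
  expect_equal(sr$n_spliced[1], 9L)
  expect_equal(sr$n_unspliced[1], 1L)
  # intron 2 has no candidates
  expect_true(is.na(sr$splice_rate[2]))
  expect_equal(attr(sr, "mean_rate"), 0.9)
})

test_that("antisense introns are detected and sense-equal gaps excluded", {
  # gene whose exon carries a planted antisense-strand GT...AG intron
  gene <- make_test_gene(54L, exon_lengths = c(100, 200, 100),
                         intron_lengths = c(25, 25))
  sp <- gene_span(gene)
  pre <- substr(gene$sequence, sp[1] + 1, sp[2])
  # plant antisense donor/acceptor inside exon 2 at gene-relative [200, 228)
  substr(pre, 201, 202) <- "CT"
  substr(pre, 227, 228) <- "AC"
  seq2 <- gene$sequence
  substr(seq2, sp[1] + 201, sp[1] + 202) <- "CT"
  substr(seq2, sp[1] + 227, sp[1] + 228) <- "AC"
  gene$sequence <- seq2
  G <- nchar(pre)
  A <- rc_chr(pre)
  # antisense read spliced over the planted intron: A-coordinates of the gap
  i0 <- G - 228
  r <- paste0(substr(A, i0 - 39, i0), substr(A, i0 + 29, i0 + 68))
  res <- detect_antisense_introns(data.frame(read_id = "as1", seq = r), gene)
  expect_equal(nrow(res), 1L)
  expect_equal(unname(unlist(res[1, c("start", "end")])), c(200L, 228L))
  expect_equal(res$n_support, 1L)
  expect_equal(res$n_support_sense_retained, 1L)

  # sense-only reads produce nothing
  sr <- data.frame(read_id = "s1", seq = substr(pre, 10, 109))
  expect_equal(nrow(detect_antisense_introns(sr, gene)), 0L)

  # a gap identical to a sense intron is excluded even with matching motifs
  intr <- gene_introns(gene)
  ia <- intr[1, "start"] - sp[1]; ib <- intr[1, "end"] - sp[1]
  seq3 <- gene$sequence
  substr(seq3, sp[1] + ia + 1, sp[1] + ia + 2) <- "CT"
  substr(seq3, sp[1] + ib - 1, sp[1] + ib) <- "AC"
  gene3 <- gene
  gene3$sequence <- seq3
  pre3 <- substr(seq3, sp[1] + 1, sp[2])
  A3 <- rc_chr(pre3)
  j0 <- G - ib
  r3 <- paste0(substr(A3, j0 - 39, j0), substr(A3, j0 + 26, j0 + 65))
  res3 <- detect_antisense_introns(data.frame(read_id = "as2", seq = r3), gene3)
  expect_false(any(res3$start == ia & res3$end == ib))
})

test_that("strand coverage counts aligned blocks only", {
  gene <- make_test_gene(55L, exon_lengths = c(80, 90, 80),
                         intron_lengths = c(25, 25))
  mk <- function(id, s, e, mask, strand = "+") data.frame(
    read_id = id, aligned = TRUE, strand = strand, span_start = s,
    span_end = e, gap_mask = mask, n_gaps = 0L, mismatches = 0L,
    length = e - s, seq = "A", stringsAsFactors = FALSE)
  al <- mk("u1", 10L, 110L, 0L)
  cov <- strand_coverage(al, gene)
  expect_equal(sum(cov$plus), 100L)
  expect_true(all(cov$plus[11:110] == 1L))
  expect_equal(sum(cov$minus), 0L)
  # two identical reads stack to depth 2; gapped reads contribute nothing in
  # the gap, and totals equal summed block lengths
  intr <- gene_introns(gene)
  sp <- gene_span(gene)
  a <- intr[1, "start"] - sp[1]; b <- intr[1, "end"] - sp[1]
  al2 <- rbind(al, al, mk("g1", a - 10L, b + 10L, 1L, "-"))
  cov2 <- strand_coverage(al2, gene)
  expect_equal(max(cov2$plus), 2L)
  expect_equal(sum(cov2$minus), 20L)
  expect_equal(sum(cov2$minus[(a + 1):b]), 0L)
})
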