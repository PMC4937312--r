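reads_df <- function(seqs, prefix = "r") {
  data.frame(read_id = sprintf("%s%03d", prefix, seq_along(seqs)), seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("length filter keeps the inclusive 17-25 window", {
  r <- reads_df(c(strrep("A", 16), strrep("C", 17), strrep("G", 23),
                  strrep("T", 25), strrep("A", 26)))
  kept <- length_filter(r)
  expect_identical(nchar(kept$seq), c(17L, 23L, 25L))
  expect_equal(nrow(length_filter(r[0, ])), 0L)
  all23 <- reads_df(rep(strrep("A", 23), 5))
  expect_identical(length_filter(all23), all23)
  expect_error(length_filter(r, min = 25, max = 17), "min > max")
})

test_that("exact_match reports planted forward and reverse hits", {
  set.seed(42)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  fwd <- substr(ref, 101, 123)
  rev <- rc_chr(substr(ref, 301, 323))
  aln <- exact_match(reads_df(c(fwd, rev)), c(refA = ref))
  a1 <- aln[aln$read_id == "r001", ]
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$start, 100L)
  expect_identical(a1$strand, "+")
  a2 <- aln[aln$read_id == "r002", ]
  expect_equal(a2$start, 300L)
  expect_identical(a2$strand, "-")
})

test_that("ambiguous-base reads are skipped with a warning", {
  expect_warning(aln <- exact_match(reads_df(c("ACGTNACGTACGTACGTACGTAC")),
                                    c(refA = strrep("ACGT", 50))),
                 "ambiguous")
  expect_equal(nrow(aln), 0L)
})

test_that("exact_match equals the naive sliding-window oracle", {
  set.seed(7)
  refs <- c(refA = paste(sample(c("A", "T", "G", "C"), 10000, replace = TRUE,
                                prob = c(.36, .36, .14, .14)), collapse = ""),
            refB = paste(sample(c("A", "T", "G", "C"), 3000, replace = TRUE,
                                prob = c(.36, .36, .14, .14)), collapse = ""))
  # mix of planted substrings (guaranteed hits, some multimapping) and
  # random 23-mers (mostly misses)
  starts <- sample(1:9000, 60)
  planted <- substring(refs[["refA"]], starts, starts + 22)
  random <- vapply(1:60, function(i)
    paste(sample(c("A", "T", "G", "C"), 23, replace = TRUE), collapse = ""),
    character(1))
  reads <- reads_df(c(planted, rc_chr(planted[1:10]), random))
  aln <- exact_match(reads, refs)
  for (i in seq_len(nrow(reads))) {
    got <- aln[aln$read_id == reads$read_id[i],
               c("reference_id", "start", "strand")]
    rownames(got) <- NULL
    want <- naive_scan(reads$seq[i], refs)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("read", i))
  }
  # multimap bookkeeping equals the total hit count per read
  tab <- table(aln$read_id)
  expect_true(all(aln$multimap == as.integer(tab[aln$read_id])))
})

test_that("two-round alignment labels contaminants first", {
  set.seed(8)
  cont <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  targ <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  shared <- substr(cont, 51, 73)
  # read matching both sets is labelled contaminant and kept out of round 2
  targ2 <- paste0(substr(targ, 1, 200), shared, substr(targ, 201, 400))
  r <- reads_df(c(shared, substr(targ, 101, 123), strrep("ACT", 8)))
  res <- two_round_align(r, c(cont = cont), c(targ = targ2))
  expect_identical(res$read_status$status, c("contaminant", "mapped", "unmapped"))
  expect_false("r001" %in% res$alignments$read_id)
  expect_error(two_round_align(r, c(cont = cont), character(0)), "empty")
})

test_that("region counting respects overlap and conserves totals", {
  regions <- data.frame(
    name = c("left", "right"), reference_id = "chr1",
    start = c(0L, 100L), end = c(100L, 200L),
    role = "primary_capable", subregion = FALSE, stringsAsFactors = FALSE)
  attr(regions, "coding_strand") <- "+"
  aln <- data.frame(
    read_id = c("a", "b", "c"), reference_id = "chr1",
    start = c(10L, 90L, 150L), length = c(23L, 23L, 23L),
    strand = c("+", "-", "-"), multimap = 1L, seq = strrep("A", 23),
    stringsAsFactors = FALSE)
  rc <- count_regions(aln, regions)
  left <- rc[rc$region == "left" & rc$length == 23, ]
  right <- rc[rc$region == "right" & rc$length == 23, ]
  # "a" wholly in left; "b" straddles and counts in both; "c" in right
  expect_equal(left$sense_count + left$antisense_count, 2L)
  expect_equal(right$sense_count + right$antisense_count, 2L)
  expect_equal(left$sense_count, 1L)
  # overlapped bases: "b" contributes 10 to left and 13 to right
  expect_equal(left$antisense_bases, 10L)
  expect_equal(right$antisense_bases, 13L + 23L)
  # conservation over a disjoint region set that covers all alignments
  expect_equal(sum(rc$sense_count + rc$antisense_count) - 1L, nrow(aln))
})

test_that("antisense ratio handles edge cases and scale invariance", {
  counts <- data.frame(region = c("x", "y", "z"), role = "primary_capable",
                       length = 23L, sense_count = c(0L, 10L, 0L),
                       antisense_count = c(10L, 10L, 0L),
                       sense_bases = 0L, antisense_bases = 0L,
                       stringsAsFactors = FALSE)
  r <- antisense_ratio(counts)
  expect_equal(r$antisense_ratio[r$region == "x"], 1.0)
  expect_equal(r$antisense_ratio[r$region == "y"], 0.5)
  expect_true(is.na(r$antisense_ratio[r$region == "z"]))
  scaled <- counts
  scaled$sense_count <- scaled$sense_count * 7L
  scaled$antisense_count <- scaled$antisense_count * 7L
  expect_equal(antisense_ratio(scaled)$antisense_ratio, r$antisense_ratio)
})

test_that("length histograms conserve alignment counts and report the mode", {
  set.seed(9)
  lens <- sample(17:25, 200, replace = TRUE, prob = c(rep(0.05, 6), 0.5, 0.1, 0.1))
  aln <- data.frame(read_id = sprintf("r%03d", 1:200), reference_id = "chr1",
                    start = sample(0:400, 200, replace = TRUE), length = lens,
                    strand = sample(c("+", "-"), 200, replace = TRUE),
                    multimap = 1L, seq = "A", stringsAsFactors = FALSE)
  h <- length_histogram(aln)
  expect_equal(sum(h$count), 200L)
  expect_equal(length_mode(h), as.integer(names(which.max(table(lens)))))
})

test_that("junction and intron reads are classified disjointly", {
  gene <- make_test_gene(40L, exon_lengths = c(80, 90, 80),
                         intron_lengths = c(25, 25))
  ss <- spliced_sequence(gene)
  sp <- gene_span(gene)
  # 23-mer crossing junction 1 with a 12|11 split, absent from the genome
  j <- ss$junctions[1]
  jr <- substr(ss$seq, j - 11, j + 11)
  # 23-mer wholly inside intron 1
  intr <- gene_introns(gene)
  ir_start <- intr[1, "start"] + 1
  ir <- substr(gene$sequence, ir_start + 1, ir_start + 23)
  # exonic read matches both genome and mRNA: neither junction nor intron
  ex <- substr(gene$sequence, sp[1] + 11, sp[1] + 33)
  res <- classify_junction_intron(reads_df(c(jr, rc_chr(ir), ex)), gene)
  expect_identical(res$read_class$class, c("junction", "intron", "none"))
  expect_equal(res$junction$sense_count[1], 1L)
  expect_equal(res$intron$antisense_count[1], 1L)
  # junction requires >= 4 nt on each side: a 3|20 split is not a junction read
  jr3 <- substr(ss$seq, j - 2, j + 20)
  res3 <- classify_junction_intron(reads_df(jr3), gene)
  expect_identical(res3$read_class$class, "none")
  # intron-less gene yields empty tables
  g0 <- make_test_gene(41L, exon_lengths = 150, intron_lengths = integer(0))
  res0 <- classify_junction_intron(reads_df(jr), g0)
  expect_equal(nrow(res0$junction), 0L)
})
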