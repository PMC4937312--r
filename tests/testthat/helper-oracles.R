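# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (string scans, exhaustive enumeration) and
# share no code with the implementation paths they check.

rc_chr <- function(x) {
  unname(chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1))))
}

# brute-force substring scan: every exact occurrence of read (or its
# reverse complement) in every reference, both strands
naive_scan <- function(read, references) {
  hits <- list()
  for (ref in names(references)) {
    subj <- references[[ref]]
    L <- nchar(read)
    n <- nchar(subj) - L + 1L
    if (n < 1L) next
    starts <- seq_len(n)
    wins <- substring(subj, starts, starts + L - 1L)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc_chr(read)
      at <- which(wins == pat)
      if (length(at))
        hits[[length(hits) + 1L]] <- data.frame(
          reference_id = ref, start = at - 1L, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(reference_id = character(0), start = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$reference_id, out$start, out$strand), , drop = FALSE]
}

# independent string-splice oracle for transgene construction
splice_oracle <- function(parent_seq, deletions, replacements = list()) {
  edits <- c(lapply(deletions, function(d) list(a = d[1], b = d[2], s = "")),
             lapply(replacements, function(r)
               list(a = r$interval[1], b = r$interval[2], s = r$seq)))
  edits <- edits[order(vapply(edits, `[[`, numeric(1), "a"))]
  out <- ""
  cur <- 0
  for (e in edits) {
    out <- paste0(out, substr(parent_seq, cur + 1, e$a), e$s)
    cur <- e$b
  }
  paste0(out, substr(parent_seq, cur + 1, nchar(parent_seq)))
}

# exhaustive all-isoform, all-offset, both-strand aligner for small genes:
# returns the best (mismatches, n_gaps, genomic start) alignment
brute_align <- function(read, gene, max_mm = 1L) {
  sp <- gene_span(gene)
  pre <- substr(gene$sequence, sp[1] + 1, sp[2])
  intr <- gene_introns(gene)
  n <- nrow(intr)
  ia <- intr[, "start"] - sp[1]; ib <- intr[, "end"] - sp[1]
  best <- NULL
  for (mask in seq_len(2^n) - 1L) {
    spliced <- if (n) as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L))) else logical(0)
    iso <- pre
    for (i in rev(which(spliced)))
      iso <- paste0(substr(iso, 1, ia[i]), substr(iso, ib[i] + 1, nchar(iso)))
    # genomic position lookup for isoform coordinates
    kept <- setdiff(seq_len(nchar(pre)) - 1L,
                    unlist(lapply(which(spliced), function(i) ia[i]:(ib[i] - 1L))))
    L <- nchar(read)
    if (nchar(iso) < L) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc_chr(read)
      pv <- strsplit(pat, "")[[1]]
      for (off in 0:(nchar(iso) - L)) {
        wv <- strsplit(substr(iso, off + 1, off + L), "")[[1]]
        mm <- sum(pv != wv)
        if (mm > max_mm) next
        gpos <- kept[(off + 1):(off + L)]
        span <- c(gpos[1], gpos[L] + 1L)
        gaps <- sum(vapply(seq_len(n), function(i)
          spliced[i] && span[1] < ia[i] && span[2] > ib[i], logical(1)))
        key <- list(mm = mm, gaps = gaps, start = span[1], end = span[2],
                    strand = strand)
        if (is.null(best) ||
            mm < best$mm ||
            (mm == best$mm && gaps < best$gaps) ||
            (mm == best$mm && gaps == best$gaps && span[1] < best$start) ||
            (mm == best$mm && gaps == best$gaps && span[1] == best$start &&
             strand == "+" && best$strand == "-"))
          best <- key
      }
    }
  }
  best
}

# deterministic random gene model fixture
make_test_gene <- function(seed = 1L, exon_lengths = c(60, 80, 70),
                           intron_lengths = c(25, 25), flank = 20L,
                           gene_id = "g1", reference_id = "chr1") {
  set.seed(seed)
  bases <- c("A", "T", "G", "C")
  rand <- function(n) paste(sample(bases, n, replace = TRUE,
                                   prob = c(.36, .36, .14, .14)), collapse = "")
  pieces <- character(0)
  exons <- NULL
  pos <- 0L
  for (i in seq_along(exon_lengths)) {
    exons <- rbind(exons, c(pos, pos + exon_lengths[i]))
    pieces <- c(pieces, rand(exon_lengths[i]))
    pos <- pos + exon_lengths[i]
    if (i <= length(intron_lengths)) {
      pieces <- c(pieces, paste0("GT", rand(intron_lengths[i] - 4L), "AG"))
      pos <- pos + intron_lengths[i]
    }
  }
  seq <- paste0(rand(flank), paste(pieces, collapse = ""), rand(flank))
  colnames(exons) <- c("start", "end")
  gene_model(gene_id, reference_id, exons + flank, seq)
}

# scaled-down simulation config for fast tests (extra overrides are
# deep-merged over the scaled-down base)
small_cfg <- function(seed = 3L, ...) {
  base <- list(
    seed = seed,
    contigs = list(background_length = 20000L),
    smallrna = list(counts = list(primary = 1500L, junction = 120L,
                                  background = 4000L, contaminant = 300L,
                                  structural = 300L, feeding_vector = 600L,
                                  feeding_induced = 400L)),
    longrna = list(n_reads = 1200L))
  read_sim_config(overrides = sirnascope:::merge_config(base, list(...)))
}
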