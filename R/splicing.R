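#' Long-read alignment and splice-rate estimation
#'
#' Long reads are aligned against the enumerated isoform set of a gene model
#' (every retain/splice combination of its introns, at most 8, plus the
#' plain genomic sequence, which is the all-retained isoform) on both
#' strands, allowing up to one mismatch. The best alignment (fewest
#' mismatches, then fewest gaps, then leftmost start, then forward strand)
#' is projected back to genomic blocks and gaps. Per intron, a read is
#' called spliced when its alignment gaps exactly at the intron with at
#' least one aligned base on each flank, un-spliced when it covers both
#' flanks and aligns to more than four basepairs of the intron, and is
#' otherwise not a candidate.
#'
#' @name splicing
NULL

#' Filter long reads by minimum length (strict)
#'
#' Reads strictly longer than `min_len` are kept (a 60 nt read is dropped,
#' a 61 nt read kept).
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param min_len strict lower bound in nt (default 60).
#' @export
filter_long_reads <- function(reads, min_len = 60L) {
  reads[nchar(reads$seq) > min_len, , drop = FALSE]
}

# Enumerate the 2^n retain/splice isoforms of a gene (gene-relative
# coordinates; intron bit i set <=> intron i RETAINED). Each isoform carries
# its sequence and a segment table mapping isoform -> genomic positions.
isoform_set <- function(gene) {
  sp <- gene_span(gene)
  glen <- sp[2L] - sp[1L]
  pre <- gene_pre_mrna(gene)
  intr <- gene_introns(gene)
  n <- nrow(intr)
  if (n > 8L) stop("isoform enumeration supports at most 8 introns")
  ia <- intr[, "start"] - sp[1L]; ib <- intr[, "end"] - sp[1L]
  lapply(seq_len(2^n) - 1L, function(mask) {
    retained <- if (n) as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L)))) else logical(0)
    # kept genomic pieces: whole span minus spliced introns
    cuts_a <- ia[!retained]; cuts_b <- ib[!retained]
    g_start <- c(0L, cuts_b); g_end <- c(cuts_a, glen)
    keep <- g_end > g_start
    g_start <- g_start[keep]; g_end <- g_end[keep]
    w <- g_end - g_start
    iso_start <- cumsum(c(0L, w[-length(w)]))
    list(mask = mask, retained = retained,
         seq = paste(subseq_chr(pre, g_start, g_end), collapse = ""),
         segs = data.frame(iso_start = iso_start, iso_end = iso_start + w,
                           g_start = g_start))
  })
}

# Vectorized projection of isoform-coordinate hits [s0, s0+len) to genomic
# spans and the intron set each alignment gaps over.
project_iso_hits <- function(iso, s0, len, intr_a, intr_b) {
  segs <- iso$segs
  gpos <- function(p) {   # genomic positions of isoform positions (0-based)
    i <- findInterval(p, segs$iso_start)
    segs$g_start[i] + (p - segs$iso_start[i])
  }
  span_start <- gpos(s0)
  span_end <- gpos(s0 + len - 1L) + 1L
  gap_mask <- integer(length(s0))
  if (length(intr_a)) {
    for (i in which(!iso$retained)) {
      crossing <- span_start < intr_a[i] & span_end > intr_b[i]
      gap_mask <- gap_mask + bitwShiftL(1L, i - 1L) * crossing
    }
  }
  list(span_start = span_start, span_end = span_end,
       gap_mask = as.integer(gap_mask))
}

count_bits <- function(mask) {
  n <- integer(length(mask))
  for (b in 0:7) n <- n + (bitwAnd(mask, bitwShiftL(1L, b)) > 0)
  n
}

#' Align long reads to a gene model's isoform set
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param gene a `GeneModel` with at most 8 introns.
#' @param max_mismatch maximum mismatches tolerated (default 1).
#' @return data.frame of class `LongReadAlignment` (gene-relative, 0-based
#'   half-open coordinates): `read_id`, `aligned`, `strand`, `span_start`,
#'   `span_end`, `gap_mask` (bit i set = alignment gaps over intron i),
#'   `n_gaps`, `mismatches`, `length`, `seq`. Unaligned reads keep a row
#'   with `aligned = FALSE`.
#' @export
align_long <- function(reads, gene, max_mismatch = 1L) {
  stopifnot(inherits(gene, "GeneModel"))
  sp <- gene_span(gene)
  intr <- gene_introns(gene)
  intr_a <- intr[, "start"] - sp[1L]; intr_b <- intr[, "end"] - sp[1L]
  isos <- isoform_set(gene)
  n_reads <- nrow(reads)
  out <- data.frame(read_id = reads$read_id, aligned = FALSE,
                    strand = NA_character_, span_start = NA_integer_,
                    span_end = NA_integer_, gap_mask = NA_integer_,
                    n_gaps = NA_integer_, mismatches = NA_integer_,
                    length = nchar(reads$seq), seq = reads$seq,
                    stringsAsFactors = FALSE)
  if (!n_reads) {
    class(out) <- c("LongReadAlignment", class(out))
    return(out)
  }

  # flat hit accumulators (one projection batch per isoform x strand)
  acc <- list()
  push <- function(ridx, strand, iso, s0, mm) {
    p <- project_iso_hits(iso, s0, out$length[ridx], intr_a, intr_b)
    acc[[length(acc) + 1L]] <<- data.frame(
      ridx = ridx, strand = strand, span_start = p$span_start,
      span_end = p$span_end, gap_mask = p$gap_mask, mismatches = mm,
      stringsAsFactors = FALSE)
  }

  # all isoforms in one N-separated subject (exact matches cannot cross the
  # spacer); one fixed-width prefix PDict per strand, with the remaining
  # suffix verified by vectorized string comparison
  iso_len <- vapply(isos, function(i) nchar(i$seq), integer(1))
  iso_off <- cumsum(c(0L, iso_len[-length(iso_len)] + 1L))
  subj_chr <- paste(vapply(isos, `[[`, character(1), "seq"), collapse = "N")
  subj_all <- Biostrings::DNAString(subj_chr)
  lens <- out$length
  w <- min(lens)
  for (strand in c("+", "-")) {
    seqs_s <- if (strand == "+") reads$seq else revcomp_chr(reads$seq)
    pd <- Biostrings::PDict(substr(seqs_s, 1L, w))
    si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj_all))
    nh <- lengths(si)
    if (!sum(nh)) next
    j <- which(nh > 0L)
    ridx <- rep.int(j, nh[j])
    pos <- unlist(si[j], use.names = FALSE) - 1L
    L_r <- lens[ridx]
    ok <- pos + L_r <= nchar(subj_chr)
    ok[ok] <- substring(subj_chr, pos[ok] + w + 1L, pos[ok] + L_r[ok]) ==
      substring(seqs_s[ridx[ok]], w + 1L, L_r[ok])
    if (!any(ok)) next
    ridx <- ridx[ok]; pos <- pos[ok]
    iso_idx <- findInterval(pos, iso_off)
    s0 <- pos - iso_off[iso_idx]
    for (ii in unique(iso_idx)) {
      sel <- iso_idx == ii
      push(ridx[sel], strand, isos[[ii]], s0[sel], rep(0L, sum(sel)))
    }
  }
  hit_reads <- if (length(acc)) unique(unlist(lapply(acc, `[[`, "ridx"))) else integer(0)
  # mismatch-tolerant fallback for reads without an exact hit
  if (max_mismatch > 0L) {
    for (ridx in setdiff(seq_len(n_reads), hit_reads)) {
      pat_f <- Biostrings::DNAString(reads$seq[ridx])
      pat_r <- Biostrings::reverseComplement(pat_f)
      for (iso in isos) {
        if (nchar(iso$seq) < out$length[ridx]) next
        subj <- Biostrings::DNAString(iso$seq)
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") pat_f else pat_r
          m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
          if (!length(m)) next
          st <- Biostrings::start(m)
          mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st)
          keep <- mm <= max_mismatch
          if (any(keep))
            push(rep(ridx, sum(keep)), strand, iso, st[keep] - 1L, mm[keep])
        }
      }
    }
  }

  if (length(acc)) {
    h <- do.call(rbind, acc)
    h <- h[!duplicated(h[c("ridx", "strand", "span_start", "span_end",
                           "gap_mask", "mismatches")]), , drop = FALSE]
    h$n_gaps <- count_bits(h$gap_mask)
    o <- order(h$ridx, h$mismatches, h$n_gaps, h$span_start, h$strand)
    h <- h[o, , drop = FALSE]
    best <- h[!duplicated(h$ridx), , drop = FALSE]
    r <- best$ridx
    out$aligned[r] <- TRUE
    out$strand[r] <- best$strand
    out$span_start[r] <- best$span_start
    out$span_end[r] <- best$span_end
    out$gap_mask[r] <- best$gap_mask
    out$n_gaps[r] <- best$n_gaps
    out$mismatches[r] <- best$mismatches
  }
  class(out) <- c("LongReadAlignment", class(out))
  out
}

#' Genomic blocks and gaps of long-read alignments
#'
#' @param alignments `LongReadAlignment` rows.
#' @param gene the `GeneModel` they were aligned to.
#' @return list per alignment with `blocks` and `gaps` (0-based half-open,
#'   gene-relative matrices).
#' @export
alignment_blocks <- function(alignments, gene) {
  sp <- gene_span(gene)
  intr <- gene_introns(gene)
  ia <- intr[, "start"] - sp[1L]; ib <- intr[, "end"] - sp[1L]
  lapply(seq_len(nrow(alignments)), function(r) {
    if (!alignments$aligned[r]) return(list(blocks = iv(integer(0), integer(0)),
                                            gaps = iv(integer(0), integer(0))))
    s <- alignments$span_start[r]; e <- alignments$span_end[r]
    mask <- alignments$gap_mask[r]
    gi <- if (nrow(intr)) which(bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(intr)) - 1L)) > 0) else integer(0)
    ga <- ia[gi]; gb <- ib[gi]
    o <- order(ga)
    ga <- ga[o]; gb <- gb[o]
    starts <- c(s, gb); ends <- c(ga, e)
    list(blocks = iv(starts, ends), gaps = iv(ga, gb))
  })
}

#' Classify alignments against one intron
#'
#' Candidates must align to the exon regions on both flanks of the intron.
#' A candidate is `spliced` when the alignment gaps exactly at the intron,
#' `unspliced` when it aligns to more than four basepairs of the intron;
#' reads entering the intron by 1-4 bp without a gap, or touching only one
#' flank, are `not_candidate`.
#'
#' @param alignments a `LongReadAlignment` data.frame.
#' @param gene the `GeneModel`.
#' @param intron_index which intron (1-based).
#' @param max_incursion maximum tolerated intron incursion for a read to
#'   stay out of the un-spliced class (default 4 bp).
#' @return Character vector over alignments: `spliced`, `unspliced` or
#'   `not_candidate`.
#' @export
classify_splice <- function(alignments, gene, intron_index,
                            max_incursion = 4L) {
  sp <- gene_span(gene)
  intr <- gene_introns(gene)
  if (intron_index < 1L || intron_index > nrow(intr))
    stop("intron not in gene model")
  a <- intr[intron_index, "start"] - sp[1L]
  b <- intr[intron_index, "end"] - sp[1L]
  res <- rep("not_candidate", nrow(alignments))
  ok <- alignments$aligned %in% TRUE
  both <- ok & alignments$span_start < a & alignments$span_end > b
  gap <- both & bitwAnd(alignments$gap_mask, bitwShiftL(1L, intron_index - 1L)) > 0
  gap[is.na(gap)] <- FALSE
  intron_bases <- pmax(0L, pmin(alignments$span_end, b) -
                         pmax(alignments$span_start, a))
  res[both & gap] <- "spliced"
  res[both & !gap & intron_bases > max_incursion] <- "unspliced"
  res
}

#' Per-intron splice rates
#'
#' For each intron, counts spliced and un-spliced candidates and reports
#' `splice_rate = n_spliced / (n_spliced + n_unspliced)` (`NA` with no
#' candidates), plus the unweighted mean over introns. Antisense long reads
#' retain sense introns by construction in bidirectionally transcribed
#' loci, so rates are computed on sense-strand alignments by default.
#'
#' @param alignments a `LongReadAlignment` data.frame.
#' @param gene the `GeneModel`.
#' @param strand `"sense"` (default: alignments on the coding strand) or
#'   `"both"`.
#' @return data.frame of class `SpliceCallSummary` (`intron_index`,
#'   `n_spliced`, `n_unspliced`, `n_excluded_ambiguous`, `splice_rate`) with
#'   attribute `mean_rate`.
#' @export
splice_rates <- function(alignments, gene, strand = c("sense", "both")) {
  strand <- match.arg(strand)
  if (strand == "sense")
    alignments <- alignments[alignments$aligned %in% TRUE &
                               alignments$strand == gene$coding_strand, ,
                             drop = FALSE]
  intr <- gene_introns(gene)
  sp <- gene_span(gene)
  n <- nrow(intr)
  out <- data.frame(intron_index = seq_len(n), n_spliced = 0L,
                    n_unspliced = 0L, n_excluded_ambiguous = 0L,
                    splice_rate = NA_real_)
  for (i in seq_len(n)) {
    cls <- classify_splice(alignments, gene, i)
    a <- intr[i, "start"] - sp[1L]; b <- intr[i, "end"] - sp[1L]
    overlapping <- alignments$aligned %in% TRUE &
      alignments$span_start < b & alignments$span_end > a
    out$n_spliced[i] <- sum(cls == "spliced")
    out$n_unspliced[i] <- sum(cls == "unspliced")
    out$n_excluded_ambiguous[i] <- sum(overlapping & cls == "not_candidate")
    denom <- out$n_spliced[i] + out$n_unspliced[i]
    if (denom > 0) out$splice_rate[i] <- out$n_spliced[i] / denom
  }
  attr(out, "mean_rate") <- mean(out$splice_rate, na.rm = TRUE)
  class(out) <- c("SpliceCallSummary", class(out))
  out
}

#' Detect spliced antisense introns in antisense long reads
#'
#' Scans reads for a single novel gap on the antisense strand whose length
#' lies in `gap_range`, whose boundaries read GT...AG on the read's strand
#' (the canonical intron dinucleotides), and whose interval does not equal
#' any annotated sense intron. For each candidate the number of supporting
#' reads is reported, along with how many supporting reads retain (align
#' through) every sense intron overlapped by their footprint — splicing of
#' an antisense intron in reads that keep sense introns demonstrates
#' bidirectional transcription.
#'
#' @param reads data.frame with columns `read_id`, `seq` (sequences in read
#'   orientation; typically reads that failed sense-isoform alignment).
#' @param gene the `GeneModel`.
#' @param gap_range inclusive intron length window (default 18-35 nt).
#' @param min_flank minimum read bases on each side of the gap (default 5).
#' @param anchor prefix length used to seed the alignment (default 20).
#' @return data.frame: `start`, `end` (gene-relative genomic, 0-based
#'   half-open), `width`, `n_support`, `n_support_sense_retained`.
#' @export
detect_antisense_introns <- function(reads, gene, gap_range = c(18L, 35L),
                                     min_flank = 5L, anchor = 20L) {
  A <- revcomp_chr(gene_pre_mrna(gene))
  G <- nchar(A)
  sp <- gene_span(gene)
  intr <- gene_introns(gene)
  # candidate gaps on the antisense strand: GT ... AG within the window
  gt <- which(substring(A, 1:(G - 1L), 2:G) == "GT") - 1L   # 0-based
  cand <- list()
  for (i0 in gt) {
    for (g in seq(gap_range[1L], gap_range[2L])) {
      if (i0 + g > G) next
      if (substring(A, i0 + g - 1L, i0 + g) != "AG") next
      gen_a <- G - (i0 + g); gen_b <- G - i0
      is_sense <- nrow(intr) &&
        any(intr[, "start"] - sp[1L] == gen_a & intr[, "end"] - sp[1L] == gen_b)
      if (is_sense) next   # gap equal to a sense intron: not antisense
      cand[[length(cand) + 1L]] <- c(i0 = i0, g = g)
    }
  }
  hits <- list()
  if (length(cand) && nrow(reads)) {
    ci0 <- vapply(cand, `[[`, numeric(1), "i0")
    cg <- vapply(cand, `[[`, numeric(1), "g")
    subjA <- Biostrings::DNAString(A)
    for (r in seq_len(nrow(reads))) {
      seq <- reads$seq[r]
      len <- nchar(seq)
      if (len < anchor + min_flank) next
      m <- Biostrings::matchPattern(Biostrings::DNAString(substr(seq, 1L, anchor)), subjA)
      for (s0 in Biostrings::start(m) - 1L) {
        # a contiguous full-length match means no novel gap for this anchor
        if (s0 + len <= G &&
            substring(A, s0 + 1L, s0 + len) == seq) next
        sel <- which(ci0 >= s0 + min_flank & ci0 <= s0 + len - min_flank)
        for (k in sel) {
          i0 <- ci0[k]; g <- cg[k]; j <- i0 - s0
          if (i0 + g + (len - j) > G) next
          if (substring(A, s0 + 1L, i0) != substr(seq, 1L, j)) next
          if (substring(A, i0 + g + 1L, i0 + g + (len - j)) !=
              substr(seq, j + 1L, len)) next
          foot_a <- G - (s0 + len + g); foot_b <- G - s0   # genomic footprint
          gap_a <- G - (i0 + g); gap_b <- G - i0
          retained <- TRUE
          if (nrow(intr)) {
            oa <- intr[, "start"] - sp[1L]; ob <- intr[, "end"] - sp[1L]
            ovl <- oa < foot_b & ob > foot_a
            inside_gap <- oa >= gap_a & ob <= gap_b
            retained <- all(!ovl | !inside_gap)
          }
          hits[[length(hits) + 1L]] <- data.frame(
            start = gap_a, end = gap_b, retained = retained,
            stringsAsFactors = FALSE)
          break   # one supporting gap per anchor
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0), width = integer(0),
                      n_support = integer(0),
                      n_support_sense_retained = integer(0)))
  h <- do.call(rbind, hits)
  key <- paste(h$start, h$end)
  agg <- data.frame(
    start = as.integer(tapply(h$start, key, `[`, 1L)),
    end = as.integer(tapply(h$end, key, `[`, 1L)),
    n_support = as.integer(tapply(h$start, key, length)),
    n_support_sense_retained = as.integer(tapply(h$retained, key, sum)))
  agg$width <- agg$end - agg$start
  agg <- agg[order(-agg$n_support, agg$start),
             c("start", "end", "width", "n_support",
               "n_support_sense_retained")]
  rownames(agg) <- NULL
  agg
}

#' Strand-specific per-base coverage from long-read alignments
#'
#' Aligned blocks contribute depth; gaps contribute zero.
#' @param alignments a `LongReadAlignment` data.frame.
#' @param gene the `GeneModel` (coverage over its span).
#' @return data.frame `pos` (0-based gene-relative), `plus`, `minus`.
#' @export
strand_coverage <- function(alignments, gene) {
  sp <- gene_span(gene)
  glen <- sp[2L] - sp[1L]
  blocks <- alignment_blocks(alignments, gene)
  cov_for <- function(strand) {
    keep <- which(alignments$aligned %in% TRUE & alignments$strand == strand)
    if (!length(keep)) return(integer(glen))
    b <- do.call(rbind, lapply(keep, function(r) blocks[[r]]$blocks))
    ir <- IRanges::IRanges(start = b[, "start"] + 1L, end = b[, "end"])
    as.integer(IRanges::coverage(ir, width = glen))
  }
  data.frame(pos = seq_len(glen) - 1L, plus = cov_for("+"),
             minus = cov_for("-"))
}
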