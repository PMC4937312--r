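#' Small-RNA filtering, exact mapping and classification
#'
#' Small RNAs are mapped by exact (zero-mismatch) matching of the read or its
#' reverse complement against a reference set; every occurrence on either
#' strand is reported, and multi-mapped reads carry their hit count rather
#' than an arbitrary best-hit choice. Alignment is done in two rounds: reads
#' hitting a contaminant reference in round one are excluded from the target
#' round.
#'
#' @name smallrna
NULL

#' Filter reads by length (inclusive bounds)
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param min,max inclusive length bounds in nt.
#' @return The subset of `reads` with `min <= nchar(seq) <= max`.
#' @export
length_filter <- function(reads, min = 17L, max = 25L) {
  if (min > max) stop("length filter: min > max")
  len <- nchar(reads$seq)
  reads[len >= min & len <= max, , drop = FALSE]
}

#' Exact-match small reads against references
#'
#' Reports every zero-mismatch occurrence of each read (forward) or its
#' reverse complement (reverse) on every reference. Reads containing
#' ambiguous bases are skipped with a warning.
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param references named character vector of reference sequences.
#' @return data.frame with columns `read_id`, `reference_id`, `start`
#'   (0-based), `length`, `strand` (`"+"`/`"-"` relative to the reference),
#'   `multimap` (total hit count of that read across all references and
#'   strands) and `seq`.
#' @export
exact_match <- function(reads, references) {
  stopifnot(is.data.frame(reads), !is.null(names(references)))
  empty <- data.frame(read_id = character(0), reference_id = character(0),
                      start = integer(0), length = integer(0),
                      strand = character(0), multimap = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  ok <- grepl("^[ACGT]+$", reads$seq)
  if (!all(ok)) {
    warning(sprintf("%d read(s) with ambiguous bases skipped", sum(!ok)))
    reads <- reads[ok, , drop = FALSE]
    if (!nrow(reads)) return(empty)
  }
  lens <- nchar(reads$seq)
  hits <- list()
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    fwd <- Biostrings::DNAStringSet(reads$seq[idx])
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
    for (ref in names(references)) {
      subj <- Biostrings::DNAString(references[[ref]])
      if (length(subj) < L) next
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_f else pd_r
        si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
        n <- lengths(si)
        if (!sum(n)) next
        ridx <- idx[rep.int(seq_along(si), n)]
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = reads$read_id[ridx], reference_id = ref,
          start = unlist(si, use.names = FALSE) - 1L, length = L,
          strand = strand, seq = reads$seq[ridx], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  mm <- table(out$read_id)
  out$multimap <- as.integer(mm[out$read_id])
  out <- out[order(out$reference_id, out$start, out$strand, out$read_id),
             c("read_id", "reference_id", "start", "length", "strand",
               "multimap", "seq")]
  rownames(out) <- NULL
  out
}

#' Two-round alignment with contaminant pre-filtering
#'
#' Round one matches all reads against contaminant references; any read with
#' at least one exact hit there is labelled `contaminant` and excluded. The
#' remaining reads are matched against the target references.
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param contaminant_refs named character vector (may be empty).
#' @param target_refs named character vector (must be non-empty).
#' @return list with `alignments` (target-round alignments, see
#'   [exact_match()]) and `read_status` (data.frame `read_id`, `status` in
#'   contaminant/mapped/unmapped).
#' @export
two_round_align <- function(reads, contaminant_refs, target_refs) {
  if (!length(target_refs)) stop("target reference set is empty")
  contaminated <- character(0)
  if (length(contaminant_refs)) {
    r1 <- exact_match(reads, contaminant_refs)
    contaminated <- unique(r1$read_id)
  }
  rest <- reads[!(reads$read_id %in% contaminated), , drop = FALSE]
  aln <- exact_match(rest, target_refs)
  status <- rep("unmapped", nrow(reads))
  status[reads$read_id %in% contaminated] <- "contaminant"
  status[reads$read_id %in% aln$read_id] <- "mapped"
  list(alignments = aln,
       read_status = data.frame(read_id = reads$read_id, status = status,
                                stringsAsFactors = FALSE))
}

#' Count alignments per region, read length and strand
#'
#' An alignment is counted in every region its interval overlaps by at least
#' one nucleotide (boundary-straddling reads therefore count in all regions
#' they touch). Sense/antisense is resolved against the coding strand of the
#' target gene carried by the RegionSet. Besides read counts, the number of
#' overlapped bases is accumulated, so per-base coverage is
#' `bases / region length`.
#'
#' @param alignments alignment data.frame from [exact_match()].
#' @param regions a `RegionSet` (see [derive_regions()]).
#' @param coding_strand coding strand of the target gene; defaults to the
#'   RegionSet attribute.
#' @return data.frame of class `RegionCounts`: `region`, `role`, `length`,
#'   `sense_count`, `antisense_count`, `sense_bases`, `antisense_bases`.
#' @export
count_regions <- function(alignments, regions,
                          coding_strand = attr(regions, "coding_strand")) {
  stopifnot(!is.null(coding_strand))
  refs_known <- unique(regions$reference_id)
  aln <- alignments[alignments$reference_id %in% refs_known, , drop = FALSE]
  lens <- sort(unique(c(17:25, aln$length)))
  grid <- expand.grid(region = regions$name, length = lens,
                      stringsAsFactors = FALSE)
  grid$role <- regions$role[match(grid$region, regions$name)]
  grid$sense_count <- 0L; grid$antisense_count <- 0L
  grid$sense_bases <- 0L; grid$antisense_bases <- 0L
  if (nrow(aln)) {
    for (ref in unique(aln$reference_id)) {
      a <- aln[aln$reference_id == ref, , drop = FALSE]
      r <- regions[regions$reference_id == ref, , drop = FALSE]
      if (!nrow(r)) next
      ir_a <- IRanges::IRanges(start = a$start + 1L, width = a$length)
      ir_r <- IRanges::IRanges(start = r$start + 1L, end = r$end)
      fo <- IRanges::findOverlaps(ir_a, ir_r)
      if (!length(fo)) next
      qa <- S4Vectors::queryHits(fo); sa <- S4Vectors::subjectHits(fo)
      ov <- IRanges::width(IRanges::pintersect(ir_a[qa], ir_r[sa]))
      sense <- a$strand[qa] == coding_strand
      key <- paste(r$name[sa], a$length[qa], sep = "\r")
      gkey <- paste(grid$region, grid$length, sep = "\r")
      for (s in c(TRUE, FALSE)) {
        sel <- sense == s
        if (!any(sel)) next
        cnt <- tapply(rep(1L, sum(sel)), key[sel], sum)
        bts <- tapply(ov[sel], key[sel], sum)
        m <- match(names(cnt), gkey)
        if (s) {
          grid$sense_count[m] <- grid$sense_count[m] + as.integer(cnt)
          grid$sense_bases[m] <- grid$sense_bases[m] + as.integer(bts)
        } else {
          grid$antisense_count[m] <- grid$antisense_count[m] + as.integer(cnt)
          grid$antisense_bases[m] <- grid$antisense_bases[m] + as.integer(bts)
        }
      }
    }
  }
  grid <- grid[order(grid$region, grid$length),
               c("region", "role", "length", "sense_count", "antisense_count",
                 "sense_bases", "antisense_bases")]
  rownames(grid) <- NULL
  class(grid) <- c("RegionCounts", class(grid))
  grid
}

#' Antisense ratio per region
#'
#' `antisense / (sense + antisense)` at the length of interest; `NA` when no
#' read of that length maps to the region. The ratio is invariant under
#' uniform scaling of counts, so raw and normalized counts give the same
#' value.
#'
#' @param counts a `RegionCounts` data.frame.
#' @param length_of_interest read length to evaluate (default 23), or `NULL`
#'   for all lengths pooled.
#' @return data.frame `region`, `role`, `antisense_ratio`.
#' @export
antisense_ratio <- function(counts, length_of_interest = 23L) {
  x <- if (is.null(length_of_interest)) counts else
    counts[counts$length == length_of_interest, , drop = FALSE]
  s <- tapply(x$sense_count, x$region, sum)
  a <- tapply(x$antisense_count, x$region, sum)
  regions <- names(s)
  denom <- s + a
  out <- data.frame(region = regions,
                    role = counts$role[match(regions, counts$region)],
                    antisense_ratio = ifelse(denom > 0, a / denom, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$region), ]
}

#' Read-length histogram (17-25 nt) by region and strand
#'
#' @param alignments alignment data.frame.
#' @param regions optional `RegionSet`; when given, the histogram is
#'   stratified by region (an alignment contributes once to every region it
#'   overlaps) and strand relative to the coding strand. Without it, a
#'   single pooled histogram over all alignments is returned.
#' @param range inclusive length range of the histogram.
#' @return data.frame with columns `region` (or `"all"`), `orientation`
#'   (`sense`/`antisense`, or `all`), `length`, `count`.
#' @export
length_histogram <- function(alignments, regions = NULL, range = c(17L, 25L)) {
  lens <- seq(range[1L], range[2L])
  if (is.null(regions)) {
    cnt <- vapply(lens, function(L) sum(alignments$length == L), integer(1))
    return(data.frame(region = "all", orientation = "all", length = lens,
                      count = cnt, stringsAsFactors = FALSE))
  }
  cs <- attr(regions, "coding_strand")
  counts <- count_regions(alignments, regions, coding_strand = cs)
  counts <- counts[counts$length %in% lens, , drop = FALSE]
  out <- rbind(
    data.frame(region = counts$region, orientation = "sense",
               length = counts$length, count = counts$sense_count,
               stringsAsFactors = FALSE),
    data.frame(region = counts$region, orientation = "antisense",
               length = counts$length, count = counts$antisense_count,
               stringsAsFactors = FALSE))
  out[order(out$region, out$orientation, out$length), ]
}

#' Modal read length of a histogram
#' @param hist data.frame from [length_histogram()] (optionally pre-filtered
#'   to a region/orientation).
#' @return Integer modal length (smallest in case of a tie).
#' @export
length_mode <- function(hist) {
  tot <- tapply(hist$count, hist$length, sum)
  as.integer(names(tot)[which.max(tot)])
}

#' Classify small reads as exon-exon junction or intron reads
#'
#' A junction read matches the spliced mRNA exactly (either strand), crosses
#' an exon-exon boundary with at least `min_overhang` nt on each side, and
#' has no exact match to the unspliced genomic sequence (which would make the
#' template ambiguous). An intron read matches the genomic sequence and
#' overlaps an intron interval by at least one nt. The two classes are
#' disjoint by construction.
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param gene a `GeneModel`.
#' @param min_overhang minimum nt on each side of the junction (default 4,
#'   mirroring the splice-rate convention).
#' @return list with `junction` and `intron` count tables (per index:
#'   `sense_count`, `antisense_count`, `antisense_ratio`) and `read_class`
#'   (per read: `class` in junction/intron/none, `index`). Genes without
#'   introns yield empty tables.
#' @export
classify_junction_intron <- function(reads, gene, min_overhang = 4L) {
  stopifnot(inherits(gene, "GeneModel"))
  intr <- gene_introns(gene)
  ss <- spliced_sequence(gene)
  sp <- gene_span(gene)
  empty_tab <- function(n) data.frame(
    index = seq_len(n), sense_count = integer(n), antisense_count = integer(n),
    antisense_ratio = rep(NA_real_, n))
  read_class <- data.frame(read_id = reads$read_id, class = "none",
                           index = NA_integer_, stringsAsFactors = FALSE)
  if (!nrow(intr) || !nrow(reads))
    return(list(junction = empty_tab(nrow(intr)), intron = empty_tab(nrow(intr)),
                read_class = read_class))
  refs <- c(mrna = ss$seq, genomic = gene_pre_mrna(gene))
  aln <- exact_match(reads, refs)
  genomic_ids <- unique(aln$read_id[aln$reference_id == "genomic"])
  jt <- empty_tab(length(ss$junctions)); it <- empty_tab(nrow(intr))

  # junction reads: mRNA hits crossing a boundary with >= min_overhang,
  # excluding reads that also match the genomic sequence
  ma <- aln[aln$reference_id == "mrna" & !(aln$read_id %in% genomic_ids), ,
            drop = FALSE]
  if (nrow(ma)) {
    for (j in seq_along(ss$junctions)) {
      pos <- ss$junctions[j]
      hit <- ma$start + min_overhang <= pos &
        ma$start + ma$length - min_overhang >= pos
      if (!any(hit)) next
      sense <- ma$strand[hit] == gene$coding_strand
      jt$sense_count[j] <- sum(sense)
      jt$antisense_count[j] <- sum(!sense)
      idx <- match(ma$read_id[hit], read_class$read_id)
      read_class$class[idx] <- "junction"
      read_class$index[idx] <- j
    }
  }
  # intron reads: genomic hits overlapping an intron by >= 1 nt
  ga <- aln[aln$reference_id == "genomic", , drop = FALSE]
  if (nrow(ga)) {
    gs <- ga$start            # gene-relative (genomic ref = gene span)
    ge <- ga$start + ga$length
    for (i in seq_len(nrow(intr))) {
      a <- intr[i, "start"] - sp[1L]; b <- intr[i, "end"] - sp[1L]
      hit <- gs < b & ge > a
      if (!any(hit)) next
      sense <- ga$strand[hit] == gene$coding_strand
      it$sense_count[i] <- sum(sense)
      it$antisense_count[i] <- sum(!sense)
      idx <- match(ga$read_id[hit], read_class$read_id)
      newly <- read_class$class[idx] == "none"
      read_class$class[idx[newly]] <- "intron"
      read_class$index[idx[newly]] <- i
    }
  }
  ratio <- function(t) {
    d <- t$sense_count + t$antisense_count
    t$antisense_ratio <- ifelse(d > 0, t$antisense_count / d, NA_real_)
    t
  }
  list(junction = ratio(jt), intron = ratio(it), read_class = read_class)
}
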