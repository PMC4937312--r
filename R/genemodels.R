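#' Gene, transgene and analysis-region models
#'
#' The unit of analysis is a single protein-coding gene on a reference
#' contig, its truncated transgene derivatives, and the partition of the
#' endogenous locus into regions shared with the transgene (capable of
#' producing primary siRNAs) and regions absent from it (where any siRNA must
#' be secondary, i.e. evidence of transitivity).
#'
#' @name genemodels
NULL

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param reference_id identifier of the reference contig the gene lies on.
#' @param exons integer matrix with columns `start`, `end`: exon intervals in
#'   0-based half-open reference coordinates, sorted and non-overlapping.
#'   Introns are the gaps between consecutive exons.
#' @param sequence character scalar, the full reference contig sequence.
#' @param coding_strand `"+"` or `"-"`; strand the coding sequence is
#'   annotated on.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, reference_id, exons, sequence,
                       coding_strand = "+") {
  stopifnot(is.character(gene_id), is.character(reference_id),
            coding_strand %in% c("+", "-"),
            is.matrix(exons), ncol(exons) == 2L, nrow(exons) >= 1L)
  exons <- iv(exons[, 1L], exons[, 2L])
  if (nrow(exons) > 1L && is.unsorted(exons[, "start"], strictly = TRUE))
    stop("exons must be sorted by start")
  check_disjoint(exons, "exons")
  if (max(exons[, "end"]) > nchar(sequence))
    stop("exons extend beyond reference sequence")
  structure(list(gene_id = gene_id, reference_id = reference_id,
                 coding_strand = coding_strand, exons = exons,
                 sequence = sequence),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("GeneModel %s on %s (%s strand): span [%d, %d), %d exon(s), %d intron(s)\n",
              x$gene_id, x$reference_id, x$coding_strand,
              sp[1L], sp[2L], nrow(x$exons), nrow(gene_introns(x))))
  invisible(x)
}

#' Gene span on the reference (0-based half-open)
#' @param gene a `GeneModel`.
#' @return Integer vector `c(start, end)`.
#' @export
gene_span <- function(gene) {
  unname(c(gene$exons[1L, "start"], gene$exons[nrow(gene$exons), "end"]))
}

#' Intron intervals of a gene model
#'
#' Introns are the gaps between consecutive exons, in 0-based half-open
#' reference coordinates.
#' @param gene a `GeneModel`.
#' @return Integer matrix with columns `start`, `end` (0 rows for a
#'   single-exon gene).
#' @export
gene_introns <- function(gene) {
  n <- nrow(gene$exons)
  if (n < 2L) return(iv(integer(0), integer(0)))
  iv(gene$exons[-n, "end"], gene$exons[-1L, "start"])
}

# Genomic sequence of the gene span (pre-mRNA, coding-strand orientation is
# handled downstream; stored sequence is always the reference + strand).
gene_pre_mrna <- function(gene) {
  sp <- gene_span(gene)
  subseq_chr(gene$sequence, sp[1L], sp[2L])
}

#' Specify a truncated/edited transgene construct
#'
#' Coordinates are gene-relative (0 at the gene span start, 0-based
#' half-open), matching how construct boundaries are reported for truncated
#' transgenes.
#'
#' @param parent_gene_id id of the parent gene.
#' @param deletions list of length-2 integer vectors `c(start, end)`.
#' @param replacements list of lists with elements `interval` (length-2
#'   integer vector), `seq` (foreign sequence) and `name` (foreign label).
#' @param linearization_offset integer >= 0; extra downstream filler retained
#'   after plasmid linearization.
#' @param promoter `"bidirectional"` or `"unidirectional"`.
#' @return An object of class `TransgeneSpec`.
#' @export
transgene_spec <- function(parent_gene_id, deletions = list(),
                           replacements = list(),
                           linearization_offset = 0L,
                           promoter = "bidirectional") {
  stopifnot(linearization_offset >= 0L,
            promoter %in% c("bidirectional", "unidirectional"))
  for (d in deletions) stopifnot(length(d) == 2L, d[2L] > d[1L], d[1L] >= 0L)
  for (r in replacements) {
    stopifnot(is.list(r), length(r$interval) == 2L,
              r$interval[2L] > r$interval[1L], r$interval[1L] >= 0L,
              is.character(r$seq), nzchar(r$name))
  }
  edits <- rbind(
    do.call(rbind, lapply(deletions, function(d) iv(d[1L], d[2L]))),
    do.call(rbind, lapply(replacements, function(r) iv(r$interval[1L], r$interval[2L])))
  )
  if (!is.null(edits) && nrow(edits) > 1L) check_disjoint(edits, "edits")
  structure(list(parent_gene_id = parent_gene_id, deletions = deletions,
                 replacements = replacements,
                 linearization_offset = as.integer(linearization_offset),
                 promoter = promoter),
            class = "TransgeneSpec")
}

#' Build a transgene from a parent gene and an edit specification
#'
#' The transgene sequence is the parent gene span with the specified
#' deletions excised and replacement intervals substituted by their foreign
#' sequences, followed by `linearization_offset` bases of seeded random
#' filler (transcription of truncated constructs runs on to the
#' linearization site). A coordinate map records, for every transgene
#' interval, the parent interval (or foreign name) it derives from; junctions
#' are the transgene positions where non-adjacent parent coordinates abut.
#'
#' @param gene parent `GeneModel`.
#' @param spec a `TransgeneSpec` for that gene.
#' @param transgene_id id for the construct.
#' @param filler_seed seed for the linearization filler sequence.
#' @return An object of class `Transgene` with elements `transgene_id`,
#'   `sequence`, `coordinate_map` (data.frame: `tg_start`, `tg_end`, `src`,
#'   `parent_start`, `parent_end`), `junctions` (transgene positions) and
#'   `parent_gene_id`.
#' @export
build_transgene <- function(gene, spec, transgene_id = "transgene",
                            filler_seed = 1L) {
  stopifnot(inherits(gene, "GeneModel"), inherits(spec, "TransgeneSpec"))
  if (spec$parent_gene_id != gene$gene_id)
    stop("spec is not for this gene")
  sp <- gene_span(gene)
  glen <- sp[2L] - sp[1L]
  parent_seq <- gene_pre_mrna(gene)

  edits <- list()
  for (d in spec$deletions)
    edits[[length(edits) + 1L]] <- list(start = d[1L], end = d[2L],
                                        type = "del")
  for (r in spec$replacements)
    edits[[length(edits) + 1L]] <- list(start = r$interval[1L],
                                        end = r$interval[2L], type = "repl",
                                        seq = r$seq, name = r$name)
  if (length(edits)) {
    m <- do.call(rbind, lapply(edits, function(e) c(e$start, e$end)))
    if (any(m[, 2L] > glen)) stop("edit interval out of parent range")
    check_disjoint(iv(m[, 1L], m[, 2L]), "edits")
    edits <- edits[order(m[, 1L])]
  }

  pieces <- character(0)
  map <- list()
  junctions <- integer(0)
  cursor <- 0L   # parent position
  tg_pos <- 0L   # transgene position
  emit_parent <- function(a, b) {
    if (b <= a) return(invisible(NULL))
    pieces[[length(pieces) + 1L]] <<- subseq_chr(parent_seq, a, b)
    map[[length(map) + 1L]] <<- data.frame(
      tg_start = tg_pos, tg_end = tg_pos + (b - a), src = "parent",
      parent_start = a, parent_end = b, stringsAsFactors = FALSE)
    tg_pos <<- tg_pos + (b - a)
  }
  for (e in edits) {
    emit_parent(cursor, e$start)
    at <- tg_pos
    if (e$type == "repl") {
      pieces[[length(pieces) + 1L]] <- e$seq
      map[[length(map) + 1L]] <- data.frame(
        tg_start = tg_pos, tg_end = tg_pos + nchar(e$seq), src = e$name,
        parent_start = NA_integer_, parent_end = NA_integer_,
        stringsAsFactors = FALSE)
      tg_pos <- tg_pos + nchar(e$seq)
      junctions <- c(junctions, at)           # replacements always internal
    } else {
      if (e$end < glen) junctions <- c(junctions, at)  # internal deletion
    }
    cursor <- e$end
  }
  emit_parent(cursor, glen)

  if (spec$linearization_offset > 0L) {
    set.seed(derive_seed(filler_seed, "linearization_filler"))
    filler <- random_dna(spec$linearization_offset)
    pieces[[length(pieces) + 1L]] <- filler
    map[[length(map) + 1L]] <- data.frame(
      tg_start = tg_pos, tg_end = tg_pos + spec$linearization_offset,
      src = "linearization_filler", parent_start = NA_integer_,
      parent_end = NA_integer_, stringsAsFactors = FALSE)
    tg_pos <- tg_pos + spec$linearization_offset
  }

  structure(list(transgene_id = transgene_id,
                 sequence = paste(pieces, collapse = ""),
                 coordinate_map = do.call(rbind, map),
                 junctions = junctions,
                 parent_gene_id = gene$gene_id,
                 promoter = spec$promoter),
            class = "Transgene")
}

#' @export
print.Transgene <- function(x, ...) {
  cat(sprintf("Transgene %s (parent %s): %d nt, %d junction(s)\n",
              x$transgene_id, x$parent_gene_id, nchar(x$sequence),
              length(x$junctions)))
  invisible(x)
}

#' Map a transgene position to parent gene-relative coordinates
#'
#' Identity round trip holds on parent-derived intervals; foreign and filler
#' positions map to `NA`.
#' @param transgene a `Transgene`.
#' @param pos transgene positions (0-based).
#' @return Integer vector of parent positions (`NA` for foreign bases).
#' @export
transgene_to_parent <- function(transgene, pos) {
  map <- transgene$coordinate_map
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(map))) {
    hit <- pos >= map$tg_start[i] & pos < map$tg_end[i]
    if (map$src[i] == "parent")
      out[hit] <- map$parent_start[i] + (pos[hit] - map$tg_start[i])
  }
  out
}

#' Map a parent gene-relative position to transgene coordinates
#' @param transgene a `Transgene`.
#' @param pos parent positions (0-based, gene-relative).
#' @return Integer vector of transgene positions (`NA` where deleted).
#' @export
parent_to_transgene <- function(transgene, pos) {
  map <- transgene$coordinate_map
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(map))) {
    if (map$src[i] != "parent") next
    hit <- pos >= map$parent_start[i] & pos < map$parent_end[i]
    out[hit] <- map$tg_start[i] + (pos[hit] - map$parent_start[i])
  }
  out
}

#' Derive the primary/secondary region partition induced by a transgene
#'
#' Parent intervals present in the transgene become `primary_capable`
#' regions (they can template primary siRNAs); parent intervals absent from
#' it become `secondary_only` regions, where any siRNA demonstrates
#' transitivity at the endogenous locus. Foreign inserts become `foreign`
#' regions on the transgene itself. A 5' sub-region from the transcription
#' start to the first intron is additionally emitted (flagged
#' `subregion = TRUE`), since siRNAs there show distinct strand behaviour.
#'
#' @param gene parent `GeneModel`.
#' @param transgene `Transgene` built from `gene`.
#' @param prefix name prefix for secondary-only regions (numbered in genomic
#'   order as `<prefix>_1`, `<prefix>_2`, ...); primary regions are named
#'   `shared_<i>` and the 5' sub-region `five_prime`.
#' @return A data.frame of class `RegionSet` with columns `name`,
#'   `reference_id`, `start`, `end` (0-based half-open reference
#'   coordinates; transgene coordinates for foreign regions), `role` and
#'   `subregion`. The gene's coding strand is attached as attribute
#'   `coding_strand`.
#' @export
derive_regions <- function(gene, transgene, prefix = "endo") {
  stopifnot(inherits(gene, "GeneModel"), inherits(transgene, "Transgene"))
  if (transgene$parent_gene_id != gene$gene_id)
    stop("transgene was not derived from this gene")
  sp <- gene_span(gene)
  glen <- sp[2L] - sp[1L]
  map <- transgene$coordinate_map
  kept <- map[map$src == "parent", , drop = FALSE]
  kept <- kept[order(kept$parent_start), , drop = FALSE]
  # merge parent intervals that are contiguous in parent coordinates
  merged <- list()
  for (i in seq_len(nrow(kept))) {
    if (length(merged) && merged[[length(merged)]][2L] == kept$parent_start[i]) {
      merged[[length(merged)]][2L] <- kept$parent_end[i]
    } else {
      merged[[length(merged) + 1L]] <- c(kept$parent_start[i], kept$parent_end[i])
    }
  }
  rows <- list()
  add <- function(name, ref, a, b, role, sub = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, reference_id = ref, start = a, end = b, role = role,
      subregion = sub, stringsAsFactors = FALSE)
  }
  # secondary_only: gaps of the merged kept cover within [0, glen)
  cursor <- 0L; k <- 0L
  bounds <- do.call(rbind, merged)
  gaps <- list()
  for (i in seq_len(nrow(bounds))) {
    if (bounds[i, 1L] > cursor) gaps[[length(gaps) + 1L]] <- c(cursor, bounds[i, 1L])
    cursor <- bounds[i, 2L]
  }
  if (cursor < glen) gaps[[length(gaps) + 1L]] <- c(cursor, glen)
  for (g in gaps) {
    k <- k + 1L
    add(sprintf("%s_%d", prefix, k), gene$reference_id,
        sp[1L] + g[1L], sp[1L] + g[2L], "secondary_only")
  }
  for (i in seq_len(nrow(bounds))) {
    add(sprintf("shared_%d", i), gene$reference_id,
        sp[1L] + bounds[i, 1L], sp[1L] + bounds[i, 2L], "primary_capable")
  }
  # foreign inserts (transgene coordinates)
  fmap <- map[!(map$src %in% c("parent", "linearization_filler")), , drop = FALSE]
  for (i in seq_len(nrow(fmap))) {
    add(fmap$src[i], transgene$transgene_id, fmap$tg_start[i], fmap$tg_end[i],
        "foreign")
  }
  # 5' sub-region: transcription start to first intron start
  intr <- gene_introns(gene)
  five_end <- if (nrow(intr)) intr[1L, "start"] else sp[2L]
  add("five_prime", gene$reference_id, sp[1L], five_end,
      "primary_capable", sub = TRUE)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name)) stop("region names are not unique")
  attr(out, "coding_strand") <- gene$coding_strand
  class(out) <- c("RegionSet", class(out))
  out
}

#' Spliced mRNA sequence and junction positions of a gene model
#'
#' @param gene a `GeneModel`.
#' @return A list with `seq` (exon concatenation, reference + strand),
#'   `junctions` (0-based mRNA positions of each exon-exon boundary, one per
#'   intron: the position of the first base after the junction),
#'   `exon_mrna_start` (mRNA start of each exon) and `exons` (reference
#'   coordinates), providing the mRNA <-> genomic mapping.
#' @export
spliced_sequence <- function(gene) {
  stopifnot(inherits(gene, "GeneModel"))
  ex <- gene$exons
  seqs <- subseq_chr(gene$sequence, ex[, "start"], ex[, "end"])
  w <- iv_width(ex)
  starts <- cumsum(c(0L, w[-length(w)]))
  list(seq = paste(seqs, collapse = ""),
       junctions = if (nrow(ex) > 1L) starts[-1L] else integer(0),
       exon_mrna_start = starts,
       exons = ex)
}

#' Map an mRNA position to a genomic reference position
#' @param gene a `GeneModel`.
#' @param pos 0-based mRNA positions.
#' @return 0-based reference positions.
#' @export
mrna_to_genomic <- function(gene, pos) {
  ss <- spliced_sequence(gene)
  w <- iv_width(ss$exons)
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    e <- which(pos[i] >= ss$exon_mrna_start & pos[i] < ss$exon_mrna_start + w)[1L]
    if (is.na(e)) stop("mRNA position out of range")
    out[i] <- ss$exons[e, "start"] + (pos[i] - ss$exon_mrna_start[e])
  }
  out
}
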