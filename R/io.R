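# File-format boundaries. Sequence formats go through Biostrings, GFF3/BED
# through rtracklayer; SAM and bedGraph are written directly (plain text,
# one record per line).

#' Write reference sequences to FASTA
#' @param refs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(refs, path) {
  if (!methods::is(refs, "DNAStringSet"))
    refs <- Biostrings::DNAStringSet(refs)
  Biostrings::writeXStringSet(refs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (constant "I" qualities)
#'
#' The analysis never consumes base qualities; a constant placeholder keeps
#' the files byte-reproducible.
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file as a reads data.frame
#' @param path FASTQ path.
#' @return data.frame with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a gene model to GFF3
#'
#' Emits `gene` and `exon` features (1-based inclusive, per GFF3).
#' @param gene a `GeneModel`.
#' @param path output path.
#' @export
write_gene_gff3 <- function(gene, path) {
  sp <- gene_span(gene)
  ex <- gene$exons
  gr <- GenomicRanges::GRanges(
    seqnames = gene$reference_id,
    ranges = IRanges::IRanges(start = c(sp[1L], ex[, "start"]) + 1L,
                              end = c(sp[2L], ex[, "end"])),
    strand = gene$coding_strand,
    type = c("gene", rep("exon", nrow(ex))),
    ID = c(gene$gene_id, sprintf("%s.exon%d", gene$gene_id, seq_len(nrow(ex)))),
    Parent = c(NA_character_, rep(gene$gene_id, nrow(ex))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene model from GFF3 + FASTA
#' @param gff3_path GFF3 with `gene` and `exon` features for one gene.
#' @param fasta_path FASTA containing the reference contig.
#' @param gene_id optional gene id to select (defaults to the single gene).
#' @return A `GeneModel`.
#' @export
read_gene_gff3 <- function(gff3_path, fasta_path, gene_id = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (is.null(gene_id)) {
    if (length(genes) != 1L) stop("gff3 contains more than one gene; pass gene_id")
    gene_id <- genes$ID[1L]
  }
  ex <- gr[gr$type == "exon" & vapply(gr$Parent, function(p) gene_id %in% p, logical(1))]
  ex <- ex[order(GenomicRanges::start(ex))]
  refs <- read_fasta(fasta_path)
  ref_id <- as.character(GenomicRanges::seqnames(ex))[1L]
  if (!ref_id %in% names(refs)) stop("reference contig missing from FASTA")
  gene_model(gene_id = gene_id, reference_id = ref_id,
             exons = iv(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex)),
             sequence = refs[[ref_id]],
             coding_strand = as.character(GenomicRanges::strand(ex))[1L])
}

#' Export a RegionSet to BED
#'
#' BED is 0-based half-open; intervals are written unchanged. The role is
#' stored in the name column as `name|role`.
#' @param regions a `RegionSet`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$reference_id,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = paste(regions$name, regions$role, sep = "|"))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Serialize a TransgeneSpec to YAML
#' @param spec a `TransgeneSpec`.
#' @param path output path.
#' @export
write_transgene_spec <- function(spec, path) {
  x <- list(parent_gene_id = spec$parent_gene_id,
            deletions = lapply(spec$deletions, as.integer),
            replacements = lapply(spec$replacements, function(r)
              list(interval = as.integer(r$interval), seq = r$seq, name = r$name)),
            linearization_offset = spec$linearization_offset,
            promoter = spec$promoter)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a TransgeneSpec from YAML
#' @param path YAML path.
#' @export
read_transgene_spec <- function(path) {
  x <- yaml::read_yaml(path)
  transgene_spec(parent_gene_id = x$parent_gene_id,
                 deletions = lapply(x$deletions, as.integer),
                 replacements = lapply(x$replacements, function(r)
                   list(interval = as.integer(r$interval), seq = r$seq,
                        name = r$name)),
                 linearization_offset = x$linearization_offset %||% 0L,
                 promoter = x$promoter %||% "bidirectional")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write small-read alignments to SAM
#'
#' Reverse-strand alignments are stored reverse-complemented with flag 16,
#' following the SAM convention. Records are sorted by (reference, start,
#' strand, read id) for deterministic output.
#'
#' @param alignments alignment data.frame from [exact_match()] (must carry a
#'   `seq` column with the read sequence in read orientation).
#' @param references named character vector of reference sequences (for
#'   `@SQ` header lines).
#' @param path output path.
#' @param cigars optional character vector of CIGAR strings (defaults to
#'   `<len>M`).
#' @export
write_sam <- function(alignments, references, path, cigars = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(references))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(references[[nm]])), con)
  if (nrow(alignments)) {
    o <- order(alignments$reference_id, alignments$start,
               alignments$strand, alignments$read_id)
    a <- alignments[o, , drop = FALSE]
    if (is.null(cigars)) cigars <- sprintf("%dM", a$length) else cigars <- cigars[o]
    seqs <- a$seq
    rev <- a$strand == "-"
    if (any(rev)) seqs[rev] <- revcomp_chr(seqs[rev])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                       a$read_id, ifelse(rev, 16L, 0L), a$reference_id,
                       a$start + 1L, cigars, seqs,
                       strrep("I", nchar(seqs))), con)
  }
  invisible(path)
}

#' Write strand-specific coverage to bedGraph
#'
#' Two track sections (top/plus and bottom/minus strand) in one file;
#' positions are 0-based half-open per bedGraph.
#' @param coverage data.frame from [strand_coverage()] with columns `pos`,
#'   `plus`, `minus`.
#' @param reference_id contig name.
#' @param path output path.
#' @export
write_bedgraph <- function(coverage, reference_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(vals, label) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", label), con)
    if (!length(vals)) return(invisible(NULL))
    r <- rle(vals)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", reference_id, starts[keep],
                         ends[keep], r$values[keep]), con)
  }
  emit(coverage$plus, "coverage_top_strand")
  emit(coverage$minus, "coverage_bottom_strand")
  invisible(path)
}
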