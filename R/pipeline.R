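#' End-to-end pipeline: simulate, map, quantify, normalize, splice, ChIP
#'
#' Runs all stages from a single configuration and writes the study-style
#' report bundle: alignment SAM, raw + normalized region counts, fold
#' changes vs the control sample, antisense ratios, length histograms,
#' junction/intron tables, splice rates, strand-specific coverage, ChIP
#' report and a JSON manifest with version, config hash and per-sample
#' T/K/M bookkeeping. Output is deterministic for a fixed seed; every
#' intermediate artifact uses a documented plain-text format so any stage
#' can be fed real data instead.
#'
#' @param cfg a `SimConfig` (see [read_sim_config()]).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("simulate", simulate_cohort(cfg))
  refs <- cohort$refs
  gene <- refs$gene
  regions <- refs$regions
  target_refs <- c(refs$refs)

  # map + quantify per sample
  sample_ids <- names(cohort$samples)
  aln <- list(); counts <- list(); libs <- list()
  for (sid in sample_ids) {
    s <- cohort$samples[[sid]]
    reads <- stage("map", length_filter(s$reads))
    aln[[sid]] <- stage("map",
                        two_round_align(reads, refs$contaminant_refs, target_refs))
    counts[[sid]] <- stage("quantify",
                           count_regions(aln[[sid]]$alignments, regions))
    kd_gene <- s$feeding
    libs[[sid]] <- stage("normalize", compute_t_k(
      aln[[sid]], genome_refs = refs$genome_refs,
      exclude_refs = refs$exclude_refs, knockdown_refs = kd_gene,
      sample_id = sid))
  }
  scaling <- stage("normalize", cohort_scaling(libs))

  ctrl_id <- sample_ids[vapply(cohort$samples, `[[`, character(1), "role") == "control"]
  region_tabs <- list(); ratio_tabs <- list(); hist_tabs <- list()
  fc_tabs <- list(); ji_tabs <- list()
  for (sid in sample_ids) {
    nc <- normalize_region_counts(counts[[sid]], sid, scaling)
    nc <- cbind(sample_id = sid, nc)
    region_tabs[[sid]] <- nc
    r <- antisense_ratio(counts[[sid]])
    ratio_tabs[[sid]] <- cbind(sample_id = sid, r)
    h <- length_histogram(aln[[sid]]$alignments, regions)
    hist_tabs[[sid]] <- cbind(sample_id = sid, h)
    ji <- stage("quantify", classify_junction_intron(
      length_filter(cohort$samples[[sid]]$reads), gene))
    ji_tabs[[sid]] <- rbind(
      cbind(sample_id = sid, feature = "junction", ji$junction),
      cbind(sample_id = sid, feature = "intron", ji$intron))
    if (sid != ctrl_id) {
      fc <- stage("normalize", fold_change(
        counts[[sid]], counts[[ctrl_id]], sid, ctrl_id, scaling))
      fc_tabs[[sid]] <- cbind(sample_id = sid, control = ctrl_id, fc)
    }
  }

  # long-read stages
  long_reads <- stage("splice-rates", filter_long_reads(cohort$long$reads))
  long_aln <- stage("splice-rates", align_long(long_reads, gene))
  rates <- stage("splice-rates", splice_rates(long_aln, gene))
  cov <- stage("splice-rates", strand_coverage(long_aln, gene))
  as_introns <- stage("splice-rates", detect_antisense_introns(
    long_reads[!(long_reads$read_id %in%
                   long_aln$read_id[long_aln$aligned]), , drop = FALSE], gene))

  chip <- stage("chip", simulate_chip_ct(cfg$seed))
  chip_tab <- stage("chip", chip_report(chip$records))

  # artifacts
  p <- function(f) file.path(out_dir, f)
  ctrl_aln <- aln[[ctrl_id]]$alignments
  write_sam(ctrl_aln, target_refs, p("alignments.sam"))
  write_tsv(do.call(rbind, region_tabs), p("region_counts.tsv"))
  if (length(fc_tabs)) write_tsv(do.call(rbind, fc_tabs), p("fold_changes.tsv"))
  write_tsv(do.call(rbind, ratio_tabs), p("antisense_ratios.tsv"))
  write_tsv(do.call(rbind, hist_tabs), p("length_histograms.tsv"))
  write_tsv(do.call(rbind, ji_tabs), p("junction_intron.tsv"))
  rates_out <- cbind(rates, mean_rate = attr(rates, "mean_rate"))
  write_tsv(rates_out, p("splice_rates.tsv"))
  write_bedgraph(cov, gene$reference_id, p("strand_coverage.bedgraph"))
  write_tsv(chip_tab, p("chip_report.tsv"))
  if (nrow(as_introns)) write_tsv(as_introns, p("antisense_introns.tsv"))

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest <- list(
    package = "sirnascope",
    version = as.character(utils::packageVersion("sirnascope")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    M = scaling$M,
    samples = lapply(libs, function(l)
      list(sample_id = l$sample_id, T = l$T, K = l$K,
           factor = scaling$factors$factor[
             match(l$sample_id, scaling$factors$sample_id)])),
    artifacts = list.files(out_dir))
  unlink(cfg_file)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, cohort = cohort, alignments = aln,
                 counts = counts, libraries = libs, scaling = scaling,
                 fold_changes = fc_tabs, splice = rates,
                 coverage = cov, antisense_introns = as_introns,
                 chip = chip_tab))
}
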