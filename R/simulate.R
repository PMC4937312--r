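#' Seeded synthetic cohorts for the transgene-silencing analysis
#'
#' The generator emulates the study system: an AT-rich macronuclear genome
#' surrogate carrying a five-intron target gene (~25 nt introns), a
#' double-truncated transgene derived from it (optionally with a foreign
#' replacement insert), bidirectionally transcribed long reads with
#' per-intron retention, and small-RNA populations with a 23 nt modal
#' length, region-specific abundance (secondary siRNAs a few percent of
#' primary per-base coverage) and configurable antisense bias. Every read
#' carries a truth label. Identical seeds give byte-identical output; each
#' generator stage draws from its own derived RNG stream.
#'
#' @name synthetic_data
NULL

#' Load the packaged default simulation configuration
#'
#' @param path optional YAML path; defaults to the packaged configuration.
#' @param overrides optional named list merged over the file contents.
#' @return A validated `SimConfig` list.
#' @export
read_sim_config <- function(path = NULL, overrides = list()) {
  if (is.null(path))
    path <- system.file("extdata", "default_sim_config.yaml",
                        package = "sirnascope", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  validate_sim_config(cfg)
}

# recursive config merge: named lists merge by key, anything else (vectors,
# unnamed lists) replaces the default wholesale
merge_config <- function(base, override) {
  if (is.list(override) && length(override) == 0L) return(base)
  if (!is.list(base) || !is.list(override) ||
      is.null(names(override)) || any(names(override) == ""))
    return(override)
  for (k in names(override)) {
    base[[k]] <- if (k %in% names(base))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Validate a simulation configuration
#' @param cfg configuration list.
#' @return The config, invisibly classed as `SimConfig`.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed),
            all(unlist(cfg$smallrna$length_probs) >= 0),
            abs(sum(unlist(cfg$smallrna$length_probs)) - 1) < 1e-6)
  probs <- c(cfg$smallrna$antisense$body, cfg$smallrna$antisense$five_prime,
             cfg$smallrna$antisense$secondary, cfg$smallrna$antisense$junction,
             cfg$smallrna$antisense$background, cfg$smallrna$antisense$other,
             unlist(cfg$smallrna$secondary_fractions),
             cfg$longrna$retention, cfg$longrna$antisense_fraction,
             cfg$longrna$antisense_intron_splice_prob)
  if (any(probs < 0 | probs > 1)) stop("config probabilities must be in [0,1]")
  counts <- unlist(cfg$smallrna$counts)
  if (any(counts < 0)) stop("config counts must be >= 0")
  class(cfg) <- c("SimConfig", class(cfg))
  invisible(cfg)
}

#' Build the synthetic reference set
#'
#' Constructs the target locus (gene with flanks), its spliced mRNA, the
#' transgene, knockdown and neutral feeding genes with their vector
#' inserts, a structural-RNA locus, a background genome contig and a
#' contaminant contig. Sense introns carry canonical GT...AG boundaries and
#' an antisense-strand GT...AG intron is planted inside an exon.
#'
#' @param cfg a `SimConfig`.
#' @return list with `gene` (`GeneModel`), `transgene`, `regions`
#'   (`RegionSet`), `refs` (named character vector of target references),
#'   `contaminant_refs`, `genome_refs`, `exclude_refs` (structural +
#'   vectors) and `vector_of` (feeding gene -> vector reference id).
#' @export
build_references <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "references"))
  at <- cfg$at_content
  g <- cfg$gene
  exon_len <- as.integer(unlist(g$exon_lengths))
  intron_len <- as.integer(unlist(g$intron_lengths))
  stopifnot(length(intron_len) == length(exon_len) - 1L)
  if (any(intron_len < 15L | intron_len > 100L))
    stop("generated intron lengths must lie in [15, 100]")
  pieces <- character(0)
  exons <- matrix(integer(0), ncol = 2)
  pos <- 0L
  for (i in seq_along(exon_len)) {
    exons <- rbind(exons, c(pos, pos + exon_len[i]))
    pieces <- c(pieces, random_dna(exon_len[i], at))
    pos <- pos + exon_len[i]
    if (i <= length(intron_len)) {
      pieces <- c(pieces, paste0("GT", random_dna(intron_len[i] - 4L, at), "AG"))
      pos <- pos + intron_len[i]
    }
  }
  gene_seq <- paste(pieces, collapse = "")
  # plant an antisense-strand GT...AG intron (genomic CT ... AC)
  asi <- as.integer(unlist(cfg$longrna$antisense_intron))
  substr(gene_seq, asi[1L] + 1L, asi[1L] + 2L) <- "CT"
  substr(gene_seq, asi[2L] - 1L, asi[2L]) <- "AC"
  flank <- as.integer(g$flank)
  locus_seq <- paste0(random_dna(flank, at), gene_seq, random_dna(flank, at))
  colnames(exons) <- c("start", "end")
  gene <- gene_model(gene_id = g$gene_id, reference_id = g$reference_id,
                     exons = exons + flank, sequence = locus_seq)

  tg <- cfg$transgene
  repl <- list()
  if (isTRUE(tg$insert$enabled)) {
    repl <- list(list(interval = as.integer(unlist(tg$insert$interval)),
                      seq = random_dna(as.integer(tg$insert$length), at),
                      name = tg$insert$name))
  }
  spec <- transgene_spec(parent_gene_id = g$gene_id,
                         deletions = lapply(tg$deletions, as.integer),
                         replacements = repl,
                         linearization_offset = as.integer(tg$linearization_offset))
  transgene <- build_transgene(gene, spec, transgene_id = "transgene",
                               filler_seed = cfg$seed)
  regions <- derive_regions(gene, transgene, prefix = cfg$region_prefix %||% "endo")

  feeding <- cfg$feeding
  kd_id <- feeding$knockdown_gene$id
  ctrl_id <- feeding$control_gene$id
  kd_seq <- random_dna(as.integer(feeding$knockdown_gene$length), at)
  ctrl_seq <- random_dna(as.integer(feeding$control_gene$length), at)
  kd_ins <- as.integer(unlist(feeding$knockdown_gene$insert))
  ctrl_ins <- as.integer(unlist(feeding$control_gene$insert))
  refs <- character(0)
  refs[g$reference_id] <- locus_seq
  refs["target_mrna"] <- spliced_sequence(gene)$seq
  refs["transgene"] <- transgene$sequence
  refs[kd_id] <- kd_seq
  refs[ctrl_id] <- ctrl_seq
  refs["background"] <- random_dna(as.integer(cfg$contigs$background_length), at)
  refs["structural_rna"] <- random_dna(as.integer(cfg$contigs$structural_length), at)
  vector_of <- stats::setNames(paste0("vector_", c(kd_id, ctrl_id)),
                               c(kd_id, ctrl_id))
  refs[vector_of[[kd_id]]] <- substr(kd_seq, kd_ins[1L] + 1L, kd_ins[2L])
  refs[vector_of[[ctrl_id]]] <- substr(ctrl_seq, ctrl_ins[1L] + 1L, ctrl_ins[2L])
  contaminant_refs <- c(contaminant_1 =
                          random_dna(as.integer(cfg$contigs$contaminant_length), at))
  genome_refs <- c(g$reference_id, "target_mrna", kd_id, ctrl_id,
                   "background", "structural_rna")
  exclude_refs <- c("structural_rna", unname(vector_of))
  list(gene = gene, transgene = transgene, regions = regions, refs = refs,
       contaminant_refs = contaminant_refs, genome_refs = genome_refs,
       exclude_refs = exclude_refs, vector_of = vector_of,
       insert_of = stats::setNames(list(kd_ins, ctrl_ins), c(kd_id, ctrl_id)))
}

# -- small-RNA simulation ----------------------------------------------------

# Deterministic largest-remainder composition of one siRNA class over
# strata x strand x length. Returns a data.frame(stratum, offset, len,
# orientation, length, count).
quota_table <- function(n, strata, length_probs, as_frac_default,
                        mult = c(sense = 1, antisense = 1)) {
  if (n <= 0L || !nrow(strata)) return(NULL)
  lens <- as.integer(names(length_probs))
  n_str <- quota_alloc(n, strata$len)
  rows <- list()
  for (si in seq_len(nrow(strata))) {
    if (n_str[si] == 0L) next
    asf <- if (is.na(strata$as_frac[si])) as_frac_default else strata$as_frac[si]
    n_as <- round(n_str[si] * asf * mult[["antisense"]])
    n_s <- round(n_str[si] * (1 - asf) * mult[["sense"]])
    for (ori in c("sense", "antisense")) {
      n_ori <- if (ori == "sense") n_s else n_as
      if (n_ori <= 0L) next
      per_len <- quota_alloc(n_ori, unlist(length_probs))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = strata$name[si], offset = strata$offset[si],
        len = strata$len[si], orientation = ori, length = lens,
        count = per_len, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab[tab$count > 0L, , drop = FALSE]
}

# Allocate reads of one siRNA class per the quota table; only positions are
# random.
alloc_reads <- function(n, strata, length_probs, as_frac_default,
                        mult = c(sense = 1, antisense = 1), ref_seq,
                        reference_id, class, sample_id, counter_env) {
  tab <- quota_table(n, strata, length_probs, as_frac_default, mult)
  if (is.null(tab)) return(NULL)
  rows <- list()
  for (ti in seq_len(nrow(tab))) {
    k <- tab$count[ti]
    L <- tab$length[ti]
    ori <- tab$orientation[ti]
    max_start <- tab$len[ti] - L
    if (max_start < 0L)
      stop(sprintf("region %s shorter than read length %d",
                   tab$stratum[ti], L))
    st <- tab$offset[ti] + sample.int(max_start + 1L, k, replace = TRUE) - 1L
    seq <- substring(ref_seq, st + 1L, st + L)
    if (ori == "antisense") seq <- revcomp_chr(seq)
    i0 <- counter_env$n
    counter_env$n <- counter_env$n + k
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("%s_%s_%06d", sample_id, class, i0 + seq_len(k)),
      seq = seq, class = class, region = tab$stratum[ti],
      reference_id = reference_id, start = st, length = L,
      orientation = ori, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Simulate one sample's small-RNA library
#'
#' Class counts and their (sub-region x strand x length) composition are
#' allocated deterministically (largest-remainder quotas) so that truth
#' counts equal configured counts exactly; read positions are drawn
#' uniformly within their sub-region. Secondary-region read counts are
#' derived from the configured fraction of the transgene-covered region's
#' expected 23 nt antisense per-base coverage.
#'
#' @param cfg a `SimConfig`.
#' @param refs reference bundle from [build_references()].
#' @param sample sample description list (`id`, `role`, `feeding`,
#'   optional `multipliers` per class: single factor or named
#'   `c(sense =, antisense =)`).
#' @return list with `reads` (data.frame `read_id`, `seq`) and `truth`
#'   (per-read origin class, region, orientation, length, start).
#' @export
simulate_small_rnas <- function(cfg, refs, sample) {
  set.seed(derive_seed(cfg$seed, paste0("smallrna_", sample$id)))
  sr <- cfg$smallrna
  lens_probs <- sr$length_probs
  gene <- refs$gene
  sp <- gene_span(gene)
  regions <- refs$regions
  mult_of <- function(class) {
    m <- sample$multipliers[[class]]
    if (is.null(m)) return(c(sense = 1, antisense = 1))
    if (length(m) == 1L && is.null(names(m))) return(c(sense = m, antisense = m))
    c(sense = m[["sense"]] %||% 1, antisense = m[["antisense"]] %||% 1)
  }
  counter <- new.env(); counter$n <- 0L
  out <- list()

  # primary strata: transgene-covered pieces of the endogenous locus, with
  # the 5' sub-region (transcription start to first intron) sense-biased
  prim <- regions[regions$role == "primary_capable" & !regions$subregion, ,
                  drop = FALSE]
  five <- regions[regions$subregion, , drop = FALSE]
  strata <- list()
  for (i in seq_len(nrow(prim))) {
    a <- prim$start[i]; b <- prim$end[i]
    if (nrow(five) && five$start[1L] < b && five$end[1L] > a) {
      fa <- max(a, five$start[1L]); fb <- min(b, five$end[1L])
      if (fa > a) strata[[length(strata) + 1L]] <-
          data.frame(name = prim$name[i], offset = a, len = fa - a,
                     as_frac = sr$antisense$body)
      strata[[length(strata) + 1L]] <-
        data.frame(name = five$name[1L], offset = fa, len = fb - fa,
                   as_frac = sr$antisense$five_prime)
      if (fb < b) strata[[length(strata) + 1L]] <-
          data.frame(name = prim$name[i], offset = fb, len = b - fb,
                     as_frac = sr$antisense$body)
    } else {
      strata[[length(strata) + 1L]] <-
        data.frame(name = prim$name[i], offset = a, len = b - a,
                   as_frac = sr$antisense$body)
    }
  }
  prim_strata <- do.call(rbind, strata)
  locus_seq <- refs$refs[[gene$reference_id]]
  out$primary <- alloc_reads(sr$counts$primary, prim_strata, lens_probs,
                             sr$antisense$body, mult_of("primary"),
                             locus_seq, gene$reference_id, "primary",
                             sample$id, counter)

  # expected 23 nt antisense per-base coverage of the transgene-covered
  # region at *baseline* composition (multipliers excluded): secondary
  # abundance is anchored to what the primary population would be without
  # the knockdown, so the secondary multiplier alone carries the knockdown
  # response
  base_tab <- quota_table(sr$counts$primary, prim_strata, lens_probs,
                          sr$antisense$body)
  p23 <- if (!is.null(base_tab)) {
    sel <- base_tab$length == 23L & base_tab$orientation == "antisense"
    sum(base_tab$count[sel]) * 23 / sum(prim_strata$len)
  } else 0
  sec <- regions[regions$role == "secondary_only", , drop = FALSE]
  sec <- sec[order(sec$start), , drop = FALSE]
  fracs <- rep_len(unlist(sr$secondary_fractions), nrow(sec))
  for (i in seq_len(nrow(sec))) {
    L_k <- sec$end[i] - sec$start[i]
    n_23as <- round(fracs[i] * p23 * L_k / 23)
    n_as <- round(n_23as / unlist(lens_probs)[["23"]])
    asf <- sr$antisense$secondary
    n_tot <- round(n_as / asf)
    st_i <- data.frame(name = sec$name[i], offset = sec$start[i], len = L_k,
                       as_frac = asf)
    out[[paste0("secondary_", i)]] <-
      alloc_reads(n_tot, st_i, lens_probs, asf, mult_of("secondary"),
                  locus_seq, gene$reference_id, "secondary", sample$id,
                  counter)
  }

  # exon-exon junction reads from the spliced mRNA
  n_j <- sr$counts$junction
  if (n_j > 0L) {
    ss <- spliced_sequence(gene)
    mult <- mult_of("junction")
    per_j <- quota_alloc(n_j, rep(1, length(ss$junctions)))
    rows <- list()
    for (j in seq_along(ss$junctions)) {
      if (per_j[j] == 0L) next
      asf <- sr$antisense$junction
      n_as <- round(per_j[j] * asf * mult[["antisense"]])
      n_s <- round(per_j[j] * (1 - asf) * mult[["sense"]])
      for (ori in c("sense", "antisense")) {
        n_ori <- if (ori == "sense") n_s else n_as
        if (n_ori <= 0L) next
        per_len <- quota_alloc(n_ori, unlist(lens_probs))
        lens <- as.integer(names(lens_probs))
        for (li in seq_along(lens)) {
          k <- per_len[li]
          if (k == 0L) next
          L <- lens[li]
          ov <- 4L + sample.int(L - 8L + 1L, k, replace = TRUE) - 1L
          st <- ss$junctions[j] - ov
          seq <- substring(ss$seq, st + 1L, st + L)
          if (ori == "antisense") seq <- revcomp_chr(seq)
          i0 <- counter$n; counter$n <- counter$n + k
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = sprintf("%s_%s_%06d", sample$id, "primary", i0 + seq_len(k)),
            seq = seq, class = "primary", region = sprintf("junction_%d", j),
            reference_id = "target_mrna", start = st, length = L,
            orientation = ori, stringsAsFactors = FALSE)
        }
      }
    }
    out$junction <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(out$junction)) out$junction$template <- "mrna"
  }

  simple <- function(class, count, ref_id, seq, asf, offset = 0L,
                     len = nchar(seq), region = ref_id, mult = c(sense = 1, antisense = 1)) {
    alloc_reads(count, data.frame(name = region, offset = offset, len = len,
                                  as_frac = asf),
                lens_probs, asf, mult, seq, ref_id, class, sample$id, counter)
  }
  out$background <- simple("background", sr$counts$background, "background",
                           refs$refs[["background"]], sr$antisense$background)
  out$contaminant <- simple("contaminant", sr$counts$contaminant,
                            "contaminant_1", refs$contaminant_refs[["contaminant_1"]],
                            sr$antisense$other)
  out$structural <- simple("structural", sr$counts$structural, "structural_rna",
                           refs$refs[["structural_rna"]], sr$antisense$other)

  # feeding: vector-insert siRNAs plus knockdown-induced siRNAs from the fed
  # gene outside the insert
  fed <- sample$feeding
  vec_id <- refs$vector_of[[fed]]
  fed_seq <- refs$refs[[fed]]
  ins <- refs$insert_of[[fed]]
  out$feeding_vector <- simple("feeding", sr$counts$feeding_vector, vec_id,
                               refs$refs[[vec_id]], sr$antisense$other,
                               region = "feeding_vector")
  outside <- data.frame(
    name = c("feeding_gene_5p", "feeding_gene_3p"),
    offset = c(0L, ins[2L]),
    len = c(ins[1L], nchar(fed_seq) - ins[2L]),
    as_frac = sr$antisense$body)
  outside <- outside[outside$len >= 25L, , drop = FALSE]
  out$feeding_induced <- alloc_reads(sr$counts$feeding_induced, outside,
                                     lens_probs, sr$antisense$body,
                                     c(sense = 1, antisense = 1), fed_seq,
                                     fed, "feeding", sample$id, counter)

  parts <- Filter(Negate(is.null), unname(out))
  parts <- lapply(parts, function(d) {
    if (is.null(d$template)) d$template <- "genomic"
    d
  })
  truth <- do.call(rbind, parts)
  truth$sample_id <- sample$id
  rownames(truth) <- NULL
  list(reads = truth[, c("read_id", "seq")], truth = truth)
}

# -- long-read simulation ----------------------------------------------------

#' Simulate long RNA-seq reads with per-intron retention
#'
#' Fragments are parameterized by a fixed-width genomic window with a
#' uniformly drawn start; the emitted read is the transcript-coherent
#' subsequence inside that window (so a read over a spliced intron is
#' shorter by the intron length). Each sense read comes from its own
#' transcript copy in which every intron is retained independently with the
#' configured probability. A configurable fraction of reads is antisense
#' (bidirectional transcription): sense introns are retained and a planted
#' antisense intron is spliced out with its own probability.
#'
#' @param cfg a `SimConfig`.
#' @param refs reference bundle from [build_references()].
#' @param retention optional override of the per-intron retention
#'   probability.
#' @param n_reads optional override of the read count.
#' @return list with `reads` and `truth` (orientation, window start,
#'   per-intron retention, antisense-intron splice status).
#' @export
simulate_long_rnas <- function(cfg, refs, retention = NULL, n_reads = NULL) {
  set.seed(derive_seed(cfg$seed, "longrna"))
  lr <- cfg$longrna
  p <- retention %||% lr$retention
  n <- n_reads %||% lr$n_reads
  gene <- refs$gene
  sp <- gene_span(gene)
  G <- sp[2L] - sp[1L]
  W <- as.integer(lr$window)
  if (W > G) stop("read window longer than the transcript span")
  pre <- gene_pre_mrna(gene)
  intr <- gene_introns(gene)
  ia <- intr[, "start"] - sp[1L]; ib <- intr[, "end"] - sp[1L]
  n_int <- nrow(intr)
  n_as <- round(n * lr$antisense_fraction)
  n_s <- n - n_as

  starts <- sample.int(G - W + 1L, n, replace = TRUE) - 1L
  orientation <- rep(c("sense", "antisense"), c(n_s, n_as))
  retained <- matrix(TRUE, nrow = n, ncol = max(n_int, 1L))
  if (n_int && n_s)
    retained[seq_len(n_s), ] <- matrix(stats::runif(n_s * n_int) < p,
                                       nrow = n_s)
  asi <- as.integer(unlist(lr$antisense_intron))
  as_spliced <- rep(FALSE, n)
  if (n_as)
    as_spliced[n_s + seq_len(n_as)] <-
      stats::runif(n_as) < lr$antisense_intron_splice_prob

  # transcript-coherent subsequence of window [S, S+W) given removed
  # intervals (vectorized per unique removal pattern)
  kept_before <- function(pos, rem_a, rem_b) {
    k <- pos
    for (j in seq_along(rem_a))
      k <- k - pmax(0L, pmin(pos, rem_b[j]) - rem_a[j]) * (pos > rem_a[j])
    k
  }
  seqs <- character(n)
  pat <- if (n_int) apply(retained, 1L, function(r) paste(as.integer(r), collapse = "")) else rep("", n)
  pat[orientation == "antisense"] <- paste0(pat[orientation == "antisense"],
                                            "|as", as.integer(as_spliced[orientation == "antisense"]))
  for (pt in unique(pat)) {
    sel <- which(pat == pt)
    first <- sel[1L]
    rem_a <- integer(0); rem_b <- integer(0)
    if (n_int) {
      spl <- !retained[first, ]
      rem_a <- ia[spl]; rem_b <- ib[spl]
    }
    if (orientation[first] == "antisense" && as_spliced[first]) {
      rem_a <- c(rem_a, asi[1L]); rem_b <- c(rem_b, asi[2L])
    }
    o <- order(rem_a); rem_a <- rem_a[o]; rem_b <- rem_b[o]
    iso_seq <- if (length(rem_a)) {
      keep_a <- c(0L, rem_b); keep_b <- c(rem_a, G)
      ok <- keep_b > keep_a
      paste(subseq_chr(pre, keep_a[ok], keep_b[ok]), collapse = "")
    } else pre
    a <- kept_before(starts[sel], rem_a, rem_b)
    b <- kept_before(starts[sel] + W, rem_a, rem_b)
    seqs[sel] <- substring(iso_seq, a + 1L, b)
  }
  anti <- orientation == "antisense"
  if (any(anti)) seqs[anti] <- revcomp_chr(seqs[anti])
  if (any(nchar(seqs) < 1L)) stop("degenerate read of zero length")
  truth <- data.frame(
    read_id = sprintf("long_%06d", seq_len(n)),
    orientation = orientation, window_start = starts,
    length = nchar(seqs),
    retained = if (n_int) apply(retained, 1L, function(r) paste(as.integer(r), collapse = "")) else "",
    antisense_intron_spliced = as_spliced, stringsAsFactors = FALSE)
  list(reads = data.frame(read_id = truth$read_id, seq = seqs,
                          stringsAsFactors = FALSE),
       truth = truth)
}

# -- cohort ------------------------------------------------------------------

#' Simulate a full cohort (control + knockdown samples)
#'
#' Knockdown samples have class-specific siRNA counts scaled by their
#' configured multipliers and carry feeding reads against the knockdown
#' gene; the control carries feeding reads against a neutral gene.
#'
#' @param cfg a `SimConfig`.
#' @param refs optional pre-built reference bundle.
#' @return list with `refs`, per-sample `samples` (each with `reads`,
#'   `truth`) and `long` (long-read simulation).
#' @export
simulate_cohort <- function(cfg, refs = NULL) {
  roles <- vapply(cfg$samples, `[[`, character(1), "role")
  if (sum(roles == "control") != 1L)
    stop("cohort must contain exactly one control sample")
  if (is.null(refs)) refs <- build_references(cfg)
  samples <- list()
  for (s in cfg$samples) {
    samples[[s$id]] <- simulate_small_rnas(cfg, refs, s)
    samples[[s$id]]$role <- s$role
    samples[[s$id]]$feeding <- s$feeding
  }
  list(refs = refs, samples = samples,
       long = simulate_long_rnas(cfg, refs))
}

# -- ChIP Ct tables ----------------------------------------------------------

#' Simulate a ChIP-qPCR Ct table with planted enrichments
#'
#' Generates one row per well for a wild-type and a transgene-silenced
#' sample over four antibodies and three loci, with configured true
#' percent-input values, multiplicative biological variability (log2 scale)
#' and technical Ct noise. The default plant reproduces the silencing
#' signature: increased H3 occupancy at the target, loss of active marks,
#' and an H3-occupancy-corrected H3K27me3 gain of 4-fold at the target
#' 3' CDS.
#'
#' @param seed RNG seed.
#' @param truth optional data.frame `sample_id`, `antibody`, `locus`,
#'   `percent_input` of true values (defaults to the planted design).
#' @param n_bio,n_tech replicate counts.
#' @param tech_sd technical Ct noise SD (cycles).
#' @param bio_sd_log2 biological variability SD on the log2 enrichment
#'   scale.
#' @param input_fraction input chromatin fraction.
#' @return list with `records` (Ct table for [chip_report()]) and `truth`.
#' @export
simulate_chip_ct <- function(seed = 1L, truth = NULL, n_bio = 3L, n_tech = 3L,
                             tech_sd = 0.02, bio_sd_log2 = 0.01,
                             input_fraction = 0.10) {
  set.seed(derive_seed(seed, "chip"))
  if (is.null(truth)) truth <- default_chip_truth()
  base_ct <- c(target_5prime = 24, target_3prime = 24.5,
               reference_promoter = 25)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (br in seq_len(n_bio)) {
      pi_rep <- truth$percent_input[i] * 2^stats::rnorm(1, 0, bio_sd_log2)
      for (tr in seq_len(n_tech)) {
        ct_in <- base_ct[[truth$locus[i]]] + stats::rnorm(1, 0, tech_sd)
        ct_adj <- ct_in - log2(1 / input_fraction)
        ct_ip <- ct_adj - log2(pi_rep / 100) + stats::rnorm(1, 0, tech_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = truth$sample_id[i], antibody = truth$antibody[i],
          locus = truth$locus[i], ct_ip = ct_ip, ct_input = ct_in,
          input_fraction = input_fraction, bio_rep = br, tech_rep = tr,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rows), truth = truth)
}

#' Default planted ChIP truth (percent input per sample/antibody/locus)
#' @return data.frame used by [simulate_chip_ct()].
#' @export
default_chip_truth <- function() {
  g <- expand.grid(
    sample_id = c("wild_type", "transgenic"),
    antibody = c("H3", "H3K9ac", "H3K4me3", "H3K27me3"),
    locus = c("target_5prime", "target_3prime", "reference_promoter"),
    stringsAsFactors = FALSE)
  val <- function(s, ab, loc) {
    if (ab == "H3") return(if (s == "transgenic" && loc != "reference_promoter") 15 else 10)
    if (ab == "H3K27me3") {
      if (loc == "reference_promoter") return(1)
      if (s == "wild_type") return(0.5)
      # transgenic: H3-corrected 4-fold gain at the 3' CDS, 2-fold at 5'
      return(if (loc == "target_3prime") 3.0 else 1.5)
    }
    # active marks: enriched when expressed, depleted when silenced
    if (loc == "reference_promoter") return(6)
    if (s == "wild_type") return(8)
    2
  }
  g$percent_input <- mapply(val, g$sample_id, g$antibody, g$locus)
  g
}
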