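#' Knockdown-aware total-count-scaling normalization
#'
#' Sequencing depth differs between libraries, and knockdown libraries are
#' additionally flooded with siRNAs against the knockdown gene itself, which
#' would bias a plain total-count scaling factor. The effective library size
#' of a sample is therefore `T - K`, where `T` counts genome-mapped reads
#' after removing structural-RNA and feeding-vector reads, and `K` counts
#' the reads (within `T`) that map to the knockdown gene. The normalized
#' count of a region with raw count `R` is
#'
#'   R_hat = R * M / (T - K),   M = max_i (T_i - K_i) over the cohort,
#'
#' so exactly one sample (the arg-max) keeps its raw counts and all scaling
#' factors are >= 1.
#'
#' @name normalization
NULL

#' Compute the T and K bookkeeping quantities for one sample
#'
#' @param aln_result result of [two_round_align()] for this sample.
#' @param genome_refs reference ids that constitute the genome (reads must
#'   hit at least one of these to count towards `T`).
#' @param exclude_refs reference ids whose exact-match membership removes a
#'   read from `T` (structural-RNA loci, feeding-vector inserts).
#' @param knockdown_refs reference ids of the knockdown gene(s); reads in
#'   `T` hitting any of them constitute `K`.
#' @param sample_id sample label.
#' @return An object of class `SampleLibrary` with elements `sample_id`,
#'   `T`, `K`.
#' @export
compute_t_k <- function(aln_result, genome_refs, exclude_refs = character(0),
                        knockdown_refs = character(0), sample_id = "sample") {
  aln <- aln_result$alignments
  in_genome <- unique(aln$read_id[aln$reference_id %in% genome_refs])
  excluded <- unique(aln$read_id[aln$reference_id %in% exclude_refs])
  t_ids <- setdiff(in_genome, excluded)
  t_count <- length(t_ids)
  k_count <- if (length(knockdown_refs))
    length(intersect(t_ids,
                     aln$read_id[aln$reference_id %in% knockdown_refs]))
  else 0L
  if (t_count <= k_count)
    stop(sprintf("degenerate library %s: T (%d) <= K (%d)",
                 sample_id, t_count, k_count))
  structure(list(sample_id = sample_id, T = as.integer(t_count),
                 K = as.integer(k_count)),
            class = "SampleLibrary")
}

#' @export
print.SampleLibrary <- function(x, ...) {
  cat(sprintf("SampleLibrary %s: T = %d, K = %d, T - K = %d\n",
              x$sample_id, x$T, x$K, x$T - x$K))
  invisible(x)
}

#' Cohort scaling factors
#'
#' @param libraries list of `SampleLibrary` objects (the full cohort; `M` is
#'   computed once per invocation over all supplied samples).
#' @return An object of class `CohortScaling`: `M` and a data.frame
#'   `factors` with `sample_id`, `T`, `K`, `factor = M / (T - K)`.
#' @export
cohort_scaling <- function(libraries) {
  stopifnot(length(libraries) >= 1L,
            all(vapply(libraries, inherits, logical(1), "SampleLibrary")))
  tk <- vapply(libraries, function(l) l$T - l$K, numeric(1))
  M <- max(tk)
  factors <- data.frame(
    sample_id = vapply(libraries, `[[`, character(1), "sample_id"),
    T = vapply(libraries, `[[`, integer(1), "T"),
    K = vapply(libraries, `[[`, integer(1), "K"),
    factor = M / tk, stringsAsFactors = FALSE)
  structure(list(M = M, factors = factors), class = "CohortScaling")
}

#' @export
print.CohortScaling <- function(x, ...) {
  cat(sprintf("CohortScaling: M = %d over %d sample(s)\n",
              as.integer(x$M), nrow(x$factors)))
  print(x$factors)
  invisible(x)
}

scaling_factor <- function(scaling, sample_id) {
  stopifnot(inherits(scaling, "CohortScaling"))
  i <- match(sample_id, scaling$factors$sample_id)
  if (is.na(i)) stop(sprintf("sample %s absent from cohort scaling", sample_id))
  scaling$factors$factor[i]
}

#' Normalize raw counts of one sample
#'
#' `R_hat = R * M / (T - K)`; linear in `R` and invariant under uniform
#' depth scaling of the sample's counts.
#'
#' @param R numeric raw counts.
#' @param sample_id sample the counts belong to.
#' @param scaling a `CohortScaling` containing that sample.
#' @return Normalized counts (floating point).
#' @export
normalize_counts <- function(R, sample_id, scaling) {
  R * scaling_factor(scaling, sample_id)
}

#' Normalize a RegionCounts table
#'
#' Adds `norm_` columns for the count and base columns.
#' @param counts a `RegionCounts` data.frame.
#' @inheritParams normalize_counts
#' @return The table with `norm_sense_count`, `norm_antisense_count`,
#'   `norm_sense_bases`, `norm_antisense_bases` columns added.
#' @export
normalize_region_counts <- function(counts, sample_id, scaling) {
  f <- scaling_factor(scaling, sample_id)
  for (col in c("sense_count", "antisense_count", "sense_bases",
                "antisense_bases"))
    counts[[paste0("norm_", col)]] <- counts[[col]] * f
  counts
}

#' Fold change of normalized counts, knockdown vs control
#'
#' Both samples must have been normalized under the same cohort scaling.
#' Regions whose control normalized count is zero yield `NA` with a warning
#' (no pseudocount is fabricated by default).
#'
#' @param kd_counts,ctrl_counts `RegionCounts` for knockdown and control.
#' @param kd_sample,ctrl_sample sample ids.
#' @param scaling a `CohortScaling`.
#' @param length_of_interest read length compared (default 23).
#' @param orientation `"antisense"` (default), `"sense"` or `"both"`.
#' @param pseudocount optional value added to both normalized counts before
#'   the ratio (default 0 = off).
#' @return data.frame `region`, `role`, `kd_norm`, `ctrl_norm`,
#'   `fold_change`, `log2_fold_change`.
#' @export
fold_change <- function(kd_counts, ctrl_counts, kd_sample, ctrl_sample,
                        scaling, length_of_interest = 23L,
                        orientation = c("antisense", "sense", "both"),
                        pseudocount = 0) {
  orientation <- match.arg(orientation)
  pick <- function(counts) {
    x <- counts[counts$length == length_of_interest, , drop = FALSE]
    v <- switch(orientation,
                antisense = x$antisense_count,
                sense = x$sense_count,
                both = x$sense_count + x$antisense_count)
    data.frame(region = x$region, role = x$role, raw = v,
               stringsAsFactors = FALSE)
  }
  kd <- pick(kd_counts); ct <- pick(ctrl_counts)
  if (!identical(kd$region, ct$region))
    stop("mismatched region definitions between samples")
  kd_norm <- normalize_counts(kd$raw, kd_sample, scaling) + pseudocount
  ct_norm <- normalize_counts(ct$raw, ctrl_sample, scaling) + pseudocount
  fc <- ifelse(ct_norm > 0, kd_norm / ct_norm, NA_real_)
  if (any(ct_norm == 0))
    warning("control normalized count 0 for some region(s); fold change NA")
  data.frame(region = kd$region, role = kd$role, kd_norm = kd_norm,
             ctrl_norm = ct_norm, fold_change = fc,
             log2_fold_change = log2(fc), stringsAsFactors = FALSE)
}
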