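#' ChIP-qPCR enrichment normalization
#'
#' Enrichment is expressed relative to a known fraction of pre-IP chromatin
#' (percent input), optionally normalized to a reference locus (a native
#' promoter unaffected by the silencing) and, for histone modifications, to
#' histone H3 occupancy at the same locus. Amplification efficiency is fixed
#' at 2 (perfect doubling per cycle); the entire arithmetic chain is the
#' standard reconstruction of that description. Technical PCR replicates are
#' averaged on the Ct scale (geometric mean on the quantity scale);
#' biological replicates are summarized on the enrichment scale.
#'
#' @name chipquant
NULL

#' Percent of input from IP and input Ct values
#'
#' `100 * E^(Ct_input_adj - Ct_IP)` with `E = 2` and
#' `Ct_input_adj = Ct_input - log2(1 / input_fraction)` correcting the
#' input Ct to the full-chromatin equivalent.
#'
#' @param ct_ip IP Ct value(s).
#' @param ct_input input Ct value(s).
#' @param input_fraction fraction of chromatin used as input (default 0.10).
#' @param efficiency amplification efficiency (default 2).
#' @return Percent input (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.10,
                          efficiency = 2) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  adj <- ct_input - log(1 / input_fraction, base = efficiency)
  100 * efficiency^(adj - ct_ip)
}

#' Normalize a target enrichment to a reference locus
#' @param target_enr,reference_enr enrichments from the same sample and
#'   antibody.
#' @return `target_enr / reference_enr`.
#' @export
normalize_to_reference <- function(target_enr, reference_enr) {
  if (any(reference_enr == 0)) stop("reference enrichment is zero")
  target_enr / reference_enr
}

#' Normalize a modification enrichment to H3 occupancy at the same locus
#' @param mod_enr modification enrichment.
#' @param h3_enr H3 enrichment at the same locus (must be present).
#' @return `mod_enr / h3_enr`.
#' @export
normalize_to_h3 <- function(mod_enr, h3_enr) {
  if (any(is.na(h3_enr))) stop("missing H3 record for locus")
  if (any(h3_enr == 0)) stop("H3 enrichment is zero")
  mod_enr / h3_enr
}

#' Aggregate a Ct table into an enrichment report
#'
#' Expects one row per well: columns `sample_id`, `antibody`, `locus`,
#' `ct_ip`, `ct_input`, `input_fraction`, `bio_rep`, `tech_rep`. Technical
#' replicates are averaged on the Ct scale first; percent input is computed
#' per biological replicate and summarized as mean and SD across biological
#' replicates (`SD = NA` with a single replicate).
#'
#' @param records Ct-table data.frame.
#' @return data.frame of class `EnrichmentReport`: per (sample, antibody,
#'   locus) `percent_input_mean`, `percent_input_sd`, `n_bio_reps`, plus a
#'   `per_rep` attribute with the per-biological-replicate values.
#' @export
aggregate_replicates <- function(records) {
  req <- c("sample_id", "antibody", "locus", "ct_ip", "ct_input",
           "input_fraction", "bio_rep", "tech_rep")
  if (!all(req %in% names(records)))
    stop("Ct table lacks required columns: ",
         paste(setdiff(req, names(records)), collapse = ", "))
  if (any(records$ct_ip <= 0 | records$ct_ip >= 45 |
          records$ct_input <= 0 | records$ct_input >= 45))
    stop("Ct values must lie in (0, 45)")
  key <- interaction(records$sample_id, records$antibody, records$locus,
                     records$bio_rep, drop = TRUE)
  tech <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(sample_id = d$sample_id[1L], antibody = d$antibody[1L],
               locus = d$locus[1L], bio_rep = d$bio_rep[1L],
               ct_ip = mean(d$ct_ip), ct_input = mean(d$ct_input),
               input_fraction = d$input_fraction[1L],
               stringsAsFactors = FALSE)
  }))
  tech$percent_input <- percent_input(tech$ct_ip, tech$ct_input,
                                      tech$input_fraction)
  key2 <- interaction(tech$sample_id, tech$antibody, tech$locus, drop = TRUE)
  out <- do.call(rbind, lapply(split(tech, key2), function(d) {
    data.frame(sample_id = d$sample_id[1L], antibody = d$antibody[1L],
               locus = d$locus[1L],
               percent_input_mean = mean(d$percent_input),
               percent_input_sd = if (nrow(d) > 1L) stats::sd(d$percent_input) else NA_real_,
               n_bio_reps = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$antibody, out$locus), ]
  rownames(out) <- NULL
  attr(out, "per_rep") <- tech[order(tech$sample_id, tech$antibody,
                                     tech$locus, tech$bio_rep), ]
  class(out) <- c("EnrichmentReport", class(out))
  out
}

#' Full ChIP enrichment report with reference and H3 normalization
#'
#' Per biological replicate, percent input is computed for every
#' (antibody, locus); each target locus is then normalized to the reference
#' locus (same antibody) and each modification additionally to H3 occupancy
#' at the same locus relative to H3 at the reference. Replicate chains are
#' evaluated per biological replicate and then averaged.
#'
#' @param records Ct-table data.frame (see [aggregate_replicates()]).
#' @param reference_locus locus used for reference normalization.
#' @param h3_antibody antibody name of unmodified H3 (default `"H3"`).
#' @return data.frame: per (sample, antibody, locus) `percent_input`,
#'   `ref_norm` (target/reference), `h3_norm` (ref_norm of the modification
#'   divided by ref_norm of H3; `NA` for the H3 rows themselves), each as
#'   mean and SD over biological replicates.
#' @export
chip_report <- function(records, reference_locus = "reference_promoter",
                        h3_antibody = "H3") {
  rep_tab <- attr(aggregate_replicates(records), "per_rep")
  if (!reference_locus %in% rep_tab$locus)
    stop("reference locus absent from Ct table")
  out <- list()
  for (s in unique(rep_tab$sample_id)) {
    ds <- rep_tab[rep_tab$sample_id == s, , drop = FALSE]
    for (ab in unique(ds$antibody)) {
      d <- ds[ds$antibody == ab, , drop = FALSE]
      h3 <- ds[ds$antibody == h3_antibody, , drop = FALSE]
      for (loc in setdiff(unique(d$locus), reference_locus)) {
        per_rep <- vapply(unique(d$bio_rep), function(br) {
          pi_t <- d$percent_input[d$locus == loc & d$bio_rep == br]
          pi_r <- d$percent_input[d$locus == reference_locus & d$bio_rep == br]
          if (!length(pi_t) || !length(pi_r)) return(c(NA_real_, NA_real_, NA_real_))
          rn <- normalize_to_reference(pi_t, pi_r)
          hn <- NA_real_
          if (ab != h3_antibody && nrow(h3)) {
            h3_t <- h3$percent_input[h3$locus == loc & h3$bio_rep == br]
            h3_r <- h3$percent_input[h3$locus == reference_locus & h3$bio_rep == br]
            if (length(h3_t) && length(h3_r))
              hn <- normalize_to_h3(rn, normalize_to_reference(h3_t, h3_r))
          }
          c(pi_t, rn, hn)
        }, numeric(3))
        msd <- function(v) c(mean = mean(v[!is.na(v)]),
                             sd = if (sum(!is.na(v)) > 1L) stats::sd(v[!is.na(v)]) else NA_real_)
        pi_ <- msd(per_rep[1L, ]); rn_ <- msd(per_rep[2L, ]); hn_ <- msd(per_rep[3L, ])
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, antibody = ab, locus = loc,
          percent_input = pi_[1L], percent_input_sd = pi_[2L],
          ref_norm = rn_[1L], ref_norm_sd = rn_[2L],
          h3_norm = if (ab == h3_antibody) NA_real_ else hn_[1L],
          h3_norm_sd = if (ab == h3_antibody) NA_real_ else hn_[2L],
          n_bio_reps = length(unique(d$bio_rep)), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$antibody, res$locus), ]
  rownames(res) <- NULL
  res
}
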