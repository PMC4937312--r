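# Internal helpers shared across modules. Intervals are 0-based half-open
# throughout the package internals; 1-based coordinates appear only at the
# BED/GFF3/SAM/bedGraph boundaries and in printed reports.

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each simulator stage draws from its own stream so that adding or reordering
#' stages never perturbs the output of earlier ones. The derived seed is kept
#' below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Largest-remainder integer allocation of n among classes with weights
# `probs`. Deterministic (ties broken by index order); sums exactly to n.
quota_alloc <- function(n, probs) {
  stopifnot(n >= 0, all(probs >= 0), sum(probs) > 0)
  probs <- probs / sum(probs)
  raw <- n * probs
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Random AT-rich DNA (Paramecium-like base composition).
random_dna <- function(n, at = 0.72) {
  if (n == 0L) return("")
  p <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = p),
        collapse = "")
}

revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open interval utilities (matrices with columns start, end).
iv <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (any(m[, "end"] < m[, "start"])) stop("interval end < start")
  m
}

iv_width <- function(m) m[, "end"] - m[, "start"]

iv_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}

# Validate a list of 0-based half-open intervals for non-overlap.
check_disjoint <- function(m, what = "intervals") {
  if (nrow(m) < 2L) return(invisible(TRUE))
  o <- order(m[, "start"])
  m <- m[o, , drop = FALSE]
  if (any(m[-1L, "start"] < m[-nrow(m), "end"]))
    stop(sprintf("overlapping %s", what))
  invisible(TRUE)
}

subseq_chr <- function(seq, start0, end0) {
  # vectorized 0-based half-open substring
  substring(seq, start0 + 1L, end0)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
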