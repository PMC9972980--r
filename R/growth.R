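# In situ growth: an iRep-style replication index from the
# origin-to-terminus coverage gradient, and mismatch-filtered relative
# abundance.

#' Replication index from a coverage gradient
#'
#' Sliding-window mean coverages (window `window`, slide `step`, computed on
#' the per-position coverage concatenated across contigs in genome order)
#' are sorted ascending; the lowest and highest `trim` fractions are removed
#' as outliers; a least-squares line is fit to log2(coverage) against the
#' window's original rank scaled to \[0, 1\]; the index is
#' `2^(fit(1) - fit(0))`.  Sorting before fitting removes any dependence on
#' knowing where the replication origin lies.  A perfectly flat coverage
#' yields index 1 and, by convention, `fit_r2 = 1` (zero-variance fit).
#'
#' @param pileup In-memory pileup data.frame (`depth` column used).
#' @param window Window size in bases.
#' @param step Slide in bases.
#' @param trim Fraction of windows trimmed at each extreme.
#' @param min_windows Minimum number of windows required.
#' @return List with `index`, `fit_r2`, `slope` (log2 coverage across the
#'   genome-fraction axis), `windows_used`, and `reason` (`NA` on success).
#'   On failure `index` is `NA` and `reason` explains why.
#' @export
replicationIndex <- function(pileup, window = 5000L, step = 100L,
                             trim = 0.05, min_windows = 20L) {
  fail <- function(why) list(index = NA_real_, fit_r2 = NA_real_,
                             slope = NA_real_, windows_used = 0L,
                             reason = why)
  cov <- pileup$depth[order(pileup$contig, pileup$pos)]
  L <- length(cov)
  if (L < window) return(fail("covered length shorter than one window"))
  starts <- seq(1L, L - window + 1L, by = step)
  if (length(starts) < min_windows)
    return(fail(sprintf("fewer than %d windows", min_windows)))
  cs <- cumsum(c(0, cov))
  wmean <- (cs[starts + window] - cs[starts]) / window
  ord <- order(wmean)
  n <- length(wmean)
  lo <- floor(trim * n)
  keep_ranks <- seq.int(lo + 1L, n - lo)
  vals <- wmean[ord][keep_ranks]
  if (any(vals <= 0))
    return(fail("retained window with zero coverage"))
  x <- (keep_ranks - 1) / (n - 1)          # original rank scaled to [0, 1]
  y <- log2(vals)
  if (stats::sd(y) == 0) {
    return(list(index = 1.0, fit_r2 = 1.0, slope = 0,
                windows_used = length(vals), reason = NA_character_))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(index = 2^slope, fit_r2 = r2, slope = slope,
       windows_used = length(vals), reason = NA_character_)
}

#' Mismatch-filtered relative abundance
#'
#' Reads mapping with at least `max_mismatches_exclusive` mismatches are
#' discarded (they likely originate from closely related strains); the
#' relative abundance is kept reads over the sample's total read count.
#'
#' @param reads Read-summary data.frame with a `mismatches` column.
#' @param total Total reads in the sample; defaults to the mapped reads in
#'   `reads` (abundance 1 means every sample read maps cleanly).
#' @param max_mismatches_exclusive Reads with this many mismatches or more
#'   are discarded.
#' @return List with `mapped_reads_kept`, `reads_discarded_by_mismatch`,
#'   `total_sample_reads`, `relative_abundance`.
#' @export
relativeAbundance <- function(reads, total = nrow(reads),
                              max_mismatches_exclusive = 2L) {
  if (is.null(total) || total <= 0) stop("total read count must be > 0")
  kept <- sum(reads$mismatches < max_mismatches_exclusive)
  discarded <- nrow(reads) - kept
  if (kept + discarded > total)
    stop("mapped reads exceed the sample's total read count")
  list(mapped_reads_kept = kept,
       reads_discarded_by_mismatch = discarded,
       total_sample_reads = total,
       relative_abundance = kept / total)
}
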