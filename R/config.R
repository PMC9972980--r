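# Flat key=value run configuration.  Every threshold used anywhere in the
# pipeline is a named key with its documented default, so a run's effective
# parameters are auditable from one place.

#' Default analysis thresholds
#'
#' Returns the full set of named thresholds with their defaults: variant
#' filters (`min_depth` 8, `min_vaf` 0.20, `dominant_vaf` 0.80), the
#' heterogeneity flag (`snps_per_kb_flag` 5), minor-lineage tracking
#' (`minor_max_vaf` 0.50, `min_shared_snps` 20), quasi-coding-sequence
#' filters (`quasi_min_depth` 10, `quasi_min_vaf` 0.50), the fixed-mutation
#' threshold (`fixed_vaf` 0.80), gene-flux bounds (`flux_target_max` 3,
#' `flux_ref_min` 10), the mutation rate (`mu` 7e-7 per base per year),
#' replication-index windows (`irep_window` 5000, `irep_step` 100,
#' `irep_trim` 0.05, `irep_min_windows` 20), the abundance mismatch filter
#' (`max_mismatches` 2) and ANI fragments (`ani_fragment` 1000,
#' `ani_min_identity` 0.8).
#'
#' @param ... Overrides as `name = value`.
#' @return Named list of thresholds.
#' @export
lumenThresholds <- function(...) {
  defaults <- list(
    min_depth = 8L, min_vaf = 0.20, dominant_vaf = 0.80,
    snps_per_kb_flag = 5, minor_max_vaf = 0.50, min_shared_snps = 20L,
    quasi_min_depth = 10L, quasi_min_vaf = 0.50, fixed_vaf = 0.80,
    flux_target_max = 3L, flux_ref_min = 10L, mu = 7e-7,
    irep_window = 5000L, irep_step = 100L, irep_trim = 0.05,
    irep_min_windows = 20L, max_mismatches = 2L,
    ani_fragment = 1000L, ani_min_identity = 0.8)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  .validateThresholds(defaults)
  defaults
}

.validateThresholds <- function(th) {
  chk <- function(ok, what) if (!ok) stop("threshold out of range: ", what)
  chk(th$min_depth >= 1, "min_depth")
  chk(th$min_vaf > 0 && th$min_vaf <= 1, "min_vaf")
  chk(th$dominant_vaf > 0 && th$dominant_vaf <= 1, "dominant_vaf")
  chk(th$minor_max_vaf >= th$min_vaf && th$minor_max_vaf <= 1,
      "minor_max_vaf")
  chk(th$quasi_min_vaf > 0 && th$quasi_min_vaf <= 1, "quasi_min_vaf")
  chk(th$fixed_vaf > 0 && th$fixed_vaf <= 1, "fixed_vaf")
  chk(th$mu > 0, "mu")
  chk(th$irep_trim >= 0 && th$irep_trim < 0.5, "irep_trim")
  invisible(th)
}

#' Read a flat key=value run configuration
#'
#' Parses a text file of `key = value` lines (`#` comments allowed; values
#' may be numbers, `true`/`false`, or quoted strings).  Threshold keys are
#' merged over [lumenThresholds()] defaults; any other keys are returned
#' under `$extra`.
#'
#' @param path Config file path.
#' @return List with `thresholds` and `extra`.
#' @export
readRunConfig <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed config line: ", ln[which(bad)[1]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    v <- sub('^"(.*)"$', "\\1", v)
    if (tolower(v) %in% c("true", "false")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  th_keys <- intersect(keys, names(lumenThresholds()))
  thresholds <- do.call(lumenThresholds, vals[th_keys])
  list(thresholds = thresholds, extra = vals[setdiff(keys, th_keys)])
}
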