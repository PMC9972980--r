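# End-to-end per-individual orchestration.  Stages run in dependency order
# (variants -> tracking / flux / selection / growth); a failure in one stage
# is recorded as skipped-with-reason and never aborts the others, because
# partially analyzable individuals (a site without coverage, a missing read
# summary) are the norm in this study design.

.stage <- function(name, expr, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(
    list(status = "ok", value = force(expr), reason = NULL),
    error = function(e) list(status = "skipped", value = NULL,
                             reason = conditionMessage(e)))
  if (verbose)
    message(sprintf("[%s] %s (%.2fs)%s", name, res$status,
                    proc.time()[["elapsed"]] - t0,
                    if (is.null(res$reason)) "" else paste0(": ", res$reason)))
  res
}

.loadGenomeInput <- function(x) {
  if (methods::is(x, "AnnotatedGenome")) return(x)
  if (is.list(x)) return(readAnnotatedGenome(x$genome, x$genes))
  stop("reference must be an AnnotatedGenome or list(genome=, genes=)")
}

.loadPileupInput <- function(x) {
  if (is.data.frame(x)) return(validatePileup(x))
  readPileupTable(x)
}

.loadReadsInput <- function(x) {
  if (is.data.frame(x)) return(x)
  readReadSummary(x)
}

#' Run the full per-individual analysis
#'
#' Consumes a manifest describing one individual — a reference genome with
#' gene coordinates, and per site a pileup table (reads of that site mapped
#' against the reference) and optionally a read summary — and produces a
#' machine-readable report: heterogeneity per site, SNP-distance matrix
#' against the reference, minor-lineage evidence, gene-flux calls, the
#' selection summary (dN/dS, fixed mutations, divergence time), resistance
#' genotype, and replication index plus relative abundance per site.  Every
#' section is present or explicitly marked skipped-with-reason.
#'
#' @param manifest List with elements `reference` (an
#'   [AnnotatedGenome-class] or `list(genome = fasta, genes = gff)`),
#'   `sites` (named list; each element a list with `pileup` and optionally
#'   `reads`, as paths or data.frames), and optionally `individual`,
#'   `gyrA_id`, `parC_id`.
#' @param thresholds From [lumenThresholds()] or [readRunConfig()].
#' @param seed Integer seed (currently only recorded; all stages are
#'   deterministic).
#' @param out_dir If non-`NULL`, the report JSON is written there.
#' @param verbose Log stage names and elapsed times (results are unchanged).
#' @return The report list; `$errors` counts skipped stages.
#' @export
runIndividual <- function(manifest, thresholds = lumenThresholds(),
                          seed = 1L, out_dir = NULL, verbose = FALSE) {
  .validateThresholds(thresholds)
  if (is.null(manifest$sites) || !length(manifest$sites))
    stop("manifest must list at least one site")
  if (is.null(names(manifest$sites)))
    stop("manifest$sites must be named by site label")
  ref <- .loadGenomeInput(manifest$reference)
  sites <- names(manifest$sites)
  pileups <- list()
  reads <- list()
  for (s in sites) {
    pileups[[s]] <- .stage(paste0("load/", s), {
      if (is.null(manifest$sites[[s]]$pileup)) stop("no pileup provided")
      .loadPileupInput(manifest$sites[[s]]$pileup)
    }, verbose)
    reads[[s]] <- .stage(paste0("reads/", s), {
      if (is.null(manifest$sites[[s]]$reads))
        stop("no read summary provided")
      .loadReadsInput(manifest$sites[[s]]$reads)
    }, verbose)
  }
  th <- thresholds
  report <- list(individual = manifest$individual, seed = seed,
                 thresholds = th)

  calls <- list()
  for (s in sites) {
    calls[[s]] <- .stage(paste0("variants/", s), {
      p <- pileups[[s]]
      if (p$status != "ok") stop(p$reason)
      cs <- callSnps(p$value, min_depth = th$min_depth,
                     min_vaf = th$min_vaf)
      flagDominant(annotateEffects(cs, ref), threshold = th$dominant_vaf)
    }, verbose)
  }
  report$heterogeneity <- lapply(sites, function(s) .stage(
    paste0("heterogeneity/", s), {
      p <- pileups[[s]]
      if (p$status != "ok") stop(p$reason)
      heterogeneity(p$value, min_depth = th$min_depth)
    }, verbose))
  names(report$heterogeneity) <- sites

  report$snp_distance <- lapply(sites, function(s) .stage(
    paste0("snp_distance/", s), {
      p <- pileups[[s]]
      if (p$status != "ok") stop(p$reason)
      d <- snpDistance(p$value, min_depth = th$min_depth,
                       min_vaf = th$min_vaf)
      d$calls <- NULL
      d
    }, verbose))
  names(report$snp_distance) <- sites

  report$minor_lineage <- .stage("minor_lineage", {
    ok <- sites[vapply(pileups, function(p) p$status == "ok", TRUE)]
    if (length(ok) < 2) stop("fewer than two sites with pileups")
    ev <- detectMinorLineage(lapply(pileups[ok], `[[`, "value"), ref,
                             min_depth = th$min_depth, min_vaf = th$min_vaf,
                             max_vaf = th$minor_max_vaf,
                             min_shared = th$min_shared_snps,
                             individual = manifest$individual)
    ev$shared_snps <- NULL
    ev
  }, verbose)

  report$gene_flux <- .stage("gene_flux", {
    ok <- sites[vapply(reads, function(r) r$status == "ok", TRUE)]
    if (length(ok) < 2) stop("fewer than two sites with read summaries")
    cols <- lapply(reads[ok], function(r) geneReadCounts(r$value, ref))
    tab <- geneCoverageTable(cols)
    out <- list()
    for (a in ok) for (b in setdiff(ok, a)) {
      fx <- detectFlux(tab, reference_sample = a, target_sample = b,
                       target_max = th$flux_target_max,
                       ref_min = th$flux_ref_min)
      out[[paste(a, "vs", b)]] <-
        list(missing = fx$gene_id[fx$status == "missing"],
             n_missing = sum(fx$status == "missing"),
             n_genes = nrow(fx))
    }
    out
  }, verbose)

  report$selection <- .stage("selection", {
    ok <- sites[vapply(calls, function(x) x$status == "ok", TRUE)]
    if (!length(ok)) stop("no callable site")
    per_site <- lapply(ok, function(s) {
      q <- buildQuasiCds(calls[[s]]$value, ref,
                         min_mean_depth = th$quasi_min_depth,
                         min_vaf = th$quasi_min_vaf)
      dn <- if (nzchar(q$ref_seq)) dnds(q) else
        list(Sd = 0, Nd = 0, S = 0, N = 0, omega = NA_real_,
             interpretation = NA_character_)
      fx <- fixedMutations(calls[[s]]$value, threshold = th$fixed_vaf)
      list(dnds = dn, fixed = fx)
    })
    names(per_site) <- ok
    fixed_all <- unique(do.call(rbind, lapply(per_site, function(x)
      x$fixed[, c("contig", "pos", "alt")])))
    div <- divergenceTime(nrow(fixed_all), genomeLength(ref), mu = th$mu)
    list(per_site = lapply(per_site, function(x)
           c(x$dnds, list(fixed_mutations = nrow(x$fixed)))),
         unique_fixed_mutations = nrow(fixed_all),
         divergence = div)
  }, verbose)

  report$resistance <- .stage("resistance", {
    if (is.null(manifest$gyrA_id) || is.null(manifest$parC_id))
      stop("gyrA_id/parC_id not provided in manifest")
    resistanceGenotype(ref, manifest$gyrA_id, manifest$parC_id)
  }, verbose)

  report$growth <- lapply(sites, function(s) .stage(
    paste0("growth/", s), {
      p <- pileups[[s]]
      if (p$status != "ok") stop(p$reason)
      ri <- replicationIndex(p$value, window = th$irep_window,
                             step = th$irep_step, trim = th$irep_trim,
                             min_windows = th$irep_min_windows)
      ab <- if (reads[[s]]$status == "ok")
        relativeAbundance(reads[[s]]$value,
                          max_mismatches_exclusive = th$max_mismatches)
      else list(skipped = reads[[s]]$reason)
      list(replication = ri, abundance = ab)
    }, verbose))
  names(report$growth) <- sites

  skipped <- function(x) if (identical(x$status, "skipped")) 1L else 0L
  report$errors <- sum(vapply(report$heterogeneity, skipped, 0L)) +
    sum(vapply(report$snp_distance, skipped, 0L)) +
    sum(vapply(report$growth, skipped, 0L)) +
    skipped(report$minor_lineage) + skipped(report$gene_flux) +
    skipped(report$selection) + skipped(report$resistance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeIndividualReport(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write / read an individual report as JSON
#'
#' @param report List from [runIndividual()].
#' @param path JSON path.
#' @return `writeIndividualReport()` returns `path` invisibly;
#'   `readIndividualReport()` returns the parsed list.
#' @export
writeIndividualReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", force = TRUE)
  invisible(path)
}

#' @rdname writeIndividualReport
#' @export
readIndividualReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
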