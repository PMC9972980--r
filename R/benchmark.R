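# Truth-vs-estimate benchmark driver over a grid of simulation scenarios.

# pool quasi-coding sequences of several sites into one dN/dS estimate
.pooledOmega <- function(truth, scenario, reference_site, thresholds) {
  refg <- truth@siteGenomes[[reference_site]]
  pileups <- simulatePileups(truth, scenario, reference = reference_site)
  others <- setdiff(names(pileups), reference_site)
  qr <- character()
  qv <- character()
  for (s in others) {
    cs <- callSnps(pileups[[s]], min_depth = thresholds$min_depth,
                   min_vaf = thresholds$min_vaf)
    cs <- annotateEffects(cs, refg)
    q <- buildQuasiCds(cs, refg, min_mean_depth = thresholds$quasi_min_depth,
                       min_vaf = thresholds$quasi_min_vaf)
    qr <- c(qr, q$ref_seq)
    qv <- c(qv, q$var_seq)
  }
  q <- list(ref_seq = paste(qr, collapse = ""),
            var_seq = paste(qv, collapse = ""))
  if (!nzchar(q$ref_seq)) return(NA_real_)
  dnds(q)$omega
}

#' Benchmark parameter recovery over a scenario grid
#'
#' For each scenario the full individual is simulated and the pipeline's
#' estimates are compared against the ground truth: pooled dN/dS against
#' `omega_true`, the replication index (mean over sites) against `ptr_true`,
#' minor-lineage detection against whether one was implanted, gene-flux
#' sensitivity/specificity against the implanted deletions, and the ANI of
#' the first two site genomes.
#'
#' @param scenarios List of [SimScenario-class] objects (may be empty).
#' @param thresholds From [lumenThresholds()].
#' @return data.frame, one row per scenario.
#' @export
runBenchmark <- function(scenarios, thresholds = lumenThresholds()) {
  cols <- c("scenario", "seed", "omega_true", "omega_est", "ptr_true",
            "ptr_est", "minor_truth", "minor_detected", "flux_sensitivity",
            "flux_specificity", "ani_site12")
  if (!length(scenarios))
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    founder <- generateFounder(sc)
    truth <- diversify(founder, sc)
    ref_site <- sc@sites[1]
    omega_est <- .pooledOmega(truth, sc, ref_site, thresholds)

    self_pileups <- simulatePileups(truth, sc, reference = "self")
    ptr_est <- mean(vapply(self_pileups, function(p)
      replicationIndex(p, window = thresholds$irep_window,
                       step = thresholds$irep_step,
                       trim = thresholds$irep_trim,
                       min_windows = thresholds$irep_min_windows)$index,
      numeric(1)), na.rm = TRUE)

    shared_pileups <- simulatePileups(truth, sc, reference = ref_site)
    lumen <- utils::head(names(shared_pileups), 3L)
    minor <- detectMinorLineage(shared_pileups[lumen],
                                truth@siteGenomes[[ref_site]],
                                min_depth = thresholds$min_depth,
                                min_vaf = thresholds$min_vaf,
                                max_vaf = thresholds$minor_max_vaf,
                                min_shared = thresholds$min_shared_snps)

    flux_sens <- NA_real_
    flux_spec <- NA_real_
    if (length(truth@deletedGeneIds)) {
      ref_reads <- simulateReads(truth, sc, ref_site)
      tgt_reads <- simulateReads(truth, sc, ref_site,
                                 exclude_gene_ids = truth@deletedGeneIds)
      tab <- geneCoverageTable(list(
        reference = geneReadCounts(ref_reads, founder),
        target = geneReadCounts(tgt_reads, founder)))
      fx <- detectFlux(tab, "reference", "target",
                       target_max = thresholds$flux_target_max,
                       ref_min = thresholds$flux_ref_min)
      hit <- fx$gene_id[fx$status == "missing"]
      flux_sens <- mean(truth@deletedGeneIds %in% hit)
      fp <- setdiff(hit, truth@deletedGeneIds)
      neg <- nrow(fx) - length(truth@deletedGeneIds)
      flux_spec <- if (neg > 0) 1 - length(fp) / neg else NA_real_
    }

    sg <- truth@siteGenomes
    ani12 <- if (length(sg) >= 2)
      ani(sg[[1]], sg[[2]], fragment = thresholds$ani_fragment,
          min_identity_to_count = thresholds$ani_min_identity)$ani_percent
    else NA_real_

    data.frame(scenario = i, seed = sc@seed, omega_true = sc@omega_true,
               omega_est = omega_est, ptr_true = sc@ptr_true,
               ptr_est = ptr_est,
               minor_truth = sc@minor_lineage_snps > 0,
               minor_detected = minor$present,
               flux_sensitivity = flux_sens, flux_specificity = flux_spec,
               ani_site12 = ani12, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
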