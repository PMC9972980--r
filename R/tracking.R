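# Strain relationships: fecal-vs-lumen SNP distances, minor-lineage
# detection by shared-SNP intersection across sites, and fragment-based
# average nucleotide identity.

#' SNP distance between a sample and a reference genome
#'
#' Counts SNPs in the pileup of one sample's reads mapped against another
#' sample's genome: positions with depth at least `min_depth` whose top
#' alternative allele reaches `min_vaf`, and among these the dominant SNPs
#' (variant allele frequency >= 0.80).
#'
#' @param pileup Pileup of sample A's reads against sample B's genome.
#' @param min_depth Minimum read depth.
#' @param min_vaf Minimum variant allele frequency for a counted SNP.
#' @return List with `total_snps`, `dominant_snps` and the underlying
#'   `calls` data.frame.
#' @export
snpDistance <- function(pileup, min_depth = 8L, min_vaf = 0.20) {
  if (!nrow(pileup)) {
    warning("empty pileup: zero SNP counts")
    return(list(total_snps = 0L, dominant_snps = 0L,
                calls = callSnps(pileup)))
  }
  calls <- flagDominant(callSnps(pileup, min_depth = min_depth,
                                 min_vaf = min_vaf))
  list(total_snps = nrow(calls),
       dominant_snps = sum(calls$dominant),
       calls = calls)
}

#' Detect a minor co-resident lineage from SNPs shared across sites
#'
#' All site pileups must be computed against one shared reference genome.
#' Per site, SNPs with `min_vaf <= vaf <= max_vaf` are retained (variants
#' above 50% are attributed to the major lineage and filtered out; exactly
#' 50% is retained).  The shared set is the exact intersection on
#' (contig, position, variant allele) across all sites; at least
#' `min_shared` shared SNPs indicate a minor lineage.
#'
#' @param site_pileups Named list (site -> pileup) against one reference.
#' @param reference The shared reference [AnnotatedGenome-class] (used for a
#'   coordinate sanity check; may be `NULL`).
#' @param min_depth,min_vaf Call filters as in [callSnps()].
#' @param max_vaf Maximum retained variant allele frequency (inclusive).
#' @param min_shared Minimum shared-SNP count indicating presence.
#' @param individual Identifier carried into the result.
#' @return List with `individual`, `shared_snp_count`, `sites_compared`,
#'   `present` and the `shared_snps` data.frame.
#' @export
detectMinorLineage <- function(site_pileups, reference = NULL,
                               min_depth = 8L, min_vaf = 0.20,
                               max_vaf = 0.50, min_shared = 20L,
                               individual = NA_character_) {
  if (length(site_pileups) < 2L)
    stop("need pileups from at least two sites")
  refs <- lapply(site_pileups, function(p) {
    key <- paste(p$contig, p$pos)
    stats::setNames(p$ref, key)
  })
  common <- Reduce(intersect, lapply(refs, names))
  for (r in refs[-1])
    if (!identical(unname(refs[[1]][common]), unname(r[common])))
      stop("site pileups disagree on reference bases: ",
           "were they mapped to different references?")
  per_site <- lapply(site_pileups, function(p) {
    calls <- callSnps(p, min_depth = min_depth, min_vaf = min_vaf)
    calls[calls$vaf <= max_vaf, c("contig", "pos", "alt")]
  })
  keys <- lapply(per_site, function(d) paste(d$contig, d$pos, d$alt))
  shared_keys <- Reduce(intersect, keys)
  shared <- per_site[[1]][keys[[1]] %in% shared_keys, , drop = FALSE]
  rownames(shared) <- NULL
  list(individual = individual,
       shared_snp_count = nrow(shared),
       sites_compared = length(site_pileups),
       present = nrow(shared) >= min_shared,
       shared_snps = shared)
}

# align one fragment to a window of the subject; returns percent identity
# over the fragment (global-local: the whole fragment must align)
.fragmentIdentity <- function(frag, window) {
  if (length(window) < 1L) return(0)
  aln <- Biostrings::pairwiseAlignment(frag, window, type = "global-local")
  100 * Biostrings::nmatch(aln) / length(frag)
}

#' Fragment-based average nucleotide identity
#'
#' Genome A is cut into consecutive fragments of `fragment` bases (per
#' contig; tails shorter than a fragment are dropped).  Each fragment is
#' aligned to its best-matching region of genome B: first against the
#' colinear window at the same coordinates (the fast path for genomes that
#' share contig structure), and when that alignment falls below
#' `min_identity_to_count`, against windows located by exact-seed search
#' (three 18-mers per fragment), accommodating shuffled contigs.  The ANI is
#' the mean identity over fragments whose best identity reaches
#' `min_identity_to_count`.
#'
#' @param genome_A,genome_B [AnnotatedGenome-class] objects.
#' @param fragment Fragment length in bases.
#' @param min_identity_to_count Minimum identity (fraction) for a fragment
#'   to enter the mean.
#' @return List with `ani_percent` (`NA` when no fragment passes),
#'   `fragments_aligned` and `fragments_total`.
#' @export
ani <- function(genome_A, genome_B, fragment = 1000L,
                min_identity_to_count = 0.8) {
  seqs_a <- genomeSeqs(genome_A)
  seqs_b <- genomeSeqs(genome_B)
  if (!sum(Biostrings::width(seqs_a)) || !sum(Biostrings::width(seqs_b)))
    stop("both genomes must be non-empty")
  margin <- max(100L, fragment %/% 5L)
  ids <- numeric()
  total <- 0L
  for (ctg in names(seqs_a)) {
    sa <- seqs_a[[ctg]]
    nfrag <- length(sa) %/% fragment
    if (!nfrag) next
    sb_col <- if (ctg %in% names(seqs_b)) seqs_b[[ctg]] else NULL
    for (k in seq_len(nfrag)) {
      total <- total + 1L
      fs <- (k - 1L) * fragment + 1L
      frag <- Biostrings::subseq(sa, fs, fs + fragment - 1L)
      best <- 0
      if (!is.null(sb_col)) {
        ws <- max(1L, fs - margin)
        we <- min(length(sb_col), fs + fragment - 1L + margin)
        best <- .fragmentIdentity(frag, Biostrings::subseq(sb_col, ws, we))
      }
      if (best < 100 * min_identity_to_count) {
        # seed-and-extend fallback for rearranged/renamed contigs
        seed_at <- unique(pmin(c(1L, fragment %/% 2L, fragment - 17L),
                               fragment - 17L))
        for (sb_name in names(seqs_b)) {
          sb <- seqs_b[[sb_name]]
          for (s0 in seed_at) {
            seed <- Biostrings::subseq(frag, s0, s0 + 17L)
            hits <- Biostrings::matchPattern(seed, sb)
            if (!length(hits)) next
            h <- Biostrings::start(hits)[1]
            ws <- max(1L, h - s0 + 1L - margin)
            we <- min(length(sb), h - s0 + fragment + margin)
            cand <- .fragmentIdentity(frag, Biostrings::subseq(sb, ws, we))
            best <- max(best, cand)
            if (best >= 100 * min_identity_to_count) break
          }
          if (best >= 100 * min_identity_to_count) break
        }
      }
      if (best >= 100 * min_identity_to_count) ids <- c(ids, best)
    }
  }
  list(ani_percent = if (length(ids)) mean(ids) else NA_real_,
       fragments_aligned = length(ids),
       fragments_total = total)
}

#' Pairwise ANI matrix
#'
#' @param genomes Named list of [AnnotatedGenome-class] objects.
#' @param ... Passed to [ani()].
#' @return Square numeric matrix of ANI percentages (diagonal 100).
#' @export
aniMatrix <- function(genomes, ...) {
  n <- length(genomes)
  m <- matrix(100, n, n, dimnames = list(names(genomes), names(genomes)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- ani(genomes[[i]], genomes[[j]], ...)$ani_percent
  }
  m
}
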