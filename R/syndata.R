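# Founder-diversification simulator: one founder genome diverges
# independently at several intestinal sites, an optional minor lineage
# co-resides at all sites, and per-site pileups/read summaries are emitted
# with an origin-to-terminus replication gradient and base-call error.

# map global (concatenated, 1-based) indices to (contig, pos)
.globalToContig <- function(genome, idx) {
  off <- .contigOffsets(genome)
  w <- Biostrings::width(genomeSeqs(genome))
  ctg_i <- findInterval(idx, c(off, sum(w)) + 1L, rightmost.closed = FALSE)
  ctg_i[ctg_i > length(off)] <- length(off)
  data.frame(contig = names(off)[ctg_i],
             pos = as.integer(idx - off[ctg_i]),
             stringsAsFactors = FALSE)
}

#' Generate a founder genome
#'
#' Builds a random genome of the requested length split into contigs, laid
#' out as alternating intergenic spacers and complete open reading frames
#' (ATG start, internal codons drawn from the 61 sense codons, one stop
#' codon; length divisible by 3, random strand).  Genes never overlap and
#' cover approximately `gene_fraction` of the genome.
#'
#' @param scenario A [SimScenario-class].
#' @return An [AnnotatedGenome-class]; deterministic for a fixed seed.
#' @examples
#' founder <- generateFounder(SimScenario(seed = 1, genome_length = 20000L))
#' founder
#' @export
generateFounder <- function(scenario) {
  stopifnot(methods::is(scenario, "SimScenario"))
  methods::validObject(scenario)
  gf <- scenario@gene_fraction
  m <- scenario@mean_gene_length
  withr::with_seed(scenario@seed, {
    L <- scenario@genome_length
    nc <- scenario@n_contigs
    clens <- diff(round(seq(0, L, length.out = nc + 1)))
    gap_mean <- if (gf > 0) m * (1 - gf) / gf else Inf
    contigs <- character(nc)
    gene_rows <- list()
    gene_n <- 0L
    for (ci in seq_len(nc)) {
      clen <- clens[ci]
      cname <- sprintf("contig_%d", ci)
      pieces <- character()
      pos <- 1L
      while (gf > 0 && pos <= clen) {
        gap <- 1L + stats::rpois(1L, max(gap_mean - 1, 0))
        glen <- 3L * round(stats::rnorm(1L, m, m / 4) / 3)
        glen <- max(33L, as.integer(glen))
        if (pos + gap + glen - 1L > clen) break
        pieces <- c(pieces, paste(sample(.BASES, gap, replace = TRUE),
                                  collapse = ""))
        ncod <- glen %/% 3L
        orf <- paste0("ATG",
                      paste(sample(.SENSE_CODONS, ncod - 2L, replace = TRUE),
                            collapse = ""),
                      sample(.STOP_CODONS, 1L))
        strand <- sample(c("+", "-"), 1L)
        block <- if (strand == "+") orf else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
        pieces <- c(pieces, block)
        gene_n <- gene_n + 1L
        gene_rows[[gene_n]] <- data.frame(
          contig = cname, start = pos + gap, end = pos + gap + glen - 1L,
          strand = strand, gene_id = sprintf("gene_%04d", gene_n),
          stringsAsFactors = FALSE)
        pos <- pos + gap + glen
      }
      if (pos <= clen)
        pieces <- c(pieces, paste(sample(.BASES, clen - pos + 1L,
                                         replace = TRUE), collapse = ""))
      contigs[ci] <- paste(pieces, collapse = "")
    }
    seqs <- Biostrings::DNAStringSet(contigs)
    names(seqs) <- sprintf("contig_%d", seq_len(nc))
    genes <- NULL
    if (gene_n) {
      gdf <- do.call(rbind, gene_rows)
      genes <- GenomicRanges::GRanges(
        gdf$contig, IRanges::IRanges(gdf$start, gdf$end),
        strand = gdf$strand, gene_id = gdf$gene_id)
    }
    AnnotatedGenome(seqs, genes)
  })
}

# draw accepted substitutions: candidates are uniform over unused positions
# with a uniform alternative base; nonsense changes are always rejected and
# nonsynonymous (omega <= 1) or synonymous (omega > 1) changes are thinned so
# the realised nonsynonymous/synonymous ratio targets omega_true
.drawSubstitutions <- function(genome, n, used, omega) {
  L <- length(used)
  acc <- NULL
  tries <- 0L
  while (is.null(acc) || nrow(acc) < n) {
    need <- n - if (is.null(acc)) 0L else nrow(acc)
    free <- which(!used)
    if (!length(free)) stop("requested substitutions exceed genome size")
    tries <- tries + 1L
    if (tries > 200L) stop("could not place requested substitutions")
    take <- min(length(free), max(100L, need * 3L))
    idx <- if (length(free) == 1L) free else sample(free, take)
    cand <- .globalToContig(genome, idx)
    cand$global <- idx
    alt_pick <- sample.int(3L, nrow(cand), replace = TRUE)
    cls0 <- .classifyVariants(genome, transform(cand, alt = "A"))
    alt_mat <- vapply(cls0$ref, function(r) setdiff(.BASES, r),
                      character(3))
    cand$alt <- alt_mat[cbind(alt_pick, seq_len(nrow(cand)))]
    cls <- .classifyVariants(genome, cand)
    keep <- cls$effect != "nonsense"
    u <- stats::runif(nrow(cls))
    if (omega <= 1) {
      keep <- keep & !(cls$effect == "nonsynonymous" & u >= omega)
    } else {
      keep <- keep & !(cls$effect == "synonymous" & u >= 1 / omega)
    }
    keep <- keep & !duplicated(cand$global)
    cls$global <- cand$global
    new <- cls[keep, , drop = FALSE]
    if (!is.null(acc)) new <- new[!(new$global %in% acc$global), , drop = FALSE]
    acc <- rbind(acc, new)
    if (nrow(acc) >= n) acc <- acc[seq_len(n), , drop = FALSE]
    used[acc$global] <- TRUE
  }
  rownames(acc) <- NULL
  acc
}

#' Diversify a founder genome across intestinal sites
#'
#' Implants `shared_substitutions` common to every site (accumulated before
#' the founder split) and `per_site_substitutions` private to each site, at
#' globally unique positions.  Candidate changes creating a premature stop
#' are rejected; nonsynonymous candidates are thinned by rejection sampling
#' so the realised nonsynonymous/synonymous ratio targets `omega_true`.  An
#' optional minor lineage receives its own SNP set (shared across all sites)
#' at positions untouched by the major lineage.
#'
#' @param founder An [AnnotatedGenome-class] from [generateFounder()].
#' @param scenario The [SimScenario-class] used throughout.
#' @return A [TruthBundle-class] recording every change with its effect class.
#' @export
diversify <- function(founder, scenario) {
  stopifnot(methods::is(founder, "AnnotatedGenome"),
            methods::is(scenario, "SimScenario"))
  sites <- scenario@sites
  L <- genomeLength(founder)
  n_major <- scenario@shared_substitutions +
    scenario@per_site_substitutions * length(sites)
  if (n_major + scenario@minor_lineage_snps > L)
    stop("requested substitutions exceed genome size")
  withr::with_seed(scenario@seed + 1L, {
    used <- logical(L)
    major <- NULL
    if (n_major > 0) {
      major <- .drawSubstitutions(founder, n_major, used, scenario@omega_true)
      used[major$global] <- TRUE
      major$scope <- rep(c("shared", sites),
                         times = c(scenario@shared_substitutions,
                                   rep(scenario@per_site_substitutions,
                                       length(sites))))
      major$lineage <- "major"
    } else {
      major <- data.frame()
    }
    minor <- data.frame()
    if (scenario@minor_lineage_snps > 0) {
      minor <- .drawSubstitutions(founder, scenario@minor_lineage_snps,
                                  used, 1)
      minor$scope <- "all"
      minor$lineage <- "minor"
    }
    keep_cols <- c("contig", "pos", "ref", "alt", "scope", "lineage",
                   "region", "gene_id", "effect")
    site_genomes <- lapply(sites, function(s) {
      df <- if (nrow(major))
        major[major$scope %in% c("shared", s), , drop = FALSE]
      else major
      AnnotatedGenome(.applySubstitutions(genomeSeqs(founder), df),
                      geneRanges(founder))
    })
    names(site_genomes) <- sites
    # the minor lineage split from the major after the pre-split (shared)
    # substitutions accrued, so it carries shared + its own SNPs; this keeps
    # shared-SNP intersections across sites equal to the minor SNP set
    minor_genome <- if (nrow(minor)) {
      base <- if (nrow(major))
        major[major$scope == "shared", , drop = FALSE] else major
      AnnotatedGenome(
        .applySubstitutions(genomeSeqs(founder), rbind(base, minor)),
        geneRanges(founder))
    } else founder
    deleted <- character()
    gn <- geneRanges(founder)
    if (scenario@deleted_genes_per_individual > 0 && length(gn))
      deleted <- sample(gn$gene_id,
                        min(scenario@deleted_genes_per_individual, length(gn)))
    methods::new("TruthBundle",
      founder = founder,
      siteGenomes = site_genomes,
      minorGenome = minor_genome,
      implantedSnps = if (nrow(major)) major[, keep_cols] else
        stats::setNames(data.frame(matrix(ncol = 9, nrow = 0)), keep_cols),
      minorPositions = if (nrow(minor)) minor[, keep_cols] else
        stats::setNames(data.frame(matrix(ncol = 9, nrow = 0)), keep_cols),
      deletedGeneIds = deleted,
      ptrTrue = scenario@ptr_true,
      omegaTrue = scenario@omega_true,
      minorFreq = scenario@minor_lineage_freq,
      origin = 1,
      terminus = floor(L / 2))
  })
}

# per-position expected coverage: log2-linear ("piecewise log-linear,
# bidirectional replication") from log2(ptr * d_ter) at the origin (global
# position 1) to log2(d_ter) at the terminus (genome midpoint), symmetric on
# the circular genome; d_ter scaled so the genome-wide mean equals mean_depth
.coverageLambda <- function(L, mean_depth, ptr) {
  x <- seq_len(L) - 1
  d <- pmin(x, L - x)               # circular distance to the origin
  t <- d / (L / 2)
  if (ptr <= 1) return(rep(mean_depth, L))
  d_ter <- mean_depth * log(ptr) / (ptr - 1)
  d_ter * ptr^(1 - t)
}

#' Simulate per-site pileup tables
#'
#' For every site, per-position read depth is drawn Poisson around an
#' expectation that decays log2-linearly from the replication origin (global
#' position 1) to the terminus (genome midpoint, circular symmetric), and
#' allele counts mix the major site lineage (`1 - minor_lineage_freq`), the
#' minor lineage (`minor_lineage_freq`) and uniform base-call error.
#'
#' @param truth A [TruthBundle-class] from [diversify()].
#' @param scenario The same [SimScenario-class].
#' @param reference `"self"` (each site's reads against its own genome,
#'   the default), `"founder"`, one of the site labels (a single shared
#'   reference, as when all samples are mapped against an individual's best
#'   genome), or an [AnnotatedGenome-class].
#' @return Named list (site -> pileup `data.frame` with columns `contig`,
#'   `pos` (1-based), `ref`, `depth`, `A`, `C`, `G`, `T`).
#' @export
simulatePileups <- function(truth, scenario, reference = "self") {
  stopifnot(methods::is(truth, "TruthBundle"))
  if (scenario@mean_depth <= 0) stop("mean_depth must be > 0")
  sites <- names(truth@siteGenomes)
  L <- genomeLength(truth@founder)
  lambda <- .coverageLambda(L, scenario@mean_depth, scenario@ptr_true)
  f <- scenario@minor_lineage_freq
  e <- scenario@error_rate
  minor_chars <- .seqChars(truth@minorGenome)
  coords <- .globalToContig(truth@founder, seq_len(L))
  withr::with_seed(scenario@seed + 11L, {
    out <- lapply(sites, function(s) {
      refg <- .resolveReference(truth, reference, s)
      ref_chars <- .seqChars(refg)
      major_chars <- .seqChars(truth@siteGenomes[[s]])
      depth <- stats::rpois(L, lambda)
      counts <- .mixtureCounts(depth, major_chars, minor_chars, f, e)
      data.frame(contig = coords$contig, pos = coords$pos, ref = ref_chars,
                 depth = depth, A = counts[, 1], C = counts[, 2],
                 G = counts[, 3], T = counts[, 4], stringsAsFactors = FALSE)
    })
    names(out) <- sites
    out
  })
}

.seqChars <- function(genome) {
  unlist(strsplit(as.character(genomeSeqs(genome)), ""), use.names = FALSE)
}

.resolveReference <- function(truth, reference, site) {
  if (methods::is(reference, "AnnotatedGenome")) return(reference)
  if (identical(reference, "self")) return(truth@siteGenomes[[site]])
  if (identical(reference, "founder")) return(truth@founder)
  if (reference %in% names(truth@siteGenomes))
    return(truth@siteGenomes[[reference]])
  stop("unknown reference: ", reference)
}

# multinomial allele counts via sequential binomials (vectorised over
# positions): P(base) = (1-f)[major] + f[minor], then uniform error
.mixtureCounts <- function(depth, major, minor, f, e) {
  L <- length(depth)
  p <- matrix(0, L, 4, dimnames = list(NULL, .BASES))
  for (j in 1:4) {
    b <- .BASES[j]
    pb <- (1 - f) * (major == b) + f * (minor == b)
    p[, j] <- pb * (1 - e) + (1 - pb) * e / 3
  }
  counts <- matrix(0L, L, 4, dimnames = list(NULL, .BASES))
  rem <- depth
  prem <- rep(1, L)
  for (j in 1:3) {
    pj <- ifelse(prem > 0, pmin(p[, j] / prem, 1), 0)
    counts[, j] <- stats::rbinom(L, rem, pj)
    rem <- rem - counts[, j]
    prem <- prem - p[, j]
  }
  counts[, 4] <- rem
  counts
}

#' Simulate a per-read mapping summary
#'
#' Draws reads uniformly from one site's strain and records, for each read,
#' its interval on the reference and its mismatch count (strain-vs-reference
#' differences within the read plus binomial base-call errors).  Reads
#' originating inside deleted genes are dropped, emulating a strain lacking
#' those genes.
#'
#' @param truth A [TruthBundle-class].
#' @param scenario The same [SimScenario-class].
#' @param site Site label.
#' @param reference As in [simulatePileups()].
#' @param exclude_gene_ids Gene ids whose intervals yield no reads (e.g.
#'   `truth@deletedGeneIds` when emulating a foreign individual).
#' @return `data.frame` with columns `read_id`, `contig`, `start`, `end`
#'   (1-based closed) and `mismatches`.
#' @export
simulateReads <- function(truth, scenario, site, reference = "self",
                          exclude_gene_ids = character()) {
  stopifnot(methods::is(truth, "TruthBundle"))
  rl <- scenario@read_length
  L <- genomeLength(truth@founder)
  refg <- .resolveReference(truth, reference, site)
  site_chars <- .seqChars(truth@siteGenomes[[site]])
  ref_chars <- .seqChars(refg)
  diffs <- cumsum(c(0L, as.integer(site_chars != ref_chars)))
  w <- Biostrings::width(genomeSeqs(truth@founder))
  off <- .contigOffsets(truth@founder)
  withr::with_seed(scenario@seed + 23L + match(site, names(truth@siteGenomes)), {
    n_reads <- round(scenario@mean_depth * L / rl)
    # global starts such that the read stays within one contig
    ok_start <- rep(TRUE, L)
    for (i in seq_along(w)) {
      hi <- off[i] + w[i]
      if (w[i] >= rl) ok_start[(hi - rl + 2):hi] <- FALSE
      else ok_start[(off[i] + 1):hi] <- FALSE
    }
    starts <- sample(which(ok_start), n_reads, replace = TRUE)
    if (length(exclude_gene_ids)) {
      gn <- geneRanges(truth@founder)
      gn <- gn[gn$gene_id %in% exclude_gene_ids]
      if (length(gn)) {
        gstart <- off[as.character(GenomicRanges::seqnames(gn))] +
          GenomicRanges::start(gn)
        gend <- off[as.character(GenomicRanges::seqnames(gn))] +
          GenomicRanges::end(gn)
        bad <- rep(FALSE, length(starts))
        for (k in seq_along(gstart))
          bad <- bad | (starts <= gend[k] & starts + rl - 1L >= gstart[k])
        starts <- starts[!bad]
      }
    }
    strain_mm <- diffs[starts + rl] - diffs[starts]
    err_mm <- stats::rbinom(length(starts), rl, scenario@error_rate)
    coords <- .globalToContig(truth@founder, starts)
    data.frame(
      read_id = sprintf("%s_read_%06d", site, seq_along(starts)),
      contig = coords$contig,
      start = coords$pos,
      end = coords$pos + rl - 1L,
      mismatches = as.integer(strain_mm + err_mm),
      stringsAsFactors = FALSE)
  })
}

#' Simulate one full individual
#'
#' Convenience wrapper: founder, diversification, per-site pileups (against
#' each site's own genome) and per-site read summaries.
#'
#' @param scenario A [SimScenario-class].
#' @param reference Passed to [simulatePileups()] and [simulateReads()].
#' @return List with elements `truth` ([TruthBundle-class]), `pileups`
#'   (named list of data.frames) and `reads` (named list of data.frames).
#' @examples
#' sim <- simulateIndividual(SimScenario(seed = 7, genome_length = 20000L,
#'                                       mean_depth = 20))
#' names(sim$pileups)
#' @export
simulateIndividual <- function(scenario, reference = "self") {
  founder <- generateFounder(scenario)
  truth <- diversify(founder, scenario)
  pileups <- simulatePileups(truth, scenario, reference)
  reads <- lapply(names(truth@siteGenomes), function(s)
    simulateReads(truth, scenario, s, reference))
  names(reads) <- names(truth@siteGenomes)
  list(truth = truth, pileups = pileups, reads = reads)
}

#' Apply random substitutions to a genome
#'
#' Substitutes exactly `round(rate * genomeLength(genome))` positions (drawn
#' without replacement) with a uniform alternative base.  Used to calibrate
#' identity-based comparisons such as ANI.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param rate Per-base substitution rate in \[0, 1\].
#' @param seed Integer seed.
#' @return An [AnnotatedGenome-class] with the same gene annotation.
#' @export
mutateGenome <- function(genome, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  L <- genomeLength(genome)
  n <- round(rate * L)
  if (n == 0) return(genome)
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(L, n)
    df <- .globalToContig(genome, idx)
    strs <- .contigStrings(genome)
    ref <- mapply(function(c, p) substr(strs[[c]], p, p), df$contig, df$pos,
                  USE.NAMES = FALSE)
    alt_mat <- vapply(ref, function(r) setdiff(.BASES, r), character(3))
    df$alt <- alt_mat[cbind(sample.int(3L, n, replace = TRUE), seq_len(n))]
    AnnotatedGenome(.applySubstitutions(genomeSeqs(genome), df),
                    geneRanges(genome))
  })
}

#' Write the simulator's ground truth as JSON
#'
#' @param truth A [TruthBundle-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(
    implanted_snps = truth@implantedSnps,
    minor_lineage_positions = truth@minorPositions,
    deleted_gene_ids = truth@deletedGeneIds,
    ptr_true = truth@ptrTrue,
    omega_true = truth@omegaTrue,
    minor_lineage_freq = truth@minorFreq,
    origin = truth@origin,
    terminus = truth@terminus)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
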