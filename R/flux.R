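# Gene gain/loss from read counts over gene intervals, and gene-content
# dissimilarity (Jaccard distance, principal-coordinates embedding, and a
# from-scratch permutation PERMANOVA).

#' Count reads overlapping each gene
#'
#' A read counts once for every gene it overlaps by at least one base
#' (multicov semantics).
#'
#' @param reads Read-summary data.frame with `contig`, `start`, `end`
#'   (1-based closed).
#' @param genome [AnnotatedGenome-class] supplying the gene intervals.
#' @return Named integer vector of read counts, one per `gene_id`.
#' @export
geneReadCounts <- function(reads, genome) {
  genes <- geneRanges(genome)
  counts <- stats::setNames(integer(length(genes)), genes$gene_id)
  if (!nrow(reads)) return(counts)
  lens <- Biostrings::width(genomeSeqs(genome))
  names(lens) <- names(genomeSeqs(genome))
  bad <- !(reads$contig %in% names(lens)) | reads$start < 1L |
    reads$end > lens[reads$contig]
  if (any(bad))
    stop("read ", reads$read_id[which(bad)[1]], " lies beyond contig bounds")
  gr <- GenomicRanges::GRanges(reads$contig,
                               IRanges::IRanges(reads$start, reads$end))
  counts[] <- GenomicRanges::countOverlaps(genes, gr)
  counts
}

#' Assemble a gene coverage table
#'
#' @param count_columns Named list of vectors from [geneReadCounts()]
#'   (one per sample, identical gene sets).
#' @return Integer matrix, rows = gene ids, columns = samples.
#' @export
geneCoverageTable <- function(count_columns) {
  stopifnot(length(count_columns) >= 1)
  ids <- names(count_columns[[1]])
  for (x in count_columns)
    if (!identical(names(x), ids)) stop("samples disagree on gene ids")
  do.call(cbind, count_columns)
}

#' Detect missing genes between two samples
#'
#' A gene is called missing in the target when it attracts fewer than
#' `target_max` mapped reads there while attracting at least `ref_min` reads
#' in the reference sample; otherwise it is retained.
#'
#' @param table Gene coverage matrix from [geneCoverageTable()].
#' @param reference_sample,target_sample Column names in `table`.
#' @param target_max Exclusive upper bound on target reads for a missing call.
#' @param ref_min Inclusive lower bound on reference reads.
#' @return data.frame with `gene_id`, `reference_sample`, `target_sample`,
#'   `status` (`"missing"` or `"retained"`).
#' @export
detectFlux <- function(table, reference_sample, target_sample,
                       target_max = 3L, ref_min = 10L) {
  for (s in c(reference_sample, target_sample))
    if (!s %in% colnames(table)) stop("unknown sample id: ", s)
  missing <- table[, target_sample] < target_max &
    table[, reference_sample] >= ref_min
  data.frame(gene_id = rownames(table),
             reference_sample = reference_sample,
             target_sample = target_sample,
             status = ifelse(missing, "missing", "retained"),
             stringsAsFactors = FALSE)
}

#' Jaccard distance between gene-content profiles
#'
#' @param presence Logical (or 0/1) matrix, rows = genes, columns = samples.
#' @return Symmetric sample-by-sample distance matrix,
#'   `d(i, j) = 1 - |intersection| / |union|`; pairs where both samples lack
#'   any present gene get `NA` (diagonal stays 0).
#' @export
jaccardMatrix <- function(presence) {
  if (ncol(presence) < 2) stop("need at least two samples")
  p <- (presence != 0) * 1L
  inter <- crossprod(p)
  sizes <- diag(inter)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  d[outer(sizes, sizes, pmin) == 0] <- NA_real_  # empty sample: undefined
  diag(d) <- 0
  dimnames(d) <- list(colnames(presence), colnames(presence))
  d
}

# distance-based sums of squares: total and within-group, from squared
# distances (the standard decomposition behind distance-based anova)
.permanovaSS <- function(d2, groups) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(sst = sst, ssw = ssw)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared-distance matrix into between- and within-group
#' components and tests the pseudo-F statistic by permuting group labels.
#' The p-value uses the +1 correction:
#' `p = (1 + #\{permuted F >= observed F\}) / (1 + permutations)`.
#'
#' @param dist Symmetric distance matrix (or `dist` object).
#' @param groups Group label per sample (length = number of samples); every
#'   group must contain at least two samples.
#' @param permutations Number of label permutations.
#' @param seed Integer seed making the permutation stream reproducible.
#' @return List with `R2` (between-group share of total sum of squares),
#'   `F`, `p`, `permutations`.
#' @export
permanova <- function(dist, groups, permutations = 999L, seed = 1L) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per sample required")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two samples")
  a <- length(tab)
  d2 <- d^2
  ss <- .permanovaSS(d2, groups)
  ssb <- ss["sst"] - ss["ssw"]
  f_obs <- (ssb / (a - 1)) / (ss["ssw"] / (n - a))
  r2 <- unname(ssb / ss["sst"])
  hits <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(permutations), function(i) {
      gp <- sample(groups)
      ssp <- .permanovaSS(d2, gp)
      ssbp <- ssp["sst"] - ssp["ssw"]
      fp <- (ssbp / (a - 1)) / (ssp["ssw"] / (n - a))
      fp >= f_obs
    }, logical(1)))
  })
  list(R2 = r2, F = unname(f_obs),
       p = (1 + hits) / (1 + permutations),
       permutations = permutations)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a symmetric distance matrix.  Axis signs are
#' fixed by making each axis's largest-magnitude loading positive, so plots
#' are reproducible.  When `k` exceeds the rank of the configuration the
#' trailing coordinates are zero.
#'
#' @param dist Symmetric distance matrix (or `dist` object).
#' @param k Number of coordinate axes.
#' @return List with `points` (samples x k coordinate matrix) and `eig`
#'   (all eigenvalues, negative ones included).
#' @export
pcoaCoords <- function(dist, k = 2L) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1), eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  if (ncol(pts) < k)
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig)
}
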