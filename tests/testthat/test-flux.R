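test_that("gene read counts follow multicov any-overlap semantics", {
  seqs <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 3000), collapse = "")))
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 1001), c(1000, 2000)),
                                  strand = "+", gene_id = c("g1", "g2"))
  g <- AnnotatedGenome(seqs, genes)
  # no reads -> all-zero column
  none <- geneReadCounts(data.frame(read_id = character(), contig = character(),
                                    start = integer(), end = integer()), g)
  expect_equal(unname(none), c(0L, 0L))
  # a read spanning the two adjacent genes counts once in each
  span <- data.frame(read_id = "r1", contig = "c1", start = 951L, end = 1050L)
  expect_equal(unname(geneReadCounts(span, g)), c(1L, 1L))
  # single-base overlap counts; non-overlap does not
  edge <- data.frame(read_id = c("r1", "r2"), contig = "c1",
                     start = c(1L, 1L), end = c(101L, 100L))
  expect_equal(unname(geneReadCounts(edge, g)), c(1L, 0L))
  expect_error(geneReadCounts(
    data.frame(read_id = "r", contig = "c1", start = 2950L, end = 3049L), g),
    "beyond contig bounds")
})

test_that("uniform coverage yields the length-plus-read-minus-one expectation", {
  # 20x depth, 100-b reads over a 1-kb gene: about (20/100) * (1000+100-1) reads
  sc <- SimScenario(seed = 81, genome_length = 30000L, gene_fraction = 0.5,
                    mean_gene_length = 999L, mean_depth = 20, ptr_true = 1,
                    per_site_substitutions = 0L, shared_substitutions = 0L,
                    sites = "TI", error_rate = 0)
  tr <- diversify(generateFounder(sc), sc)
  reads <- simulateReads(tr, sc, "TI")
  counts <- geneReadCounts(reads, truthFounder(tr))
  w <- GenomicRanges::width(geneRanges(truthFounder(tr)))
  expected <- (20 / 100) * (w + 100 - 1)
  # average over genes within 5% of the expectation
  expect_lt(abs(mean(counts / expected) - 1), 0.05)
})

test_that("missing genes obey the <3 target / >=10 reference rule", {
  tab <- matrix(c(12L, 2L,    # missing
                  12L, 3L,    # boundary: retained
                  9L,  0L,    # reference too shallow: retained
                  12L, 40L),  # clearly present
                ncol = 2, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), c("ref", "tgt")))
  fx <- detectFlux(tab, "ref", "tgt")
  expect_equal(fx$status, c("missing", "retained", "retained", "retained"))
  # identical samples -> zero missing
  same <- detectFlux(cbind(tab, tgt2 = tab[, "ref"]), "ref", "tgt2")
  expect_equal(sum(same$status == "missing"), 0)
  expect_error(detectFlux(tab, "ref", "nope"), "unknown sample")
})

test_that("simulated deletions are recovered exactly at 20x", {
  sc <- SimScenario(seed = 82, genome_length = 60000L, mean_gene_length = 150L,
                    mean_depth = 20, deleted_genes_per_individual = 10L,
                    per_site_substitutions = 0L, shared_substitutions = 0L,
                    sites = c("TI", "cecum"))
  f <- generateFounder(sc)
  tr <- diversify(f, sc)
  ref_reads <- simulateReads(tr, sc, "TI")
  tgt_reads <- simulateReads(tr, sc, "TI",
                             exclude_gene_ids = tr@deletedGeneIds)
  tab <- geneCoverageTable(list(reference = geneReadCounts(ref_reads, f),
                                target = geneReadCounts(tgt_reads, f)))
  fx <- detectFlux(tab, "reference", "target")
  hit <- fx$gene_id[fx$status == "missing"]
  expect_setequal(hit, tr@deletedGeneIds)
  # within-individual site pair: no implanted flux, no calls
  cecum_reads <- simulateReads(tr, sc, "cecum")
  tab2 <- geneCoverageTable(list(reference = geneReadCounts(ref_reads, f),
                                 target = geneReadCounts(cecum_reads, f)))
  expect_equal(sum(detectFlux(tab2, "reference", "target")$status == "missing"), 0)
})

test_that("jaccard distances match hand-computed set overlaps", {
  pres <- cbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1), s3 = c(1, 1, 1, 0),
                s4 = c(0, 0, 0, 0))
  rownames(pres) <- letters[1:4]
  d <- jaccardMatrix(pres)
  expect_equal(d["s1", "s2"], 0.5)   # {a,b,c} vs {b,c,d}: 1 - 2/4
  expect_equal(d["s1", "s3"], 0)     # identical
  expect_equal(d["s1", "s1"], 0)
  expect_true(is.na(d["s1", "s4"]))  # empty sample: undefined pair
  # disjoint sets -> 1
  dj <- jaccardMatrix(cbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(dj["a", "b"], 1)
})

test_that("jaccard distances satisfy the triangle inequality", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      pres <- matrix(stats::rbinom(60, 1, 0.5), nrow = 10)
      colnames(pres) <- paste0("s", 1:6)
      # guarantee non-empty samples
      pres[1, ] <- 1
      d <- jaccardMatrix(pres)
      for (i in 1:6) for (j in 1:6) for (k in 1:6)
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  })
})

test_that("permanova separates structured groups and matches vegan's decomposition", {
  # with 8 + 8 samples a random label permutation essentially never
  # reproduces the exact partition, so the p-value hits its floor
  pts <- rbind(matrix(0, 8, 2), matrix(10, 8, 2)) +
    withr::with_seed(3, matrix(stats::rnorm(32, sd = 0.01), 16))
  d <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b"), each = 8)
  res <- permanova(d, g, permutations = 199, seed = 2)
  expect_gt(res$R2, 0.999)
  # floor of the +1-corrected p; a permutation that reproduces the exact
  # partition ties the observed F, so allow at most one such tie
  expect_lte(res$p, 2 / 200)
  skip_if_not_installed("vegan")
  pts2 <- withr::with_seed(11, matrix(stats::rnorm(12 * 4), 12))
  d2 <- stats::dist(pts2)
  g2 <- rep(c("a", "b", "c"), each = 4)
  mine <- permanova(as.matrix(d2), g2, permutations = 99, seed = 1)
  ref <- vegan::adonis2(d2 ~ g2, permutations = 99)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
})

test_that("permanova is invariant to sample order and validates inputs", {
  pts <- withr::with_seed(5, matrix(stats::rnorm(10 * 3), 10))
  d <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b"), each = 5)
  res1 <- permanova(d, g, permutations = 99, seed = 4)
  perm <- withr::with_seed(6, sample(10))
  res2 <- permanova(d[perm, perm], g[perm], permutations = 99, seed = 4)
  expect_equal(res2$R2, res1$R2, tolerance = 1e-12)
  expect_equal(res2$F, res1$F, tolerance = 1e-12)
  expect_error(permanova(d, c(rep("a", 9), "b")), "at least two samples")
  expect_error(permanova(d[, 1:9], g), "symmetric")
})

test_that("pcoa round-trips Euclidean configurations and fixes axis signs", {
  pts <- withr::with_seed(8, matrix(stats::rnorm(6 * 2), 6))
  d <- as.matrix(stats::dist(pts))
  fit <- pcoaCoords(d, k = 2)
  expect_equal(as.matrix(stats::dist(fit$points)), unname(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  # largest-magnitude loading on each axis is positive
  for (j in 1:2) expect_gt(max(fit$points[, j]), abs(min(fit$points[, j])) - 1e-12)
  # three equidistant samples form an equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  tri <- pcoaCoords(d3, k = 2)$points
  dd <- stats::dist(tri)
  expect_equal(max(dd), min(dd), tolerance = 1e-8)
  # k beyond the rank pads zero coordinates
  fit5 <- pcoaCoords(d3, k = 5)
  expect_equal(ncol(fit5$points), 5)
  expect_true(all(abs(fit5$points[, 3:5]) < 1e-8))
  expect_error(pcoaCoords(matrix(1:9, 3)), "symmetric")
})
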