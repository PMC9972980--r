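test_that("founder genome has ORF genes covering the requested fraction", {
  sc <- SimScenario(seed = 1, genome_length = 100000L, gene_fraction = 0.85)
  f <- generateFounder(sc)
  expect_equal(genomeLength(f), 100000)
  gn <- geneRanges(f)
  covered <- sum(GenomicRanges::width(gn))
  expect_gte(covered, 82000)
  expect_lte(covered, 88000)
  expect_equal(sum(GenomicRanges::countOverlaps(gn, gn) > 1), 0)
  expect_true(all(GenomicRanges::width(gn) %% 3 == 0))
  # every gene is a complete ORF: start codon, no internal stop, ends in stop
  for (gid in sample(gn$gene_id, 10)) {
    aa <- as.character(Biostrings::translate(geneSequence(f, gid)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("founder generation is deterministic, byte for byte", {
  sc <- SimScenario(seed = 42, genome_length = 20000L)
  d <- withr::local_tempdir()
  for (run in 1:2) {
    f <- generateFounder(sc)
    writeAnnotatedGenome(f, file.path(d, paste0("g", run, ".fa")),
                         gff = file.path(d, paste0("g", run, ".gff3")))
  }
  expect_identical(readBin(file.path(d, "g1.fa"), "raw", 1e6),
                   readBin(file.path(d, "g2.fa"), "raw", 1e6))
  expect_identical(readLines(file.path(d, "g1.gff3")),
                   readLines(file.path(d, "g2.gff3")))
})

test_that("gene_fraction 0 yields a fully intergenic genome and bad scenarios error", {
  f <- generateFounder(SimScenario(seed = 2, genome_length = 5000L,
                                   gene_fraction = 0))
  expect_equal(length(geneRanges(f)), 0)
  expect_error(SimScenario(gene_fraction = 1), "gene_fraction")
  expect_error(SimScenario(genome_length = 500L, mean_gene_length = 900L),
               "mean_gene_length")
})

test_that("diversify implants site-private and shared substitutions consistently", {
  cs <- cleanSim()
  tr <- cs$sim$truth
  snps <- implantedSnps(tr)
  expect_equal(nrow(snps), 10 + 30 * 4)
  expect_false(anyDuplicated(paste(snps$contig, snps$pos)) > 0)
  # applying the truth set to the founder reproduces every site genome
  for (s in names(siteGenomes(tr))) {
    df <- snps[snps$scope %in% c("shared", s), ]
    rebuilt <- lumenstrain:::.applySubstitutions(
      genomeSeqs(truthFounder(tr)), df)
    expect_identical(as.character(rebuilt),
                     as.character(genomeSeqs(siteGenomes(tr)[[s]])))
  }
  # each pair of site genomes differs at exactly the private positions
  a <- strsplit(as.character(genomeSeqs(siteGenomes(tr)[["TI"]])[[1]]), "")[[1]]
  b <- strsplit(as.character(genomeSeqs(siteGenomes(tr)[["DC"]])[[1]]), "")[[1]]
  expect_equal(sum(a != b), 60)
})

test_that("diversify never creates premature stops and honours omega limits", {
  sc <- SimScenario(seed = 5, genome_length = 30000L,
                    per_site_substitutions = 50L, shared_substitutions = 0L,
                    omega_true = 0)
  tr <- diversify(generateFounder(sc), sc)
  snps <- implantedSnps(tr)
  expect_false(any(snps$effect == "nonsense"))
  expect_false(any(snps$effect == "nonsynonymous"))
  # zero-substitution scenario: all site genomes identical to the founder
  sc0 <- SimScenario(seed = 6, genome_length = 10000L,
                     per_site_substitutions = 0L, shared_substitutions = 0L)
  tr0 <- diversify(generateFounder(sc0), sc0)
  for (g in siteGenomes(tr0))
    expect_identical(as.character(genomeSeqs(g)),
                     as.character(genomeSeqs(truthFounder(tr0))))
  expect_error(
    diversify(generateFounder(sc0),
              SimScenario(seed = 6, genome_length = 10000L,
                          per_site_substitutions = 5000L)),
    "exceed")
})

test_that("truth effect labels agree with the variant annotator", {
  cs <- cleanSim()
  tr <- cs$sim$truth
  snps <- implantedSnps(tr)
  calls <- data.frame(contig = snps$contig, pos = snps$pos, ref = snps$ref,
                      alt = snps$alt, depth = 50L, vaf = 1,
                      region = NA, gene_id = NA, effect = NA, dominant = NA)
  ann <- annotateEffects(calls, truthFounder(tr))
  expect_equal(ann$effect, snps$effect)
  expect_equal(ann$region, snps$region)
  expect_equal(ann$gene_id, snps$gene_id)
})

test_that("error-free single-strain pileups carry only the site-genome allele", {
  cs <- cleanSim()
  p <- cs$sim$pileups$TI
  cnt <- as.matrix(p[, c("A", "C", "G", "T")])
  site_chars <- lumenstrain:::.seqChars(siteGenomes(cs$sim$truth)$TI)
  own <- cnt[cbind(seq_len(nrow(p)), match(site_chars, c("A", "C", "G", "T")))]
  expect_true(all(own == p$depth))
})

test_that("minor-lineage positions show the implanted allele fraction", {
  sc <- SimScenario(seed = 31, genome_length = 30000L,
                    minor_lineage_freq = 0.3, minor_lineage_snps = 20L,
                    mean_depth = 100, error_rate = 0,
                    per_site_substitutions = 0L, shared_substitutions = 0L)
  sim <- simulateIndividual(sc)
  mp <- minorPositions(sim$truth)
  p <- sim$pileups$cecum
  key <- paste(p$contig, p$pos)
  rows <- p[match(paste(mp$contig, mp$pos), key), ]
  frac <- mapply(function(i, alt) rows[i, alt] / rows$depth[i],
                 seq_len(nrow(rows)), mp$alt)
  # binomial: each fraction within 4 sd of 0.3, and the mean much tighter
  expect_true(all(abs(frac - 0.3) < 4 * sqrt(0.3 * 0.7 / 100)))
  expect_lt(abs(mean(frac) - 0.3), 0.05)
})

test_that("coverage gradient matches the requested origin/terminus ratio", {
  sc <- SimScenario(seed = 32, genome_length = 50000L, ptr_true = 2,
                    mean_depth = 50, per_site_substitutions = 0L,
                    shared_substitutions = 0L, sites = "TI")
  sim <- simulateIndividual(sc)
  d <- sim$pileups$TI$depth
  L <- length(d)
  # narrow windows so window-averaging of the exponential barely flattens
  near_ori <- mean(d[1:1000])
  near_ter <- mean(d[(L / 2 - 500):(L / 2 + 500)])
  expect_lt(abs(near_ori / near_ter - 2), 0.15)
  expect_lt(abs(mean(d) - 50), 1)
})

test_that("simulator outputs are deterministic given scenario and seed", {
  sc <- SimScenario(seed = 9, genome_length = 10000L, mean_depth = 15,
                    minor_lineage_freq = 0.25, minor_lineage_snps = 5L)
  a <- simulateIndividual(sc)
  b <- simulateIndividual(sc)
  expect_identical(a$pileups, b$pileups)
  expect_identical(a$reads, b$reads)
  expect_identical(implantedSnps(a$truth), implantedSnps(b$truth))
})

test_that("truth bundle round-trips through JSON and pileups through TSV", {
  sc <- SimScenario(seed = 12, genome_length = 8000L, mean_depth = 10,
                    minor_lineage_freq = 0.2, minor_lineage_snps = 3L)
  sim <- simulateIndividual(sc)
  d <- withr::local_tempdir()
  writeTruth(sim$truth, file.path(d, "truth.json"))
  parsed <- jsonlite::fromJSON(file.path(d, "truth.json"))
  expect_equal(nrow(parsed$implanted_snps), nrow(implantedSnps(sim$truth)))
  expect_equal(parsed$ptr_true, 1.5)
  writePileupTable(sim$pileups$TI, file.path(d, "ti.tsv"))
  back <- readPileupTable(file.path(d, "ti.tsv"))
  expect_equal(back, sim$pileups$TI)
  writeReadSummary(sim$reads$TI, file.path(d, "ti_reads.tsv"))
  back_reads <- readReadSummary(file.path(d, "ti_reads.tsv"))
  expect_equal(back_reads, sim$reads$TI)
})
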