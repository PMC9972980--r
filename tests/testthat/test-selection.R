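test_that("quasi-coding sequences concatenate filtered coding codon pairs", {
  g <- handGenome()
  mk <- function(pos, ref, alt, depth = 20L, vaf = 1) {
    df <- data.frame(contig = "c1", pos = pos, ref = ref, alt = alt,
                     depth = depth, vaf = vaf, region = NA, gene_id = NA,
                     effect = NA, dominant = NA)
    annotateEffects(df, g)
  }
  calls <- rbind(mk(9L, "A", "G"),            # AAA -> AAG
                 mk(12L, "T", "A"),           # GAT -> GAA
                 mk(2L, "T", "A"),            # intergenic: excluded
                 mk(13L, "G", "T", vaf = 0.45))  # below 50%: excluded
  q <- buildQuasiCds(calls, g)
  expect_equal(q$ref_seq, "AAAGAT")
  expect_equal(q$var_seq, "AAGGAA")
  expect_equal(nrow(q$snp_index), 2)
  expect_equal(q$snp_index$gene_id, c("gene_plus", "gene_plus"))
  # vaf 0.50 passes (inclusive), shallow depth does not
  expect_equal(nchar(buildQuasiCds(mk(9L, "A", "G", vaf = 0.5), g)$ref_seq), 3)
  expect_equal(nchar(buildQuasiCds(mk(9L, "A", "G", depth = 9L), g)$ref_seq), 0)
  # empty input
  expect_equal(buildQuasiCds(calls[0, ], g)$ref_seq, "")
})

test_that("dnds reproduces hand-counted Nei-Gojobori quantities", {
  # AAA->AAG silent, GAT->GAA Asp->Glu; per-codon sites computed by hand:
  # AAA: only pos-3 A->G is synonymous among non-stop changes -> S = 1/3
  # GAT: only pos-3 T->C is synonymous -> S = 1/3; total S = 2/3, N = 16/3
  res <- dnds(list(ref_seq = "AAAGAT", var_seq = "AAGGAA"))
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 1)
  expect_equal(res$S, 2 / 3, tolerance = 1e-12)
  expect_equal(res$N, 16 / 3, tolerance = 1e-12)
  expect_equal(res$omega, (1 / (16 / 3)) / (1 / (2 / 3)), tolerance = 1e-12)
  expect_equal(res$interpretation, "purifying")
  # identical sequences: no synonymous changes, omega undefined
  same <- dnds(list(ref_seq = "AAAGAT", var_seq = "AAAGAT"))
  expect_equal(same$Sd + same$Nd, 0)
  expect_true(is.na(same$omega))
  expect_true(is.na(same$interpretation))
  # saturated nonsynonymous changes against sparse synonymous ones read as
  # positive selection: 10x CTC (one silent CTC->CTT) + 10x TGG->TGC
  pos <- dnds(list(
    ref_seq = paste0(strrep("CTC", 10), strrep("TGG", 10)),
    var_seq = paste0("CTT", strrep("CTC", 9), strrep("TGC", 10))))
  expect_equal(pos$Sd, 1)
  expect_equal(pos$Nd, 10)
  expect_equal(pos$interpretation, "positive")
  expect_error(dnds(list(ref_seq = "", var_seq = "")), "empty")
  expect_error(dnds(list(ref_seq = "AAAA", var_seq = "AAAA")), "codon-multiple")
})

test_that("expected site counts total three per codon minus stop-adjacent paths", {
  cods <- c("AAA", "GAT", "TGG", "CTG", "ATG", "TCA")
  sites <- lumenstrain:::.ngSites(cods)
  expect_true(all(sites$S >= 0 & sites$N >= 0))
  expect_true(all(sites$S + sites$N <= 3 + 1e-12))
  expect_true(all(sites$S + sites$N >= 2))   # never loses a full position
  # TGG (Trp): no synonymous change exists
  expect_equal(sites$S[3], 0)
})

test_that("omega recovery on simulations brackets the generator target", {
  th <- lumenThresholds()
  sc <- SimScenario(seed = 91, genome_length = 60000L,
                    per_site_substitutions = 120L, shared_substitutions = 0L,
                    omega_true = 0.2, mean_depth = 40, error_rate = 0.001)
  tr <- diversify(generateFounder(sc), sc)
  om <- lumenstrain:::.pooledOmega(tr, sc, "TI", th)
  expect_lt(abs(om - 0.2) / 0.2, 0.5)
  scn <- SimScenario(seed = 92, genome_length = 60000L,
                     per_site_substitutions = 120L, shared_substitutions = 0L,
                     omega_true = 1, mean_depth = 40, error_rate = 0.001)
  trn <- diversify(generateFounder(scn), scn)
  omn <- lumenstrain:::.pooledOmega(trn, scn, "TI", th)
  expect_gt(omn, 0.7)
  expect_lt(omn, 1.4)
})

test_that("fixed mutations keep coding and intergenic calls at vaf >= 0.80", {
  calls <- data.frame(contig = "c", pos = 1:4, ref = "A", alt = "G",
                      depth = 50L, vaf = c(0.80, 0.79, 0.9, 1),
                      region = c("coding", "coding", "intergenic", "coding"),
                      gene_id = NA, effect = NA, dominant = NA)
  fx <- fixedMutations(calls)
  expect_equal(fx$pos, c(1L, 3L, 4L))
  expect_true("intergenic" %in% fx$region)
  expect_equal(nrow(fixedMutations(calls[0, ])), 0)
})

test_that("fixed differences from error-free simulations equal the implanted set", {
  cs <- cleanSim()
  tr <- cs$sim$truth
  pl <- simulatePileups(tr, cs$scenario, reference = "founder")
  calls <- flagDominant(annotateEffects(callSnps(pl$cecum),
                                        truthFounder(tr)))
  fx <- fixedMutations(calls)
  want <- implantedSnps(tr)
  want <- want[want$scope %in% c("shared", "cecum"), ]
  expect_setequal(paste(fx$contig, fx$pos, fx$alt),
                  paste(want$contig, want$pos, want$alt))
})

test_that("divergence time arithmetic matches the mutation-rate bound", {
  d <- divergenceTime(19, 5e6, mu = 7e-7)
  expect_equal(d$per_genome_rate, 3.5)
  expect_lt(d$per_genome_rate, 4)
  expect_equal(d$years, 19 / 3.5, tolerance = 1e-12)
  expect_equal(divergenceTime(0, 5e6)$years, 0)
  expect_error(divergenceTime(3, 0), "G and mu")
  expect_error(divergenceTime(-1, 5e6), ">= 0")
})

test_that("ciprofloxacin genotype counts non-wild-type QRDR residues", {
  wt <- resistanceGenotype(qrdrGenome(), "gyrA", "parC")
  expect_equal(wt$n_resistance_mutations, 0)
  expect_equal(wt$category, "sensitive")
  expect_equal(wt$gyrA_codon83, "S")
  expect_equal(wt$gyrA_codon87, "D")
  expect_equal(wt$parC_codon80, "S")
  # Ser83Leu + Asp87Asn + Ser80Ile: complete resistance
  res <- resistanceGenotype(qrdrGenome("CTG", "AAT", "ATT"), "gyrA", "parC")
  expect_equal(res$n_resistance_mutations, 3)
  expect_equal(res$category, "resistant")
  # single mutation: partial
  one <- resistanceGenotype(qrdrGenome(gyrA83 = "CTG"), "gyrA", "parC")
  expect_equal(one$n_resistance_mutations, 1)
  expect_equal(one$category, "partial")
  # a too-short gene errors
  g <- handGenome()
  expect_error(resistanceGenotype(g, "gene_plus", "gene_minus"),
               "shorter than codon")
})

test_that("selection report serialises to JSON and TSV", {
  d <- withr::local_tempdir()
  summ <- dnds(list(ref_seq = "AAAGAT", var_seq = "AAGGAA"))
  fixed <- data.frame(contig = "c", pos = 1L, ref = "A", alt = "G",
                      vaf = 0.9)
  rep <- writeSelectionReport(summ, fixed, divergenceTime(19, 5e6),
                              path_json = file.path(d, "sel.json"),
                              path_tsv = file.path(d, "fixed.tsv"))
  parsed <- jsonlite::fromJSON(file.path(d, "sel.json"))
  expect_equal(parsed$selection$omega, summ$omega, tolerance = 1e-12)
  expect_equal(parsed$fixed_mutation_count, 1)
  expect_equal(nrow(utils::read.delim(file.path(d, "fixed.tsv"))), 1)
})
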