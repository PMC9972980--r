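# Shared fixtures, built in code and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, factory) {
  if (!exists(name, envir = .fixtures)) assign(name, factory(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a tiny hand-built genome with one plus-strand and one minus-strand gene,
# for codon-level oracle tests
#   c1: TTT | ATG AAA GAT GAA TAA | GGGCC      gene_plus at 4..18
#   c2: GG | TTA AAA CAT | AA                  gene_minus at 3..11 (sense ATG TTT TAA)
handGenome <- function() {
  seqs <- Biostrings::DNAStringSet(c(c1 = "TTTATGAAAGATGAATAAGGGCC",
                                     c2 = "GGTTAAAACATAA"))
  genes <- GenomicRanges::GRanges(
    c("c1", "c2"), IRanges::IRanges(c(4L, 3L), c(18L, 11L)),
    strand = c("+", "-"), gene_id = c("gene_plus", "gene_minus"))
  AnnotatedGenome(seqs, genes)
}

# build a pileup row block: pure counts for a single allele plus optional alt
pileupRow <- function(contig, pos, ref, depth, alt = NULL, alt_n = 0L) {
  cnt <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
  cnt[ref] <- depth - alt_n
  if (!is.null(alt)) cnt[alt] <- cnt[alt] + alt_n
  data.frame(contig = contig, pos = pos, ref = ref, depth = depth,
             A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
             stringsAsFactors = FALSE)
}

# default-sized individual with error-free sequencing, used by several
# recovery tests (30 private substitutions per site, 10 shared, no minor)
cleanSim <- function() fixture("cleanSim", function() {
  sc <- SimScenario(seed = 101, genome_length = 50000L,
                    per_site_substitutions = 30L, shared_substitutions = 10L,
                    omega_true = 0.2, minor_lineage_freq = 0,
                    minor_lineage_snps = 0L, ptr_true = 1, mean_depth = 40,
                    error_rate = 0)
  list(scenario = sc, sim = simulateIndividual(sc))
})

# synthetic gyrA/parC genes for resistance genotyping: poly-Ala backbone
# with the wild-type (or mutant) QRDR residues written in
qrdrGenome <- function(gyrA83 = "TCT", gyrA87 = "GAT", parC80 = "TCT") {
  gene <- function(n_codons, spec) {
    cods <- rep("GCT", n_codons)
    cods[1] <- "ATG"
    cods[n_codons] <- "TAA"
    for (i in seq_along(spec)) cods[as.integer(names(spec)[i])] <- spec[i]
    paste(cods, collapse = "")
  }
  gyrA <- gene(90L, c(`83` = gyrA83, `87` = gyrA87))
  parC <- gene(85L, c(`80` = parC80))
  seqs <- Biostrings::DNAStringSet(c(chr = paste0("TT", gyrA, "CC", parC, "AA")))
  genes <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(3L, 3L + 270L + 2L),
                            width = c(270L, 255L)),
    strand = "+", gene_id = c("gyrA", "parC"))
  AnnotatedGenome(seqs, genes)
}
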