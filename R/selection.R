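# Selection-regime analysis: quasi-coding sequences from filtered coding
# SNPs, a Nei-Gojobori counting estimate of dN/dS, the fixed/near-fixed
# mutation set, divergence-time arithmetic, and quinolone-resistance
# genotyping of gyrA/parC.

#' Build a quasi-coding sequence from filtered coding SNPs
#'
#' Coding SNPs with depth at least `min_mean_depth` and variant allele
#' frequency at least `min_vaf` each contribute one codon pair, in genome
#' order: the reference codon and the variant codon (differing only at the
#' SNP's within-codon offset, in the gene's sense frame).  The concatenated
#' reference and variant codon strings form the quasi-coding sequence pair
#' used for dN/dS estimation.  Calls lacking gene context are skipped with a
#' warning.
#'
#' @param calls Annotated calls from [annotateEffects()].
#' @param genome The [AnnotatedGenome-class] supplying codon context.
#' @param min_mean_depth Minimum read coverage per retained SNP.
#' @param min_vaf Minimum variant allele frequency per retained SNP.
#' @return List with `ref_seq`, `var_seq` (character strings of equal,
#'   codon-multiple length) and `snp_index` (data.frame mapping each codon
#'   to its source SNP).
#' @export
buildQuasiCds <- function(calls, genome, min_mean_depth = 10L,
                          min_vaf = 0.50) {
  empty <- list(ref_seq = "", var_seq = "",
                snp_index = data.frame(contig = character(), pos = integer(),
                                       gene_id = character(),
                                       codon = integer()))
  if (!nrow(calls)) return(empty)
  if (any(is.na(calls$region)))
    stop("calls must be annotated with annotateEffects() first")
  n_noctx <- sum(calls$region == "coding" & is.na(calls$gene_id))
  if (n_noctx) warning(n_noctx, " coding call(s) lack gene context; skipped")
  keep <- calls$region == "coding" & !is.na(calls$gene_id) &
    calls$depth >= min_mean_depth & calls$vaf >= min_vaf
  sel <- calls[keep, , drop = FALSE]
  if (!nrow(sel)) return(empty)
  sel <- sel[order(sel$contig, sel$pos), , drop = FALSE]
  cls <- .classifyVariants(genome, sel[, c("contig", "pos", "alt")])
  list(ref_seq = paste(cls$ref_codon, collapse = ""),
       var_seq = paste(cls$var_codon, collapse = ""),
       snp_index = data.frame(contig = sel$contig, pos = sel$pos,
                              gene_id = cls$gene_id,
                              codon = seq_len(nrow(sel)),
                              stringsAsFactors = FALSE))
}

#' Nei-Gojobori dN/dS from a quasi-coding sequence pair
#'
#' Expected synonymous (S) and nonsynonymous (N) site counts come from the
#' reference codons only (each codon pair differs by at most one base, so
#' averaging with the variant adds nothing), enumerating the three possible
#' changes per position, excluding changes that create a stop codon.
#' Observed synonymous (Sd) and nonsynonymous (Nd) differences come from
#' translating each codon pair, averaging over mutational paths with equal
#' weight where a pair differs at more than one position.  Then
#' `omega = (Nd / N) / (Sd / S)`.  No multiple-hit correction is applied:
#' SNP-derived codon pairs differ at a single position, so corrections are
#' moot.
#'
#' @param q Quasi-coding sequence list from [buildQuasiCds()].
#' @return List with `Sd`, `Nd`, `S`, `N`, `omega` (`NA` when `Sd == 0`; no
#'   pseudocount) and `interpretation` (`"purifying"`, `"neutral"` or
#'   `"positive"`; `NA` when omega is undefined).
#' @examples
#' q <- list(ref_seq = "AAAGAT", var_seq = "AAGGAA")
#' dnds(q)   # one synonymous (AAA->AAG) and one nonsynonymous (GAT->GAA)
#' @export
dnds <- function(q) {
  ref <- q$ref_seq
  var <- q$var_seq
  if (!nzchar(ref)) stop("empty quasi-coding sequence")
  if (nchar(ref) != nchar(var) || nchar(ref) %% 3 != 0)
    stop("ref/var sequences must be equal length and codon-multiple")
  nc <- nchar(ref) %/% 3
  starts <- 3L * (seq_len(nc) - 1L) + 1L
  ref_cod <- substring(ref, starts, starts + 2L)
  var_cod <- substring(var, starts, starts + 2L)
  sites <- .ngSites(ref_cod)
  S <- sum(sites$S)
  N <- sum(sites$N)
  obs <- vapply(seq_len(nc),
                function(i) .ngObserved(ref_cod[i], var_cod[i]), numeric(2))
  Sd <- sum(obs["sd", ])
  Nd <- sum(obs["nd", ])
  if (Sd == 0 || S == 0 || N == 0) {
    omega <- NA_real_
    interp <- NA_character_
  } else {
    omega <- (Nd / N) / (Sd / S)
    interp <- if (omega < 1) "purifying" else if (omega > 1) "positive"
              else "neutral"
  }
  list(Sd = Sd, Nd = Nd, S = S, N = N, omega = omega,
       interpretation = interp)
}

#' Fixed and near-fixed mutations
#'
#' Subsets annotated calls to those with variant allele frequency at least
#' `threshold` (inclusive), keeping both coding and intergenic positions.
#'
#' @param calls Annotated calls from [annotateEffects()].
#' @param threshold Minimum variant allele frequency.
#' @return The retained calls, order preserved.
#' @export
fixedMutations <- function(calls, threshold = 0.80) {
  calls[!is.na(calls$vaf) & calls$vaf >= threshold, , drop = FALSE]
}

#' Divergence time from fixed mutations
#'
#' Given `m` fixed/near-fixed mutations accumulated on a genome of `G`
#' bases mutating at `mu` mutations per base per year, the per-genome rate
#' is `mu * G` mutations per year and the divergence time is
#' `m / (mu * G)` years.
#'
#' @param m Count of fixed/near-fixed mutations.
#' @param G Genome size in bases.
#' @param mu Mutation rate per base per year.
#' @return List with `fixed_mutations`, `genome_size`, `mu`,
#'   `per_genome_rate` and `years`.
#' @examples
#' divergenceTime(19, 5e6)   # about 5.4 years at 3.5 mutations/genome/year
#' @export
divergenceTime <- function(m, G, mu = 7e-7) {
  if (m < 0) stop("m must be >= 0")
  if (G <= 0 || mu <= 0) stop("G and mu must be > 0")
  rate <- mu * G
  list(fixed_mutations = m, genome_size = G, mu = mu,
       per_genome_rate = rate, years = m / rate)
}

#' Ciprofloxacin-resistance genotype from gyrA/parC
#'
#' Translates the two quinolone target genes and inspects the three
#' quinolone-resistance-determining-region (QRDR) residues of *E. coli*
#' numbering: GyrA Ser83 and Asp87, ParC Ser80.  Each non-wild-type residue
#' counts as a resistance mutation; three mutations confer complete
#' resistance, none leaves the strain sensitive, and one or two give a
#' partial genotype.
#'
#' @param genome [AnnotatedGenome-class] holding both genes.
#' @param gyrA_id,parC_id Gene ids of gyrA and parC.
#' @param wildtype Named wild-type residues; override for other species or
#'   numbering schemes.
#' @return List with `gyrA_codon83`, `gyrA_codon87`, `parC_codon80`,
#'   `n_resistance_mutations` and `category` (`"sensitive"`, `"partial"`,
#'   `"resistant"`).
#' @export
resistanceGenotype <- function(genome, gyrA_id, parC_id,
                               wildtype = c(gyrA_83 = "S", gyrA_87 = "D",
                                            parC_80 = "S")) {
  residue <- function(gene_id, codon) {
    seq <- geneSequence(genome, gene_id)
    if (length(seq) < 3 * codon)
      stop("gene ", gene_id, " shorter than codon ", codon)
    if (length(seq) %% 3 != 0)
      stop("gene ", gene_id, " length not a codon multiple")
    cod <- as.character(Biostrings::subseq(seq, 3L * (codon - 1L) + 1L,
                                           3L * codon))
    unname(.GC[cod])
  }
  res <- c(gyrA_83 = residue(gyrA_id, 83L),
           gyrA_87 = residue(gyrA_id, 87L),
           parC_80 = residue(parC_id, 80L))
  n <- sum(res != wildtype[names(res)])
  list(gyrA_codon83 = res[["gyrA_83"]],
       gyrA_codon87 = res[["gyrA_87"]],
       parC_codon80 = res[["parC_80"]],
       n_resistance_mutations = n,
       category = if (n == 3) "resistant" else if (n == 0) "sensitive"
                  else "partial")
}

#' Per-individual selection report
#'
#' Writes the selection summary (observed/expected counts, omega), the
#' fixed-mutation table, divergence estimate and resistance category as JSON
#' plus a TSV of fixed mutations.
#'
#' @param summary List from [dnds()].
#' @param fixed data.frame from [fixedMutations()].
#' @param divergence List from [divergenceTime()].
#' @param resistance List from [resistanceGenotype()], or `NULL`.
#' @param path_json,path_tsv Output paths (`NULL` skips).
#' @return The report list, invisibly.
#' @export
writeSelectionReport <- function(summary, fixed, divergence,
                                 resistance = NULL, path_json = NULL,
                                 path_tsv = NULL) {
  report <- list(selection = summary, divergence = divergence,
                 resistance = resistance,
                 fixed_mutation_count = nrow(fixed))
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path_tsv))
    utils::write.table(fixed, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(report)
}
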