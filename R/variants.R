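# SNP calling and classification from pileup tables, with the coverage and
# allele-frequency filters used throughout: minimum depth 8, minimum variant
# allele frequency 20%, dominant (near-fixed) threshold 80%.

#' Call SNPs from a pileup table
#'
#' Emits one call per position whose depth reaches `min_depth` and whose most
#' frequent non-reference allele reaches `min_vaf` of the depth.  At
#' multi-allelic positions only the single most frequent alternative allele
#' is reported; ties are broken lexicographically.
#'
#' @param pileup In-memory pileup data.frame (see [validatePileup()]).
#' @param min_depth Minimum read depth for a position to be considered.
#' @param min_vaf Minimum variant allele frequency (inclusive).
#' @return data.frame of calls: `contig`, `pos` (1-based), `ref`, `alt`,
#'   `depth`, `vaf`, plus `region`, `gene_id`, `effect` (`NA` until
#'   [annotateEffects()]) and `dominant` (`NA` until [flagDominant()]).
#' @examples
#' p <- data.frame(contig = "c", pos = 1:2, ref = "A", depth = c(7L, 8L),
#'                 A = c(3L, 6L), C = c(4L, 2L), G = 0L, T = 0L)
#' callSnps(p)   # depth-7 row filtered, depth-8 row called at vaf 0.25
#' @export
callSnps <- function(pileup, min_depth = 8L, min_vaf = 0.20) {
  validatePileup(pileup)
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(), depth = integer(),
                      vaf = numeric(), region = character(),
                      gene_id = character(), effect = character(),
                      dominant = logical(), stringsAsFactors = FALSE)
  if (!nrow(pileup)) return(empty)
  keep <- pileup$depth >= min_depth
  p <- pileup[keep, , drop = FALSE]
  if (!nrow(p)) return(empty)
  cnt <- as.matrix(p[, .BASES])
  # mask the reference allele, then take the most frequent alternative;
  # which.max on the masked matrix breaks ties lexicographically (A<C<G<T)
  cnt[cbind(seq_len(nrow(p)), match(p$ref, .BASES))] <- -1L
  alt_i <- max.col(cnt, ties.method = "first")
  alt_count <- cnt[cbind(seq_len(nrow(p)), alt_i)]
  vaf <- alt_count / p$depth
  sel <- vaf >= min_vaf
  if (!any(sel)) return(empty)
  data.frame(contig = p$contig[sel], pos = p$pos[sel], ref = p$ref[sel],
             alt = .BASES[alt_i[sel]], depth = p$depth[sel], vaf = vaf[sel],
             region = NA_character_, gene_id = NA_character_,
             effect = NA_character_, dominant = NA,
             stringsAsFactors = FALSE)
}

#' Flag dominant (near-fixed) SNPs
#'
#' A call is dominant when the fraction of reads carrying the variant allele
#' is at least `threshold` (inclusive boundary).
#'
#' @param calls data.frame from [callSnps()].
#' @param threshold Dominance threshold on the variant allele frequency.
#' @return The calls with the `dominant` column set; order preserved.
#' @export
flagDominant <- function(calls, threshold = 0.80) {
  calls$dominant <- calls$vaf >= threshold
  calls
}

#' Within-genome strain heterogeneity
#'
#' A position with depth at least `min_depth` is callable; a callable
#' position is polymorphic when its most frequent allele (reference included)
#' accounts for at most 80% of reads — i.e. nonpolymorphic when the dominant
#' allele frequency exceeds 80% (strict).  More than 5 polymorphic sites per
#' kb flags a probable strain mixture.
#'
#' @param pileup In-memory pileup data.frame.
#' @param min_depth Minimum depth for a callable position.
#' @return List with `polymorphic_sites`, `callable_bases`, `snps_per_kb`
#'   (`NA` when no base is callable) and `multi_strain_flag`.
#' @export
heterogeneity <- function(pileup, min_depth = 8L) {
  validatePileup(pileup)
  keep <- nrow(pileup) > 0 & pileup$depth >= min_depth
  p <- pileup[keep, , drop = FALSE]
  callable <- nrow(p)
  if (!callable)
    return(list(polymorphic_sites = 0L, callable_bases = 0L,
                snps_per_kb = NA_real_, multi_strain_flag = FALSE))
  top <- do.call(pmax, p[, .BASES])
  poly <- sum(top / p$depth <= 0.80)
  rate <- 1000 * poly / callable
  list(polymorphic_sites = poly, callable_bases = callable,
       snps_per_kb = rate, multi_strain_flag = rate > 5)
}

#' Annotate SNP calls with region and coding effect
#'
#' Region is set by gene-interval lookup; for coding SNPs the reference and
#' variant codons are translated (standard genetic code, identical to table
#' 11 for all codons; strand-aware) and the change classified as synonymous,
#' nonsynonymous or nonsense.  Intergenic calls get `effect = "none"`.
#'
#' @param calls data.frame from [callSnps()].
#' @param genome The [AnnotatedGenome-class] the pileup was computed against.
#' @return The calls with `region`, `gene_id` and `effect` filled in.
#' @export
annotateEffects <- function(calls, genome) {
  if (!nrow(calls)) return(calls)
  lens <- Biostrings::width(genomeSeqs(genome))
  names(lens) <- names(genomeSeqs(genome))
  bad <- !(calls$contig %in% names(lens)) | calls$pos < 1L |
    calls$pos > lens[calls$contig]
  if (any(bad))
    stop("call at ", calls$contig[which(bad)[1]], ":", calls$pos[which(bad)[1]],
         " lies outside the genome")
  cls <- .classifyVariants(genome, calls[, c("contig", "pos", "alt")])
  calls$region <- cls$region
  calls$gene_id <- cls$gene_id
  calls$effect <- cls$effect
  calls
}

#' Write SNP calls as minimal VCF 4.2 or TSV
#'
#' `writeSnpVcf()` emits a minimal VCF 4.2 (CHROM POS ID REF ALT QUAL FILTER
#' INFO) with `DP` and `VAF` INFO keys; `writeSnpTable()` writes the call
#' data.frame as TSV.
#'
#' @param calls data.frame from [callSnps()].
#' @param path Output path.
#' @param genome Optional [AnnotatedGenome-class] supplying `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(calls, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lumenstrain",
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele frequency">')
  if (!is.null(genome)) {
    sq <- genomeSeqs(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sq),
                          Biostrings::width(sq)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(calls))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;VAF=%.6g",
            calls$contig, calls$pos, calls$ref, calls$alt,
            calls$depth, calls$vaf)
  else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeSnpVcf
#' @export
writeSnpTable <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
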