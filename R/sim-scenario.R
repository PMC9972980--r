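#' Construct a simulation scenario
#'
#' All arguments have defaults describing one healthy-adult individual
#' carrying a single founder strain that diversified independently at three
#' intestinal sites plus feces: tens of substitutions per site, strong
#' purifying selection (dN/dS target 0.2), a moderate replication gradient
#' (origin/terminus ratio 1.5, the *E. coli* scale), 50x mean depth and a
#' 0.1% base-call error.  See the methods vignette for the rationale behind
#' each default.
#'
#' @param seed Integer seed driving every random draw.
#' @param genome_length Founder length in bases.
#' @param n_contigs Number of contigs.
#' @param gene_fraction Fraction of the genome inside coding genes, in
#'   \[0, 1).
#' @param mean_gene_length Mean gene length in bases.
#' @param sites Site labels; defaults to terminal ileum (TI), cecum,
#'   descending colon (DC) and feces.
#' @param per_site_substitutions Substitutions private to each site.
#' @param shared_substitutions Substitutions shared by all sites.
#' @param omega_true Target dN/dS for implanted coding changes.
#' @param minor_lineage_freq Minor-lineage cell fraction (0 disables).
#' @param minor_lineage_snps SNPs carried by the minor lineage.
#' @param ptr_true True origin/terminus coverage ratio (>= 1).
#' @param mean_depth Mean reads-per-position.
#' @param error_rate Per-base miscall probability.
#' @param deleted_genes_per_individual Genes deleted relative to a foreign
#'   reference (between-individual gene flux only).
#' @param read_length Simulated read length.
#' @return A [SimScenario-class] object.
#' @examples
#' SimScenario(seed = 1, genome_length = 50000L)
#' @export
SimScenario <- function(seed = 1L,
                        genome_length = 100000L,
                        n_contigs = 1L,
                        gene_fraction = 0.85,
                        mean_gene_length = 900L,
                        sites = c("TI", "cecum", "DC", "feces"),
                        per_site_substitutions = 30L,
                        shared_substitutions = 10L,
                        omega_true = 0.2,
                        minor_lineage_freq = 0,
                        minor_lineage_snps = 0L,
                        ptr_true = 1.5,
                        mean_depth = 50,
                        error_rate = 0.001,
                        deleted_genes_per_individual = 0L,
                        read_length = 100L) {
  methods::new("SimScenario",
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    gene_fraction = gene_fraction,
    mean_gene_length = as.integer(mean_gene_length),
    sites = sites,
    per_site_substitutions = as.integer(per_site_substitutions),
    shared_substitutions = as.integer(shared_substitutions),
    omega_true = omega_true,
    minor_lineage_freq = minor_lineage_freq,
    minor_lineage_snps = as.integer(minor_lineage_snps),
    ptr_true = ptr_true,
    mean_depth = mean_depth,
    error_rate = error_rate,
    deleted_genes_per_individual = as.integer(deleted_genes_per_individual),
    read_length = as.integer(read_length))
}

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario: seed", object@seed, "|", object@genome_length, "bp,",
      object@n_contigs, "contig(s), gene fraction", object@gene_fraction, "\n")
  cat("  sites:", paste(object@sites, collapse = ", "), "\n")
  cat("  substitutions:", object@per_site_substitutions, "per site +",
      object@shared_substitutions, "shared; omega_true", object@omega_true, "\n")
  cat("  minor lineage:", object@minor_lineage_snps, "SNPs at freq",
      object@minor_lineage_freq, "\n")
  cat("  coverage: depth", object@mean_depth, ", PTR", object@ptr_true,
      ", error", object@error_rate, "\n")
})

#' Accessors for TruthBundle
#'
#' @param x A [TruthBundle-class].
#' @return `siteGenomes()` the named list of per-site genomes;
#'   `implantedSnps()` the major-lineage substitution table;
#'   `minorPositions()` the minor-lineage SNP table; `truthFounder()` the
#'   founder genome.
#' @name TruthBundle-accessors
NULL

#' @rdname TruthBundle-accessors
#' @export
setGeneric("siteGenomes", function(x) standardGeneric("siteGenomes"))

#' @rdname TruthBundle-accessors
#' @export
setMethod("siteGenomes", "TruthBundle", function(x) x@siteGenomes)

#' @rdname TruthBundle-accessors
#' @export
setGeneric("implantedSnps", function(x) standardGeneric("implantedSnps"))

#' @rdname TruthBundle-accessors
#' @export
setMethod("implantedSnps", "TruthBundle", function(x) x@implantedSnps)

#' @rdname TruthBundle-accessors
#' @export
setGeneric("minorPositions", function(x) standardGeneric("minorPositions"))

#' @rdname TruthBundle-accessors
#' @export
setMethod("minorPositions", "TruthBundle", function(x) x@minorPositions)

#' @rdname TruthBundle-accessors
#' @export
setGeneric("truthFounder", function(x) standardGeneric("truthFounder"))

#' @rdname TruthBundle-accessors
#' @export
setMethod("truthFounder", "TruthBundle", function(x) x@founder)

setMethod("show", "TruthBundle", function(object) {
  cat("TruthBundle:", length(object@siteGenomes), "site genome(s) from a",
      genomeLength(object@founder), "bp founder\n")
  cat("  implanted major SNPs:", nrow(object@implantedSnps),
      "| minor-lineage SNPs:", nrow(object@minorPositions),
      "at freq", object@minorFreq, "\n")
  cat("  PTR", object@ptrTrue, "| omega_true", object@omegaTrue, "\n")
})
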