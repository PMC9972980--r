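#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Reference genome with gene annotation
#'
#' Holds the contig sequences of one (draft) genome together with its
#' protein-coding gene coordinates.  This is the reference object against
#' which all per-site inference (variant calling, effect annotation, gene
#' read counting, resistance genotyping) is performed.
#'
#' Coordinates are stored the Bioconductor way: 1-based, closed intervals in
#' a [GenomicRanges::GRanges].  On disk, GFF3 and VCF are 1-based and BED and
#' the pileup TSV dialect are 0-based; conversions happen at I/O only.
#'
#' @slot sequences A [Biostrings::DNAStringSet], one element per contig.
#' @slot genes A [GenomicRanges::GRanges] of coding genes with a `gene_id`
#'   metadata column; strand is `+` or `-`.
#'
#' @seealso [AnnotatedGenome()] for construction, [readAnnotatedGenome()],
#'   [writeAnnotatedGenome()].
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  representation(sequences = "DNAStringSet", genes = "GRanges")
)

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  sq <- object@sequences
  gn <- object@genes
  if (is.null(names(sq)) || anyDuplicated(names(sq)))
    msg <- c(msg, "contigs must have unique names")
  if (length(gn)) {
    if (is.null(gn$gene_id) || anyDuplicated(gn$gene_id))
      msg <- c(msg, "genes must carry unique 'gene_id' metadata")
    bad <- !(as.character(GenomicRanges::seqnames(gn)) %in% names(sq))
    if (any(bad))
      msg <- c(msg, "gene contig names absent from sequences")
    else {
      lens <- Biostrings::width(sq)[match(
        as.character(GenomicRanges::seqnames(gn)), names(sq))]
      if (any(GenomicRanges::start(gn) < 1L) ||
          any(GenomicRanges::end(gn) > lens))
        msg <- c(msg, "gene coordinates outside contig bounds")
    }
    if (any(as.character(GenomicRanges::strand(gn)) == "*"))
      msg <- c(msg, "gene strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation scenario for the founder-diversification generator
#'
#' Bundles every knob of the synthetic-data generator: the founder genome
#' layout, the number of substitutions private to each intestinal site and
#' shared among all sites, the dN/dS target used to thin nonsynonymous
#' changes, an optional minor co-resident lineage, the origin-to-terminus
#' coverage gradient, sequencing depth and base-call error.  Defaults
#' describe one healthy-adult individual sampled at terminal ileum (TI),
#' cecum, descending colon (DC) and feces.
#'
#' @slot seed Integer seed; every downstream draw is derived from it.
#' @slot genome_length Total founder length in bases.
#' @slot n_contigs Number of contigs the founder is split into.
#' @slot gene_fraction Fraction of the genome covered by coding genes.
#' @slot mean_gene_length Mean gene length in bases (rounded to codons).
#' @slot sites Character vector of site labels.
#' @slot per_site_substitutions Substitutions private to each site.
#' @slot shared_substitutions Substitutions common to all sites (pre-split).
#' @slot omega_true Target dN/dS used to thin nonsynonymous changes.
#' @slot minor_lineage_freq Minor-lineage cell fraction in \[0, 0.5\]; 0 disables.
#' @slot minor_lineage_snps Number of SNPs private to the minor lineage.
#' @slot ptr_true Origin/terminus coverage ratio (>= 1).
#' @slot mean_depth Mean reads-per-position.
#' @slot error_rate Per-base miscall probability in \[0, 0.25).
#' @slot deleted_genes_per_individual Genes deleted when this individual's
#'   reads are mapped to another individual's reference (between-individual
#'   gene flux only).
#' @slot read_length Simulated read length in bases.
#'
#' @seealso [SimScenario()] for construction with defaults.
#' @exportClass SimScenario
setClass("SimScenario",
  representation(
    seed = "integer",
    genome_length = "integer",
    n_contigs = "integer",
    gene_fraction = "numeric",
    mean_gene_length = "integer",
    sites = "character",
    per_site_substitutions = "integer",
    shared_substitutions = "integer",
    omega_true = "numeric",
    minor_lineage_freq = "numeric",
    minor_lineage_snps = "integer",
    ptr_true = "numeric",
    mean_depth = "numeric",
    error_rate = "numeric",
    deleted_genes_per_individual = "integer",
    read_length = "integer"
  )
)

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@genome_length <= 0L) msg <- c(msg, "genome_length must be > 0")
  if (object@n_contigs < 1L) msg <- c(msg, "n_contigs must be >= 1")
  if (object@gene_fraction < 0 || object@gene_fraction >= 1)
    msg <- c(msg, "gene_fraction must lie in [0, 1)")
  if (object@mean_gene_length > object@genome_length)
    msg <- c(msg, "mean_gene_length exceeds genome_length")
  if (!length(object@sites)) msg <- c(msg, "at least one site required")
  if (object@minor_lineage_freq < 0 || object@minor_lineage_freq > 0.5)
    msg <- c(msg, "minor_lineage_freq must lie in [0, 0.5]")
  if (any(object@ptr_true < 1)) msg <- c(msg, "ptr_true must be >= 1")
  if (object@error_rate < 0 || object@error_rate >= 0.25)
    msg <- c(msg, "error_rate must lie in [0, 0.25)")
  counts <- c(object@per_site_substitutions, object@shared_substitutions,
              object@minor_lineage_snps, object@deleted_genes_per_individual)
  if (any(counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@omega_true < 0) msg <- c(msg, "omega_true must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of one simulated individual
#'
#' Records everything the generator did: the founder genome, the diversified
#' per-site genomes, every implanted substitution with its effect class and
#' lineage, the minor-lineage positions and genome, deleted gene ids, and the
#' true replication ratio and dN/dS target.  Parameter-recovery tests compare
#' pipeline estimates against this object.
#'
#' @slot founder The [AnnotatedGenome-class] all sites descend from.
#' @slot siteGenomes Named list of per-site [AnnotatedGenome-class] objects.
#' @slot minorGenome The minor lineage's genome (founder + minor SNPs), or the
#'   founder itself when no minor lineage was simulated.
#' @slot implantedSnps data.frame: `contig`, `pos` (1-based), `ref`, `alt`,
#'   `scope` (`"shared"` or a site label), `lineage` (`"major"`), `region`,
#'   `gene_id`, `effect`.
#' @slot minorPositions data.frame with the same columns for the minor
#'   lineage (`lineage == "minor"`, `scope == "all"`).
#' @slot deletedGeneIds Gene ids absent from this individual relative to a
#'   foreign reference.
#' @slot ptrTrue True origin/terminus coverage ratio.
#' @slot omegaTrue dN/dS target used to thin nonsynonymous changes.
#' @slot minorFreq Minor-lineage cell fraction.
#' @slot origin Global (concatenated) 1-based coordinate of the replication
#'   origin.
#' @slot terminus Global coordinate of the terminus.
#'
#' @exportClass TruthBundle
setClass("TruthBundle",
  representation(
    founder = "AnnotatedGenome",
    siteGenomes = "list",
    minorGenome = "AnnotatedGenome",
    implantedSnps = "data.frame",
    minorPositions = "data.frame",
    deletedGeneIds = "character",
    ptrTrue = "numeric",
    omegaTrue = "numeric",
    minorFreq = "numeric",
    origin = "numeric",
    terminus = "numeric"
  )
)

setValidity("TruthBundle", function(object) {
  msg <- character()
  lens <- Biostrings::width(object@founder@sequences)
  names(lens) <- names(object@founder@sequences)
  check_pos <- function(df) {
    if (!nrow(df)) return(TRUE)
    ok <- df$contig %in% names(lens)
    all(ok) && all(df$pos >= 1L) && all(df$pos <= lens[df$contig])
  }
  if (!check_pos(object@implantedSnps))
    msg <- c(msg, "implanted SNP positions outside founder coordinates")
  if (!check_pos(object@minorPositions))
    msg <- c(msg, "minor-lineage positions outside founder coordinates")
  if (nrow(object@minorPositions) && nrow(object@implantedSnps)) {
    key <- function(df) paste(df$contig, df$pos)
    if (any(key(object@minorPositions) %in% key(object@implantedSnps)))
      msg <- c(msg, "minor-lineage positions overlap major-lineage positions")
  }
  if (length(msg)) msg else TRUE
})
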