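#' Construct an AnnotatedGenome
#'
#' @param sequences A [Biostrings::DNAStringSet] (or named character vector)
#'   of contig sequences.
#' @param genes A [GenomicRanges::GRanges] of coding genes with a `gene_id`
#'   metadata column, or `NULL` for a genome without annotation.
#' @return An [AnnotatedGenome-class] object.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chr = "ATGAAATTTTAAGGGG"))
#' genes <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 12),
#'                                 strand = "+", gene_id = "g1")
#' AnnotatedGenome(seqs, genes)
#' @export
AnnotatedGenome <- function(sequences, genes = NULL) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(genes))
    genes <- GenomicRanges::GRanges(gene_id = character())
  methods::new("AnnotatedGenome", sequences = sequences, genes = genes)
}

#' @rdname AnnotatedGenome
#' @param x,object An `AnnotatedGenome`.
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))

#' @rdname AnnotatedGenome
#' @export
setMethod("genomeSeqs", "AnnotatedGenome", function(x) x@sequences)

#' @rdname AnnotatedGenome
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname AnnotatedGenome
#' @export
setMethod("geneRanges", "AnnotatedGenome", function(x) x@genes)

#' @rdname AnnotatedGenome
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname AnnotatedGenome
#' @export
setMethod("genomeLength", "AnnotatedGenome",
          function(x) sum(Biostrings::width(x@sequences)))

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", length(object@sequences), "contig(s),",
      genomeLength(object), "bases,", length(object@genes), "gene(s)\n")
})

#' Extract the coding sequence of one gene
#'
#' Returns the strand-aware coding sequence (reverse-complemented for
#' minus-strand genes), ready for translation.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param gene_id Gene identifier present in `geneRanges(genome)$gene_id`.
#' @return A [Biostrings::DNAString].
#' @export
geneSequence <- function(genome, gene_id) {
  gn <- geneRanges(genome)
  i <- match(gene_id, gn$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  g <- gn[i]
  seq <- Biostrings::subseq(
    genomeSeqs(genome)[[as.character(GenomicRanges::seqnames(g))]],
    GenomicRanges::start(g), GenomicRanges::end(g))
  if (as.character(GenomicRanges::strand(g)) == "-")
    seq <- Biostrings::reverseComplement(seq)
  seq
}

#' Read / write an annotated genome
#'
#' `readAnnotatedGenome()` reads contigs from FASTA and gene coordinates
#' from GFF3 or BED; `writeAnnotatedGenome()` writes FASTA plus GFF3 (and
#' optionally a BED6 mirror).
#'
#' @param fasta Path to a FASTA file.
#' @param genes Path to a GFF3 (`.gff`, `.gff3`) or BED file, or `NULL`.
#' @return `readAnnotatedGenome()` returns an [AnnotatedGenome-class];
#'   `writeAnnotatedGenome()` returns its paths invisibly.
#' @export
readAnnotatedGenome <- function(fasta, genes = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- NULL
  if (!is.null(genes)) {
    gr <- rtracklayer::import(genes)
    if (is.null(gr$gene_id)) {
      gr$gene_id <- if (!is.null(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("gene_%04d", seq_along(gr))
    }
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["gene_id"]
  }
  AnnotatedGenome(seqs, gr)
}

#' @rdname readAnnotatedGenome
#' @param genome An [AnnotatedGenome-class].
#' @param gff Output GFF3 path, or `NULL` to skip.
#' @param bed Output BED path, or `NULL` to skip.
#' @export
writeAnnotatedGenome <- function(genome, fasta, gff = NULL, bed = NULL) {
  Biostrings::writeXStringSet(genomeSeqs(genome), fasta)
  gn <- geneRanges(genome)
  if (!is.null(gff)) {
    out <- gn
    out$type <- "CDS"
    out$ID <- out$gene_id
    out$phase <- 0L
    rtracklayer::export(out, gff, format = "gff3")
  }
  if (!is.null(bed)) {
    out <- gn
    out$name <- out$gene_id
    rtracklayer::export(out, bed, format = "bed")
  }
  invisible(c(fasta = fasta, gff = gff, bed = bed))
}
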