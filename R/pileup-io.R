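# Pileup-table I/O.  The on-disk TSV dialect is
#   contig  pos  ref  depth  A  C  G  T
# with 0-based positions; in memory the `pos` column is 1-based to match the
# GRanges convention used throughout the package.

#' Validate a pileup table
#'
#' Checks the in-memory pileup contract: required columns, per-contig unique
#' positions, `ref` in A/C/G/T and allele counts summing to `depth`.  Errors
#' name the first offending row.
#'
#' @param pileup data.frame with columns `contig`, `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`.
#' @return The validated pileup, invisibly.
#' @export
validatePileup <- function(pileup) {
  need <- c("contig", "pos", "ref", "depth", "A", "C", "G", "T")
  miss <- setdiff(need, names(pileup))
  if (length(miss))
    stop("pileup lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(pileup)) return(invisible(pileup))
  bad <- which(pileup$A + pileup$C + pileup$G + pileup$T != pileup$depth)
  if (length(bad))
    stop("pileup row ", bad[1], " (", pileup$contig[bad[1]], ":",
         pileup$pos[bad[1]], "): allele counts do not sum to depth")
  bad <- which(!(pileup$ref %in% .BASES))
  if (length(bad))
    stop("pileup row ", bad[1], ": ref base not in A/C/G/T")
  if (anyDuplicated(paste(pileup$contig, pileup$pos)))
    stop("duplicated (contig, pos) in pileup")
  invisible(pileup)
}

#' Read / write a pileup table
#'
#' On-disk positions are 0-based per the TSV dialect; they are converted to
#' 1-based on read and back on write.
#'
#' @param path File path.
#' @return `readPileupTable()` returns the validated in-memory pileup.
#' @export
readPileupTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         rep("integer", 5)))
  df$pos <- df$pos + 1L
  validatePileup(df)
  df
}

#' @rdname readPileupTable
#' @param pileup In-memory pileup data.frame (1-based `pos`).
#' @export
writePileupTable <- function(pileup, path) {
  validatePileup(pileup)
  out <- pileup
  out$pos <- out$pos - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert samtools-style pileup text to a pileup table
#'
#' Ingests the classic 6-column `samtools mpileup` text (contig, 1-based
#' position, reference base, depth, read bases, qualities).  Read-start
#' (`^` + mapping quality), read-end (`$`) and indel (`+n`/`-n` + sequence)
#' markers are stripped; `.`/`,` count toward the reference base and ACGT
#' letters toward their allele.  Deletion placeholders (`*`) remain in the
#' depth but carry no allele, so rows are re-balanced by recomputing depth as
#' the sum of the four allele counts.
#'
#' @param path Path to samtools pileup text.
#' @return In-memory pileup data.frame (1-based `pos`).
#' @export
readSamtoolsPileup <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  contig <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  ref <- toupper(vapply(parts, `[`, "", 3L))
  bases <- vapply(parts, `[`, "", 5L)
  bases <- gsub("\\^.", "", bases)
  bases <- gsub("\\$", "", bases)
  # strip indel runs: +/- followed by a length then that many bases
  strip_indels <- function(x) {
    repeat {
      m <- regexpr("[+-][0-9]+", x)
      if (m < 0) break
      len <- as.integer(substr(x, m + 1, m + attr(m, "match.length") - 1))
      x <- paste0(substr(x, 1, m - 1),
                  substr(x, m + attr(m, "match.length") + len, nchar(x)))
    }
    x
  }
  bases <- vapply(bases, strip_indels, "", USE.NAMES = FALSE)
  bases <- toupper(bases)
  cnt <- function(x, ch) nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
  match_n <- cnt(bases, ".") + cnt(bases, ",")
  counts <- sapply(.BASES, function(b) cnt(bases, b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, .BASES))
  for (b in .BASES) {
    sel <- ref == b
    counts[sel, b] <- counts[sel, b] + match_n[sel]
  }
  depth <- rowSums(counts)
  df <- data.frame(contig = contig, pos = pos, ref = ref,
                   depth = as.integer(depth),
                   A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
                   G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]),
                   stringsAsFactors = FALSE)
  validatePileup(df)
  df
}

#' Read / write a per-read mapping summary
#'
#' TSV with columns `read_id`, `contig`, `start`, `end` (0-based half-open on
#' disk, 1-based closed in memory) and `mismatches`.
#'
#' @param path File path.
#' @return `readReadSummary()` returns the in-memory data.frame.
#' @export
readReadSummary <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("read_id", "contig", "mismatches") %in% names(df)))
    stop("read summary needs read_id, contig, mismatches columns")
  if (all(c("start", "end") %in% names(df))) {
    df$start <- df$start + 1L
  }
  df
}

#' @rdname readReadSummary
#' @param reads In-memory read summary data.frame.
#' @export
writeReadSummary <- function(reads, path) {
  out <- reads
  if (all(c("start", "end") %in% names(out))) out$start <- out$start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
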