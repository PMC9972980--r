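# Codon arithmetic shared by the simulator, the variant annotator and the
# dN/dS estimator.  All translation uses the standard genetic code, which is
# identical to bacterial/archaeal table 11 for every codon (the tables differ
# only in permitted start codons, irrelevant for substitution effects).

.BASES <- c("A", "C", "G", "T")
.GC <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.GC)[.GC == "*"]
.SENSE_CODONS <- names(.GC)[.GC != "*"]

.complement <- function(x) chartr("ACGT", "TGCA", x)

# reverse-complement of codon strings (vectorised, 3-mers only)
.revcompCodon <- function(x) {
  paste0(.complement(substr(x, 3L, 3L)),
         .complement(substr(x, 2L, 2L)),
         .complement(substr(x, 1L, 1L)))
}

.substituteAt <- function(codon, offset, base) {
  substr(codon, offset, offset) <- base
  codon
}

# cumulative 0-based offsets of contigs in genome order, for a single
# concatenated ("global") coordinate system used by the coverage gradient
.contigOffsets <- function(genome) {
  w <- Biostrings::width(genomeSeqs(genome))
  off <- cumsum(c(0, w[-length(w)]))
  names(off) <- names(genomeSeqs(genome))
  off
}

.contigStrings <- function(genome) {
  lapply(as.list(as.character(genomeSeqs(genome))), identity)
}

# Vectorised classification of candidate substitutions against a genome.
# df needs columns contig, pos (1-based), alt.  Adds: ref, region, gene_id,
# strand, effect, ref_codon, var_codon (sense frame), codon_offset (1..3).
.classifyVariants <- function(genome, df) {
  n <- nrow(df)
  out <- data.frame(
    contig = df$contig, pos = as.integer(df$pos), ref = NA_character_,
    alt = df$alt, region = "intergenic", gene_id = NA_character_,
    strand = NA_character_, effect = "none",
    ref_codon = NA_character_, var_codon = NA_character_,
    codon_offset = NA_integer_, stringsAsFactors = FALSE)
  if (!n) return(out)
  strs <- .contigStrings(genome)
  out$ref <- mapply(function(ctg, p) substr(strs[[ctg]], p, p),
                    df$contig, df$pos, USE.NAMES = FALSE)
  genes <- geneRanges(genome)
  if (!length(genes)) return(out)
  qry <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$pos, df$pos))
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(qry, genes, select = "first"))
  inside <- !is.na(hit)
  if (!any(inside)) return(out)
  gi <- hit[inside]
  gs <- GenomicRanges::start(genes)[gi]
  ge <- GenomicRanges::end(genes)[gi]
  strand <- as.character(GenomicRanges::strand(genes))[gi]
  pos <- df$pos[inside]
  plus <- strand == "+"
  off0 <- ifelse(plus, pos - gs, ge - pos)      # 0-based offset in sense frame
  codon_idx <- off0 %/% 3L
  within <- (off0 %% 3L) + 1L                   # 1..3 in the sense codon
  ctg <- df$contig[inside]
  cstart <- ifelse(plus, gs + 3L * codon_idx, ge - 3L * codon_idx - 2L)
  fwd <- mapply(function(c, s) substr(strs[[c]], s, s + 2L), ctg, cstart,
                USE.NAMES = FALSE)
  ref_codon <- ifelse(plus, fwd, .revcompCodon(fwd))
  sense_alt <- ifelse(plus, df$alt[inside], .complement(df$alt[inside]))
  var_codon <- mapply(.substituteAt, ref_codon, within, sense_alt,
                      USE.NAMES = FALSE)
  aa_ref <- unname(.GC[ref_codon])
  aa_var <- unname(.GC[var_codon])
  effect <- ifelse(aa_ref == aa_var, "synonymous",
            ifelse(aa_var == "*", "nonsense", "nonsynonymous"))
  out$region[inside] <- "coding"
  out$gene_id[inside] <- genes$gene_id[gi]
  out$strand[inside] <- strand
  out$effect[inside] <- effect
  out$ref_codon[inside] <- ref_codon
  out$var_codon[inside] <- var_codon
  out$codon_offset[inside] <- within
  out
}

# apply substitutions (data.frame contig/pos/alt) to a DNAStringSet
.applySubstitutions <- function(seqs, df) {
  if (!nrow(df)) return(seqs)
  for (ctg in unique(df$contig)) {
    sel <- df$contig == ctg
    seqs[[ctg]] <- Biostrings::replaceLetterAt(
      seqs[[ctg]], at = df$pos[sel], letter = paste(df$alt[sel], collapse = ""))
  }
  seqs
}

# Nei-Gojobori expected synonymous/nonsynonymous site counts per codon.
# Per codon position the 3 possible changes are enumerated; changes creating
# a stop codon are excluded, and the position contributes f_syn sites to S
# and 1 - f_syn to N (f_syn = synonymous fraction among non-stop changes).
.ngSiteTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    s <- numeric(length(.SENSE_CODONS))
    names(s) <- .SENSE_CODONS
    for (cod in .SENSE_CODONS) {
      aa <- .GC[cod]
      tot <- 0
      for (p in 1:3) {
        alts <- setdiff(.BASES, substr(cod, p, p))
        vars <- vapply(alts, function(b) .substituteAt(cod, p, b), "")
        keep <- .GC[vars] != "*"
        if (!any(keep)) next
        tot <- tot + sum(.GC[vars[keep]] == aa) / sum(keep)
      }
      s[cod] <- tot
    }
    tab <<- s
    tab
  }
})

.ngSites <- function(codons) {
  s <- .ngSiteTable()[codons]
  s[is.na(s)] <- 0          # stop codons in the reference contribute nothing
  n <- ifelse(codons %in% .SENSE_CODONS, 3 - unname(s), 0)
  list(S = unname(s), N = n)
}

# observed synonymous/nonsynonymous differences between two codons,
# averaging over all mutational paths with equal weight (paths through stop
# codons are dropped; if every path hits a stop the direct classification of
# each single change is used)
.ngObserved <- function(ref, var) {
  diffs <- which(strsplit(ref, "")[[1]] != strsplit(var, "")[[1]])
  k <- length(diffs)
  if (k == 0L) return(c(sd = 0, nd = 0))
  if (k == 1L) {
    syn <- .GC[ref] == .GC[var] && .GC[var] != "*"
    if (.GC[var] == "*") return(c(sd = 0, nd = 1))   # nonsense counted as N
    return(c(sd = as.numeric(syn), nd = as.numeric(!syn)))
  }
  perms <- if (k == 2L) list(diffs, rev(diffs)) else {
    idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(i) diffs[i])
  }
  acc <- matrix(0, 0, 2)
  for (ord in perms) {
    cur <- ref; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- .substituteAt(cur, p, substr(var, p, p))
      if (.GC[nxt] == "*") { ok <- FALSE; break }
      if (.GC[cur] == .GC[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc <- rbind(acc, c(sd, nd))
  }
  if (!nrow(acc)) return(c(sd = 0, nd = k))
  c(sd = mean(acc[, 1]), nd = mean(acc[, 2]))
}
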