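#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width findOverlaps
#' @importFrom BiocGenerics start<- end<-
#' @importFrom BiocGenerics sort
NULL

#' TranscriptModel: a spliced, coding transcript structure
#'
#' Exon structure and coding span of one transcript on a genome. Exons
#' are stored as 1-based inclusive [IRanges::IRanges] in genomic order
#' regardless of strand; all protein-coordinate arithmetic operates in
#' transcript (5'->3') space after strand resolution. `cdsStart` and
#' `cdsEnd` are genomic positions (cdsStart <= cdsEnd) delimiting the
#' coding span including the stop codon.
#'
#' @slot transcriptId,geneId,chrom character scalars.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon genomic intervals.
#' @slot cdsStart,cdsEnd integer genomic positions of the coding span.
#' @export
setClass("TranscriptModel",
  representation(transcriptId = "character", geneId = "character",
                 chrom = "character", strand = "character",
                 exons = "IRanges", cdsStart = "integer",
                 cdsEnd = "integer"))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) == 0) return("transcript has no exons")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (is.unsorted(start(ex), strictly = TRUE) &&
      length(ex) > 1) return("exons must be sorted by genomic start")
  if (length(ex) > 1 && any(start(ex)[-1] <= end(ex)[-length(ex)]))
    return("exons must be non-overlapping and sorted")
  cs <- object@cdsStart; ce <- object@cdsEnd
  if (cs > ce) return("cdsStart must be <= cdsEnd")
  inExon <- function(p) any(p >= start(ex) & p <= end(ex))
  if (!inExon(cs) || !inExon(ce))
    return(sprintf("CDS boundary outside exons in %s", object@transcriptId))
  if (splicedCdsLength(object) < 3) return("spliced CDS shorter than 3 nt")
  TRUE
})

#' @describeIn TranscriptModel constructor.
#' @param transcriptId,geneId,chrom,strand,exons,cdsStart,cdsEnd see slots.
#' @export
TranscriptModel <- function(transcriptId, geneId, chrom, strand, exons,
                            cdsStart, cdsEnd) {
  new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
      chrom = chrom, strand = strand, exons = exons,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("(%s, gene %s)\n", object@geneId, object@chrom),
      sprintf("  strand %s, %d exons, CDS %d-%d\n", object@strand,
              length(object@exons), object@cdsStart, object@cdsEnd))
})

#' @describeIn TranscriptModel accessor for the transcript identifier.
#' @param x a TranscriptModel.
#' @export
transcriptId <- function(x) x@transcriptId

#' @describeIn TranscriptModel accessor for the exon intervals.
#' @export
exons <- function(x) x@exons

# spliced length of the coding span (exonic bases within [cdsStart, cdsEnd])
splicedCdsLength <- function(t) {
  ov <- pmin(end(t@exons), t@cdsEnd) - pmax(start(t@exons), t@cdsStart) + 1L
  sum(pmax(ov, 0L))
}

#' Read a genome from FASTA
#'
#' Loads a (toy or real) genome as an uppercase [Biostrings::DNAStringSet].
#' Only the alphabet \{A, C, G, T, N\} is accepted; other IUPAC ambiguity
#' codes are rejected because downstream translation must be
#' deterministic.
#'
#' @param path FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("readGenome: file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0) stop("readGenome: no sequences in ", path)
  names(g) <- sub("\\s.*$", "", names(g))
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  if (any(Biostrings::width(g) == 0))
    stop("readGenome: empty sequence present")
  af <- Biostrings::alphabetFrequency(g)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                    drop = FALSE])
  if (any(bad > 0))
    stop("readGenome: ambiguity codes other than N are not supported")
  g
}

# fetch one chromosome or raise a defined error
chromSeq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom)
  genome[[chrom]]
}

#' Read transcript models from GTF
#'
#' Parses exon and CDS features (grouped by `transcript_id`) into
#' [TranscriptModel] objects. Parsing of well-formed files is delegated
#' to [rtracklayer::import()]; a structural pre-scan reports the line
#' number of any malformed record first.
#'
#' @param path GTF file.
#' @return a named list of `TranscriptModel` objects.
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("readTranscripts: file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9))
    stop("readTranscripts: malformed GTF line ",
         which(body)[which(nf < 9)[1]], " (expected 9 tab-separated fields)")
  if (!any(body)) return(list())
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- gr$type %in% c("exon", "CDS")
  gr <- gr[keep]
  if (length(gr) == 0) return(list())
  byTx <- split(seq_along(gr), gr$transcript_id)
  out <- lapply(names(byTx), function(tx) {
    sub <- gr[byTx[[tx]]]
    ex <- sub[sub$type == "exon"]
    cds <- sub[sub$type == "CDS"]
    if (length(ex) == 0)
      stop("readTranscripts: transcript ", tx, " has no exon features")
    if (length(cds) == 0)
      stop("readTranscripts: transcript ", tx, " has no CDS features")
    exr <- sort(IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)))
    TranscriptModel(
      transcriptId = tx,
      geneId = unique(ex$gene_id)[1],
      chrom = as.character(GenomicRanges::seqnames(ex))[1],
      strand = as.character(GenomicRanges::strand(ex))[1],
      exons = exr,
      cdsStart = min(GenomicRanges::start(cds)),
      cdsEnd = max(GenomicRanges::end(cds)))
  })
  names(out) <- names(byTx)
  out
}

#' Write transcript models to GTF
#'
#' @param transcripts list of [TranscriptModel].
#' @param path output file.
#' @export
writeTranscriptsGtf <- function(transcripts, path) {
  rows <- lapply(transcripts, function(t) {
    attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                    t@geneId, t@transcriptId)
    ex <- data.frame(seqname = t@chrom, source = "rejuvomics",
                     feature = "exon", start = start(t@exons),
                     end = end(t@exons), score = ".", strand = t@strand,
                     frame = ".", attributes = attr)
    cdsEx <- IRanges::restrict(t@exons, start = t@cdsStart, end = t@cdsEnd)
    cdsEx <- cdsEx[width(cdsEx) > 0]
    cds <- data.frame(seqname = t@chrom, source = "rejuvomics",
                      feature = "CDS", start = start(cdsEx),
                      end = end(cdsEx), score = ".", strand = t@strand,
                      frame = ".", attributes = attr)
    rbind(ex, cds)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of a transcript, reverse-complemented
#' for minus-strand transcripts, yielding the mature mRNA in 5'->3'
#' orientation.
#'
#' @param t a [TranscriptModel].
#' @param genome a `DNAStringSet` (see [readGenome()]).
#' @return a [Biostrings::DNAString].
#' @export
splicedSequence <- function(t, genome) {
  cs <- chromSeq(genome, t@chrom)
  if (any(end(t@exons) > length(cs)) || any(start(t@exons) < 1))
    stop("splicedSequence: exon out of chromosome bounds in ",
         t@transcriptId)
  pieces <- Biostrings::extractAt(cs, t@exons)
  s <- unlist(pieces)
  if (t@strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# transcript (5'->3') coordinate of a genomic position; position must be exonic
genomicToTranscript <- function(t, gpos) {
  ex <- t@exons
  hit <- which(gpos >= start(ex) & gpos <= end(ex))
  if (length(hit) != 1) stop("position ", gpos, " is not exonic")
  upstream <- if (hit > 1) sum(width(ex)[seq_len(hit - 1)]) else 0L
  plusCoord <- upstream + (gpos - start(ex)[hit]) + 1L
  if (t@strand == "+") plusCoord
  else sum(width(ex)) - plusCoord + 1L
}

# genomic position of a transcript (5'->3') coordinate
transcriptToGenomic <- function(t, tpos) {
  total <- sum(width(t@exons))
  if (tpos < 1 || tpos > total) stop("transcript coordinate out of range")
  plusCoord <- if (t@strand == "+") tpos else total - tpos + 1L
  cw <- cumsum(width(t@exons))
  hit <- which(plusCoord <= cw)[1]
  offs <- plusCoord - (if (hit > 1) cw[hit - 1] else 0L)
  start(t@exons)[hit] + offs - 1L
}

# transcript coordinate of the first base of the start codon
cdsStartTranscript <- function(t) {
  anchor <- if (t@strand == "+") t@cdsStart else t@cdsEnd
  genomicToTranscript(t, anchor)
}

#' Translate an open reading frame
#'
#' Translates from a 1-based start position within an mRNA to the first
#' in-frame stop codon (or the end of the sequence), using the standard
#' genetic code. A trailing partial codon is dropped.
#'
#' @param mrna character or `DNAString`.
#' @param cdsStart 1-based position of the first base of the start codon.
#' @return list with `peptide` (character, stop codon excluded) and
#'   `stop` (logical: was an in-frame stop reached?).
#' @examples
#' translateOrf("ATGAAATAG", 1)   # peptide "MK", stop TRUE
#' @export
translateOrf <- function(mrna, cdsStart = 1L) {
  s <- as.character(mrna)
  if (cdsStart < 1 || cdsStart > nchar(s))
    stop("translateOrf: cdsStart outside sequence")
  orf <- substr(s, cdsStart, nchar(s))
  n <- 3L * (nchar(orf) %/% 3L)
  if (n == 0L) return(list(peptide = "", stop = FALSE))
  orf <- substr(orf, 1L, n)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  stopAt <- regexpr("*", aa, fixed = TRUE)
  if (stopAt > 0)
    list(peptide = substr(aa, 1L, stopAt - 1L), stop = TRUE)
  else
    list(peptide = aa, stop = FALSE)
}

# canonical protein of a transcript: translation from the annotated start
canonicalProtein <- function(t, genome) {
  translateOrf(splicedSequence(t, genome), cdsStartTranscript(t))
}

#' Map protein coordinates to genomic intervals
#'
#' Converts a 1-based inclusive amino-acid interval of a transcript's
#' protein to the genomic interval(s) of the encoding bases, split
#' across exons where necessary. The returned intervals always cover
#' exactly `3 * (endAa - startAa + 1)` bases.
#'
#' @param t a [TranscriptModel].
#' @param startAa,endAa 1-based inclusive protein coordinates.
#' @return an [IRanges::IRanges] of genomic intervals, sorted by start.
#' @export
proteinToGenomic <- function(t, startAa, endAa) {
  if (startAa < 1 || endAa < startAa)
    stop("proteinToGenomic: invalid amino-acid interval")
  cdsLen <- splicedCdsLength(t)
  ntFrom <- (startAa - 1L) * 3L + 1L
  ntTo <- endAa * 3L
  if (ntTo > cdsLen - 3L)  # exclude the stop codon from protein space
    stop("proteinToGenomic: interval exceeds protein length")
  off <- cdsStartTranscript(t)
  gpos <- vapply(seq(ntFrom, ntTo), function(p)
    transcriptToGenomic(t, off + p - 1L), 1L)
  gpos <- sort(gpos)
  brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
  IRanges(start = gpos[brk[-length(brk)] + 1L], end = gpos[brk[-1L]])
}

#' Read protein-domain annotations
#'
#' Reads a BED-dialect file of protein-domain intervals in which the
#' first column carries the transcript identifier (instead of a
#' chromosome), with BED-style 0-based half-open coordinates on the
#' protein, and the fourth column the domain name.
#'
#' @param path BED file (transcript_id, start, end, name).
#' @return data.frame with `transcriptId`, `startAa`, `endAa` (1-based
#'   inclusive), `name`.
#' @export
readDomains <- function(path) {
  if (!file.exists(path)) stop("readDomains: file not found: ", path)
  if (length(readLines(path, n = 1)) == 0)
    return(data.frame(transcriptId = character(), startAa = integer(),
                      endAa = integer(), name = character()))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("readDomains: expected 4 BED columns")
  out <- data.frame(transcriptId = df[[1]],
                    startAa = as.integer(df[[2]]) + 1L,
                    endAa = as.integer(df[[3]]),
                    name = df[[4]], stringsAsFactors = FALSE)
  if (any(out$startAa < 1 | out$endAa < out$startAa))
    stop("readDomains: invalid domain interval")
  out
}

#' Write protein-domain annotations (BED dialect of [readDomains()])
#' @param domains data.frame as returned by [readDomains()].
#' @param path output file.
#' @export
writeDomains <- function(domains, path) {
  bed <- data.frame(domains$transcriptId, domains$startAa - 1L,
                    domains$endAa, domains$name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
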