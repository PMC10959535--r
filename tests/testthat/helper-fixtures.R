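# Hand-built toy genome and transcripts used across test files.
# Layout of chrT (1-based):
#   exon1 101-139 (39 nt: 9 nt 5'UTR + 30 nt CDS)
#   intron1 140-199
#   exon2 200-298 (99 nt CDS)
#   intron2 299-358
#   exon3 359-418 (60 nt CDS)
#   intron3 419-478
#   exon4 479-556 (45 nt CDS + TAA + 30 nt 3'UTR)
# CDS: 110..529 (234 coding nt = 78 aa, then TAA at 527-529).
NONSTOP <- setdiff(as.vector(outer(outer(c("A","C","G","T"),
                                         c("A","C","G","T"), paste0),
                                   c("A","C","G","T"), paste0)),
                   c("TAA", "TAG", "TGA"))

randCodonSeq <- function(n) paste(sample(NONSTOP, n, TRUE), collapse = "")
randDnaSeq <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                collapse = "")

makeToyLocus <- function(seed = 42, intron2 = NULL) {
  withr::with_seed(seed, {
    cds <- paste0(randCodonSeq(78), "TAA")
    e1 <- paste0(randDnaSeq(9), substr(cds, 1, 30))
    e2 <- substr(cds, 31, 129)
    e3 <- substr(cds, 130, 189)
    e4 <- paste0(substr(cds, 190, 237), randDnaSeq(30))
    i1 <- randDnaSeq(60)
    i2 <- if (is.null(intron2)) randCodonSeq(20) else intron2
    i3 <- randDnaSeq(60)
    pre <- paste0(e1, i1, e2, i2, e3, i3, e4)
    chr <- paste0(randDnaSeq(100), pre, randDnaSeq(50))
    genome <- Biostrings::DNAStringSet(chr)
    names(genome) <- "chrT"
    i2len <- nchar(i2)
    exStarts <- c(101, 200, 299 + i2len, 419 + i2len)
    exEnds <- exStarts + c(39, 99, 60, 78) - 1
    t <- TranscriptModel("txT", "geneT", "chrT", "+",
                         IRanges::IRanges(exStarts, exEnds),
                         cdsStart = 110L,
                         cdsEnd = as.integer(exStarts[4] + 47))
    list(genome = genome, t = t,
         exons = IRanges::IRanges(exStarts, exEnds), i2len = i2len)
  })
}

# independent codon-table translation oracle (no Biostrings)
CODON_TABLE <- local({
  bases <- c(T = "T", C = "C", A = "A", G = "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  # codons vary third base fastest in the standard table ordering
  codons <- c(sapply(c("T","C","A","G"), function(b1)
    sapply(c("T","C","A","G"), function(b2)
      paste0(b1, b2, c("T","C","A","G")))))
  stats::setNames(aa, codons)
})

oracleTranslate <- function(dna, from = 1) {
  s <- substr(dna, from, nchar(dna))
  n <- nchar(s) %/% 3
  pep <- character(0)
  for (i in seq_len(n)) {
    aa <- CODON_TABLE[[substr(s, 3 * i - 2, 3 * i)]]
    if (aa == "*") return(list(peptide = paste(pep, collapse = ""),
                               stop = TRUE))
    pep <- c(pep, aa)
  }
  list(peptide = paste(pep, collapse = ""), stop = FALSE)
}

# naive O(m^2) Benjamini-Hochberg step-up oracle
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, 1)
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# brute-force GSEA running-sum oracle
oracleES <- function(metric, setGenes, weight = 1) {
  hits <- names(metric) %in% setGenes
  N <- length(metric); nS <- sum(hits)
  w <- abs(metric)^weight
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hits[i]) w[i] / sum(w[hits]) else -1 / (N - nS)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

writeTempTsv <- function(df, ...) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir =
                               parent.frame())
  writeTsv(df, f, ...)
  f
}
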