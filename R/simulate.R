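# Synthetic-data generation with known ground truth.
#
# The annotation generator designs, for every gene, a canonical mRNA
# (9 nt 5'UTR, 78 stop-free codons, TAA, 3'UTR) and cuts it into exons
# so that the gene's alternative-splicing event realizes a requested
# protein-consequence category *by construction*: exon boundaries are
# codon-aligned except where a frameshift is intended, inserted intronic
# segments are built from stop-free codons unless a premature stop is
# intended, and protein domains are placed exactly on (or safely away
# from) the codons an event alters. Both strands are exercised: a
# minus-strand gene is written into the genome as the reverse
# complement of its designed pre-mRNA.

STOP_CODONS <- c("TAA", "TAG", "TGA")

allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

randCodons <- function(n) {
  pool <- setdiff(allCodons(), STOP_CODONS)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# construction type pools per consequence category (an SE exclusion of a
# codon-aligned exon cannot create a new stop codon, and an MXE swap
# cannot be confined to the UTR in this template)
typePool <- function(category) {
  switch(category,
    frameshift = c("SE", "RI", "A5SS", "A3SS", "MXE"),
    premature_stop = c("RI", "A5SS", "A3SS", "MXE"),
    domain_loss = c("SE", "RI", "A5SS", "A3SS", "MXE"),
    no_disruption = c("SE", "RI", "A5SS", "A3SS", "MXE"),
    noncoding_region = c("SE", "RI", "A5SS", "A3SS"))
}

# build one gene realizing (type, category); returns local-coordinate
# structures plus the gene's pre-mRNA sequence (transcript orientation)
buildGene <- function(gid, type, category, strand, secondEvent = FALSE) {
  u5 <- 9L; c1 <- 30L
  codingTotal <- 234L  # 78 codons
  c2 <- if (type == "SE" && category == "frameshift") 100L else 99L
  # keep the exon3/exon4 boundary codon-aligned even when exon 2 carries
  # a deliberate frame break, so a secondary intron-3 event stays in frame
  c3 <- if (c2 %% 3L == 0L) 60L else 59L
  c4 <- codingTotal - c1 - c2 - c3
  sixExon <- category == "noncoding_region"

  cdsSeq <- paste0(randCodons(codingTotal / 3L), "TAA")
  utr3 <- if (sixExon) randDna(12L) else randDna(30L)
  # exonic (mature) pieces, in transcript order
  e1 <- paste0(randDna(u5), substr(cdsSeq, 1L, c1))
  e2 <- substr(cdsSeq, c1 + 1L, c1 + c2)
  e3 <- substr(cdsSeq, c1 + c2 + 1L, c1 + c2 + c3)
  e4 <- paste0(substr(cdsSeq, c1 + c2 + c3 + 1L, codingTotal + 3L), utr3)
  exSeqs <- list(e1, e2, e3, e4)
  if (sixExon) exSeqs <- c(exSeqs, list(randDna(36L), randDna(30L)))

  # intron contents; i2 and i5 carry the designed alternative segments
  i2ext <- NULL  # local offset + length of the alt segment inside i2
  mkExt <- function(side) {
    k <- if (category == "frameshift") 7L else 9L
    ext <- if (category == "premature_stop") paste0("TAA", randCodons(2L))
           else if (k == 9L) randCodons(3L) else randDna(7L)
    filler <- randDna(51L)
    if (side == "left") list(seq = paste0(ext, filler), off = 1L, len = k)
    else list(seq = paste0(filler, ext), off = 51L + 1L, len = k)
  }
  i2 <- switch(type,
    SE = list(seq = randDna(60L), off = NA, len = NA),
    RI = {
      s <- if (category == "frameshift") randDna(61L)
           else if (category == "premature_stop")
             paste0("TAA", randCodons(19L))
           else randCodons(20L)
      list(seq = s, off = 1L, len = nchar(s))
    },
    A5SS = mkExt("left"),
    A3SS = mkExt("right"),
    MXE = {
      lenB <- if (category == "frameshift") 98L else 99L
      bSeq <- if (category == "premature_stop")
        paste0("TAA", randCodons((lenB - 3L) / 3L))
      else if (lenB %% 3L == 0L) randCodons(lenB / 3L) else randDna(lenB)
      list(seq = paste0(randDna(20L), bSeq, randDna(20L)),
           off = 21L, len = lenB)
    })
  # intron 3 always ends with three stop-free in-frame codons so a
  # secondary A3SS extension of exon 4 is no_disruption by construction
  introns <- list(randDna(60L), i2$seq, paste0(randDna(51L), randCodons(3L)))
  if (sixExon) introns <- c(introns, list(randDna(60L), randDna(60L)))

  # local (pre-mRNA) layout
  exLen <- vapply(exSeqs, nchar, 1L)
  inLen <- vapply(introns, nchar, 1L)
  pieces <- character(0); types <- character(0)
  for (i in seq_along(exSeqs)) {
    pieces <- c(pieces, exSeqs[[i]])
    types <- c(types, "exon")
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[[i]])
      types <- c(types, "intron")
    }
  }
  lens <- vapply(pieces, nchar, 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  exIdx <- which(types == "exon")
  inIdx <- which(types == "intron")
  exLocal <- IRanges(starts[exIdx], ends[exIdx])
  inLocal <- IRanges(starts[inIdx], ends[inIdx])
  cdsLocal <- c(u5 + 1L, u5 + codingTotal + 3L)  # within exonic space
  # map exonic (mature) CDS coordinates to local pre-mRNA coordinates
  matureToLocal <- function(mpos) {
    cw <- cumsum(exLen)
    i <- which(mpos <= cw)[1]
    off <- mpos - (if (i > 1) cw[i - 1] else 0L)
    start(exLocal)[i] + off - 1L
  }
  cdsLocalStart <- matureToLocal(cdsLocal[1])
  cdsLocalEnd <- matureToLocal(cdsLocal[2])

  # alternative segment in local coordinates
  altLocal <- switch(type,
    SE = if (sixExon) exLocal[5] else exLocal[2],
    RI = if (sixExon) inLocal[5] else inLocal[2],
    A5SS = , A3SS = {
      base <- if (sixExon) inLocal[5] else inLocal[2]
      o <- if (sixExon) { # UTR variant: plain 9 nt extension
        if (type == "A5SS") IRanges(start(base), start(base) + 8L)
        else IRanges(end(base) - 8L, end(base))
      } else IRanges(start(base) + i2$off - 1L,
                     start(base) + i2$off + i2$len - 2L)
      o
    },
    MXE = {
      base <- inLocal[2]
      c(exLocal[2],
        IRanges(start(base) + i2$off - 1L,
                start(base) + i2$off + i2$len - 2L))
    })

  # domain placement (protein coordinates); the event's affected codons
  # are aa 11-43 for SE/MXE removals and aa 43-44 for insertions
  aaJunction <- (c1 + c2) %/% 3L  # 43 for codon-aligned templates
  domain <- switch(category,
    domain_loss = if (type %in% c("SE", "MXE")) c(12L, 20L)
                  else c(aaJunction, aaJunction + 1L),
    c(47L, 52L))

  list(gid = gid, type = type, category = category, strand = strand,
       preMrna = paste(pieces, collapse = ""), exLocal = exLocal,
       cdsLocalStart = cdsLocalStart, cdsLocalEnd = cdsLocalEnd,
       altLocal = altLocal, domain = domain, secondEvent = secondEvent,
       inLocal = inLocal)
}

# map a local interval to genomic coordinates for a gene chunk placed at
# `offset` with total length G (minus strand mirrors the interval)
localToGenomic <- function(r, offset, G, strand) {
  if (strand == "+") IRanges(offset + start(r) - 1L, offset + end(r) - 1L)
  else IRanges(offset + G - end(r), offset + G - start(r))
}

#' Simulate a toy genome with designed splicing events
#'
#' Generates a single-chromosome genome, multi-exon transcripts on both
#' strands, protein-domain annotations, and one alternative-splicing
#' event per gene whose protein-consequence category is realized by
#' construction (see the package vignette for the construction rules).
#' Event types cycle over SE, RI, A5SS, A3SS and MXE within each
#' category's compatible pool.
#'
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param nGenes number of genes (one primary event each).
#' @param categoryMix named proportions over the five consequence
#'   categories; realized as exact counts (largest-remainder rounding).
#'   The default places 30% of events in damaging categories.
#' @param eventsPerGene 1, or 2 to add a secondary in-frame A3SS
#'   `no_disruption` event on intron 3 of every gene.
#' @return list with `genome` (`DNAStringSet`), `transcripts` (named
#'   list of [TranscriptModel]), `events` (list of [SpliceEvent]),
#'   `domains` (data.frame), `truth` (data.frame with the designed
#'   category per event).
#' @export
simulateGenomeAnnotation <- function(seed = 1, nGenes = 20,
    categoryMix = c(frameshift = 0.10, premature_stop = 0.10,
                    domain_loss = 0.10, no_disruption = 0.55,
                    noncoding_region = 0.15),
    eventsPerGene = 1) {
  stopifnot(nGenes >= 1, eventsPerGene %in% c(1, 2))
  cats <- c("frameshift", "premature_stop", "domain_loss",
            "no_disruption", "noncoding_region")
  if (!all(names(categoryMix) %in% cats) ||
      abs(sum(categoryMix) - 1) > 1e-8)
    stop("simulateGenomeAnnotation: categoryMix must be proportions ",
         "over the five categories summing to 1")
  mix <- setNames(rep(0, length(cats)), cats)
  mix[names(categoryMix)] <- categoryMix
  # exact counts by largest remainder
  raw <- mix * nGenes
  cnt <- floor(raw)
  left <- nGenes - sum(cnt)
  if (left > 0) {
    o <- order(-(raw - cnt))
    cnt[o[seq_len(left)]] <- cnt[o[seq_len(left)]] + 1
  }
  withSeed(seed, {
    assign <- sample(rep(cats, cnt))
    genes <- vector("list", nGenes)
    for (g in seq_len(nGenes)) {
      category <- assign[g]
      pool <- typePool(category)
      type <- pool[((g - 1L) %% length(pool)) + 1L]
      strand <- sample(c("+", "-"), 1)
      genes[[g]] <- buildGene(sprintf("gene%03d", g), type, category,
                              strand, secondEvent = eventsPerGene == 2)
    }
    # assemble the chromosome
    offset <- 1L
    chunks <- character(0)
    transcripts <- list(); events <- list()
    domains <- list(); truth <- list()
    for (gn in genes) {
      spacer <- randDna(100L)
      chunks <- c(chunks, spacer)
      offset <- offset + 100L
      G <- nchar(gn$preMrna)
      chunk <- if (gn$strand == "+") gn$preMrna else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gn$preMrna)))
      chunks <- c(chunks, chunk)
      exG <- sort(localToGenomic(gn$exLocal, offset, G, gn$strand))
      cdsG <- range(c(
        start(localToGenomic(IRanges(gn$cdsLocalStart, gn$cdsLocalStart),
                             offset, G, gn$strand)),
        start(localToGenomic(IRanges(gn$cdsLocalEnd, gn$cdsLocalEnd),
                             offset, G, gn$strand))))
      txId <- paste0(gn$gid, ".t1")
      tm <- TranscriptModel(txId, gn$gid, "chr1", gn$strand, exG,
                            cdsG[1], cdsG[2])
      transcripts[[txId]] <- tm
      altG <- sort(localToGenomic(gn$altLocal, offset, G, gn$strand))
      if (gn$type == "MXE" && gn$strand == "-")
        altG <- rev(altG)  # annotated exon first
      if (gn$type == "MXE" && gn$strand == "+") {
        # localToGenomic preserves order on the plus strand, but make
        # the annotated-exon-first convention explicit
        ordBy <- order(match(
          start(altG), start(localToGenomic(gn$altLocal, offset, G,
                                            gn$strand))))
        altG <- altG[ordBy]
      }
      evId <- paste0("ev_", gn$gid)
      lens <- switch(gn$type, SE = c(2, 1), RI = c(2, 1),
                     A5SS = c(1, 1), A3SS = c(1, 1), MXE = c(2, 2))
      events[[length(events) + 1]] <-
        SpliceEvent(evId, gn$type, gn$gid, txId, "chr1", gn$strand,
                    altG, lens[1], lens[2])
      truth[[length(truth) + 1]] <-
        data.frame(event_id = evId, gene_id = gn$gid,
                   transcript_id = txId, type = gn$type,
                   category = gn$category, stringsAsFactors = FALSE)
      if (gn$secondEvent) {
        alt2 <- IRanges(end(gn$inLocal[3]) - 8L, end(gn$inLocal[3]))
        alt2G <- localToGenomic(alt2, offset, G, gn$strand)
        ev2 <- paste0("ev2_", gn$gid)
        events[[length(events) + 1]] <-
          SpliceEvent(ev2, "A3SS", gn$gid, txId, "chr1", gn$strand,
                      alt2G, 1, 1)
        truth[[length(truth) + 1]] <-
          data.frame(event_id = ev2, gene_id = gn$gid,
                     transcript_id = txId, type = "A3SS",
                     category = "no_disruption", stringsAsFactors = FALSE)
      }
      domains[[length(domains) + 1]] <-
        data.frame(transcriptId = txId, startAa = gn$domain[1],
                   endAa = gn$domain[2],
                   name = paste0("DOM_", gn$gid), stringsAsFactors = FALSE)
      offset <- offset + G
    }
    chunks <- c(chunks, randDna(100L))
    genome <- Biostrings::DNAStringSet(paste(chunks, collapse = ""))
    names(genome) <- "chr1"
    list(genome = genome, transcripts = transcripts, events = events,
         domains = do.call(rbind, domains), truth = do.call(rbind, truth))
  })
}

#' Write a simulated annotation to disk
#'
#' Writes `genome.fa`, `annotation.gtf`, `domains.bed`, `events.tsv`
#' and `truth_events.tsv` under `dir`.
#'
#' @param sim output of [simulateGenomeAnnotation()].
#' @param dir output directory (created if needed).
#' @return named vector of the written paths.
#' @export
writeAnnotation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             domains = file.path(dir, "domains.bed"),
             events = file.path(dir, "events.tsv"),
             truth = file.path(dir, "truth_events.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"], width = 70)
  writeTranscriptsGtf(sim$transcripts, paths["gtf"])
  writeDomains(sim$domains, paths["domains"])
  writeEvents(sim$events, paths["events"])
  writeTsv(sim$truth, paths["truth"])
  paths
}

#' Simulate junction counts around group-specific true Psi
#'
#' Per event and replicate, the inclusion count is drawn as
#' `I ~ Binomial(depth, p*)` with
#' `p* = psi * lenI / (psi * lenI + (1 - psi) * lenS)` (the read-level
#' inclusion probability implied by the length-normalized Psi), and
#' `S = depth - I`. The treated group uses `psi + delta`, clipped to
#' \[0, 1\].
#'
#' @param events list of [SpliceEvent].
#' @param psiControl true control Psi per event (recycled).
#' @param delta true Psi difference (treated - control) per event.
#' @param nReps replicates per group.
#' @param depth junction reads per event and replicate.
#' @param seed integer seed.
#' @return list with `counts` (long data.frame in the [psiMatrix()]
#'   layout), `groups` (named group factor per sample) and `truth`
#'   (data.frame with `event_id`, `psi_control`, `psi_treated`,
#'   `delta`).
#' @export
simulateSplicingCounts <- function(events, psiControl, delta = 0,
                                   nReps = 4, depth = 200, seed = 1) {
  nEv <- length(events)
  psiControl <- rep_len(psiControl, nEv)
  delta <- rep_len(delta, nEv)
  psiTreated <- pmin(pmax(psiControl + delta, 0), 1)
  if (any(psiControl < 0 | psiControl > 1))
    stop("simulateSplicingCounts: psi must lie in [0, 1]")
  samples <- c(paste0("ctrl_", seq_len(nReps)),
               paste0("trt_", seq_len(nReps)))
  groups <- setNames(factor(rep(c("control", "treated"), each = nReps),
                            levels = c("control", "treated")), samples)
  withSeed(seed, {
    rows <- lapply(seq_len(nEv), function(i) {
      e <- events[[i]]
      p <- ifelse(groups == "treated", psiTreated[i], psiControl[i])
      pStar <- p * e@lenInclusion /
        (p * e@lenInclusion + (1 - p) * e@lenSkipping)
      pStar[p == 0] <- 0; pStar[p == 1] <- 1
      I <- rbinom(length(samples), depth, pStar)
      data.frame(event_id = e@eventId, type = e@type, sample = samples,
                 inclusion_count = I, skipping_count = depth - I,
                 len_inclusion = e@lenInclusion,
                 len_skipping = e@lenSkipping, stringsAsFactors = FALSE)
    })
    list(counts = do.call(rbind, rows), groups = groups,
         truth = data.frame(
           event_id = vapply(events, function(e) e@eventId, ""),
           psi_control = psiControl, psi_treated = psiTreated,
           delta = psiTreated - psiControl, stringsAsFactors = FALSE))
  })
}

#' Simulate a negative-binomial count matrix with group effects
#'
#' Gene baselines are log-normal; designated DE genes are shifted by
#' `lfcMagnitude` (random sign) in the treated group; per-sample
#' library-size factors are drawn uniformly and recorded in the truth.
#'
#' @param nGenes number of genes.
#' @param nPerGroup samples per group (control / treated).
#' @param fracDe fraction of genes with a true effect.
#' @param lfcMagnitude absolute log2 fold change of true DE genes.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param libFactorRange range of true library-size factors.
#' @param seed integer seed.
#' @param trueLfc optional fixed per-gene true log2 fold changes
#'   (length `nGenes`), e.g. to simulate a replicate experiment of the
#'   same underlying effects; overrides `fracDe`/`lfcMagnitude`.
#' @return list with `counts` (matrix), `groups` (factor), `truth`
#'   (data.frame: `gene`, `is_de`, `lfc`) and `libFactors`.
#' @export
simulateExpression <- function(nGenes = 500, nPerGroup = 4,
                               fracDe = 0.1, lfcMagnitude = 2,
                               dispersion = 0.1,
                               libFactorRange = c(0.7, 1.4), seed = 1,
                               trueLfc = NULL) {
  withSeed(seed, {
    samples <- c(paste0("ctrl_", seq_len(nPerGroup)),
                 paste0("trt_", seq_len(nPerGroup)))
    groups <- factor(rep(c("control", "treated"), each = nPerGroup),
                     levels = c("control", "treated"))
    baseMu <- exp(rnorm(nGenes, log(100), 1))
    if (is.null(trueLfc)) {
      isDe <- seq_len(nGenes) <= round(fracDe * nGenes)
      lfc <- ifelse(isDe, sample(c(-1, 1), nGenes, replace = TRUE) *
                      lfcMagnitude, 0)
    } else {
      if (length(trueLfc) != nGenes)
        stop("simulateExpression: trueLfc must have length nGenes")
      lfc <- trueLfc
      isDe <- lfc != 0
    }
    libF <- runif(length(samples), libFactorRange[1], libFactorRange[2])
    mu <- outer(baseMu, libF)
    mu[, groups == "treated"] <- mu[, groups == "treated"] *
      2^lfc[row(mu[, groups == "treated", drop = FALSE])]
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nGenes, length(samples))
    dimnames(counts) <- list(sprintf("g%04d", seq_len(nGenes)), samples)
    list(counts = counts, groups = setNames(groups, samples),
         truth = data.frame(gene = rownames(counts), is_de = isDe,
                            lfc = lfc, stringsAsFactors = FALSE),
         libFactors = setNames(libF, samples))
  })
}

#' Simulate beta-value methylation data with state-structured DMPs
#'
#' Probes are assigned to chromatin states; per-probe baseline
#' M-values sit around state-specific levels and samples vary around
#' them with Gaussian noise on the M scale (a logistic-normal model,
#' so beta values always lie in (0, 1)). True DMPs are shifted by
#' `deltaM` in the treated group — hypomethylated by default — and are
#' preferentially placed in `targetState`.
#'
#' @param nProbes number of probes.
#' @param states chromatin-state names.
#' @param fracDmp fraction of probes with a true shift.
#' @param deltaM absolute M-value shift of true DMPs.
#' @param nPerGroup samples per group.
#' @param targetState state receiving `targetFraction` of the DMPs.
#' @param targetFraction fraction of DMPs placed in `targetState`.
#' @param direction `"hypo"` (shift = -deltaM) or `"hyper"`.
#' @param noiseSd per-sample Gaussian noise on the M scale.
#' @param seed integer seed.
#' @return list with `beta` (matrix), `detection` (matrix of detection
#'   p-values), `groups`, `stateMap` (data.frame `probe`, `state`) and
#'   `truth` (data.frame `probe`, `is_dmp`, `delta_m`, `state`).
#' @export
simulateMethylation <- function(nProbes = 1000,
    states = c("promoter", "enhancer", "transcription", "quiescent",
               "heterochromatin"),
    fracDmp = 0.05, deltaM = 2, nPerGroup = 5,
    targetState = "enhancer", targetFraction = 0.8,
    direction = c("hypo", "hyper"), noiseSd = 0.3, seed = 1) {
  direction <- match.arg(direction)
  if (fracDmp < 0 || fracDmp > 1)
    stop("simulateMethylation: fracDmp must lie in [0, 1]")
  withSeed(seed, {
    samples <- c(paste0("ctrl_", seq_len(nPerGroup)),
                 paste0("trt_", seq_len(nPerGroup)))
    groups <- factor(rep(c("control", "treated"), each = nPerGroup),
                     levels = c("control", "treated"))
    baseBeta <- seq(0.15, 0.85, length.out = length(states))
    probeState <- sample(states, nProbes, replace = TRUE)
    nDmp <- round(fracDmp * nProbes)
    inTarget <- which(probeState == targetState)
    nTar <- min(length(inTarget), round(targetFraction * nDmp))
    dmpIdx <- c(sample(inTarget, nTar),
                sample(setdiff(seq_len(nProbes), inTarget),
                       nDmp - nTar))
    isDmp <- seq_len(nProbes) %in% dmpIdx
    shift <- ifelse(isDmp, if (direction == "hypo") -deltaM else deltaM, 0)
    baseM <- betaToM(baseBeta[match(probeState, states)]) +
      rnorm(nProbes, 0, 0.5)
    M <- matrix(baseM, nProbes, length(samples)) +
      matrix(rnorm(nProbes * length(samples), 0, noiseSd),
             nProbes, length(samples))
    M[, groups == "treated"] <- M[, groups == "treated"] + shift
    beta <- mToBeta(M)
    dimnames(beta) <- list(sprintf("cg%05d", seq_len(nProbes)), samples)
    detection <- matrix(runif(length(beta), 0, 0.005), nProbes,
                        length(samples), dimnames = dimnames(beta))
    list(beta = beta, detection = detection,
         groups = setNames(groups, samples),
         stateMap = data.frame(probe = rownames(beta),
                               state = probeState,
                               stringsAsFactors = FALSE),
         truth = data.frame(probe = rownames(beta), is_dmp = isDmp,
                            delta_m = shift, state = probeState,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic linear transcriptomic clock
#'
#' Positive weights summing to about one, training statistics on the
#' log2 expression scale, and imputation values equal to the training
#' means (so a fully imputed sample predicts the intercept).
#'
#' @param nGenes number of clock genes.
#' @param intercept age-units intercept.
#' @param seed integer seed.
#' @return a [ClockModel].
#' @export
syntheticClock <- function(nGenes = 50, intercept = 12, seed = 1) {
  withSeed(seed, {
    # training means are kept high enough on the log2 scale that
    # standardized excursions over a realistic age range (a few units
    # per unit weight sum) never drive expression negative
    tm <- runif(nGenes, 15, 17)
    ClockModel(intercept, data.frame(
      gene = sprintf("clk%03d", seq_len(nGenes)),
      weight = runif(nGenes, 0.5, 1.5) / nGenes,
      training_mean = tm,
      training_sd = runif(nGenes, 0.5, 1.0),
      imputation_value = tm, stringsAsFactors = FALSE))
  })
}

#' Simulate expression from a known clock
#'
#' Constructs clock-gene expression so that [applyClock()] on noiseless
#' data returns the true ages exactly (all standardized clock genes of
#' a sample share one value solving the linear model), then adds
#' Gaussian noise on the log2 scale. An optional rejuvenation `shift`
#' is subtracted from the true age of designated samples before
#' expression is generated.
#'
#' @param clock a [ClockModel].
#' @param trueAges named numeric vector of true ages (names = samples).
#' @param noiseSd Gaussian noise sd on the log2 expression scale.
#' @param shift per-sample rejuvenation shift (recycled; age units).
#' @param seed integer seed.
#' @return list with `expr` (clock-gene-by-sample matrix of normalized
#'   counts) and `truth` (data.frame `sample`, `true_age`, `shift`,
#'   `target_age`).
#' @export
simulateClockStudy <- function(clock, trueAges, noiseSd = 0.5,
                               shift = 0, seed = 1) {
  g <- clock@genes
  shift <- rep_len(shift, length(trueAges))
  target <- trueAges - shift
  withSeed(seed, {
    cS <- (target - clock@intercept) / sum(g$weight)
    x <- outer(g$training_sd, cS) + g$training_mean
    x <- x + matrix(rnorm(length(x), 0, noiseSd), nrow(x), ncol(x))
    expr <- pmax(2^x - 1, 0)
    dimnames(expr) <- list(g$gene,
                           names(trueAges) %||%
                             paste0("s", seq_along(trueAges)))
    list(expr = expr,
         truth = data.frame(sample = colnames(expr),
                            true_age = trueAges, shift = shift,
                            target_age = target,
                            stringsAsFactors = FALSE))
  })
}
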