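# Protein-consequence prediction for alternative-splicing events.
#
# Each event is applied to its host transcript to obtain the altered
# mRNA, which is re-translated from the unchanged start codon. Events
# are classified into exactly one of five categories with precedence
#   noncoding_region > frameshift > premature_stop > domain_loss
#   > no_disruption
# (frameshift before premature stop because a shifted frame subsumes
# most downstream stops; precedence makes the categories mutually
# exclusive and deterministic).

DAMAGING_CATEGORIES <- c("frameshift", "premature_stop", "domain_loss")

# splice an arbitrary exon set into a 5'->3' sequence
spliceExonSet <- function(genome, chrom, strand, exonRanges) {
  cs <- chromSeq(genome, chrom)
  if (any(end(exonRanges) > length(cs)) || any(start(exonRanges) < 1))
    stop("spliceExonSet: exon out of chromosome bounds")
  s <- unlist(Biostrings::extractAt(cs, sort(exonRanges)))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# transcript coordinate of a genomic position within an arbitrary exon set
exonSetCoord <- function(exonRanges, strand, gpos) {
  ex <- sort(exonRanges)
  hit <- which(gpos >= start(ex) & gpos <= end(ex))
  if (length(hit) != 1) return(NA_integer_)
  upstream <- if (hit > 1) sum(width(ex)[seq_len(hit - 1)]) else 0L
  plusCoord <- upstream + (gpos - start(ex)[hit]) + 1L
  if (strand == "+") plusCoord else sum(width(ex)) - plusCoord + 1L
}

#' Apply a splicing event to a transcript
#'
#' Produces the exon structure and mature mRNA of the requested isoform
#' of an event. `"inclusion"` retains the alternative segment (for SE
#' and MXE this is the annotated transcript; for RI the
#' intron-retaining form; for A5SS/A3SS the extended-exon form);
#' `"exclusion"` removes it. The CDS start position is re-derived from
#' the annotated start codon, whose genomic position must survive the
#' alteration.
#'
#' @param t host [TranscriptModel].
#' @param e [SpliceEvent]; its `altRegion` must be structurally
#'   consistent with `t` (see Details).
#' @param form `"inclusion"` or `"exclusion"`.
#' @param genome `DNAStringSet`.
#' @return list with `exons` (altered [IRanges::IRanges]), `mrna`
#'   (`DNAString`), `cdsStartTx` (1-based transcript coordinate of the
#'   start codon) and `utrOnly` (does the alteration avoid the coding
#'   span entirely?).
#' @details SE: `altRegion` must equal an internal exon. RI: `altRegion`
#'   must be exactly the intron between two consecutive exons. A5SS /
#'   A3SS: `altRegion` must be intronic and adjacent to one exon
#'   boundary (the annotated transcript carries the short form). MXE:
#'   `altRegion[1]` must equal an internal exon and `altRegion[2]` must
#'   be intronic; exclusion swaps the first for the second.
#' @export
applyEvent <- function(t, e, form = c("inclusion", "exclusion"),
                       genome) {
  form <- match.arg(form)
  ex <- t@exons
  rg <- e@altRegion
  matchExon <- function(r) {
    hit <- which(start(ex) == start(r) & end(ex) == end(r))
    if (length(hit) != 1)
      stop("applyEvent: alt region does not match an exon of ",
           t@transcriptId)
    if (hit == 1 || hit == length(ex))
      stop("applyEvent: alternative exon must be internal")
    hit
  }
  newEx <- switch(e@type,
    SE = {
      hit <- matchExon(rg[1])
      if (form == "inclusion") ex else ex[-hit]
    },
    RI = {
      gapOk <- which(end(ex)[-length(ex)] + 1L == start(rg[1]) &
                       start(ex)[-1] - 1L == end(rg[1]))
      if (length(gapOk) != 1)
        stop("applyEvent: RI region is not an intron between ",
             "consecutive exons of ", t@transcriptId)
      if (form == "exclusion") ex
      else {  # merge flanking exons across the retained intron
        merged <- IRanges(start(ex)[gapOk], end(ex)[gapOk + 1L])
        sort(c(ex[-c(gapOk, gapOk + 1L)], merged))
      }
    },
    A5SS = , A3SS = {
      r <- rg[1]
      if (length(findOverlaps(r, ex)) > 0)
        stop("applyEvent: A5SS/A3SS extension overlaps an exon")
      down <- which(end(ex) + 1L == start(r))
      up <- which(start(ex) - 1L == end(r))
      if (length(down) + length(up) != 1)
        stop("applyEvent: extension not adjacent to exactly one ",
             "exon boundary of ", t@transcriptId)
      if (form == "exclusion") ex
      else {
        if (length(down) == 1) {
          ex2 <- ex; end(ex2)[down] <- end(r); ex2
        } else {
          ex2 <- ex; start(ex2)[up] <- start(r); ex2
        }
      }
    },
    MXE = {
      hit <- matchExon(rg[1])
      other <- rg[2]
      if (length(findOverlaps(other, ex)) > 0)
        stop("applyEvent: MXE partner exon overlaps annotated exons")
      if (form == "inclusion") ex
      else sort(c(ex[-hit], other))
    })
  anchor <- if (t@strand == "+") t@cdsStart else t@cdsEnd
  cdsStartTx <- exonSetCoord(newEx, t@strand, anchor)
  if (is.na(cdsStartTx))
    stop("applyEvent: alteration removes the annotated start codon")
  coding <- IRanges(t@cdsStart, t@cdsEnd)
  touched <- sum(width(IRanges::intersect(rg, coding)))
  list(exons = sort(newEx),
       mrna = spliceExonSet(genome, t@chrom, t@strand, newEx),
       cdsStartTx = cdsStartTx,
       utrOnly = touched == 0)
}

#' Classify the protein consequence of a splicing event
#'
#' Determines the protein-level effect of the isoform that deviates from
#' the annotated transcript ([altForm()]): `noncoding_region` when the
#' alteration lies entirely outside the coding span; `frameshift` when
#' the net altered coding length is not a multiple of 3;
#' `premature_stop` when re-translation from the unchanged start codon
#' terminates earlier than the in-frame expectation; `domain_loss` when
#' the in-frame removed (or insertion-junction) peptide interval
#' overlaps an annotated protein domain; otherwise `no_disruption`.
#'
#' @param t host [TranscriptModel] (must have a valid ORF).
#' @param e [SpliceEvent].
#' @param genome `DNAStringSet`.
#' @param domains data.frame from [readDomains()] (may be empty).
#' @return one-row data.frame: `event_id`, `transcript_id`, `alt_form`,
#'   `category`, `altered_aa_start`, `altered_aa_end`, `new_stop_aa`.
#' @export
classifyConsequence <- function(t, e, genome, domains = NULL) {
  can <- canonicalProtein(t, genome)
  if (!can$stop)
    stop("classifyConsequence: transcript ", t@transcriptId,
         " has no in-frame stop codon")
  form <- altForm(e)
  coding <- IRanges(t@cdsStart, t@cdsEnd)
  removed <- switch(e@type, SE = e@altRegion[1], MXE = e@altRegion[1],
                    NULL)
  added <- switch(e@type, RI = e@altRegion[1], A5SS = e@altRegion[1],
                  A3SS = e@altRegion[1], MXE = e@altRegion[2], NULL)
  remW <- if (is.null(removed)) 0L else
    sum(width(IRanges::intersect(removed, coding)))
  addW <- if (is.null(added)) 0L else
    sum(width(IRanges::intersect(added, coding)))
  mkRow <- function(category, aaStart = NA, aaEnd = NA, newStop = NA) {
    data.frame(event_id = e@eventId, transcript_id = t@transcriptId,
               alt_form = form, category = category,
               altered_aa_start = aaStart, altered_aa_end = aaEnd,
               new_stop_aa = newStop, stringsAsFactors = FALSE)
  }
  if (remW + addW == 0L) return(mkRow("noncoding_region"))
  codingDelta <- addW - remW
  if (codingDelta %% 3L != 0L) return(mkRow("frameshift"))

  alt <- applyEvent(t, e, form, genome)
  pep <- translateOrf(alt$mrna, alt$cdsStartTx)
  expectedLen <- nchar(can$peptide) + codingDelta / 3L
  if (pep$stop && nchar(pep$peptide) < expectedLen)
    return(mkRow("premature_stop", newStop = nchar(pep$peptide) + 1L))

  aa <- affectedAaInterval(t, e, coding, removed, added, remW)
  if (!is.null(domains) && nrow(domains) > 0 && !any(is.na(aa))) {
    dom <- domains[domains$transcriptId == t@transcriptId, , drop = FALSE]
    if (nrow(dom) > 0 &&
        any(dom$startAa <= aa[2] & dom$endAa >= aa[1]))
      return(mkRow("domain_loss", aaStart = aa[1], aaEnd = aa[2]))
  }
  mkRow("no_disruption", aaStart = aa[1], aaEnd = aa[2])
}

# canonical-protein amino-acid interval touched by the alteration:
# the removed codons for deletions, the junction codon(s) for insertions
affectedAaInterval <- function(t, e, coding, removed, added, remW) {
  cdsOff <- cdsStartTranscript(t)
  toCds <- function(gpos) genomicToTranscript(t, gpos) - cdsOff + 1L
  if (remW > 0) {
    seg <- IRanges::intersect(removed, coding)
    p <- sort(c(toCds(start(seg)[1]), toCds(end(seg)[length(seg)])))
  } else {
    flanks <- c(start(added)[1] - 1L, end(added)[1] + 1L)
    p <- sort(vapply(flanks, function(g) {
      tp <- tryCatch(toCds(g), error = function(e) NA_integer_)
      tp
    }, 1L))
    p <- p[!is.na(p)]
    if (length(p) == 0) return(c(NA_integer_, NA_integer_))
  }
  p <- p[p >= 1]
  if (length(p) == 0) return(c(NA_integer_, NA_integer_))
  c((min(p) - 1L) %/% 3L + 1L, (max(p) - 1L) %/% 3L + 1L)
}

#' Classify many events
#'
#' @param transcripts named list of [TranscriptModel] (by transcript id).
#' @param events list of [SpliceEvent].
#' @param genome `DNAStringSet`.
#' @param domains data.frame from [readDomains()].
#' @return data.frame, one row per event (see [classifyConsequence()]),
#'   plus a logical `damaging` column.
#' @export
classifyConsequences <- function(transcripts, events, genome,
                                 domains = NULL) {
  rows <- lapply(events, function(e) {
    t <- transcripts[[e@transcriptId]]
    if (is.null(t))
      stop("classifyConsequences: unknown transcript ", e@transcriptId)
    classifyConsequence(t, e, genome, domains)
  })
  out <- do.call(rbind, rows)
  out$damaging <- out$category %in% DAMAGING_CATEGORIES
  rownames(out) <- NULL
  out
}

#' Splicing-damage proportion
#'
#' The proportion of alternative-splicing events predicted to disrupt
#' protein function (frameshift, premature stop, or domain loss).
#'
#' In `"differential"` mode the denominator is the set of selected
#' differentially spliced events from [differentialSplicing()]. In
#' `"standing"` mode the proportion is computed per sample over events
#' with defined Psi: an event counts as damaging in a sample when its
#' damaging isoform (the [altForm()] isoform) is present at
#' `psi >= presenceThreshold`.
#'
#' @param calls data.frame from [classifyConsequences()].
#' @param records [differentialSplicing()] output (differential mode).
#' @param psi `SummarizedExperiment` from [psiMatrix()] (standing mode).
#' @param mode `"differential"` or `"standing"`.
#' @param presenceThreshold minimum damaging-isoform Psi (standing mode).
#' @return differential mode: one-row data.frame with `n_events`,
#'   `n_damaging`, `proportion`; standing mode: one row per sample.
#' @export
splicingDamage <- function(calls, records = NULL, psi = NULL,
                           mode = c("differential", "standing"),
                           presenceThreshold = 0.1) {
  mode <- match.arg(mode)
  if (mode == "differential") {
    if (is.null(records)) stop("splicingDamage: records required")
    sel <- records$event_id[records$selected]
    if (length(sel) == 0)
      stop("splicingDamage: no selected events; proportion undefined")
    dmg <- calls$damaging[match(sel, calls$event_id)]
    if (any(is.na(dmg)))
      stop("splicingDamage: consequence call missing for selected event")
    data.frame(n_events = length(sel), n_damaging = sum(dmg),
               proportion = mean(dmg))
  } else {
    if (is.null(psi)) stop("splicingDamage: psi matrix required")
    m <- SummarizedExperiment::assay(psi, "psi")
    af <- calls$alt_form[match(rownames(m), calls$event_id)]
    dmg <- calls$damaging[match(rownames(m), calls$event_id)]
    if (any(is.na(af)))
      stop("splicingDamage: consequence call missing for some events")
    damPsi <- m
    flip <- af != "inclusion"
    damPsi[flip, ] <- 1 - m[flip, , drop = FALSE]
    out <- do.call(rbind, lapply(colnames(m), function(s) {
      v <- damPsi[, s]
      ok <- !is.na(v)
      if (!any(ok))
        stop("splicingDamage: no events with coverage in sample ", s)
      present <- ok & v >= presenceThreshold
      data.frame(sample = s, n_events = sum(ok),
                 n_damaging = sum(present & dmg),
                 proportion = sum(present & dmg) / sum(ok))
    }))
    rownames(out) <- NULL
    out
  }
}
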