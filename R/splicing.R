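#' SpliceEvent: one alternative-splicing event
#'
#' Describes an alternative-splicing event anchored on a host transcript.
#' `altRegion` holds the genomic interval of the alternative segment
#' (two intervals for MXE: the annotated exon first, its mutually
#' exclusive partner second). Effective lengths weight the inclusion and
#' skipping junction counts when Psi is computed.
#'
#' The "inclusion" form always contains the alternative segment:
#' for SE and MXE that is the annotated transcript, for RI it is the
#' intron-retaining form, and for A5SS/A3SS the long (extended-exon)
#' form; the annotated transcript carries the short form. The form that
#' deviates from the annotated transcript (the one whose protein
#' consequence is assessed) is returned by [altForm()].
#'
#' @slot eventId,geneId,transcriptId character identifiers.
#' @slot type one of SE, RI, A5SS, A3SS, MXE.
#' @slot chrom,strand location of the host transcript.
#' @slot altRegion [IRanges::IRanges] (length 1, or 2 for MXE).
#' @slot lenInclusion,lenSkipping positive effective lengths.
#' @export
setClass("SpliceEvent",
  representation(eventId = "character", type = "character",
                 geneId = "character", transcriptId = "character",
                 chrom = "character", strand = "character",
                 altRegion = "IRanges", lenInclusion = "numeric",
                 lenSkipping = "numeric"))

setValidity("SpliceEvent", function(object) {
  if (!object@type %in% c("SE", "RI", "A5SS", "A3SS", "MXE"))
    return("type must be one of SE, RI, A5SS, A3SS, MXE")
  need <- if (object@type == "MXE") 2L else 1L
  if (length(object@altRegion) != need)
    return(sprintf("%s event needs %d alt region(s)", object@type, need))
  if (object@lenInclusion <= 0 || object@lenSkipping <= 0)
    return("effective lengths must be positive")
  TRUE
})

#' @describeIn SpliceEvent constructor.
#' @param eventId,type,geneId,transcriptId,chrom,strand,altRegion,lenInclusion,lenSkipping see slots.
#' @export
SpliceEvent <- function(eventId, type, geneId, transcriptId, chrom, strand,
                        altRegion, lenInclusion, lenSkipping) {
  new("SpliceEvent", eventId = eventId, type = type, geneId = geneId,
      transcriptId = transcriptId, chrom = chrom, strand = strand,
      altRegion = altRegion, lenInclusion = as.numeric(lenInclusion),
      lenSkipping = as.numeric(lenSkipping))
}

setMethod("show", "SpliceEvent", function(object) {
  cat(sprintf("SpliceEvent %s [%s] on %s (%s:%s)\n", object@eventId,
              object@type, object@transcriptId, object@chrom,
              paste(sprintf("%d-%d", start(object@altRegion),
                            end(object@altRegion)), collapse = ",")))
})

#' @describeIn SpliceEvent which form (inclusion/exclusion) deviates from
#'   the annotated transcript.
#' @param e a SpliceEvent.
#' @export
altForm <- function(e) {
  switch(e@type,
         SE = "exclusion", MXE = "exclusion",
         RI = "inclusion", A5SS = "inclusion", A3SS = "inclusion")
}

#' Percent spliced-in from junction counts
#'
#' Length-normalized inclusion ratio
#' `psi = (I/lenI) / (I/lenI + S/lenS)`. The estimate is reported as
#' missing (`NA`) when total junction coverage `I + S` falls below
#' `minCoverage`, or when both counts are zero. All arguments are
#' vectorized.
#'
#' @param I,S inclusion- and skipping-supporting read counts (>= 0).
#' @param lenInclusion,lenSkipping positive effective lengths.
#' @param minCoverage minimum `I + S` for a defined estimate.
#' @return numeric vector of Psi values in \[0, 1\], NA where missing.
#' @examples
#' computePsi(18, 6, lenInclusion = 2, lenSkipping = 1, minCoverage = 10)
#' @export
computePsi <- function(I, S, lenInclusion, lenSkipping, minCoverage = 10) {
  if (any(I < 0 | S < 0)) stop("computePsi: counts must be non-negative")
  if (any(lenInclusion <= 0 | lenSkipping <= 0))
    stop("computePsi: effective lengths must be positive")
  ni <- I / lenInclusion
  ns <- S / lenSkipping
  psi <- ni / (ni + ns)
  psi[I + S < minCoverage | (I == 0 & S == 0)] <- NA_real_
  psi
}

#' Assemble a Psi matrix from a junction-count table
#'
#' Builds an event-by-sample [SummarizedExperiment::SummarizedExperiment]
#' with assays `psi` and `coverage` from a long-format junction-count
#' table (columns `event_id`, `type`, `sample`, `inclusion_count`,
#' `skipping_count`, `len_inclusion`, `len_skipping`).
#'
#' @param counts data.frame in the junction-count layout above.
#' @param minCoverage minimum coverage passed to [computePsi()].
#' @return a `SummarizedExperiment`; `rowData` carries the event type
#'   and effective lengths.
#' @export
psiMatrix <- function(counts, minCoverage = 10) {
  need <- c("event_id", "type", "sample", "inclusion_count",
            "skipping_count", "len_inclusion", "len_skipping")
  if (!all(need %in% names(counts)))
    stop("psiMatrix: missing columns: ",
         paste(setdiff(need, names(counts)), collapse = ", "))
  evs <- unique(counts$event_id)
  smp <- unique(counts$sample)
  psi <- matrix(NA_real_, length(evs), length(smp),
                dimnames = list(evs, smp))
  cov <- matrix(0, length(evs), length(smp), dimnames = list(evs, smp))
  idx <- cbind(match(counts$event_id, evs), match(counts$sample, smp))
  psi[idx] <- computePsi(counts$inclusion_count, counts$skipping_count,
                         counts$len_inclusion, counts$len_skipping,
                         minCoverage)
  cov[idx] <- counts$inclusion_count + counts$skipping_count
  info <- counts[!duplicated(counts$event_id),
                 c("event_id", "type", "len_inclusion", "len_skipping")]
  info <- info[match(evs, info$event_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(psi = psi, coverage = cov),
    rowData = S4Vectors::DataFrame(type = info$type,
                                   len_inclusion = info$len_inclusion,
                                   len_skipping = info$len_skipping,
                                   row.names = evs))
}

#' Differential splicing between two groups
#'
#' Per-event comparison of replicate-level Psi values by Welch t test,
#' with Benjamini-Hochberg adjustment across all tested events. Events
#' with fewer than two non-missing replicates in either group are
#' reported as untested and excluded from the BH family. An event is
#' `selected` when `|delta_psi| > deltaCutoff` and its adjusted p-value
#' (or, with `selectBy = "pvalue"`, its raw p-value) falls below
#' `sigCutoff`.
#'
#' @param psi a `SummarizedExperiment` from [psiMatrix()], or a plain
#'   event-by-sample Psi matrix.
#' @param groups group label per sample (exactly two levels); the first
#'   level is treated as control, delta_psi = mean(treated) -
#'   mean(control).
#' @param deltaCutoff minimum |delta Psi| (default 0.1).
#' @param sigCutoff significance threshold (default 0.05).
#' @param selectBy `"fdr"` (default) or `"pvalue"`.
#' @return data.frame with one row per event: `event_id`, `type`,
#'   `mean_control`, `mean_treated`, `delta_psi`, `p_value`, `fdr`,
#'   `tested`, `selected`.
#' @export
differentialSplicing <- function(psi, groups, deltaCutoff = 0.1,
                                 sigCutoff = 0.05,
                                 selectBy = c("fdr", "pvalue")) {
  selectBy <- match.arg(selectBy)
  if (methods::is(psi, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(psi, "psi")
    types <- SummarizedExperiment::rowData(psi)$type
  } else {
    m <- as.matrix(psi)
    types <- rep(NA_character_, nrow(m))
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("differentialSplicing: exactly two groups required")
  if (length(groups) != ncol(m))
    stop("differentialSplicing: group labels must match samples")
  ctrl <- levels(groups)[1]; trt <- levels(groups)[2]
  res <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, groups == trt]; y <- m[i, groups == ctrl]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      return(c(mc = if (length(y)) mean(y) else NA_real_,
               mt = if (length(x)) mean(x) else NA_real_,
               d = NA_real_, p = NA_real_, tested = 0))
    w <- welchT(x, y)
    c(mc = mean(y), mt = mean(x), d = mean(x) - mean(y),
      p = w$p.value, tested = 1)
  })
  res <- do.call(rbind, res)
  out <- data.frame(event_id = rownames(m), type = types,
                    mean_control = res[, "mc"], mean_treated = res[, "mt"],
                    delta_psi = res[, "d"], p_value = res[, "p"],
                    tested = res[, "tested"] == 1,
                    stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  out$fdr[out$tested] <- bhAdjust(out$p_value[out$tested])
  sig <- if (selectBy == "fdr") out$fdr else out$p_value
  out$selected <- out$tested & !is.na(sig) & sig < sigCutoff &
    abs(out$delta_psi) > deltaCutoff
  rownames(out) <- NULL
  out
}

#' Direction summary of selected splicing events
#'
#' Counts selected events with positive vs negative delta Psi, per event
#' type — the summary behind "more retained introns are lost than
#' gained" style statements.
#'
#' @param records output of [differentialSplicing()].
#' @return data.frame with `type`, `n_positive`, `n_negative`.
#' @export
directionSummary <- function(records) {
  sel <- records[records$selected & !is.na(records$delta_psi), ]
  types <- sort(unique(records$type[!is.na(records$type)]))
  if (length(types) == 0) types <- character()
  out <- data.frame(type = types,
                    n_positive = vapply(types, function(tp)
                      sum(sel$type == tp & sel$delta_psi > 0), 1L),
                    n_negative = vapply(types, function(tp)
                      sum(sel$type == tp & sel$delta_psi < 0), 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read / write the event-definition table
#'
#' Event definitions are exchanged as a TSV with columns `event_id`,
#' `type`, `gene_id`, `transcript_id`, `chrom`, `strand`, `alt_start`,
#' `alt_end`, `alt_start2`, `alt_end2` (NA unless MXE), `len_inclusion`,
#' `len_skipping`.
#'
#' @param path TSV file.
#' @return list of [SpliceEvent] objects.
#' @export
readEvents <- function(path) {
  df <- readTsv(path)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    rg <- if (!is.na(r$alt_start2))
      IRanges(c(r$alt_start, r$alt_start2), c(r$alt_end, r$alt_end2))
    else IRanges(r$alt_start, r$alt_end)
    SpliceEvent(r$event_id, r$type, r$gene_id, r$transcript_id,
                r$chrom, r$strand, rg, r$len_inclusion, r$len_skipping)
  })
}

#' @rdname readEvents
#' @param events list of [SpliceEvent] objects.
#' @param meta optional named character vector of metadata header lines.
#' @export
writeEvents <- function(events, path, meta = character()) {
  df <- do.call(rbind, lapply(events, function(e) {
    two <- length(e@altRegion) == 2
    data.frame(event_id = e@eventId, type = e@type, gene_id = e@geneId,
               transcript_id = e@transcriptId, chrom = e@chrom,
               strand = e@strand,
               alt_start = start(e@altRegion)[1],
               alt_end = end(e@altRegion)[1],
               alt_start2 = if (two) start(e@altRegion)[2] else NA,
               alt_end2 = if (two) end(e@altRegion)[2] else NA,
               len_inclusion = e@lenInclusion,
               len_skipping = e@lenSkipping)
  }))
  writeTsv(df, path, meta = meta)
}
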