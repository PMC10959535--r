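# Preranked gene set enrichment on the signed -log10(p) metric:
# signature construction from differential-expression tables, a
# weighted running-sum enrichment score with a gene-sampling
# permutation null, signature-association matrices, and pairwise
# signature correlation.

#' Signed ranking metric
#'
#' Per-gene GSEA ranking statistic `-log10(pv) * sgn(lfc)`: magnitude
#' from the evidence against the null, sign from the direction of
#' regulation. P-values are floored at `pvFloor` before the log so that
#' underflowed p-values stay finite; a zero log fold change yields a
#' zero metric regardless of the p-value.
#'
#' @param pv p-values in (0, 1].
#' @param lfc log fold changes (finite).
#' @param pvFloor lower bound applied to `pv`.
#' @return numeric vector of ranking metrics.
#' @export
rankingMetric <- function(pv, lfc, pvFloor = 1e-300) {
  if (any(pv <= 0 | pv > 1)) stop("rankingMetric: pv must be in (0, 1]")
  if (any(!is.finite(lfc))) stop("rankingMetric: lfc must be finite")
  -log10(pmax(pv, pvFloor)) * sign(lfc)
}

#' Ranked list from a differential-expression table
#'
#' Orders genes by the signed ranking metric, descending, with ties
#' broken by gene identifier for cross-platform determinism.
#'
#' @param de data.frame with `gene`, `lfc`, `pv`.
#' @param pvFloor passed to [rankingMetric()].
#' @return named numeric vector (names = genes), sorted descending.
#' @export
rankedList <- function(de, pvFloor = 1e-300) {
  if (anyDuplicated(de$gene)) stop("rankedList: duplicate genes")
  metric <- rankingMetric(de$pv, de$lfc, pvFloor)
  names(metric) <- de$gene
  metric[order(-metric, names(metric))]
}

#' Build an expression signature from a DE table
#'
#' Among genes significant at `adjCutoff` (BH-adjusted p), takes the
#' `n` with the largest absolute log fold change; fewer if fewer
#' qualify (an empty signature triggers a warning). With
#' `split = TRUE`, also returns the up- and down-regulated halves.
#'
#' @param de data.frame with `gene`, `lfc`, `fdr`.
#' @param n maximum signature size.
#' @param adjCutoff significance cutoff on `fdr`.
#' @param split also return `_up` / `_down` subsets?
#' @param name signature name.
#' @return named list of character vectors (a GMT-ready gene-set list).
#' @export
buildSignature <- function(de, n = 500, adjCutoff = 0.05,
                           split = FALSE, name = "signature") {
  sig <- de[!is.na(de$fdr) & de$fdr < adjCutoff, , drop = FALSE]
  sig <- sig[order(-abs(sig$lfc), sig$gene), , drop = FALSE]
  sig <- head(sig, n)
  if (nrow(sig) == 0)
    warning("buildSignature: no significant genes; empty signature")
  out <- list(sig$gene)
  names(out) <- name
  if (split) {
    out[[paste0(name, "_up")]] <- sig$gene[sig$lfc > 0]
    out[[paste0(name, "_down")]] <- sig$gene[sig$lfc < 0]
  }
  out
}

# weighted running-sum enrichment score over a ranked universe.
# hits step up by |metric|^weight normalized over in-set genes; misses
# step down by 1/(N - |S|); ES is the extremum of the running sum.
enrichmentScore <- function(metric, inSet, weight = 1) {
  N <- length(metric)
  nS <- sum(inSet)
  if (nS == 0 || nS == N) stop("enrichmentScore: degenerate set size")
  w <- abs(metric)^weight
  tot <- sum(w[inSet])
  hitStep <- if (tot > 0) w / tot else
    rep(1 / nS, N)  # all-zero metrics: fall back to equal hit weights
  steps <- ifelse(inSet, hitStep, -1 / (N - nS))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Preranked gene set enrichment analysis
#'
#' Computes, for each gene set, the weighted running-sum enrichment
#' score over the ranked list, a permutation p-value from random
#' same-size gene sets drawn from the universe, and a normalized
#' enrichment score (ES divided by the mean |ES| of same-sign null
#' scores). P-values use the add-one correction; BH adjustment is
#' applied across all scored sets. Null scores are shared between sets
#' of equal size, so results are deterministic for a given seed
#' regardless of the number of sets.
#'
#' @param ranked named metric vector from [rankedList()].
#' @param sets named list of gene sets (e.g. [readGmt()]).
#' @param nPerm number of permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @param weight running-sum weight exponent (1 = weighted, 0 =
#'   Kolmogorov-Smirnov-like).
#' @param minSize minimum set size after intersection with the universe.
#' @param fdrCutoff threshold for the `significant` flag (default 0.1).
#' @return data.frame with `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr`, `significant`, `error` (NA, or why a set was skipped).
#' @export
gseaPreranked <- function(ranked, sets, nPerm = 5000, seed = 1,
                          weight = 1, minSize = 5, fdrCutoff = 0.1) {
  if (anyDuplicated(names(ranked))) stop("gseaPreranked: duplicate genes")
  universe <- names(ranked)
  N <- length(universe)
  memb <- lapply(sets, function(s) intersect(s, universe))
  sizes <- lengths(memb)
  err <- rep(NA_character_, length(sets))
  err[sizes == 0] <- "set disjoint from universe"
  err[sizes > 0 & sizes < minSize] <- "set smaller than minSize"
  err[sizes >= N] <- "set covers the whole universe"
  ok <- is.na(err)

  es <- rep(NA_real_, length(sets))
  for (i in which(ok)) {
    inSet <- universe %in% memb[[i]]
    es[i] <- enrichmentScore(ranked, inSet, weight)
  }

  # one shared null per distinct set size
  uSizes <- sort(unique(sizes[ok]))
  nulls <- withSeed(seed, {
    out <- list()
    for (s in uSizes) {
      nullEs <- numeric(nPerm)
      for (b in seq_len(nPerm)) {
        idx <- sample.int(N, s)
        inSet <- logical(N); inSet[idx] <- TRUE
        nullEs[b] <- enrichmentScore(ranked, inSet, weight)
      }
      out[[as.character(s)]] <- nullEs
    }
    out
  })

  pval <- nes <- rep(NA_real_, length(sets))
  for (i in which(ok)) {
    nullEs <- nulls[[as.character(sizes[i])]]
    same <- nullEs[sign(nullEs) == sign(es[i])]
    if (length(same) == 0) {
      pval[i] <- 1 / (nPerm + 1)
      nes[i] <- sign(es[i]) * abs(es[i])  # no same-sign null mass
    } else {
      pval[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
      nes[i] <- es[i] / mean(abs(same))
    }
  }
  out <- data.frame(set = names(sets) %||% as.character(seq_along(sets)),
                    size = sizes, es = es, nes = nes, p_value = pval,
                    stringsAsFactors = FALSE)
  out$fdr <- NA_real_
  out$fdr[ok] <- bhAdjust(pval[ok])
  out$significant <- !is.na(out$fdr) & out$fdr < fdrCutoff
  out$error <- err
  rownames(out) <- NULL
  out
}

#' Signature-association matrix
#'
#' Runs [gseaPreranked()] for every condition's DE table against a
#' collection of signatures, producing the NES / FDR matrix behind
#' condition-by-signature association heatmaps, with conventional
#' significance stars.
#'
#' @param deTables named list of DE data.frames (`gene`, `lfc`, `pv`).
#' @param signatures named list of gene sets.
#' @param nPerm,seed,minSize,weight passed to [gseaPreranked()].
#' @return data.frame with `condition`, `set`, `nes`, `p_value`, `fdr`,
#'   `stars` ("" / "*" / "**" / "***" at FDR 0.05 / 0.01 / 0.001).
#' @export
signatureAssociation <- function(deTables, signatures, nPerm = 5000,
                                 seed = 1, minSize = 5, weight = 1) {
  rows <- lapply(names(deTables), function(cond) {
    r <- gseaPreranked(rankedList(deTables[[cond]]), signatures,
                       nPerm = nPerm, seed = seed, weight = weight,
                       minSize = minSize)
    data.frame(condition = cond, set = r$set, nes = r$nes,
               p_value = r$p_value, fdr = r$fdr, error = r$error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- ifelse(is.na(out$fdr), "",
                 ifelse(out$fdr < 0.001, "***",
                   ifelse(out$fdr < 0.01, "**",
                     ifelse(out$fdr < 0.05, "*", ""))))
  rownames(out) <- NULL
  out
}

#' Pairwise signature correlation
#'
#' Spearman correlation of log fold changes over the union of the top
#' `n` lowest-p genes of each of two DE tables (genes present in both
#' universes).
#'
#' @param deA,deB data.frames with `gene`, `lfc`, `pv`.
#' @param n number of top genes taken from each table (default 650).
#' @return list with `rho` and `n_union`.
#' @export
signatureCorrelation <- function(deA, deB, n = 650) {
  shared <- intersect(deA$gene, deB$gene)
  a <- deA[deA$gene %in% shared, ]
  b <- deB[deB$gene %in% shared, ]
  topA <- head(a$gene[order(a$pv, a$gene)], n)
  topB <- head(b$gene[order(b$pv, b$gene)], n)
  un <- union(topA, topB)
  if (length(un) < 3)
    stop("signatureCorrelation: union smaller than 3 genes")
  rho <- spearmanRho(a$lfc[match(un, a$gene)], b$lfc[match(un, b$gene)])
  list(rho = rho, n_union = length(un))
}
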