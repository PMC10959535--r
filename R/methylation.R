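# DNA-methylation analysis: probe filtering, beta -> M conversion,
# per-probe differential methylation on M-values, mean-methylation
# summaries, and chromatin-state enrichment of differentially
# methylated probes with signed log10 adjusted p-values.

#' Filter methylation probes
#'
#' A probe is retained only when it has no missing beta value and no
#' detection p-value above `detectionCutoff` in any sample.
#'
#' @param beta probe-by-sample matrix of beta values in \[0, 1\].
#' @param detection optional matrix of detection p-values, same
#'   dimensions and dimnames.
#' @param detectionCutoff maximum tolerated detection p (default 0.01).
#' @return the filtered beta matrix.
#' @export
filterProbes <- function(beta, detection = NULL, detectionCutoff = 0.01) {
  beta <- as.matrix(beta)
  keep <- complete.cases(beta)
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dim(beta), dim(detection)) ||
        !identical(rownames(beta), rownames(detection)))
      stop("filterProbes: beta and detection matrices are misaligned")
    keep <- keep & rowSums(is.na(detection) |
                             detection > detectionCutoff) == 0
  }
  beta[keep, , drop = FALSE]
}

#' Beta to M-value conversion
#'
#' `M = log2(beta / (1 - beta))` after clamping beta to
#' `[eps, 1 - eps]` so boundary values stay finite.
#'
#' @param beta numeric vector or matrix of values in \[0, 1\].
#' @param eps clamping margin (default 1e-6).
#' @return M-values, same shape as the input.
#' @export
betaToM <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("betaToM: beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) {
    out <- matrix(out, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  out
}

#' @rdname betaToM
#' @param M numeric vector or matrix of M-values.
#' @export
mToBeta <- function(M) 2^M / (1 + 2^M)

#' Differential methylation on M-values
#'
#' Per-probe Welch t test of M-values between two groups. `lfcM` is the
#' difference of group-mean M-values (treated - control, control being
#' the first factor level); a probe is `selected` when
#' `|lfcM| > lfcCutoff` and its BH-adjusted p-value is below
#' `fdrCutoff`.
#'
#' @param M probe-by-sample matrix of M-values.
#' @param groups group label per sample (two levels, >= 2 samples each).
#' @param lfcCutoff minimum |lfcM| (default 1).
#' @param fdrCutoff significance threshold (default 0.05).
#' @return data.frame with `probe`, `lfcM`, `pv`, `fdr`, `direction`
#'   ("hyper"/"hypo"), `selected`.
#' @export
differentialMethylation <- function(M, groups, lfcCutoff = 1,
                                    fdrCutoff = 0.05) {
  M <- as.matrix(M)
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("differentialMethylation: exactly two groups required")
  if (any(table(groups) < 2))
    stop("differentialMethylation: each group needs >= 2 samples")
  ctrl <- groups == levels(groups)[1]
  res <- t(apply(M, 1, function(v) {
    w <- welchT(v[!ctrl], v[ctrl])
    c(lfcM = w$estimate, pv = w$p.value)
  }))
  out <- data.frame(probe = rownames(M), lfcM = res[, "lfcM"],
                    pv = res[, "pv"], stringsAsFactors = FALSE)
  out$fdr <- bhAdjust(out$pv)
  out$direction <- ifelse(out$lfcM >= 0, "hyper", "hypo")
  out$selected <- abs(out$lfcM) > lfcCutoff & out$fdr < fdrCutoff
  rownames(out) <- NULL
  out
}

#' Mean methylation per sample
#'
#' @param beta probe-by-sample beta matrix.
#' @return named numeric vector of per-sample mean beta.
#' @export
meanMethylation <- function(beta) {
  beta <- as.matrix(beta)
  if (nrow(beta) == 0) stop("meanMethylation: empty matrix")
  colMeans(beta, na.rm = TRUE)
}

#' Chromatin-state enrichment of differentially methylated probes
#'
#' For each chromatin state and each DMP direction (hyper / hypo),
#' forms the 2x2 table (in-state vs not) x (DMP vs not) over the probe
#' universe, computes the odds ratio (Haldane +0.5 correction when any
#' cell is zero), and tests enrichment with the upper hypergeometric
#' tail when OR > 1 or depletion with the lower tail otherwise. All
#' state-direction p-values enter a single BH family and are reported
#' as signed log10 adjusted p-values: `-log10(adj p)` with sign +1 for
#' enrichment (OR > 1) and -1 for depletion.
#'
#' @param dmps data.frame from [differentialMethylation()] (only
#'   `selected` probes are used).
#' @param universe character vector of all analyzed probes.
#' @param stateMap data.frame with columns `probe`, `state` (at most
#'   one state per probe; duplicated probes keep the first-listed state
#'   with a warning).
#' @return data.frame with `state`, `direction`, `n_state`, `n_dmp`,
#'   `overlap`, `odds_ratio`, `p_value`, `adj_p`,
#'   `signed_log10_adj_p`.
#' @export
chromatinStateEnrichment <- function(dmps, universe, stateMap) {
  if (anyDuplicated(stateMap$probe)) {
    warning("chromatinStateEnrichment: probes mapped to several states; ",
            "keeping the first-listed state")
    stateMap <- stateMap[!duplicated(stateMap$probe), ]
  }
  sel <- dmps[dmps$selected, , drop = FALSE]
  if (!all(sel$probe %in% universe))
    stop("chromatinStateEnrichment: DMP outside the probe universe")
  states <- sort(unique(stateMap$state))
  N <- length(universe)
  probeState <- stateMap$state[match(universe, stateMap$probe)]
  rows <- list()
  for (dir in c("hyper", "hypo")) {
    dmpSet <- universe %in% sel$probe[sel$direction == dir]
    n <- sum(dmpSet)
    for (st in states) {
      inState <- !is.na(probeState) & probeState == st
      K <- sum(inState)
      k <- sum(inState & dmpSet)
      a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
      if (min(a, b, cc, d) == 0) {
        orv <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else {
        orv <- (a * d) / (b * cc)
      }
      p <- if (orv > 1) hypergeomTail(k, K, n, N)
           else phyper(k, K, N - K, n)
      rows[[length(rows) + 1]] <-
        data.frame(state = st, direction = dir, n_state = K, n_dmp = n,
                   overlap = k, odds_ratio = orv, p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bhAdjust(out$p_value)
  out$signed_log10_adj_p <-
    ifelse(out$odds_ratio > 1, 1, -1) * (-log10(pmax(out$adj_p, 1e-300)))
  rownames(out) <- NULL
  out
}

#' Read a probe-to-chromatin-state map
#'
#' Accepts either a two-column TSV (`probe`, `state`) or a BED-style
#' file whose fourth column is the state and first column the probe.
#'
#' @param path file path.
#' @return data.frame with `probe` and `state`.
#' @export
readStateMap <- function(path) {
  df <- readTsv(path)
  if (all(c("probe", "state") %in% names(df)))
    return(df[, c("probe", "state")])
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) >= 4)
    return(data.frame(probe = df[[1]], state = df[[4]],
                      stringsAsFactors = FALSE))
  stop("readStateMap: unrecognized state-map layout")
}
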