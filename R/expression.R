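# Gene-level RNA-seq count processing: low-count filtering, relative
# log expression (median-of-ratios) normalization, and a simple
# replicate-level differential-expression test feeding the ranking
# metric, signatures, and clocks.

#' Filter low-count genes
#'
#' Retains a gene when at least a fraction `minFraction` of samples show
#' at least `minReads` reads (boundary inclusive: with 10 samples and
#' the defaults, 2 qualifying samples retain the gene).
#'
#' @param counts gene-by-sample matrix of non-negative counts.
#' @param minReads minimum read count per qualifying sample.
#' @param minFraction minimum fraction of qualifying samples.
#' @return the filtered count matrix.
#' @export
filterGenes <- function(counts, minReads = 5, minFraction = 0.2) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop("filterGenes: empty count matrix")
  if (any(counts < 0)) stop("filterGenes: negative counts")
  keep <- rowMeans(counts >= minReads) >= minFraction
  counts[keep, , drop = FALSE]
}

#' Relative log expression (median-of-ratios) normalization
#'
#' Per-sample size factor = median, over reference genes, of the ratio
#' of the sample's count to the gene's geometric mean across samples;
#' reference genes are those with strictly positive counts in every
#' sample. Normalized counts are counts divided by the size factor.
#'
#' @param counts gene-by-sample count matrix.
#' @return list with `normalized` (matrix) and `sizeFactors` (named
#'   numeric vector).
#' @export
rleNormalize <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts <= 0) == 0
  if (!any(ref))
    stop("rleNormalize: no gene with positive counts in all samples")
  logGeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - logGeo)))
  list(normalized = sweep(counts, 2, sf, "/"), sizeFactors = sf)
}

#' Differential expression between two groups
#'
#' Per-gene Welch t test on `log2(normalized + 1)` values; the log2
#' fold change is the difference of group means on that scale
#' (treated - control, where control is the first factor level);
#' p-values are BH-adjusted across all tested genes.
#'
#' @param normalized gene-by-sample matrix of normalized counts.
#' @param groups group label per sample (two levels, >= 2 samples each).
#' @return data.frame with `gene`, `lfc`, `pv`, `fdr`.
#' @export
differentialExpression <- function(normalized, groups) {
  m <- as.matrix(normalized)
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("differentialExpression: exactly two groups required")
  if (any(table(groups) < 2))
    stop("differentialExpression: each group needs >= 2 samples")
  if (length(groups) != ncol(m))
    stop("differentialExpression: groups must match samples")
  lm2 <- log2(m + 1)
  ctrl <- groups == levels(groups)[1]
  res <- t(apply(lm2, 1, function(v) {
    w <- welchT(v[!ctrl], v[ctrl])
    c(lfc = w$estimate, pv = w$p.value)
  }))
  out <- data.frame(gene = rownames(m), lfc = res[, "lfc"],
                    pv = res[, "pv"], stringsAsFactors = FALSE)
  out$fdr <- bhAdjust(out$pv)
  rownames(out) <- NULL
  out
}
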