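#' Welch two-sample t test
#'
#' Two-sided Welch t test with Satterthwaite degrees of freedom, as used
#' for replicate-level comparisons throughout the package (differential
#' splicing on Psi values, transcriptomic-age contrasts, per-probe
#' methylation tests). Zero-variance input is handled explicitly so that
#' degenerate synthetic cases do not abort a pipeline: when both groups
#' are constant and equal the result is t = 0, p = 1; when both are
#' constant but different the result is p = 0 with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a list with elements `statistic`, `df`, `p.value`,
#'   `estimate` (mean(x) - mean(y)) and `degenerate`.
#' @examples
#' welchT(c(0.2, 0.3, 0.4), c(0.6, 0.7, 0.8))
#' @export
welchT <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("welchT: each group needs at least 2 non-missing values")
  vx <- var(x); vy <- var(y)
  est <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (est == 0)
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p.value = 1, estimate = 0, degenerate = FALSE))
    warning("welchT: zero variance in both groups with differing means")
    return(list(statistic = sign(est) * Inf,
                df = length(x) + length(y) - 2,
                p.value = 0, estimate = est, degenerate = TRUE))
  }
  se2 <- vx / length(x) + vy / length(y)
  stat <- est / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  list(statistic = stat, df = df,
       p.value = 2 * pt(-abs(stat), df),
       estimate = est, degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA F test, used for multi-group
#' comparisons of splicing-damage proportions and for the generic
#' feature screen.
#'
#' @param groups a list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return a list with `statistic` (F), `df` (numerator, denominator)
#'   and `p.value`.
#' @export
anovaOneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("anovaOneway: need a list of at least 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(vapply(groups, length, 1L) < 2))
    stop("anovaOneway: every group needs at least 2 values")
  y <- unlist(groups)
  f <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); n <- length(y)
  ssb <- sum(tapply(y, f, length) * (tapply(y, f, mean) - mean(y))^2)
  ssw <- sum(tapply(y, f, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    if (ssb == 0)
      return(list(statistic = 0, df = c(k - 1, n - k), p.value = 1))
    return(list(statistic = Inf, df = c(k - 1, n - k), p.value = 0))
  }
  stat <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = stat, df = c(k - 1, n - k),
       p.value = pf(stat, k - 1, n - k, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; thin validated wrapper around
#' [stats::p.adjust()] so that every module shares one multiple-testing
#' code path. NA entries are preserved and excluded from the family.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order as the input.
#' @export
bhAdjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("bhAdjust: p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, used for pairwise signature
#' correlations.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient rho.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("spearmanRho: length mismatch")
  if (length(x) < 3) stop("spearmanRho: need at least 3 pairs")
  cor(x, y, method = "spearman")
}

#' Upper-tail hypergeometric probability
#'
#' Exact P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' observing at least `k` annotated items in a draw of `n` from a
#' universe of `N` containing `K` annotated items. This is the
#' enrichment test behind the chromatin-state analysis (the depletion
#' test uses the complementary lower tail).
#'
#' @param k observed overlap count.
#' @param K number of annotated items in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return the one-sided upper-tail probability.
#' @examples
#' hypergeomTail(4, 5, 4, 10)   # 5/210
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("hypergeomTail: inconsistent margins")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pairwise group comparisons with BH correction
#'
#' Post-hoc pairwise contrasts after a multi-group comparison,
#' implemented as Welch t tests across all group pairs with
#' Benjamini-Hochberg adjustment of the pairwise p-values.
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group labels, same length.
#' @return data.frame with columns `group1`, `group2`, `effect`
#'   (mean1 - mean2), `p.value`, `fdr`.
#' @export
pairwiseWelch <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2) stop("pairwiseWelch: need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    w <- welchT(values[groups == pr[1]], values[groups == pr[2]])
    c(effect = w$estimate, p.value = w$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    effect = res["effect", ], p.value = res["p.value", ],
                    stringsAsFactors = FALSE)
  out$fdr <- bhAdjust(out$p.value)
  rownames(out) <- NULL
  out
}

#' Generic feature screen
#'
#' Per-feature one-way ANOVA over sample groups with BH correction —
#' the screen used, e.g., for protein-normalized metabolite abundance
#' matrices (optionally log-transformed before testing).
#'
#' @param mat feature-by-sample numeric matrix.
#' @param groups group label per column.
#' @param transform `"log"` (natural log; all values must be positive)
#'   or `"none"`.
#' @param fdrCutoff significance threshold on the adjusted p-value.
#' @return data.frame with `feature`, `statistic`, `p.value`, `fdr`,
#'   `significant`.
#' @export
featureScreen <- function(mat, groups, transform = c("log", "none"),
                          fdrCutoff = 0.05) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  groups <- factor(groups)
  if (ncol(mat) != length(groups))
    stop("featureScreen: groups must match matrix columns")
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("featureScreen: need >= 2 groups with >= 2 samples each")
  if (transform == "log") {
    if (any(mat <= 0)) stop("featureScreen: log transform needs positive values")
    mat <- log(mat)
  }
  res <- t(apply(mat, 1, function(v) {
    a <- anovaOneway(split(v, groups))
    c(a$statistic, a$p.value)
  }))
  out <- data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                    statistic = res[, 1], p.value = res[, 2],
                    stringsAsFactors = FALSE)
  out$fdr <- bhAdjust(out$p.value)
  out$significant <- out$fdr < fdrCutoff
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
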