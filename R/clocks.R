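#' ClockModel: a linear transcriptomic age predictor
#'
#' A linear clock predicts age as
#' `tAge = intercept + sum_g weight_g * z_g`, where `z_g` is the
#' sample's `log2(expr_g + 1)` expression of clock gene `g`,
#' standardized against the clock's training mean and standard
#' deviation. Clock genes missing from the data are imputed with the
#' model's precalculated average value on the log scale before
#' standardization.
#'
#' @slot intercept numeric, in age units.
#' @slot genes data.frame with columns `gene`, `weight`,
#'   `training_mean`, `training_sd`, `imputation_value` (log2 scale).
#' @export
setClass("ClockModel",
  representation(intercept = "numeric", genes = "data.frame"))

setValidity("ClockModel", function(object) {
  g <- object@genes
  need <- c("gene", "weight", "training_mean", "training_sd",
            "imputation_value")
  if (!all(need %in% names(g)))
    return(paste("clock gene table needs columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene)) return("duplicate clock genes")
  if (any(g$training_sd <= 0)) return("training_sd must be positive")
  TRUE
})

#' @describeIn ClockModel constructor.
#' @param intercept,genes see slots.
#' @export
ClockModel <- function(intercept, genes) {
  new("ClockModel", intercept = as.numeric(intercept),
      genes = as.data.frame(genes))
}

setMethod("show", "ClockModel", function(object) {
  cat(sprintf("ClockModel: %d genes, intercept %.3f\n",
              nrow(object@genes), object@intercept))
})

#' @describeIn ClockModel number of clock genes.
#' @param x a ClockModel.
#' @export
clockSize <- function(x) nrow(x@genes)

#' Read / write a clock model as TSV
#'
#' The clock file is a TSV (`gene`, `weight`, `training_mean`,
#' `training_sd`, `imputation_value`) whose metadata header carries the
#' intercept as `# intercept=<value>`.
#'
#' @param path TSV file.
#' @return a [ClockModel].
#' @export
readClockModel <- function(path) {
  meta <- tsvMeta(path)
  if (!"intercept" %in% names(meta))
    stop("readClockModel: missing '# intercept=' header")
  ClockModel(as.numeric(meta[["intercept"]]), readTsv(path))
}

#' @rdname readClockModel
#' @param clock a [ClockModel].
#' @export
writeClockModel <- function(clock, path) {
  writeTsv(clock@genes, path,
           meta = c(intercept = format(clock@intercept, digits = 17)))
}

#' Apply a transcriptomic clock
#'
#' Predicts per-sample transcriptomic age from normalized counts:
#' expression of each clock gene is log2(x + 1)-transformed, missing
#' clock genes are imputed with the model's precalculated average on
#' that scale, values are standardized against the clock's training
#' statistics, and the weighted sum plus intercept gives tAge.
#'
#' @param expr gene-by-sample matrix of normalized (non-negative)
#'   counts.
#' @param clock a [ClockModel].
#' @return data.frame with `sample`, `tAge`, `n_imputed`,
#'   `fully_imputed`.
#' @export
applyClock <- function(expr, clock) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("applyClock: expression must be non-negative")
  g <- clock@genes
  present <- g$gene %in% rownames(expr)
  if (!any(present))
    warning("applyClock: no clock gene detected; prediction fully imputed")
  x <- matrix(rep(g$imputation_value, ncol(expr)), nrow(g), ncol(expr))
  x[present, ] <- log2(expr[g$gene[present], , drop = FALSE] + 1)
  z <- (x - g$training_mean) / g$training_sd
  tAge <- clock@intercept + as.numeric(crossprod(z, g$weight))
  data.frame(sample = colnames(expr) %||% as.character(seq_len(ncol(expr))),
             tAge = tAge, n_imputed = sum(!present),
             fully_imputed = !any(present), stringsAsFactors = FALSE)
}

#' Compare predicted ages between treatments
#'
#' Welch t tests of mean tAge, treatment vs control, within each
#' stratum (e.g. donor age group).
#'
#' @param preds data.frame from [applyClock()].
#' @param groups treatment label per sample.
#' @param strata optional stratum label per sample (one test per
#'   stratum and treatment level).
#' @param control the reference treatment level.
#' @return data.frame with `stratum`, `treatment`, `effect`
#'   (mean treated - mean control, age units), `p_value`.
#' @export
compareTAges <- function(preds, groups, strata = NULL,
                         control = NULL) {
  groups <- factor(groups)
  if (is.null(control)) control <- levels(groups)[1]
  if (!control %in% levels(groups))
    stop("compareTAges: unknown control level")
  if (is.null(strata)) strata <- rep("all", nrow(preds))
  strata <- factor(strata)
  rows <- list()
  for (st in levels(strata)) {
    inSt <- strata == st
    for (tr in setdiff(levels(groups), control)) {
      x <- preds$tAge[inSt & groups == tr]
      y <- preds$tAge[inSt & groups == control]
      if (length(x) < 2 || length(y) < 2)
        stop("compareTAges: need >= 2 samples per group in stratum ", st)
      w <- welchT(x, y)
      rows[[length(rows) + 1]] <-
        data.frame(stratum = st, treatment = tr, effect = w$estimate,
                   p_value = w$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
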