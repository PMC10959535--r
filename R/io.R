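# Shared TSV I/O: every table the pipeline writes starts with '#'-prefixed
# metadata lines (tool version, config hash, run parameters), then a header
# row. readTsv() skips the metadata; tsvMeta() recovers it.

#' Write a table as annotated TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named character vector written as `# key=value` lines;
#'   the tool version is always included.
#' @export
writeTsv <- function(df, path, meta = character()) {
  meta <- c(tool = sprintf("rejuvomics %s",
                           as.character(packageVersion("rejuvomics"))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated TSV written by [writeTsv()]
#' @param path TSV file.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("readTsv: file not found: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname readTsv
#' @return `tsvMeta`: named character vector of the `# key=value` header.
#' @export
tsvMeta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[grepl("^# .*=", lines)]
  kv <- sub("^# ", "", lines)
  keys <- sub("=.*$", "", kv)
  setNames(sub("^[^=]*=", "", kv), keys)
}

#' Read and write numeric matrices as TSV
#'
#' Feature-by-sample matrices (counts, beta values, expression) are
#' exchanged as TSV with the feature identifier in the first column and
#' sample identifiers in the header.
#'
#' @param path TSV file.
#' @return `readMatrixTsv`: numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readMatrixTsv
#' @param m numeric matrix.
#' @param idColumn name for the feature-identifier column.
#' @param meta metadata passed to [writeTsv()].
#' @export
writeMatrixTsv <- function(m, path, idColumn = "feature",
                           meta = character()) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  writeTsv(df, path, meta = meta)
}

#' Read gene sets in GMT format
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated
#' `name description member1 member2 ...`.
#'
#' @param path GMT file.
#' @return named list of character vectors of member genes.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("readGmt: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("readGmt: line ", bad[1], " has fewer than 3 fields")
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[`, "", 1)
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (recycled).
#' @export
writeGmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}
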