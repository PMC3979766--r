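#' @include core.R
NULL

#' Read an expression matrix from TSV/CSV
#'
#' Expects a rectangular numeric table whose first column holds unique row
#' identifiers. Ragged rows, non-numeric cells, non-finite values and
#' duplicate identifiers are rejected with the offending coordinates in the
#' message.
#'
#' @param path file path.
#' @param delimiter `"tab"` or `"comma"`.
#' @param header whether the first line is a header (default `TRUE`).
#' @return numeric matrix with row names.
#' @export
readExpressionMatrix <- function(path, delimiter = c("tab", "comma"),
                                 header = TRUE) {
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "tab") "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("ragged table: rows have ", paste(unique(nf), collapse = "/"),
         " fields in ", path)
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row identifier(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  x <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow(body), ncol(body)))
  bad <- which(is.na(x) | is.infinite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop("non-numeric or non-finite value at row '", ids[b[1L]],
         "', data column ", b[2L])
  }
  rownames(x) <- ids
  colnames(x) <- colnames(body)
  x
}

#' Write a matrix in the package's TSV/CSV dialect
#'
#' First column `id`, then one column per feature; round-trips with
#' [readExpressionMatrix()].
#'
#' @param x numeric matrix with row names.
#' @param path file path.
#' @param delimiter `"tab"` or `"comma"`.
#' @export
writeExpressionMatrix <- function(x, path, delimiter = c("tab", "comma")) {
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "tab") "\t" else ","
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster labels as two-column TSV
#'
#' @param path file path.
#' @param ids object identifiers.
#' @param labels integer cluster labels (same length as `ids`).
#' @export
writeClusterLabels <- function(path, ids, labels) {
  if (length(ids) != length(labels))
    stop("ids and labels must have equal length")
  utils::write.table(data.frame(id = ids, cluster = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels written by [writeClusterLabels()]
#'
#' @param path file path.
#' @return data.frame with `id` and `cluster`.
#' @export
readClusterLabels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  names(df) <- c("id", "cluster")
  df
}

#' Write a plain-text run manifest
#'
#' A key=value block (method, seed, configuration, input digest, selected
#' number of clusters) followed by a TSV table of the recorded candidates —
#' enough to replay the run exactly under the same seed and input.
#'
#' @param path file path.
#' @param result a [SmartResult-class].
#' @param inputDigest optional digest string identifying the input matrix.
#' @export
writeRunManifest <- function(path, result, inputDigest = NA_character_) {
  cfg <- result@config
  con <- file(path, "w")
  on.exit(close(con))
  kv <- c(
    method = result@method,
    seed = if (is.null(cfg$seed)) "NA" else as.character(cfg$seed),
    eps = cfg$eps, gamma = cfg$gamma, mMax = cfg$mMax,
    covStructure = if (is.null(cfg$covStructure)) "auto" else cfg$covStructure,
    tol = cfg$tol, maxSweeps = cfg$maxSweeps, maxEpochs = cfg$maxEpochs,
    inputDigest = inputDigest,
    selectedK = max(result@labels),
    messageLength = format(result@messageLength, digits = 15)
  )
  writeLines(paste0(names(kv), "=", unlist(kv)), con)
  writeLines("", con)
  writeLines("candidate\tk\tmessageLength", con)
  for (i in seq_along(result@candidates)) {
    cc <- result@candidates[[i]]
    writeLines(sprintf("%d\t%d\t%s", i, cc$knz,
                       format(cc$messageLength, digits = 15)), con)
  }
  invisible(path)
}
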