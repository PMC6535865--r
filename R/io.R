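#' Read a samples-by-features matrix from delimited text
#'
#' Reads a TSV (or CSV) file whose first row holds feature names and whose
#' first column holds sample identifiers, and validates it as an expression
#' or clinical matrix.
#'
#' @param path Path to a delimited text file.
#' @param kind `"expression"` (entries must be nonnegative) or `"clinical"`
#'   (entries must lie in `[0, 1]` after normalization; raw values are only
#'   checked for being numeric and non-missing).
#' @param sep Field separator; `"\t"` by default, `","` accepted.
#' @return A numeric matrix with `rownames` = sample IDs and `colnames` =
#'   feature names.
#' @export
read_matrix <- function(path, kind = c("expression", "clinical"), sep = "\t") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE,
                   fill = FALSE, quote = "")
  if (ncol(df) < 2L) stop("matrix file needs a sample-ID column plus >=1 feature column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated sample ID(s): ", paste(dup, collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric cell(s) in column(s): ",
         paste(names(vals)[!num], collapse = ", "))
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  if (anyNA(M)) stop("missing values are not allowed in ", kind, " matrix: ", path)
  if (kind == "expression" && any(M < 0)) {
    stop("expression matrix must be nonnegative; found minimum ", min(M))
  }
  if (anyDuplicated(colnames(M))) stop("duplicated feature name(s) in ", path)
  M
}

#' Write a matrix as delimited text
#'
#' Inverse of [read_matrix()]: first column `sample_id`, header row of feature
#' names. Round-tripping is the identity up to float formatting.
#'
#' @param M Numeric matrix with rownames (sample IDs) and colnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path, sep = "\t") {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  df <- data.frame(sample_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read survival labels (and optional survival times)
#'
#' Expects columns `sample_id`, `label` and optionally `time` (years).
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator.
#' @return A list with `labels` (named 0/1 integer vector), `times` (named
#'   numeric vector or `NULL`) and `sample_ids`.
#' @export
read_labels <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("labels file must have columns sample_id and label: ", path)
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicated sample ID(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lab <- df$label
  if (anyNA(lab) || !all(lab %in% c(0, 1))) stop("labels must be 0/1 with no missing values")
  labels <- as.integer(lab)
  names(labels) <- ids
  times <- NULL
  if ("time" %in% names(df)) {
    times <- as.numeric(df$time)
    if (anyNA(times) || any(times < 0)) stop("survival times must be nonnegative and non-missing")
    names(times) <- ids
  }
  list(labels = labels, times = times, sample_ids = ids)
}

#' Write survival labels
#'
#' @param labels Named 0/1 vector (names = sample IDs).
#' @param path Output path.
#' @param times Optional named numeric vector of survival times (years).
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, times = NULL, sep = "\t") {
  stopifnot(!is.null(names(labels)))
  df <- data.frame(sample_id = names(labels), label = as.integer(labels))
  if (!is.null(times)) df$time <- as.numeric(times[names(labels)])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
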