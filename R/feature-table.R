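#' Ordinal TiME feature table
#'
#' Holds per-lesion TiME features graded on the ordinal 0-3 scale used in
#' manual RCM evaluation, plus an optional binary treatment-response label.
#'
#' @param grades integer matrix (samples x features) with values in 0:3.
#' @param feature_names unique feature names, one per column.
#' @param sample_ids one id per row; defaults to `sample_1 ...`.
#' @param response optional 0/1 vector, one per sample.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(grades, feature_names = colnames(grades),
                          sample_ids = NULL, response = NULL) {
  grades <- as.matrix(grades)
  if (is.null(feature_names)) stop("feature names are required")
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (length(feature_names) != ncol(grades))
    stop("one feature name per column is required")
  if (anyNA(grades)) stop("grades must not contain missing values")
  if (!all(grades %in% 0:3)) stop("grades must be integers in {0, 1, 2, 3}")
  storage.mode(grades) <- "integer"
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(nrow(grades)))
  if (length(sample_ids) != nrow(grades)) stop("one sample id per row is required")
  if (!is.null(response)) {
    if (length(response) != nrow(grades)) stop("one response label per row is required")
    if (!all(response %in% 0:1)) stop("response labels must be 0 or 1")
    response <- as.integer(response)
  }
  dimnames(grades) <- list(sample_ids, feature_names)
  structure(list(grades = grades, sample_ids = as.character(sample_ids),
                 feature_names = as.character(feature_names),
                 response = response),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features%s\n",
              nrow(x$grades), ncol(x$grades),
              if (is.null(x$response)) "" else " (+ response labels)"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$grades)

#' Read a feature table from CSV
#'
#' Expects a header of feature names, a first column of sample ids, and an
#' optional `response` column in \{0, 1\}.
#'
#' @param path CSV file path.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  response <- NULL
  if ("response" %in% names(df)) {
    response <- df[["response"]]
    df <- df[, setdiff(names(df), "response"), drop = FALSE]
  }
  feature_table(as.matrix(df), feature_names = names(df),
                sample_ids = ids, response = response)
}

#' Write a feature table to CSV
#'
#' @param table a [feature_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, table$grades,
                   check.names = FALSE, row.names = NULL)
  if (!is.null(table$response)) df$response <- table$response
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
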