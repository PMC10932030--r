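#' Read a sample-by-feature matrix from delimited text
#'
#' Expects tab-separated UTF-8 text with '.' decimal: first column
#' `sample_id`, remaining columns one per feature. Empty cells and "NA"
#' are read as missing (only the clinical layer tolerates missing values
#' downstream).
#'
#' @param path file path.
#' @param omics_code one of [OMICS_CODES].
#' @param sep field separator, default tab.
#' @return an [omics_matrix()].
#' @export
read_feature_matrix <- function(path, omics_code, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("read_feature_matrix: no feature columns in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("read_feature_matrix: duplicate sample IDs in ", path,
         "; merge duplicates first (merge_duplicate_samples)")
  }
  feat <- df[, -1, drop = FALSE]
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf(
          "read_feature_matrix: non-numeric value '%s' at row %d, column '%s'",
          col[bad[1]], bad[1], names(feat)[j]))
      }
      feat[[j]] <- num
    }
  }
  m <- as.matrix(feat)
  rownames(m) <- ids
  omics_matrix(m, omics_code)
}

#' Write a matrix as delimited text readable by read_feature_matrix
#'
#' Row and column order are preserved; the first column is `sample_id`.
#'
#' @param matrix an [omics_matrix()] or any numeric matrix with row names
#'   (e.g. an embedding matrix).
#' @param path output file path.
#' @param sep field separator, default tab.
#' @export
write_matrix <- function(matrix, path, sep = "\t") {
  if (length(matrix) == 0) stop("write_matrix: empty matrix")
  m <- unclass(matrix)
  if (is.null(rownames(m))) stop("write_matrix: matrix needs sample ID rownames")
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_matrix: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read subtype labels from a two-column TSV (sample_id, subtype)
#' @param path file path.
#' @return a [label_vector()].
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  label_vector(df[[2]], df[[1]])
}

#' Write subtype labels as TSV (sample_id, subtype)
#' @param labels a [label_vector()].
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), subtype = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV (sample_id, time, event)
#' @param path file path.
#' @return a [survival_table()].
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  survival_table(df$time, df$event, df$sample_id)
}

#' Write a survival table as TSV
#' @param survival a [survival_table()].
#' @param path output path.
#' @export
write_survival <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stage-tagged log line to stderr
#' @param stage short stage tag, e.g. "graph".
#' @param ... message parts passed to [message()].
#' @keywords internal
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}
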