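#' Omics codes recognised by the package
#'
#' Canonical (alphabetical) order of the eight supported omics layers:
#' clinical covariates (CLI), copy number alteration (CNA), co-expression
#' module eigengenes (COE), mRNA expression (EXP), lncRNA expression (LNC),
#' DNA methylation (MET), miRNA expression (MIR) and binary somatic
#' mutation (MUT). This order fixes block order in fused embeddings.
#'
#' @export
OMICS_CODES <- c("CLI", "CNA", "COE", "EXP", "LNC", "MET", "MIR", "MUT")

#' Omics codes holding continuous measurements that are z-score normalised
#' @keywords internal
CONTINUOUS_CODES <- c("CNA", "EXP", "LNC", "MET", "MIR")

#' Construct an omics matrix
#'
#' A sample-by-feature numeric matrix for one omics layer, with unique
#' sample IDs as row names, feature IDs as column names, and a declared
#' omics code. Mutation (MUT) matrices must be binary 0/1.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param omics_code one of [OMICS_CODES].
#' @param sample_ids,feature_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return an `omics_matrix`: a numeric matrix with attribute `omics_code`.
#' @export
omics_matrix <- function(values, omics_code,
                         sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  omics_code <- match.arg(omics_code, OMICS_CODES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    stop("omics_matrix: sample IDs are required (rownames or sample_ids=)")
  }
  if (is.null(feature_ids)) {
    feature_ids <- if (ncol(values) == 0) character(0) else
      paste0("f", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values)) {
    stop("omics_matrix: length(sample_ids) != number of rows")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("omics_matrix: length(feature_ids) != number of columns")
  }
  if (anyDuplicated(sample_ids)) {
    stop("omics_matrix: duplicate sample IDs; merge them first ",
         "(see merge_duplicate_samples)")
  }
  if (anyDuplicated(feature_ids)) {
    stop("omics_matrix: duplicate feature IDs")
  }
  if (omics_code == "MUT" && !all(values %in% c(0, 1))) {
    stop("omics_matrix: MUT values must be binary 0/1")
  }
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(feature_ids))
  structure(values, omics_code = omics_code,
            class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix %s: %d samples x %d features>\n",
              attr(x, "omics_code"), nrow(x), ncol(x)))
  invisible(x)
}

#' Omics code of an omics matrix
#' @param x an `omics_matrix`.
#' @return single character code.
#' @export
omics_code <- function(x) attr(x, "omics_code")

#' Subset an omics matrix, keeping its class and code
#'
#' @param x an `omics_matrix`.
#' @param samples,features character or integer index; `NULL` keeps all.
#' @return an `omics_matrix`.
#' @export
subset_omics <- function(x, samples = NULL, features = NULL) {
  code <- omics_code(x)
  m <- unclass(x)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  omics_matrix(m, code)
}

#' Construct a label vector of subtypes
#'
#' @param labels factor or character vector of subtype labels.
#' @param sample_ids character vector of sample IDs, one per label.
#' @return named factor with at least two levels.
#' @export
label_vector <- function(labels, sample_ids = names(labels)) {
  if (is.null(sample_ids)) stop("label_vector: sample IDs required")
  if (length(sample_ids) != length(labels)) {
    stop("label_vector: one label per sample required")
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    stop("label_vector: at least two distinct subtypes required")
  }
  names(labels) <- as.character(sample_ids)
  labels
}

#' Construct a clinical table with declared attribute kinds
#'
#' Mixed-kind per-sample clinical records. Each attribute is declared
#' `"continuous"` or `"categorical"`; missing values are explicit `NA`s.
#'
#' @param data data.frame with sample IDs as row names.
#' @param kinds named character vector mapping every column of `data` to
#'   `"continuous"` or `"categorical"`.
#' @return a `clinical_table` (data.frame with a `kinds` attribute).
#' @export
clinical_table <- function(data, kinds) {
  data <- as.data.frame(data)
  if (is.null(rownames(data))) stop("clinical_table: sample ID rownames required")
  if (!setequal(names(kinds), names(data))) {
    stop("clinical_table: every attribute needs a declared kind")
  }
  if (!all(kinds %in% c("continuous", "categorical"))) {
    stop("clinical_table: kinds must be 'continuous' or 'categorical'")
  }
  for (nm in names(data)) {
    if (kinds[[nm]] == "continuous" && !is.numeric(data[[nm]])) {
      stop("clinical_table: continuous attribute '", nm, "' is not numeric")
    }
    if (kinds[[nm]] == "categorical") data[[nm]] <- as.character(data[[nm]])
  }
  structure(data, kinds = kinds[names(data)],
            class = c("clinical_table", "data.frame"))
}

#' Attribute kinds of a clinical table
#' @param x a `clinical_table`.
#' @return named character vector.
#' @export
clinical_kinds <- function(x) attr(x, "kinds")

#' Construct a survival table
#'
#' @param time positive follow-up times (units declared by the caller).
#' @param event event indicator: 1 = death observed, 0 = censored.
#' @param sample_ids character sample IDs aligned with `time`.
#' @return data.frame `survival_table` with columns sample_id, time, event.
#' @export
survival_table <- function(time, event, sample_ids) {
  if (any(time <= 0)) stop("survival_table: all times must be > 0")
  if (!all(event %in% c(0, 1))) stop("survival_table: event must be 0/1")
  if (length(time) != length(event) || length(time) != length(sample_ids)) {
    stop("survival_table: time, event and sample_ids must align")
  }
  structure(
    data.frame(sample_id = as.character(sample_ids), time = as.numeric(time),
               event = as.integer(event), stringsAsFactors = FALSE),
    class = c("survival_table", "data.frame"))
}
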