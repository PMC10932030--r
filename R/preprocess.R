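#' Filter low-expression features
#'
#' Keeps exactly the features whose raw-scale value is `>= threshold` in at
#' least `min_fraction` of samples. Defaults follow the conventional
#' expression filters: FPKM >= 1 in >= 15% of samples for mRNA/lncRNA and
#' RPM >= 1 in >= 30% of samples for miRNA.
#'
#' @param matrix an [omics_matrix()] on the raw nonnegative scale.
#' @param threshold expression threshold (FPKM/RPM-like units).
#' @param min_fraction minimum fraction of samples meeting the threshold.
#' @return the filtered [omics_matrix()]; 0 features with a warning if
#'   nothing survives.
#' @export
filter_low_expression <- function(matrix, threshold = 1,
                                  min_fraction = if (omics_code(matrix) == "MIR") 0.30 else 0.15) {
  frac <- colMeans(unclass(matrix) >= threshold)
  keep <- frac >= min_fraction
  if (!any(keep)) warning("filter_low_expression: no features survive the filter")
  subset_omics(matrix, features = which(keep))
}

#' Merge duplicate samples belonging to the same patient
#'
#' Collapses multiple samples per patient to one row: continuous layers by
#' the per-feature arithmetic mean, binary mutation layers by logical OR.
#' Clinical tables must be resolved upstream (first record per patient).
#'
#' @param matrix an [omics_matrix()].
#' @param patient_of named character vector mapping every sample ID to its
#'   patient ID.
#' @return an [omics_matrix()] with one row per patient, rows ordered by
#'   first appearance of each patient.
#' @export
merge_duplicate_samples <- function(matrix, patient_of) {
  code <- omics_code(matrix)
  if (code == "CLI") {
    stop("merge_duplicate_samples: clinical duplicates must be resolved upstream")
  }
  ids <- rownames(matrix)
  if (!all(ids %in% names(patient_of))) {
    stop("merge_duplicate_samples: patient_of must cover all sample IDs")
  }
  pat <- factor(patient_of[ids], levels = unique(patient_of[ids]))
  counts <- as.vector(table(pat))
  sums <- rowsum(unclass(matrix), pat, reorder = FALSE)
  merged <- if (code == "MUT") (sums > 0) + 0 else sums / counts
  rownames(merged) <- levels(pat)
  omics_matrix(merged, code)
}

#' One-hot encode a clinical table into a CLI omics matrix
#'
#' Each categorical attribute expands to one indicator column per observed
#' category; samples missing that attribute get a dedicated
#' `<attr>=<missing>` indicator. Continuous attributes pass through
#' unscaled (missing continuous values are mean-imputed with a warning).
#'
#' @param table a [clinical_table()].
#' @return an [omics_matrix()] with `omics_code = "CLI"`.
#' @export
one_hot_encode_clinical <- function(table) {
  kinds <- clinical_kinds(table)
  ids <- rownames(table)
  cols <- list()
  for (nm in names(table)) {
    x <- table[[nm]]
    if (all(is.na(x))) {
      warning("one_hot_encode_clinical: attribute '", nm,
              "' is all-missing; dropped")
      next
    }
    if (kinds[[nm]] == "continuous") {
      if (anyNA(x)) {
        warning("one_hot_encode_clinical: mean-imputing missing '", nm, "'")
        x[is.na(x)] <- mean(x, na.rm = TRUE)
      }
      cols[[nm]] <- stats::setNames(data.frame(x), nm)
    } else {
      lev <- sort(unique(x[!is.na(x)]))
      if (anyNA(x)) lev <- c(lev, "<missing>")
      x2 <- ifelse(is.na(x), "<missing>", x)
      ind <- outer(x2, lev, "==") + 0
      colnames(ind) <- paste0(nm, "=", lev)
      cols[[nm]] <- as.data.frame(ind)
    }
  }
  m <- as.matrix(do.call(cbind, unname(cols)))
  rownames(m) <- ids
  omics_matrix(m, "CLI")
}

#' Restrict all inputs to the samples common to every omics layer
#'
#' Computes the intersection of sample IDs across all matrices (and labels
#' and survival, when given) and returns every object restricted to those
#' samples, rows in a shared canonical (sorted ID) order.
#'
#' @param matrices named list of [omics_matrix()].
#' @param labels optional [label_vector()].
#' @param survival optional [survival_table()].
#' @param clinical optional [clinical_table()].
#' @return list with elements `matrices`, `labels`, `survival`, `clinical`.
#' @export
intersect_common_samples <- function(matrices, labels = NULL, survival = NULL,
                                     clinical = NULL) {
  if (!length(matrices)) stop("intersect_common_samples: need >= 1 matrix")
  sets <- lapply(matrices, rownames)
  if (!is.null(labels)) sets <- c(sets, list(names(labels)))
  if (!is.null(survival)) sets <- c(sets, list(survival$sample_id))
  if (!is.null(clinical)) sets <- c(sets, list(rownames(clinical)))
  common <- sort(Reduce(intersect, sets))
  if (!length(common)) stop("intersect_common_samples: empty intersection")
  out <- list(matrices = lapply(matrices, subset_omics, samples = common))
  if (!is.null(labels)) out$labels <- labels[common]
  if (!is.null(survival)) {
    rows <- match(common, survival$sample_id)
    out$survival <- survival_table(survival$time[rows], survival$event[rows],
                                   common)
  }
  if (!is.null(clinical)) {
    out$clinical <- clinical_table(clinical[common, , drop = FALSE],
                                   clinical_kinds(clinical))
  }
  out
}

#' ANOVA-F score of each feature against subtype labels
#'
#' Vectorised one-way ANOVA F statistic per feature column; zero
#' between-group variance gives F = 0.
#'
#' @param matrix numeric sample-by-feature matrix.
#' @param labels a [label_vector()] aligned to the rows.
#' @return numeric vector of F statistics, one per feature.
#' @export
anova_f_scores <- function(matrix, labels) {
  X <- unclass(matrix)
  g <- factor(labels[rownames(X)])
  n <- nrow(X)
  K <- nlevels(g)
  ng <- as.vector(table(g))
  gm <- rowsum(X, g) / ng                       # K x m group means
  mu <- colMeans(X)
  ssb <- colSums(ng * sweep(gm, 2, mu)^2)
  sst <- colSums(sweep(X, 2, mu)^2)
  ssw <- pmax(sst - ssb, 0)
  fstat <- (ssb / (K - 1)) / (ssw / (n - K))
  fstat[ssb <= 0] <- 0
  fstat[!is.finite(fstat)] <- Inf               # ssw = 0 with signal
  stats::setNames(fstat, colnames(X))
}

#' Label-aware univariate feature selection
#'
#' Keeps the `n_keep` features with the highest score under `score_fn`
#' (default: one-way ANOVA F across subtypes), with deterministic
#' tie-breaking by feature ID. The scoring function is pluggable so any
#' ranking method (e.g. a random-forest importance) can be substituted.
#' Feature order of the retained set follows the original matrix.
#'
#' @param matrix an [omics_matrix()].
#' @param labels a [label_vector()] covering the matrix samples.
#' @param n_keep number of features to retain (>= 1).
#' @param score_fn function(matrix, labels) -> numeric scores per feature.
#' @return the reduced [omics_matrix()].
#' @export
select_features <- function(matrix, labels, n_keep,
                            score_fn = anova_f_scores) {
  if (n_keep < 1) stop("select_features: n_keep must be >= 1")
  m <- ncol(matrix)
  if (n_keep >= m) {
    if (n_keep > m) warning("select_features: n_keep > m; keeping all features")
    return(matrix)
  }
  scores <- score_fn(matrix, labels)
  ord <- order(-scores, colnames(matrix))
  keep <- sort(ord[seq_len(n_keep)])
  subset_omics(matrix, features = keep)
}

#' Z-score normalise each feature of a continuous omics matrix
#'
#' Transforms every feature column to mean 0, SD 1. Zero-variance columns
#' map to all-zeros with a warning. Binary mutation, one-hot clinical and
#' eigengene layers are refused: they are used unnormalised.
#'
#' @param matrix an [omics_matrix()] with code in CNA/EXP/LNC/MIR/MET.
#' @return the normalised [omics_matrix()].
#' @export
zscore_normalize <- function(matrix) {
  code <- omics_code(matrix)
  if (!code %in% CONTINUOUS_CODES) {
    stop("zscore_normalize: omics code ", code, " does not require normalization")
  }
  X <- unclass(matrix)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    warning("zscore_normalize: ", sum(zero), " zero-variance feature(s) set to 0")
    sd[zero] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  Z[, zero] <- 0
  omics_matrix(Z, code)
}
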