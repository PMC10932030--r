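#' Read a clinical table from TSV, inferring attribute kinds
#'
#' Numeric columns are declared continuous, everything else categorical;
#' `kinds` overrides the inference.
#'
#' @param path TSV with first column `sample_id`.
#' @param kinds optional named character vector of declared kinds.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path, kinds = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  rownames(df) <- df[[1]]
  df[[1]] <- NULL
  if (is.null(kinds)) {
    kinds <- vapply(df, function(x)
      if (is.numeric(x)) "continuous" else "categorical", "")
  }
  clinical_table(df, kinds)
}

# Per-run input builder: label-aware feature selection on train+val nodes
# only, whole-cohort z-scoring of continuous blocks, all-omics node
# feature concatenation, and one top-k similarity graph per omics layer.
build_run_inputs <- function(omics, clinical, labels, split, config) {
  trval_ids <- names(labels)[sort(c(split$train, split$val))]
  blocks <- list()
  graphs <- list()
  for (code in names(omics)) {
    mat <- omics[[code]]
    nk <- config$n_keep[code]
    if (!is.na(nk) && nk < ncol(mat)) {
      sel <- select_features(subset_omics(mat, samples = trval_ids),
                             labels, nk)
      mat <- subset_omics(mat, features = colnames(sel))
    }
    if (omics_code(mat) %in% CONTINUOUS_CODES) {
      mat <- suppressWarnings(zscore_normalize(mat))
    }
    blocks[[code]] <- mat
    graphs[[code]] <- build_topk_graph(patient_similarity(mat), config$k)
  }
  if (!is.null(clinical)) {
    blocks[["CLI"]] <- one_hot_encode_clinical(clinical)
    graphs[["CLI"]] <- build_topk_graph(gower_similarity(clinical), config$k)
  }
  codes <- intersect(OMICS_CODES, names(blocks))
  features <- do.call(cbind, lapply(codes, function(cd) {
    b <- unclass(blocks[[cd]])
    colnames(b) <- paste0(cd, ".", colnames(b))
    b
  }))
  stats::setNames(lapply(codes, function(cd)
    list(features = features, graph = graphs[[cd]])), codes)
}

#' Run the end-to-end multi-omics pipeline
#'
#' Orchestrates: synthesize-or-load inputs, expression filtering,
#' common-sample intersection, per-run feature selection and
#' normalisation, per-omics similarity graphs, per-omics GAT training,
#' embedding fusion and MLP classification over omics combinations, and
#' (when survival data are present) the survival comparison of raw fused
#' features vs fused GAT embeddings. All artifacts plus a manifest
#' recording every parameter and seed are written to `outdir`.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir output directory (created if needed).
#' @param spec a [synthetic_spec()] used when no input paths are given;
#'   defaults to the standard demo cohort seeded from the config.
#' @param paths optional list with named `omics` TSV paths, `labels`,
#'   `survival`, `clinical`.
#' @param combinations `"all"`, `"loo"` or a list of code subsets for the
#'   sweep.
#' @param survival_stage run the survival comparison (skipped with a
#'   warning when no survival table is available).
#' @param verbose log stage progress to stderr.
#' @return invisible list with `sweep`, `summary`, `survival`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("gatfuse_"),
                         spec = NULL, paths = NULL, combinations = "all",
                         survival_stage = TRUE, verbose = TRUE) {
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (is.null(paths)) {
    if (is.null(spec)) {
      spec <- synthetic_spec(omics = config$omics, seed = config$seed)
    }
    if (verbose) log_stage("synth", "generating synthetic cohort, n = ", spec$n_samples)
    cohort <- generate_multiomics_cohort(spec)
    omics <- cohort$omics
    raw <- cohort$raw
    labels <- cohort$labels
    clinical <- cohort$clinical
    surv <- generate_survival_outcomes(labels, spec)
  } else {
    codes <- names(paths$omics)
    omics <- stats::setNames(lapply(codes, function(cd)
      read_feature_matrix(paths$omics[[cd]], cd)), codes)
    raw <- list()
    labels <- read_labels(paths$labels)
    clinical <- if (!is.null(paths$clinical)) read_clinical_table(paths$clinical)
    surv <- if (!is.null(paths$survival)) read_survival(paths$survival)
  }

  # expression filters operate on the raw (FPKM/RPM-like) scale
  for (code in intersect(names(raw), names(omics))) {
    kept <- colnames(filter_low_expression(raw[[code]]))
    if (verbose) log_stage("preprocess", code, ": ", length(kept), "/",
                           ncol(omics[[code]]), " features pass expression filter")
    omics[[code]] <- subset_omics(omics[[code]], features = kept)
  }

  common <- intersect_common_samples(omics, labels = labels,
                                     survival = surv, clinical = clinical)
  omics <- common$matrices
  labels <- common$labels
  surv <- common$survival
  clinical <- common$clinical

  if (verbose) log_stage("sweep", "running ", config$runs, " repeated runs")
  sweep <- run_combination_sweep(
    NULL, labels, runs = config$runs, combinations = combinations,
    gat_config = config$gat, mlp_config = config$mlp,
    split_fractions = config$split, seed = config$seed, verbose = verbose,
    input_builder = function(split)
      build_run_inputs(omics, clinical, labels, split, config))
  summary_tab <- summarize_sweep(sweep)
  utils::write.table(sweep, file.path(outdir, "sweep_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_tab, file.path(outdir, "sweep_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # final model on one stratified split: export graphs + embeddings
  split <- stratified_split(labels, config$split)
  inputs <- build_run_inputs(omics, clinical, labels, split, config)
  embeddings <- list()
  for (code in names(inputs)) {
    if (verbose) log_stage("train", "final GAT for ", code)
    fit <- train_gat(inputs[[code]]$features, inputs[[code]]$graph, labels,
                     split, config = config$gat)
    embeddings[[code]] <- fit$embedding
    write_graph(inputs[[code]]$graph,
                file.path(outdir, paste0("graph_", code, ".tsv")))
    write_matrix(fit$embedding,
                 file.path(outdir, paste0("embedding_", code, ".tsv")))
  }
  fused <- concatenate_embeddings(embeddings)

  survival_report <- NULL
  if (survival_stage && !is.null(surv)) {
    if (verbose) log_stage("survival", "raw features vs embeddings")
    raw_features <- inputs[[1]]$features
    cmp <- compare_feature_sets(raw_features, fused, surv)
    survival_report <- list(
      p_values = as.list(cmp$p_values),
      raw = survival_summary(cmp$raw), embeddings = survival_summary(cmp$embeddings))
    jsonlite::write_json(survival_report,
                         file.path(outdir, "survival_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (arm in c("raw", "embeddings")) {
      r <- cmp[[arm]]
      if (!inherits(r, "error")) {
        utils::write.table(r$risk, file.path(outdir, paste0("risk_", arm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(r$km_low, file.path(outdir, paste0("km_low_", arm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(r$km_high, file.path(outdir, paste0("km_high_", arm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  } else if (survival_stage) {
    warning("run_pipeline: no survival table; survival stage skipped")
  }

  manifest <- list(config = unclass(config),
                   spec = if (!is.null(spec)) unclass(spec),
                   seed = config$seed,
                   n_samples = length(labels),
                   omics = names(inputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(sweep = sweep, summary = summary_tab,
                 survival = survival_report, manifest = manifest,
                 embeddings = embeddings, outdir = outdir))
}

survival_summary <- function(r) {
  if (inherits(r, "error")) {
    return(list(error = conditionMessage(r)))
  }
  list(n_selected = length(r$selected),
       n_significant = length(attr(r$risk, "kept")),
       n_low = sum(r$risk$group == "low"),
       n_high = sum(r$risk$group == "high"),
       chi_square = r$logrank$chi_square,
       p_value = r$logrank$p_value,
       hazard_ratio = r$logrank$hazard_ratio)
}
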