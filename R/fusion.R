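#' Stratified train/validation/test split
#'
#' Samples within each subtype are partitioned according to `fractions`
#' (default 70/10/20), guaranteeing every subtype appears in the training
#' set whenever it has at least one sample.
#'
#' @param labels a [label_vector()].
#' @param fractions named numeric vector (train, val, test) summing to 1.
#' @return list of integer indices `train`, `val`, `test`.
#' @export
stratified_split <- function(labels,
                             fractions = c(train = 0.7, val = 0.1, test = 0.2)) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("stratified_split: fractions must sum to 1")
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (lv in levels(labels)) {
    rows <- sample(which(labels == lv))
    n <- length(rows)
    n_tr <- max(1L, round(fractions[["train"]] * n))
    n_va <- max(1L, round(fractions[["val"]] * n))
    if (n_tr + n_va >= n) {
      n_tr <- max(1L, n - 2L)
      n_va <- if (n - n_tr >= 2) 1L else 0L
    }
    idx$train <- c(idx$train, rows[seq_len(n_tr)])
    idx$val <- c(idx$val, rows[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, rows[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(idx, sort)
}

#' Concatenate per-omics embeddings into a fused matrix
#'
#' Column blocks are ordered by canonical omics code order
#' ([OMICS_CODES]), independent of the input list order; rows are aligned
#' by sample ID.
#'
#' @param embeddings named list (by omics code) of embedding matrices with
#'   sample ID rownames.
#' @param subset omics codes to fuse (default: all present).
#' @return fused numeric matrix with attribute `blocks` (named widths).
#' @export
concatenate_embeddings <- function(embeddings, subset = names(embeddings)) {
  subset <- intersect(OMICS_CODES, subset)
  missing <- setdiff(subset, names(embeddings))
  if (length(missing)) {
    stop("concatenate_embeddings: no embedding for ", paste(missing, collapse = ", "))
  }
  ids <- rownames(embeddings[[subset[1]]])
  blocks <- lapply(subset, function(code) {
    e <- embeddings[[code]]
    if (!setequal(rownames(e), ids)) {
      stop("concatenate_embeddings: sample mismatch in block ", code)
    }
    e <- e[ids, , drop = FALSE]
    colnames(e) <- paste0(code, ".", colnames(e))
    e
  })
  fused <- do.call(cbind, blocks)
  attr(fused, "blocks") <- stats::setNames(vapply(blocks, ncol, 0L), subset)
  fused
}

#' Classification metrics: accuracy, weighted-F1, macro-F1
#'
#' Per-class F1 = 2PR/(P+R); macro-F1 is the unweighted class mean,
#' weighted-F1 the support-weighted mean. Classes absent from both truth
#' and prediction are excluded; a class with no true and no predicted
#' positives among the remaining ones scores F1 = 0.
#'
#' @param predictions predicted labels.
#' @param truth true labels.
#' @return list with `accuracy`, `weighted_f1`, `macro_f1`, `per_class`.
#' @export
evaluate_metrics <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("evaluate_metrics: length mismatch")
  }
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  classes <- sort(union(unique(truth), unique(predictions)))
  f1 <- support <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    f1[cl] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    support[cl] <- sum(truth == cl)
  }
  list(accuracy = mean(predictions == truth),
       macro_f1 = mean(f1),
       weighted_f1 = if (sum(support) > 0)
         sum(f1 * support) / sum(support) else 0,
       per_class = f1)
}

# ---- MLP classifier (dense layers, ReLU, softmax cross-entropy, Adam) ----

relu <- function(x) pmax(x, 0)

mlp_init <- function(dims) {
  lapply(seq_len(length(dims) - 1), function(l) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    list(W = matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
                    dims[l], dims[l + 1]),
         b = numeric(dims[l + 1]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(X), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1]] <- if (l < L) relu(z) else z
  }
  acts
}

#' Train the fused-embedding MLP subtype classifier
#'
#' Dense network with ReLU hidden layers and a softmax output, trained
#' full-batch with Adam on cross-entropy. Defaults are the grid-search
#' optima: hidden layers (64, 32), learning rate 0.001, 1000 epochs. With
#' `search_budget > 0`, that many configurations are sampled from `grid`
#' and the one with the best validation macro-F1 is kept.
#'
#' @param fused numeric sample-by-feature matrix (fused embeddings).
#' @param labels a [label_vector()] covering the rows.
#' @param split list of integer indices `train`, `val` (and optionally
#'   `test`, unused here).
#' @param config list with `hidden` (integer vector), `learning_rate`,
#'   `epochs`.
#' @param grid named list of candidate values (`hidden` a list of integer
#'   vectors) used when `search_budget > 0`.
#' @param search_budget number of randomly sampled configurations.
#' @return list with `layers`, `levels`, `config`, `val_macro_f1`;
#'   classify new rows with [predict_mlp()].
#' @export
train_mlp <- function(fused, labels, split, config = default_config()$mlp,
                      grid = default_config()$mlp_grid, search_budget = 0) {
  y <- factor(labels[rownames(fused)])
  if (length(unique(as.integer(y)[split$train])) < 2) {
    stop("train_mlp: training set contains a single class")
  }
  if (search_budget > 0) {
    best <- NULL
    for (s in seq_len(search_budget)) {
      cfg <- list(hidden = grid$hidden[[sample.int(length(grid$hidden), 1)]],
                  learning_rate = sample(grid$learning_rate, 1),
                  epochs = sample(grid$epochs, 1))
      fit <- train_mlp_single(fused, y, split, cfg)
      if (is.null(best) || fit$val_macro_f1 > best$val_macro_f1) best <- fit
    }
    return(best)
  }
  train_mlp_single(fused, y, split, config)
}

train_mlp_single <- function(X, y, split, config) {
  X <- unclass(X)
  y_idx <- as.integer(y)
  K <- nlevels(y)
  dims <- c(ncol(X), config$hidden, K)
  layers <- mlp_init(dims)
  L <- length(layers)
  mstate <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- mstate
  step_t <- 0
  lr <- config$learning_rate
  tr <- split$train
  has_val <- length(split$val) > 0
  best_f1 <- -Inf
  best_ep <- 0L
  best_layers <- layers
  Xtr <- X[tr, , drop = FALSE]
  n_tr <- length(tr)
  for (ep in seq_len(config$epochs)) {
    acts <- mlp_forward(layers, Xtr)
    prob <- softmax_rows(acts[[L + 1]])
    dZ <- prob
    dZ[cbind(seq_len(n_tr), y_idx[tr])] <-
      dZ[cbind(seq_len(n_tr), y_idx[tr])] - 1
    dZ <- dZ / n_tr
    grads <- vector("list", L)
    for (l in rev(seq_len(L))) {
      grads[[l]] <- list(W = t(acts[[l]]) %*% dZ, b = colSums(dZ))
      if (l > 1) dZ <- (dZ %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
    step_t <- step_t + 1
    for (l in seq_len(L)) {
      for (nm in c("W", "b")) {
        mstate[[l]][[nm]] <- 0.9 * mstate[[l]][[nm]] + 0.1 * grads[[l]][[nm]]
        vstate[[l]][[nm]] <- 0.999 * vstate[[l]][[nm]] + 0.001 * grads[[l]][[nm]]^2
        layers[[l]][[nm]] <- layers[[l]][[nm]] -
          lr * (mstate[[l]][[nm]] / (1 - 0.9^step_t)) /
          (sqrt(vstate[[l]][[nm]] / (1 - 0.999^step_t)) + 1e-8)
      }
    }
    if (has_val && (ep %% 25 == 0 || ep == config$epochs)) {
      pv <- predict_layers(layers, X[split$val, , drop = FALSE], levels(y))
      vf1 <- evaluate_metrics(pv, y[split$val])$macro_f1
      if (vf1 > best_f1) {
        best_f1 <- vf1
        best_ep <- ep
        best_layers <- layers
      }
      patience <- if (is.null(config$patience)) Inf else config$patience
      if (best_f1 >= 1 || ep - best_ep >= patience) break
    }
  }
  if (!has_val) best_layers <- layers
  list(layers = best_layers, levels = levels(y), config = config,
       val_macro_f1 = best_f1)
}

predict_layers <- function(layers, X, lev) {
  acts <- mlp_forward(layers, X)
  lev[max.col(acts[[length(acts)]], ties.method = "first")]
}

#' Predict subtype labels with a trained MLP
#' @param model result of [train_mlp()].
#' @param newdata numeric matrix with the training feature layout.
#' @return character vector of predicted labels.
#' @export
predict_mlp <- function(model, newdata) {
  predict_layers(model$layers, unclass(newdata), model$levels)
}

#' Enumerate omics combinations
#'
#' All non-empty subsets of the given codes (2^T - 1), or the
#' leave-one-omics-out ablation view (each "all except X" set plus the
#' full set).
#'
#' @param codes omics codes available.
#' @param mode `"all"` or `"loo"`.
#' @return list of character vectors.
#' @export
omics_combinations <- function(codes, mode = c("all", "loo")) {
  mode <- match.arg(mode)
  codes <- intersect(OMICS_CODES, codes)
  if (!length(codes)) stop("omics_combinations: no omics codes given")
  if (mode == "loo") {
    combos <- lapply(codes, function(cd) setdiff(codes, cd))
    combos <- combos[lengths(combos) > 0]
    names(combos) <- paste0("All except ", codes[seq_along(combos)])
    combos <- c(combos, list(`All Datatypes` = codes))
    return(combos)
  }
  combos <- unlist(lapply(seq_along(codes), function(sz)
    utils::combn(codes, sz, simplify = FALSE)), recursive = FALSE)
  names(combos) <- vapply(combos, paste, "", collapse = "+")
  combos
}

#' Combination sweep / ablation over per-omics embeddings
#'
#' For each repeated run: draw a fresh stratified split, train one GAT per
#' omics layer on that split, then for every requested omics combination
#' fuse the selected embedding blocks, train the MLP on train nodes and
#' report test-node accuracy, weighted-F1 and macro-F1.
#'
#' @param omics_inputs named list (by omics code) of
#'   list(features = node feature matrix, graph = `patient_graph`). The
#'   feature matrix is typically the all-omics concatenation, the graph
#'   omics-specific. May be `NULL` when `input_builder` is given.
#' @param labels a [label_vector()].
#' @param runs number of repeated runs (default 10).
#' @param combinations `"all"` (every non-empty subset), `"loo"`
#'   (leave-one-omics-out + all), or a list of code vectors.
#' @param gat_config,mlp_config training configurations.
#' @param split_fractions train/val/test fractions.
#' @param seed RNG seed for the whole sweep.
#' @param verbose log progress.
#' @param input_builder optional `function(split)` returning the
#'   omics-input list for one run; used to keep split-dependent steps
#'   (e.g. label-aware feature selection on train+val nodes only) out of
#'   the test nodes.
#' @return data.frame with columns combination, run, accuracy,
#'   weighted_f1, macro_f1.
#' @export
run_combination_sweep <- function(omics_inputs, labels, runs = 10,
                                  combinations = "all",
                                  gat_config = default_config()$gat,
                                  mlp_config = default_config()$mlp,
                                  split_fractions = c(train = 0.7, val = 0.1,
                                                      test = 0.2),
                                  seed = 1L, verbose = FALSE,
                                  input_builder = NULL) {
  if (is.null(omics_inputs) && is.null(input_builder)) {
    stop("run_combination_sweep: no omics inputs")
  }
  set.seed(seed)
  rows <- list()
  combos <- NULL
  for (r in seq_len(runs)) {
    split <- stratified_split(labels, split_fractions)
    if (!is.null(input_builder)) omics_inputs <- input_builder(split)
    codes <- intersect(OMICS_CODES, names(omics_inputs))
    if (!length(codes)) stop("run_combination_sweep: no omics inputs")
    if (is.null(combos)) {
      combos <- if (is.list(combinations)) {
        stats::setNames(combinations,
                        vapply(combinations, paste, "", collapse = "+"))
      } else {
        omics_combinations(codes, combinations)
      }
    }
    embeddings <- list()
    for (code in codes) {
      if (verbose) log_stage("sweep", sprintf("run %d: training GAT for %s", r, code))
      fit <- train_gat(omics_inputs[[code]]$features,
                       omics_inputs[[code]]$graph, labels, split,
                       config = gat_config)
      embeddings[[code]] <- fit$embedding
    }
    truth <- labels[split$test]
    for (cn in names(combos)) {
      fused <- concatenate_embeddings(embeddings, combos[[cn]])
      mlp <- train_mlp(fused, labels, split, config = mlp_config)
      pred <- predict_mlp(mlp, fused[split$test, , drop = FALSE])
      met <- evaluate_metrics(pred, truth)
      rows[[length(rows) + 1]] <- data.frame(
        combination = cn, run = r, accuracy = met$accuracy,
        weighted_f1 = met$weighted_f1, macro_f1 = met$macro_f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarise a sweep table as mean and SD per combination
#' @param sweep data.frame from [run_combination_sweep()].
#' @return data.frame with per-combination mean and SD of each metric.
#' @export
summarize_sweep <- function(sweep) {
  agg <- function(f) aggregate(cbind(accuracy, weighted_f1, macro_f1) ~
                                 combination, sweep, f)
  mu <- agg(mean)
  sd_ <- agg(stats::sd)
  names(mu)[-1] <- paste0(names(mu)[-1], "_mean")
  names(sd_)[-1] <- paste0(names(sd_)[-1], "_sd")
  merge(mu, sd_, by = "combination")
}
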