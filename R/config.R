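#' Default pipeline configuration
#'
#' Defaults follow the grid-search optima reported for the framework:
#' GAT hidden dimension 512, learning rate 0.001, 200 epochs, 1 attention
#' head; MLP hidden layers (64, 32), learning rate 0.001, 1000 epochs;
#' LASSO penalty grid {0.001, 0.002, 0.005, 0.01, 0.05, 1.0}; k = 3
#' similarity neighbors; ten repeated runs with stratified 70/10/20
#' train/validation/test splits.
#'
#' @return a `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    omics = c("CLI", "EXP", "MET", "MUT"),
    k = 3L,
    gat = list(hidden_dim = 512L, learning_rate = 0.001, epochs = 200L,
               heads = 1L, leaky_slope = 0.2, patience = 40L),
    gat_grid = list(hidden_dim = c(128L, 256L, 512L, 1024L),
                    learning_rate = c(0.01, 0.001, 0.0001),
                    epochs = c(100L, 200L, 500L),
                    heads = c(1L, 2L, 4L, 8L)),
    mlp = list(hidden = c(64L, 32L), learning_rate = 0.001, epochs = 1000L,
               patience = 200L),
    mlp_grid = list(
      hidden = list(32L, 64L, 128L, 256L, 512L, c(32L, 32L), c(64L, 32L),
                    c(128L, 32L), c(256L, 32L)),
      learning_rate = c(0.1, 0.01, 0.001, 1e-4, 1e-5),
      epochs = c(200L, 500L, 1000L, 1500L)),
    lasso_alpha_grid = c(0.001, 0.002, 0.005, 0.01, 0.05, 1.0),
    runs = 10L,
    split = c(train = 0.7, val = 0.1, test = 0.2),
    n_keep = c(CNA = 500L, EXP = 1000L, LNC = 500L, MET = 1000L, MUT = 200L),
    p_threshold = 0.05,
    seed = 1L
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Any field absent from the file is filled from [default_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file, or `NULL`
#'   for pure defaults.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- utils::modifyList(cfg, user, keep.null = FALSE)
    class(cfg) <- "pipeline_config"
  }
  validate_config(cfg)
}

#' Validate a pipeline configuration
#' @param cfg a `pipeline_config` list.
#' @return the validated config, with integer fields coerced.
#' @export
validate_config <- function(cfg) {
  bad <- setdiff(cfg$omics, OMICS_CODES)
  if (length(bad)) {
    stop("config: unknown omics code(s) ", paste(bad, collapse = ", "),
         "; valid codes are ", paste(OMICS_CODES, collapse = ", "))
  }
  if (!is.numeric(cfg$k) || cfg$k < 1) stop("config: k must be >= 1")
  cfg$k <- as.integer(cfg$k)
  if (cfg$runs < 1) stop("config: runs must be >= 1")
  if (abs(sum(cfg$split) - 1) > 1e-8 || any(cfg$split <= 0)) {
    stop("config: split fractions must be positive and sum to 1")
  }
  if (any(cfg$lasso_alpha_grid <= 0)) {
    stop("config: LASSO alpha grid values must be > 0 (alpha = 0 is not penalised)")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
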