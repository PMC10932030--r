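new_similarity <- function(values, metric, sample_ids) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, metric = metric,
            class = c("similarity_matrix", class(values)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix %s: %d x %d>\n",
              attr(x, "metric"), nrow(x), ncol(x)))
  invisible(x)
}

#' Pearson patient similarity
#'
#' Entry (i, j) is the Pearson correlation between the feature vectors of
#' samples i and j. Used for the continuous layers (EXP, LNC, MIR, COE,
#' CNA, MET). Raw signed correlation is used for neighbor ranking: the
#' highest correlation is the most similar patient. Zero-variance sample
#' rows get similarity 0 to every other sample, with a warning.
#'
#' @param matrix an [omics_matrix()] with >= 2 features.
#' @return an n-by-n `similarity_matrix` with metric `"pearson"`.
#' @export
pearson_similarity <- function(matrix) {
  X <- unclass(matrix)
  if (ncol(X) < 2) stop("pearson_similarity: need >= 2 features")
  sds <- apply(X, 1, stats::sd)
  degen <- sds == 0
  S <- suppressWarnings(stats::cor(t(X)))
  if (any(degen)) {
    warning("pearson_similarity: ", sum(degen),
            " zero-variance sample(s); similarity set to 0")
    S[degen, ] <- 0
    S[, degen] <- 0
    diag(S)[degen] <- 1
  }
  new_similarity(S, "pearson", rownames(X))
}

#' Jaccard patient similarity for binary mutation profiles
#'
#' Entry (i, j) = |intersection of mutated genes| / |union of mutated
#' genes|. Two all-zero profiles get similarity 0 by convention (warning).
#'
#' @param matrix a binary [omics_matrix()] (MUT).
#' @return a `similarity_matrix` with metric `"jaccard"`.
#' @export
jaccard_similarity <- function(matrix) {
  X <- unclass(matrix)
  if (!all(X %in% c(0, 1))) stop("jaccard_similarity: input must be binary 0/1")
  inter <- X %*% t(X)
  ones <- rowSums(X)
  uni <- outer(ones, ones, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  if (any(ones == 0)) {
    warning("jaccard_similarity: all-zero profile(s); pairs of empty profiles get 0")
  }
  diag(S)[ones > 0] <- 1
  new_similarity(S, "jaccard", rownames(X))
}

#' Gower patient similarity for mixed clinical data
#'
#' Per-attribute score: `1 - |x_i - x_j| / range` for continuous
#' attributes, exact-match indicator for categorical attributes. The
#' pairwise similarity is the average over attributes observed in both
#' records; zero-range continuous attributes are excluded from every
#' pair's average (with a warning). Computed on the raw mixed-kind table,
#' not its one-hot encoding.
#'
#' @param table a [clinical_table()].
#' @return a `similarity_matrix` with metric `"gower"`.
#' @export
gower_similarity <- function(table) {
  kinds <- clinical_kinds(table)
  n <- nrow(table)
  ssum <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (nm in names(table)) {
    x <- table[[nm]]
    obs <- !is.na(x)
    both <- outer(obs, obs, "&")
    if (kinds[[nm]] == "continuous") {
      rng <- diff(range(x, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("gower_similarity: attribute '", nm,
                "' has zero range; excluded")
        next
      }
      d <- 1 - abs(outer(x, x, "-")) / rng
    } else {
      d <- outer(x, x, "==") + 0
    }
    d[!both] <- 0
    ssum <- ssum + d
    cnt <- cnt + both
  }
  if (all(cnt == 0)) stop("gower_similarity: no usable attributes")
  S <- ifelse(cnt > 0, ssum / cnt, 0)
  new_similarity(S, "gower", rownames(table))
}

#' Omics-appropriate similarity dispatch
#'
#' Pearson for continuous layers (including COE), Jaccard for MUT, Gower
#' for clinical.
#'
#' @param x an [omics_matrix()] or, for CLI, a [clinical_table()].
#' @return a `similarity_matrix`.
#' @export
patient_similarity <- function(x) {
  if (inherits(x, "clinical_table")) return(gower_similarity(x))
  switch(omics_code(x),
         MUT = jaccard_similarity(x),
         CLI = stop("patient_similarity: pass the raw clinical_table for CLI"),
         pearson_similarity(x))
}

#' Build the top-k patient similarity network
#'
#' For each node, its k most similar other nodes are selected (self
#' excluded, ties broken by ascending sample ID); the resulting directed
#' pairs are symmetrised by union into an undirected edge set.
#'
#' @param sim a `similarity_matrix`.
#' @param k number of neighbors per node (default 3).
#' @return a `patient_graph`: list with `nodes` (IDs) and `edges`
#'   (data.frame from, to, weight; from < to).
#' @export
build_topk_graph <- function(sim, k = 3) {
  n <- nrow(sim)
  if (k <= 0) stop("build_topk_graph: k must be >= 1")
  if (k >= n) stop("build_topk_graph: k must be < number of nodes")
  ids <- rownames(sim)
  S <- unclass(sim)
  pairs <- matrix(0L, n * k, 2)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(-s, ids)[seq_len(k)]
    pairs[((i - 1) * k + 1):(i * k), ] <- cbind(i, nb)
  }
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  edges <- data.frame(from = ids[a], to = ids[b],
                      weight = S[cbind(a, b)], stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges, k = k),
            class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  cat(sprintf("<patient_graph: %d nodes, %d undirected edges (k = %d)>\n",
              length(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

#' Adjacency (neighbor index) list of a patient graph
#'
#' @param graph a `patient_graph`.
#' @param self_loops add each node to its own neighborhood (as used by the
#'   GAT aggregation).
#' @return list of integer neighbor indices per node.
#' @export
neighborhoods <- function(graph, self_loops = TRUE) {
  n <- length(graph$nodes)
  a <- match(graph$edges$from, graph$nodes)
  b <- match(graph$edges$to, graph$nodes)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (e in seq_along(a)) {
    nb[[a[e]]] <- c(nb[[a[e]]], b[e])
    nb[[b[e]]] <- c(nb[[b[e]]], a[e])
  }
  if (self_loops) nb <- lapply(seq_len(n), function(i) sort(c(nb[[i]], i)))
  nb
}

#' Write a patient graph as a TSV edge list
#' @param graph a `patient_graph`.
#' @param path output path.
#' @param weights include the similarity weight column.
#' @export
write_graph <- function(graph, path, weights = TRUE) {
  df <- graph$edges
  if (!weights) df$weight <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
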