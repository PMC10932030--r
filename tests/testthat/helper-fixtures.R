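# Shared fixture builders; everything is generated in code.

rand_omics <- function(n, m, code = "EXP", seed = NULL, ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  omics_matrix(matrix(rnorm(n * m), n, m,
                      dimnames = list(ids, sprintf("f%03d", seq_len(m)))),
               code)
}

rand_mut <- function(n, m, p = 0.3, seed = NULL, ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  omics_matrix(matrix(rbinom(n * m, 1, p), n, m,
                      dimnames = list(ids, sprintf("g%03d", seq_len(m)))),
               "MUT")
}

# random symmetric similarity matrix with unit diagonal
rand_sim <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(runif(n * n, -1, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(sprintf("S%03d", 1:n), sprintf("S%03d", 1:n))
  structure(S, metric = "pearson",
            class = c("similarity_matrix", class(S)))
}

# small ring graph over n nodes
ring_graph <- function(n, ids = sprintf("S%03d", seq_len(n))) {
  edges <- data.frame(from = ids, to = ids[c(2:n, 1)], weight = 1,
                      stringsAsFactors = FALSE)
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  structure(list(nodes = ids,
                 edges = data.frame(from = a, to = b, weight = 1)[order(a, b), ],
                 k = 2), class = "patient_graph")
}

# scalar loop oracle for the two attention equations and the aggregation
gat_loop_oracle <- function(params, X, graph, activation = "identity") {
  nb <- neighborhoods(graph, self_loops = TRUE)
  n <- nrow(X)
  p <- nrow(params$W)
  Wx <- lapply(seq_len(n), function(i) as.numeric(params$W %*% X[i, ]))
  a <- c(params$a_self, params$a_neigh)
  c_list <- vector("list", n)
  for (i in seq_len(n)) {
    c_list[[i]] <- vapply(nb[[i]], function(j) {
      v <- sum(a * c(Wx[[i]], Wx[[j]]))
      if (v > 0) v else params$leaky_slope * v
    }, 0)
  }
  alpha_list <- lapply(c_list, function(ci) {
    e <- exp(ci - max(ci))
    e / sum(e)
  })
  H <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (idx in seq_along(nb[[i]])) {
      H[i, ] <- H[i, ] + alpha_list[[i]][idx] * Wx[[nb[[i]][idx]]]
    }
  }
  if (activation == "elu") H <- ifelse(H > 0, H, exp(pmin(H, 0)) - 1)
  list(c = c_list, alpha = alpha_list, H = H, nb = nb)
}

tiny_gat_config <- function(hidden = 16L, epochs = 30L, heads = 1L) {
  list(hidden_dim = hidden, learning_rate = 0.01, epochs = epochs,
       heads = heads, leaky_slope = 0.2, patience = epochs)
}

tiny_mlp_config <- function(hidden = 16L, epochs = 150L) {
  list(hidden = hidden, learning_rate = 0.01, epochs = epochs,
       patience = epochs)
}
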