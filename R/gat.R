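# Graph attention network, hand-written on base matrix ops.
#
# One attention head on a graph with neighborhoods N_i (self-loop
# included):
#   c_ij   = LeakyReLU(a^T [W x_i || W x_j])          (raw attention)
#   alpha  = softmax_j over N_i of c_ij               (normalisation)
#   h_i    = sigma( sum_{j in N_i} alpha_ij W x_j )   (aggregation)
# The architecture is two layers: layer 1 concatenates H heads (ELU),
# layer 2 averages heads into class scores (identity before softmax).

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

#' Initialise the parameters of one attention head
#'
#' Glorot-uniform initialisation of the shared linear map `W` (p x m) and
#' the attention vector `a` (length 2p, stored as its two halves acting on
#' the target and source embedding).
#'
#' @param m input feature dimension.
#' @param p output (embedding) dimension of this head.
#' @param leaky_slope negative slope of the LeakyReLU on raw scores.
#' @return a `gat_layer_params` list with `W`, `a_self`, `a_neigh`.
#' @export
gat_layer_params <- function(m, p, leaky_slope = 0.2) {
  lw <- sqrt(6 / (m + p))
  la <- sqrt(6 / (2 * p + 1))
  structure(list(
    W = matrix(stats::runif(p * m, -lw, lw), p, m),
    a_self = stats::runif(p, -la, la),
    a_neigh = stats::runif(p, -la, la),
    leaky_slope = leaky_slope), class = "gat_layer_params")
}

# Directed edge index (i <- j, j in N_i incl. self) from a patient_graph.
edge_index <- function(graph) {
  nb <- neighborhoods(graph, self_loops = TRUE)
  ei <- rep.int(seq_along(nb), lengths(nb))
  list(ei = ei, ej = unlist(nb), n = length(nb))
}

#' Raw attention scores of one head on a graph
#'
#' Computes `c_ij = LeakyReLU(a^T [W x_i || W x_j])` for every directed
#' pair (i, j in N_i), neighborhoods including self-loops.
#'
#' @param params a [gat_layer_params()].
#' @param features numeric node-by-feature matrix.
#' @param graph a `patient_graph` over the feature rows.
#' @return an `attention_state` list: `ei`, `ej` (edge indices), `c` (raw
#'   scores), `Z` (projected features), `alpha` (NULL until
#'   [normalize_attention()]).
#' @export
attention_scores <- function(params, features, graph) {
  X <- unclass(features)
  if (ncol(X) != ncol(params$W)) {
    stop(sprintf("attention_scores: feature dimension mismatch (expected %d, got %d)",
                 ncol(params$W), ncol(X)))
  }
  idx <- edge_index(graph)
  Z <- X %*% t(params$W)
  s_self <- drop(Z %*% params$a_self)
  s_neigh <- drop(Z %*% params$a_neigh)
  e <- unname(s_self[idx$ei] + s_neigh[idx$ej])
  structure(list(ei = idx$ei, ej = idx$ej, n = idx$n, Z = Z, e = e,
                 c = leaky_relu(e, params$leaky_slope), alpha = NULL),
            class = "attention_state")
}

#' Softmax-normalise attention coefficients per neighborhood
#'
#' `alpha_ij = exp(c_ij) / sum_{k in N_i} exp(c_ik)`, computed with
#' per-neighborhood max subtraction for overflow safety. Self-loops
#' guarantee no neighborhood is empty.
#'
#' @param state an `attention_state` from [attention_scores()].
#' @return the state with `alpha` filled; for every node the alphas sum
#'   to 1.
#' @export
normalize_attention <- function(state) {
  stopifnot(inherits(state, "attention_state"))
  cmax <- rep(-Inf, state$n)
  cm <- vapply(split(state$c, state$ei), max, 0)
  cmax[as.integer(names(cm))] <- cm
  ex <- exp(state$c - cmax[state$ei])
  denom <- drop(rowsum(ex, state$ei))
  state$alpha <- unname(ex / denom[match(state$ei, sort(unique(state$ei)))])
  state
}

#' Attention-weighted neighbor aggregation
#'
#' `h_i = sigma( sum_{j in N_i} alpha_ij W x_j )`. The nonlinearity is ELU
#' on hidden layers and the identity on the output layer.
#'
#' @param state a normalised `attention_state`.
#' @param activation `"elu"` or `"identity"`.
#' @return node-by-p embedding matrix.
#' @export
aggregate_neighbors <- function(state, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  if (is.null(state$alpha)) stop("aggregate_neighbors: call normalize_attention first")
  pre <- rowsum(state$alpha * state$Z[state$ej, , drop = FALSE], state$ei)
  if (activation == "elu") elu(pre) else pre
}

# Forward pass of one multi-head layer. Returns output plus caches for
# backprop. mode = "concat" (hidden layer) or "average" (output layer).
layer_forward <- function(heads, X, idx, activation, mode) {
  caches <- vector("list", length(heads))
  outs <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    p <- heads[[h]]
    Z <- X %*% t(p$W)
    s_self <- drop(Z %*% p$a_self)
    s_neigh <- drop(Z %*% p$a_neigh)
    e <- s_self[idx$ei] + s_neigh[idx$ej]
    c_raw <- leaky_relu(e, p$leaky_slope)
    cmax <- vapply(split(c_raw, idx$ei), max, 0)
    ex <- exp(c_raw - cmax[idx$ei])
    denom <- drop(rowsum(ex, idx$ei))
    alpha <- ex / denom[idx$ei]
    pre <- rowsum(alpha * Z[idx$ej, , drop = FALSE], idx$ei)
    out <- if (activation == "elu") elu(pre) else pre
    caches[[h]] <- list(Z = Z, e = e, alpha = alpha, pre = pre)
    outs[[h]] <- out
  }
  list(out = if (mode == "concat") do.call(cbind, outs) else
         Reduce(`+`, outs) / length(outs),
       caches = caches)
}

# Backward pass of one multi-head layer. dOut is the gradient w.r.t. the
# layer output. Returns per-head parameter gradients and dX.
layer_backward <- function(heads, X, idx, activation, mode, caches, dOut) {
  n <- nrow(X)
  H <- length(heads)
  p_dim <- ncol(caches[[1]]$Z)
  dX <- matrix(0, n, ncol(X))
  grads <- vector("list", H)
  for (h in seq_len(H)) {
    prm <- heads[[h]]
    ch <- caches[[h]]
    dH <- if (mode == "concat") {
      dOut[, ((h - 1) * p_dim + 1):(h * p_dim), drop = FALSE]
    } else {
      dOut / H
    }
    dPre <- if (activation == "elu") dH * elu_grad(ch$pre) else dH
    Zj <- ch$Z[idx$ej, , drop = FALSE]
    dPre_i <- dPre[idx$ei, , drop = FALSE]
    dalpha <- rowSums(dPre_i * Zj)
    dZ <- rowsum(ch$alpha * dPre_i, idx$ej)          # into source nodes
    # softmax backward within each neighborhood
    srow <- drop(rowsum(ch$alpha * dalpha, idx$ei))
    dc <- ch$alpha * (dalpha - srow[idx$ei])
    de <- dc * leaky_relu_grad(ch$e, prm$leaky_slope)
    ds_self <- drop(rowsum(de, idx$ei))
    ds_neigh <- drop(rowsum(de, idx$ej))
    dZ <- dZ + outer(ds_self, prm$a_self) + outer(ds_neigh, prm$a_neigh)
    grads[[h]] <- list(W = t(dZ) %*% X,
                       a_self = drop(t(ch$Z) %*% ds_self),
                       a_neigh = drop(t(ch$Z) %*% ds_neigh))
    dX <- dX + dZ %*% prm$W
  }
  list(grads = grads, dX = dX)
}

#' Initialise a two-layer GAT node classifier
#'
#' Layer 1: `heads` attention heads of width `hidden_dim / heads`, ELU,
#' outputs concatenated (total width `hidden_dim`). Layer 2: `heads`
#' heads of width `n_classes`, averaged, identity activation (class
#' scores).
#'
#' @param m input feature dimension.
#' @param n_classes number of subtype classes.
#' @param hidden_dim total hidden width (default 512).
#' @param heads number of attention heads (must divide `hidden_dim`).
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @return a `gat_model` list.
#' @export
gat_model <- function(m, n_classes, hidden_dim = 512L, heads = 1L,
                      leaky_slope = 0.2) {
  if (hidden_dim %% heads != 0) {
    stop("gat_model: heads must divide hidden_dim")
  }
  p1 <- hidden_dim %/% heads
  structure(list(
    layer1 = lapply(seq_len(heads), function(h)
      gat_layer_params(m, p1, leaky_slope)),
    layer2 = lapply(seq_len(heads), function(h)
      gat_layer_params(hidden_dim, n_classes, leaky_slope)),
    hidden_dim = as.integer(hidden_dim), heads = as.integer(heads),
    m = as.integer(m), n_classes = as.integer(n_classes)),
    class = "gat_model")
}

#' Forward pass of the two-layer GAT
#'
#' @param model a [gat_model()].
#' @param features node-by-feature matrix (rows aligned to graph nodes).
#' @param graph a `patient_graph`.
#' @return list with `scores` (node-by-class), `hidden` (node-by-
#'   hidden_dim layer-1 embedding) and internal caches.
#' @export
gat_forward <- function(model, features, graph) {
  X <- unclass(features)
  if (ncol(X) != model$m) {
    stop(sprintf("gat_forward: feature dimension mismatch (expected %d, got %d)",
                 model$m, ncol(X)))
  }
  idx <- edge_index(graph)
  l1 <- layer_forward(model$layer1, X, idx, "elu", "concat")
  l2 <- layer_forward(model$layer2, l1$out, idx, "identity", "average")
  list(scores = l2$out, hidden = l1$out, l1 = l1, l2 = l2, idx = idx, X = X)
}

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1, max))
  e / rowSums(e)
}

cross_entropy <- function(prob, y_idx, rows) {
  -mean(log(pmax(prob[cbind(rows, y_idx[rows])], 1e-12)))
}

# One full forward/backward pass; returns loss and parameter gradients.
gat_backward <- function(model, fw, y_idx, train_rows) {
  prob <- softmax_rows(fw$scores)
  n_tr <- length(train_rows)
  dS <- matrix(0, nrow(prob), ncol(prob))
  dS[train_rows, ] <- prob[train_rows, , drop = FALSE] / n_tr
  dS[cbind(train_rows, y_idx[train_rows])] <-
    dS[cbind(train_rows, y_idx[train_rows])] - 1 / n_tr
  b2 <- layer_backward(model$layer2, fw$l1$out, fw$idx, "identity",
                       "average", fw$l2$caches, dS)
  b1 <- layer_backward(model$layer1, fw$X, fw$idx, "elu", "concat",
                       fw$l1$caches, b2$dX)
  list(loss = cross_entropy(prob, y_idx, train_rows),
       g1 = b1$grads, g2 = b2$grads)
}

# Adam update for a list-of-heads parameter structure.
adam_init <- function(model) {
  zero_like <- function(p) list(W = p$W * 0, a_self = p$a_self * 0,
                                a_neigh = p$a_neigh * 0)
  list(m1 = lapply(model$layer1, zero_like),
       v1 = lapply(model$layer1, zero_like),
       m2 = lapply(model$layer2, zero_like),
       v2 = lapply(model$layer2, zero_like), t = 0)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    for (nm in c("W", "a_self", "a_neigh")) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      p[[nm]] <- p[[nm]] - lr * (m[[nm]] / corr1) /
        (sqrt(v[[nm]] / corr2) + eps)
    }
    list(p = p, m = m, v = v)
  }
  for (h in seq_along(model$layer1)) {
    r <- upd(model$layer1[[h]], grads$g1[[h]], state$m1[[h]], state$v1[[h]])
    model$layer1[[h]] <- r$p; state$m1[[h]] <- r$m; state$v1[[h]] <- r$v
  }
  for (h in seq_along(model$layer2)) {
    r <- upd(model$layer2[[h]], grads$g2[[h]], state$m2[[h]], state$v2[[h]])
    model$layer2[[h]] <- r$p; state$m2[[h]] <- r$m; state$v2[[h]] <- r$v
  }
  list(model = model, state = state)
}

#' Train a per-omics GAT node classifier and extract embeddings
#'
#' Full-batch supervised training minimising cross-entropy on the training
#' nodes with Adam; the epoch with the best validation macro-F1 is kept.
#' If `grid` is given, every configuration in the grid is trained and the
#' one with the best validation macro-F1 is selected.
#'
#' @param features node-by-feature matrix with sample ID rownames.
#' @param graph a `patient_graph` over the same samples.
#' @param labels a [label_vector()] covering all nodes.
#' @param split list with integer indices `train` and `val`; every subtype
#'   must appear in the training set.
#' @param config list with `hidden_dim`, `learning_rate`, `epochs`,
#'   `heads`, `leaky_slope` and optionally `patience` (defaults from
#'   [default_config()]). Training stops early once the validation
#'   macro-F1 has not improved for `patience` epochs or reaches 1; the
#'   kept model is always the best-validation epoch.
#' @param grid optional named list of vectors over the same fields; the
#'   Cartesian product is searched.
#' @param verbose log progress to stderr.
#' @return list with `model`, `embedding` (all-node layer-1 hidden matrix
#'   at the best-validation epoch), `history` (per-epoch loss and val
#'   macro-F1), `val_macro_f1`, `config`.
#' @export
train_gat <- function(features, graph, labels, split,
                      config = default_config()$gat, grid = NULL,
                      verbose = FALSE) {
  y <- factor(labels[rownames(features)])
  if (anyNA(y)) stop("train_gat: labels missing for some nodes")
  if (!all(levels(y) %in% unique(as.character(y[split$train])))) {
    stop("train_gat: a subtype is absent from the training split (stratification violated)")
  }
  if (is.null(grid)) {
    return(train_gat_single(features, graph, y, split, config, verbose))
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    cfg <- utils::modifyList(config, as.list(combos[r, , drop = FALSE]))
    fit <- train_gat_single(features, graph, y, split, cfg, verbose)
    if (is.null(best) || fit$val_macro_f1 > best$val_macro_f1) best <- fit
  }
  best
}

train_gat_single <- function(features, graph, y, split, config, verbose) {
  X <- unclass(features)
  y_idx <- as.integer(y)
  model <- gat_model(ncol(X), nlevels(y), config$hidden_dim, config$heads,
                     if (is.null(config$leaky_slope)) 0.2 else config$leaky_slope)
  opt <- adam_init(model)
  patience <- if (is.null(config$patience)) Inf else config$patience
  best_f1 <- -Inf
  best_vloss <- Inf
  best_ep <- 0L
  best_hidden <- NULL
  best_model <- model
  loss_hist <- valf1_hist <- numeric(config$epochs)
  last_ep <- 0L
  for (ep in seq_len(config$epochs)) {
    fw <- gat_forward(model, X, graph)
    bw <- gat_backward(model, fw, y_idx, split$train)
    prob <- softmax_rows(fw$scores)
    pred_val <- levels(y)[max.col(fw$scores[split$val, , drop = FALSE])]
    vf1 <- evaluate_metrics(pred_val, y[split$val])$macro_f1
    vloss <- cross_entropy(prob, y_idx, split$val)
    loss_hist[ep] <- bw$loss
    valf1_hist[ep] <- vf1
    last_ep <- ep
    # selection by validation macro-F1; ties broken by validation loss
    if (vf1 > best_f1) {
      best_f1 <- vf1
      best_ep <- ep
      best_vloss <- vloss
      best_hidden <- fw$hidden
      best_model <- model
    } else if (vf1 == best_f1 && vloss < best_vloss - 1e-9) {
      best_vloss <- vloss
      best_hidden <- fw$hidden
      best_model <- model
    }
    if (ep - best_ep >= patience) break
    st <- adam_step(model, bw, opt, config$learning_rate)
    model <- st$model
    opt <- st$state
    if (verbose && ep %% 50 == 0) {
      log_stage("gat", sprintf("epoch %d loss %.4f val macro-F1 %.3f",
                               ep, bw$loss, vf1))
    }
  }
  rownames(best_hidden) <- rownames(X)
  colnames(best_hidden) <- paste0("h", seq_len(ncol(best_hidden)))
  list(model = best_model, embedding = best_hidden,
       history = data.frame(epoch = seq_len(last_ep),
                            loss = loss_hist[seq_len(last_ep)],
                            val_macro_f1 = valf1_hist[seq_len(last_ep)]),
       val_macro_f1 = best_f1, config = config)
}
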