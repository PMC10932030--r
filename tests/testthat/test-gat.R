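test_that("raw attention scores match a scalar evaluation of the edge formula", {
  set.seed(47)
  g <- ring_graph(4)
  X <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(g$nodes, NULL))
  params <- gat_layer_params(3, 5)
  st <- attention_scores(params, X, g)
  oracle <- gat_loop_oracle(params, X, g)
  expect_lt(max(abs(st$c - unlist(oracle$c))), 1e-10)

  # a = 0 -> all scores 0
  p0 <- params; p0$a_self[] <- 0; p0$a_neigh[] <- 0
  expect_true(all(attention_scores(p0, X, g)$c == 0))

  # single node with self-loop only, x = 0 -> c = 0
  g1 <- structure(list(nodes = "A",
                       edges = data.frame(from = character(0),
                                          to = character(0),
                                          weight = numeric(0)), k = 0),
                  class = "patient_graph")
  pI <- gat_layer_params(2, 2)
  pI$W <- diag(2); pI$a_self[] <- 1; pI$a_neigh[] <- 1
  stI <- attention_scores(pI, matrix(0, 1, 2, dimnames = list("A", NULL)), g1)
  expect_identical(stI$c, 0)

  expect_error(attention_scores(params, X[, 1:2], g), "expected 3, got 2")
})

test_that("softmax normalisation produces convex weights per neighborhood", {
  set.seed(53)
  g <- ring_graph(5)
  X <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(g$nodes, NULL))
  params <- gat_layer_params(4, 3)
  st <- normalize_attention(attention_scores(params, X, g))
  sums <- tapply(st$alpha, st$ei, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(st$alpha >= 0 & st$alpha <= 1))
  oracle <- gat_loop_oracle(params, X, g)
  expect_lt(max(abs(st$alpha - unlist(oracle$alpha))), 1e-10)

  # closed forms: c = (ln 2, 0) -> alpha = (2/3, 1/3); equal c -> 1/2 each
  st2 <- st
  st2$ei <- c(1L, 1L); st2$ej <- c(1L, 2L); st2$n <- 2L
  st2$c <- c(log(2), 0)
  a2 <- normalize_attention(st2)$alpha
  expect_equal(a2, c(2 / 3, 1 / 3), tolerance = 1e-12)
  st2$c <- c(0.7, 0.7)
  expect_equal(normalize_attention(st2)$alpha, c(0.5, 0.5))
  st2$ei <- c(1L, 2L)  # single neighbor each -> alpha 1
  expect_equal(normalize_attention(st2)$alpha, c(1, 1))
})

test_that("aggregation is the attention-weighted mean of projected neighbors", {
  set.seed(59)
  g <- ring_graph(5)
  params <- gat_layer_params(4, 3)

  # identical features everywhere: h_i = sigma(Wx) regardless of alpha
  x0 <- rnorm(4)
  Xsame <- matrix(rep(x0, each = 5), 5, 4, dimnames = list(g$nodes, NULL))
  st <- normalize_attention(attention_scores(params, Xsame, g))
  H <- aggregate_neighbors(st, "identity")
  expect_lt(max(abs(sweep(H, 2, as.numeric(params$W %*% x0)))), 1e-10)

  # random instance vs loop oracle, with and without ELU
  X <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(g$nodes, NULL))
  st2 <- normalize_attention(attention_scores(params, X, g))
  oracle <- gat_loop_oracle(params, X, g, activation = "elu")
  expect_lt(max(abs(aggregate_neighbors(st2, "elu") - oracle$H)), 1e-10)

  # with uniform alpha and identity activation, output = mean aggregation
  st3 <- st2
  deg <- lengths(oracle$nb)
  st3$alpha <- 1 / deg[st3$ei]
  Hmean <- aggregate_neighbors(st3, "identity")
  Z <- X %*% t(params$W)
  ref <- t(vapply(seq_len(5), function(i) colMeans(Z[oracle$nb[[i]], , drop = FALSE]),
                  numeric(3)))
  expect_lt(max(abs(Hmean - ref)), 1e-10)
})

test_that("two-layer forward is permutation-equivariant and sane at init", {
  set.seed(61)
  n <- 8L
  S <- rand_sim(n, seed = 67)
  g <- build_topk_graph(S, 2)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(g$nodes, NULL))
  model <- gat_model(6, 3, hidden_dim = 8L, heads = 2L)
  fw <- gat_forward(model, X, g)
  expect_identical(dim(fw$scores), c(n, 3L))
  expect_identical(dim(fw$hidden), c(n, 8L))

  # permuting nodes permutes outputs identically
  perm <- sample(n)
  Sp <- unclass(S)[perm, perm]
  class(Sp) <- class(S)
  gp <- build_topk_graph(Sp, 2)
  fwp <- gat_forward(model, X[perm, ], gp)
  expect_lt(max(abs(fwp$scores - fw$scores[perm, ])), 1e-8)
  expect_lt(max(abs(fwp$hidden - fw$hidden[perm, ])), 1e-8)

  # zero weights -> identical class scores across nodes
  zmodel <- model
  for (h in seq_along(zmodel$layer2)) {
    zmodel$layer2[[h]]$W[] <- 0
    zmodel$layer2[[h]]$a_self[] <- 0
    zmodel$layer2[[h]]$a_neigh[] <- 0
  }
  fz <- gat_forward(zmodel, X, g)
  expect_lt(max(abs(sweep(fz$scores, 2, fz$scores[1, ]))), 1e-12)

  # attention normalisation holds on every forward pass
  for (cache in c(fw$l1$caches, fw$l2$caches)) {
    sums <- tapply(cache$alpha, fw$idx$ei, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }

  # single-head model equals the explicit composition of the three steps
  m1 <- gat_model(6, 3, hidden_dim = 5L, heads = 1L)
  f1 <- gat_forward(m1, X, g)
  h1 <- aggregate_neighbors(
    normalize_attention(attention_scores(m1$layer1[[1]], X, g)), "elu")
  s1 <- aggregate_neighbors(
    normalize_attention(attention_scores(m1$layer2[[1]], h1, g)), "identity")
  expect_lt(max(abs(f1$hidden - h1)), 1e-12)
  expect_lt(max(abs(f1$scores - s1)), 1e-12)

  expect_error(gat_model(6, 3, hidden_dim = 10L, heads = 4L), "divide")
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  spec <- synthetic_spec(n_samples = 100, omics = "EXP",
                         n_features = c(EXP = 40L), effect_size = 3,
                         subtype_proportions = c(A = 0.4, B = 0.35, C = 0.25),
                         subtype_log_hazards = c(0, 0, 0), seed = 71)
  cohort <- generate_multiomics_cohort(spec)
  X <- unclass(zscore_normalize(cohort$omics$EXP))
  g <- build_topk_graph(pearson_similarity(cohort$omics$EXP), 3)
  set.seed(1); split <- stratified_split(cohort$labels)

  set.seed(2)
  fit <- train_gat(X, g, cohort$labels, split, config = tiny_gat_config(epochs = 60L))
  expect_gt(fit$val_macro_f1, 0.85)
  expect_identical(dim(fit$embedding), c(100L, 16L))
  expect_true(all(is.finite(fit$embedding)))
  # loss non-increasing in >= 95% of steps
  d <- diff(fit$history$loss)
  expect_gte(mean(d <= 1e-12), 0.95)

  set.seed(2)
  fit2 <- train_gat(X, g, cohort$labels, split, config = tiny_gat_config(epochs = 60L))
  expect_identical(fit$history, fit2$history)

  # a subtype missing from the training split is refused
  bad_split <- split
  bad_split$train <- setdiff(bad_split$train, which(cohort$labels == "C"))
  expect_error(train_gat(X, g, cohort$labels, bad_split, config = tiny_gat_config()),
               "stratification")
})

test_that("null cohorts stay near the majority-class baseline", {
  spec <- synthetic_spec(n_samples = 120, omics = "EXP",
                         n_features = c(EXP = 40L), effect_size = 0,
                         subtype_proportions = c(A = 0.5, B = 0.3, C = 0.2),
                         subtype_log_hazards = c(0, 0, 0), seed = 73)
  cohort <- generate_multiomics_cohort(spec)
  X <- unclass(zscore_normalize(cohort$omics$EXP))
  g <- build_topk_graph(pearson_similarity(cohort$omics$EXP), 3)
  set.seed(3); split <- stratified_split(cohort$labels)
  set.seed(4)
  fit <- train_gat(X, g, cohort$labels, split, config = tiny_gat_config(epochs = 40L))
  maj <- names(which.max(table(cohort$labels[split$train])))
  base <- evaluate_metrics(rep(maj, length(split$val)),
                           cohort$labels[split$val])$macro_f1
  expect_lte(fit$val_macro_f1, base + 0.35)
})

test_that("grid search picks the best-validating configuration", {
  spec <- synthetic_spec(n_samples = 80, omics = "EXP",
                         n_features = c(EXP = 30L), effect_size = 2,
                         subtype_proportions = c(A = 0.5, B = 0.5),
                         subtype_log_hazards = c(0, 0), seed = 79)
  cohort <- generate_multiomics_cohort(spec)
  X <- unclass(zscore_normalize(cohort$omics$EXP))
  g <- build_topk_graph(pearson_similarity(cohort$omics$EXP), 3)
  set.seed(5); split <- stratified_split(cohort$labels)
  set.seed(6)
  fit <- train_gat(X, g, cohort$labels, split,
                   config = tiny_gat_config(epochs = 25L),
                   grid = list(hidden_dim = c(8L, 16L)))
  expect_true(fit$config$hidden_dim %in% c(8L, 16L))
  expect_gte(fit$val_macro_f1, 0.5)
})
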