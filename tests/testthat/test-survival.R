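surv_fixture <- function(time, event, ids = sprintf("S%02d", seq_along(time))) {
  survival_table(time, event, ids)
}

test_that("LASSO selection shrinks fully at huge penalties and recovers signal", {
  set.seed(103)
  n <- 200
  X <- matrix(rnorm(n * 51), n, 51,
              dimnames = list(sprintf("S%03d", 1:n), paste0("f", 1:51)))
  time <- 2 * X[, 1] + rnorm(n, 0, 0.5) + 10    # keep times positive
  surv <- surv_fixture(time, rbinom(n, 1, 0.7), rownames(X))

  # huge penalty: empty selection
  expect_length(lasso_select(X, surv, alpha_grid = c(1e6, 2e6)), 0)
  # alpha = 0 is not a legal grid value
  expect_error(lasso_select(X, surv, alpha_grid = c(0, 0.01)), "> 0")
  expect_error(lasso_select(X[1:5, ], surv), "fewer than 10")

  # signal recovery across seeds at the CV-chosen penalty
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    Xs <- matrix(rnorm(n * 51), n, 51,
                 dimnames = list(rownames(X), colnames(X)))
    ts <- 2 * Xs[, 1] + rnorm(n, 0, 0.5) + 10
    ss <- surv_fixture(ts, rep(1, n), rownames(Xs))
    hits <- hits + ("f1" %in% lasso_select(Xs, ss))
  }
  expect_gte(hits, 19)
})

test_that("Cox fit recovers a known hazard ratio and rejects singular input", {
  set.seed(107)
  n <- 500
  grp <- rep(0:1, each = n / 2)
  # average the estimate over replicates to separate bias from seed noise
  coefs <- vapply(1:5, function(s) {
    time <- rexp(n, exp(log(2) * grp))
    X <- cbind(grp = grp)
    rownames(X) <- sprintf("S%03d", 1:n)
    fit_coxph(X, surv_fixture(time, rep(1, n), rownames(X)))$coef["grp"]
  }, 0)
  expect_lt(abs(mean(coefs) - log(2)), 0.15)

  time <- rexp(n, exp(log(2) * grp))
  X <- cbind(grp = grp)
  rownames(X) <- sprintf("S%03d", 1:n)
  surv <- surv_fixture(time, rep(1, n), rownames(X))
  fit <- fit_coxph(X, surv)
  expect_equal(unname(fit$hazard_ratio["grp"]), exp(unname(fit$coef["grp"])))
  expect_true(all(fit$p_value >= 0 & fit$p_value <= 1))

  # duplicate predictor columns are singular
  X2 <- cbind(a = grp, b = grp)
  rownames(X2) <- rownames(X)
  expect_error(fit_coxph(X2, surv), "singular|constant")
  # constant predictors are refused
  X3 <- cbind(a = grp, cst = 1)
  rownames(X3) <- rownames(X)
  expect_error(fit_coxph(X3, surv), "constant")
})

test_that("null covariates give calibrated Cox p-values", {
  set.seed(109)
  n <- 300
  rej <- 0
  for (s in 1:200) {
    x <- rnorm(n)
    time <- rexp(n)
    X <- cbind(x = x)
    rownames(X) <- sprintf("S%03d", 1:n)
    fit <- fit_coxph(X, surv_fixture(time, rep(1, n), rownames(X)))
    rej <- rej + (fit$p_value["x"] < 0.05)
  }
  expect_gt(rej / 200, 0.02)
  expect_lt(rej / 200, 0.09)
})

test_that("the coefficient sign tracks the shorter-lived group", {
  set.seed(113)
  ok <- 0
  for (s in 1:50) {
    n <- 80
    grp <- rep(0:1, each = n / 2)
    time <- rexp(n, ifelse(grp == 1, 3, 1))   # group 1 dies faster
    X <- cbind(grp = grp)
    rownames(X) <- sprintf("S%02d", 1:n)
    fit <- fit_coxph(X, surv_fixture(time, rep(1, n), rownames(X)))
    ok <- ok + (fit$coef["grp"] > 0)
  }
  expect_gte(ok, 48)
})

test_that("risk scores follow the significant-coefficient sum and median split", {
  model <- structure(list(coef = c(f1 = 0.5, f2 = -1),
                          hazard_ratio = exp(c(f1 = 0.5, f2 = -1)),
                          p_value = c(f1 = 0.01, f2 = 0.001),
                          predictors = c("f1", "f2")), class = "cox_model")
  X <- matrix(c(1, 2), 1, 2, dimnames = list("S1", c("f1", "f2")))
  rs <- suppressWarnings(compute_risk_scores(model, X))  # n = 1: trivial split
  expect_equal(rs$score, -1.5)

  # n = 101 distinct scores: 51 low, 50 high
  set.seed(127)
  X2 <- matrix(sample(seq_len(101)), 101, 1,
               dimnames = list(sprintf("S%03d", 1:101), "f1"))
  X2 <- cbind(X2, f2 = 0.01 * X2[, 1])
  model2 <- model
  rs2 <- compute_risk_scores(model2, X2)
  expect_identical(as.vector(table(rs2$group)[c("low", "high")]),
                   c(51L, 50L))
  expect_true(all(rs2$score[rs2$group == "low"] <= median(rs2$score)))

  # identical scores: degenerate split, everyone low-risk
  X3 <- matrix(1, 5, 2, dimnames = list(paste0("S", 1:5), c("f1", "f2")))
  expect_warning(rs3 <- compute_risk_scores(model, X3), "degenerate")
  expect_true(all(rs3$group == "low"))

  # nothing significant: advisory error
  model$p_value <- c(f1 = 0.5, f2 = 0.9)
  expect_error(compute_risk_scores(model, X), "relaxing")
})

test_that("Kaplan-Meier matches the product-limit computation", {
  km <- km_estimate(surv_fixture(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: S = 1 everywhere
  kmc <- km_estimate(surv_fixture(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(km_surv_at(kmc, c(0, 3, 10)) == 1))

  # one subject with an event at t = 5
  km1 <- km_estimate(surv_fixture(5, 1))
  expect_equal(km_surv_at(km1, c(4.99, 5)), c(1, 0))

  # no censoring: S(t) = 1 - ECDF(t)
  set.seed(131)
  times <- rexp(40)
  kmf <- km_estimate(surv_fixture(times, rep(1, 40)))
  expect_equal(km_surv_at(kmf, sort(times)),
               1 - ecdf(times)(sort(times)), tolerance = 1e-12)
})

test_that("log-rank statistic matches a hand-tabulated fixture", {
  # 6 subjects, 2 groups; group A events at 1, 3; B events at 2, 4; 5, 6 censored
  a <- surv_fixture(c(1, 3, 5), c(1, 1, 0), c("A1", "A2", "A3"))
  b <- surv_fixture(c(2, 4, 6), c(1, 1, 0), c("B1", "B2", "B3"))
  # hand tabulation over event times 1..4 (O_A - E_A and variance terms):
  # t=1: nA=3,nB=3,d=1 -> E_A=0.5,  V=0.25
  # t=2: nA=2,nB=3,d=1 -> E_A=0.4,  V=0.24
  # t=3: nA=2,nB=2,d=1 -> E_A=0.5,  V=0.25
  # t=4: nA=1,nB=2,d=1 -> E_A=1/3,  V=2/9
  oa <- 2; ea <- 0.5 + 0.4 + 0.5 + 1 / 3
  v <- 0.25 + 0.24 + 0.25 + 2 / 9
  chi_ref <- (oa - ea)^2 / v
  res <- logrank_test(a, b)
  expect_lt(abs(res$chi_square - chi_ref), 1e-10)
  expect_equal(res$p_value, pchisq(chi_ref, 1, lower.tail = FALSE))

  # identical groups: chi-square 0, p = 1
  same <- logrank_test(a, a)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # label swap leaves the statistic unchanged
  sw <- logrank_test(b, a)
  expect_equal(sw$chi_square, res$chi_square, tolerance = 1e-12)

  # disjoint time ranges separate decisively
  early <- surv_fixture(seq(0.1, 2, length.out = 20), rep(1, 20),
                        paste0("E", 1:20))
  late <- surv_fixture(seq(10, 12, length.out = 20), rep(1, 20),
                       paste0("L", 1:20))
  expect_lt(logrank_test(early, late)$p_value, 0.01)

  expect_error(logrank_test(surv_fixture(1, 0), surv_fixture(2, 0)),
               "no events")
  expect_error(logrank_test(a[0, ], b), "empty")
})

test_that("log-rank type-I error is calibrated under exchangeability", {
  set.seed(137)
  rej <- 0
  nsim <- 1000
  for (s in seq_len(nsim)) {
    time <- rexp(60)
    event <- rbinom(60, 1, 0.8)
    a <- surv_fixture(time[1:30], event[1:30], paste0("A", 1:30))
    b <- surv_fixture(time[31:60], event[31:60], paste0("B", 1:30))
    rej <- rej + (logrank_test(a, b)$p_value < 0.05)
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("the full risk chain is deterministic and validates inputs", {
  set.seed(139)
  n <- 120
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(sprintf("S%03d", 1:n), paste0("f", 1:12)))
  haz <- exp(1.2 * X[, 1])
  time <- rexp(n, haz) + 1e-3
  surv <- surv_fixture(time, rep(1, n), rownames(X))
  set.seed(1)
  res <- compare_feature_sets(X, X, surv)
  expect_equal(res$p_values[["raw"]], res$p_values[["embeddings"]])
  expect_false(is.na(res$p_values[["raw"]]))
  expect_error(compare_feature_sets(X, X[, 0], surv), "empty embedding")

  strat <- risk_stratify(X, surv)
  expect_true("f1" %in% strat$selected)
  expect_identical(sum(strat$risk$group == "low") +
                     sum(strat$risk$group == "high"), as.integer(n))
  expect_lt(strat$logrank$p_value, 0.05)
  expect_gt(strat$logrank$hazard_ratio, 1)   # high-risk group dies faster
})
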