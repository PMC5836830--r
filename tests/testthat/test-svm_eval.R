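# 1-D linear-kernel toys: K = outer(x, x)
toy_svm <- function(x, y) list(K = outer(x, x), y = as.integer(y))

# KKT optimality of a fitted model on its training Gram: the dual is
# optimal iff  y_i f_i >= 1 (alpha at 0), <= 1 (alpha at C), == 1
# (free), and the signed coefficients sum to 0.
expect_kkt <- function(model, K, labels, slack = 5e-3) {
  coef <- model$dual_coefficients
  f <- as.numeric(K %*% coef) + model$bias
  yf <- labels * f
  a <- labels * coef                      # unsigned alphas
  C <- ifelse(labels == 1L, model$c_pos, model$c_neg)
  expect_true(all(a >= -1e-12 & a <= C + 1e-12))
  expect_lt(abs(sum(coef)), 1e-9)
  at0 <- a < 1e-9
  atC <- a > C - 1e-9
  free <- !at0 & !atC
  expect_true(all(yf[at0] >= 1 - slack))
  expect_true(all(yf[atC] <= 1 + slack))
  expect_true(all(abs(yf[free] - 1) <= slack))
}

test_that("svc_fit separates a separable toy and satisfies the box", {
  t <- toy_svm(c(2, 3, 2.5, -2, -3, -2.5), c(1, 1, 1, -1, -1, -1))
  model <- svc_fit(t$K, t$y, c_pos = 10, c_neg = 10)
  pred <- svc_predict(model, t$K)
  expect_identical(pred$label, t$y)
  expect_kkt(model, t$K, t$y)
})

test_that("svc_fit rejects degenerate inputs", {
  t <- toy_svm(c(1, 2), c(1, 1))
  expect_error(svc_fit(t$K, t$y, 1, 1), "single class",
               class = "pk_validation_error")
  expect_error(svc_fit(matrix(1, 2, 3), c(1L, -1L), 1, 1),
               class = "pk_validation_error")
  expect_error(svc_fit(diag(2), c(1L, -1L), 0, 1),
               class = "pk_validation_error")
})

test_that("solver satisfies KKT conditions on random asymmetric problems", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- c(rnorm(7, 1), rnorm(14, -1))
    y <- c(rep(1L, 7), rep(-1L, 14))
    K <- outer(x, x) + diag(21) * 0.1    # strictly PD
    model <- svc_fit(K, y, c_pos = 4.5, c_neg = 1.0, tol = 1e-4)
    expect_true(model$converged)
    expect_kkt(model, K, y, slack = 5e-4)
  }
})

test_that("duplicating every training example leaves decisions unchanged", {
  t <- toy_svm(c(2, 3, 2.5, -2, -3, -2.5), c(1, 1, 1, -1, -1, -1))
  m1 <- svc_fit(t$K, t$y, 10, 10, tol = 1e-6)
  idx <- rep(1:6, 2)
  m2 <- svc_fit(t$K[idx, idx], t$y[idx], 10, 10, tol = 1e-6)
  d1 <- svc_predict(m1, t$K)$decision
  d2 <- svc_predict(m2, t$K[, idx])$decision
  expect_equal(d1, d2, tolerance = 1e-3)
})

test_that("raising c_pos never lowers training recall on a fixed toy", {
  set.seed(1)
  x <- c(rnorm(8, 0.4), rnorm(16, -0.4))
  y <- c(rep(1L, 8), rep(-1L, 16))
  K <- outer(x, x)
  recalls <- vapply(c(1, 4, 16), function(cp) {
    m <- svc_fit(K, y, cp, 1)
    mean(svc_predict(m, K)$label[y == 1L] == 1L)
  }, 0)
  expect_true(all(diff(recalls) >= 0))
})

test_that("prediction uses the f >= 0 convention and checks alignment", {
  model <- structure(list(dual_coefficients = c(1, -1), bias = 0,
                          training_pair_ids = NULL,
                          c_pos = 1, c_neg = 1),
                     class = "csvc_model")
  pred <- svc_predict(model, matrix(c(1, 1), 1))  # decision exactly 0
  expect_equal(pred$decision, 0)
  expect_equal(pred$label, 1L)
  expect_error(svc_predict(model, matrix(1, 1, 3)),
               class = "pk_validation_error")
  # permuting test rows permutes outputs identically
  Kte <- matrix(c(2, 1, 0, 1, 3, 1), 3, 2)
  p1 <- svc_predict(model, Kte)
  p2 <- svc_predict(model, Kte[3:1, ])
  expect_equal(p2$decision, rev(p1$decision))
})

test_that("prf implements the conventions exactly", {
  expect_equal(unname(prf(10, 5, 10)), c(2 / 3, 1 / 2, 4 / 7))
  # equal precision and recall give F equal to both
  m <- prf(6, 2, 2)
  expect_equal(m[["f_measure"]], m[["precision"]])
  expect_equal(unname(prf(0, 0, 5)), c(0, 0, 0))
  expect_equal(unname(prf(0, 3, 0)), c(0, 0, 0))
  expect_error(prf(-1, 0, 0), class = "pk_validation_error")
})

test_that("folds are stratified partitions, deterministic in the seed", {
  labels <- c(rep(1L, 23), rep(-1L, 61))
  f1 <- make_folds(labels, 10, seed = 5)
  f2 <- make_folds(labels, 10, seed = 5)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  pos_counts <- table(f1[labels == 1L])
  expect_lte(diff(range(pos_counts)), 1)
  neg_counts <- table(f1[labels == -1L])
  expect_lte(diff(range(neg_counts)), 1)
  expect_error(make_folds(c(1L, -1L), 10, 1), "at least",
               class = "pk_validation_error")
})

test_that("cross_validate is deterministic and averages per-fold metrics", {
  sim <- simulate_heterodimers(small_sim_params(6))
  pairs <- build_examples(sim$network, sim$catalog)
  spec <- kernel_spec("scale-normalized-min", "mlpk", "dom", 0.3)
  r1 <- cross_validate(pairs, sim$network, sim$tables, spec,
                       c_pos = 4.5, c_neg = 1.0, n_folds = 5, seed = 11)
  r2 <- cross_validate(pairs, sim$network, sim$tables, spec,
                       c_pos = 4.5, c_neg = 1.0, n_folds = 5, seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$averaged$precision, mean(r1$per_fold$precision),
               tolerance = 1e-12)
  expect_equal(r1$averaged$f_measure, mean(r1$per_fold$f_measure),
               tolerance = 1e-12)
  expect_equal(sum(r1$per_fold$tp + r1$per_fold$fn), sum(pairs$label == 1L))
  expect_equal(nrow(r1$per_fold), 5L)
})

test_that("grid_search enumerates, ranks and stays monotone", {
  sim <- simulate_heterodimers(small_sim_params(9))
  pairs <- build_examples(sim$network, sim$catalog)
  spec <- kernel_spec("scale-normalized-min", "mlpk", "dom")
  g1 <- grid_search(pairs, sim$network, sim$tables, spec,
                    alpha_grid = 0.3, cpos_grid = 4.5,
                    n_folds = 5, seed = 2)
  expect_equal(nrow(g1$table), 1L)
  expect_equal(g1$best$alpha, 0.3)
  g2 <- grid_search(pairs, sim$network, sim$tables, spec,
                    alpha_grid = c(0.3, 0.6), cpos_grid = 4.5,
                    n_folds = 5, seed = 2)
  expect_equal(nrow(g2$table), 2L)
  expect_gte(g2$best$f_measure, g1$best$f_measure)
  expect_error(grid_search(pairs, sim$network, sim$tables, spec,
                           numeric(), 4.5),
               class = "pk_validation_error")
})

test_that("the grid best is at least the psi-only baseline (alpha in grid)", {
  fs <- vapply(1:3, function(seed) {
    sim <- simulate_heterodimers(small_sim_params(40 + seed))
    pairs <- build_examples(sim$network, sim$catalog)
    spec <- kernel_spec("scale-normalized-min", "mlpk", "dom")
    res <- grid_search(pairs, sim$network, sim$tables, spec,
                       alpha_grid = c(0, 0.3, 0.6), cpos_grid = 4.5,
                       n_folds = 5, seed = seed)
    base <- res$table$f_measure[res$table$alpha == 0]
    res$best$f_measure - base
  }, 0)
  expect_gte(mean(fs), 0)
})
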