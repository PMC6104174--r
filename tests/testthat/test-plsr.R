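test_that("SIMPLS at full rank equals the least-squares solution", {
  set.seed(101)
  for (i in 1:10) {
    X <- matrix(rnorm(12 * 6), 12, 6)
    y <- rnorm(12)
    fit <- fit_simpls(X, y, n_components = 6)
    ols <- ols_oracle(X, y)
    expect_lt(max(abs(fit$coefficients - ols$coefficients)), 1e-8)
    expect_lt(abs(fit$intercept - ols$intercept), 1e-8)
    expect_equal(predict(fit, X), drop(X %*% ols$coefficients) + ols$intercept,
                 tolerance = 1e-8)
  }
})

test_that("an exact single-voxel linear response is recovered by one component", {
  set.seed(5)
  x <- rnorm(20)
  X <- cbind(x, matrix(0, 20, 4))
  y <- 3 + 2 * x
  fit <- fit_simpls(X, y, n_components = 1)
  expect_equal(fit$coefficients, c(2, 0, 0, 0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$r2[1], 1, tolerance = 1e-12)
})

test_that("duplicating every trial leaves the model unchanged", {
  set.seed(8)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- rnorm(10)
  a <- fit_simpls(X, y, 3)
  b <- fit_simpls(rbind(X, X), c(y, y), 3)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-10)
  expect_equal(a$intercept, b$intercept, tolerance = 1e-10)
})

test_that("fitted-value mean equals the training-rating mean (centering identity)", {
  set.seed(31)
  for (A in c(1, 3, 5)) {
    X <- matrix(rnorm(15 * 8), 15, 8)
    y <- rnorm(15, mean = 5)
    fit <- fit_simpls(X, y, A)
    expect_equal(mean(predict(fit, X)), mean(y), tolerance = 1e-10)
  }
  # zero feature row predicts the intercept
  fit <- fit_simpls(matrix(rnorm(12 * 3), 12, 3), rnorm(12), 2)
  expect_equal(predict(fit, rep(0, 3)), fit$intercept)
})

test_that("full-rank coefficients are equivariant under column scaling", {
  set.seed(77)
  X <- matrix(rnorm(14 * 5), 14, 5)
  y <- rnorm(14)
  a <- fit_simpls(X, y, 5)
  Xs <- X
  Xs[, 3] <- 7 * X[, 3]
  b <- fit_simpls(Xs, y, 5)
  expect_equal(b$coefficients[3], a$coefficients[3] / 7, tolerance = 1e-8)
  expect_equal(b$coefficients[-3], a$coefficients[-3], tolerance = 1e-8)
})

test_that("fit_simpls rejects invalid inputs", {
  X <- matrix(rnorm(10 * 3), 10, 3)
  expect_error(fit_simpls(X, rep(1, 10), 2), "degenerate response")
  expect_error(fit_simpls(X, rnorm(10), 4), "n_components")
  expect_error(fit_simpls(X, rnorm(9), 2), "row count")
  # rank-1 features cannot support 2 components
  Xr <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_simpls(Xr, rnorm(10), 2), "rank")
  fit <- fit_simpls(X, rnorm(10), 2)
  expect_error(predict(fit, matrix(0, 2, 5)), "column count")
})

test_that("component selection follows the fitted-variance ledger", {
  # orthonormal latent scores t1, t2; X weights t1 ten-fold so the first
  # SIMPLS component captures q1^2/SSy = 101^2/(10001*2) of the response
  set.seed(12)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(16), 8, 2))))
  t1 <- Q[, 2]; t2 <- Q[, 3]
  X <- cbind(10 * t1, t2)
  y <- t1 + t2
  fit <- fit_simpls(X, y, 2)
  expect_equal(fit$r2[1], 101^2 / (10001 * 2), tolerance = 1e-10)
  expect_equal(fit$r2[2], 1, tolerance = 1e-10)
  expect_identical(select_n_components(X, y, 0.95, 5), 2L)
  expect_identical(select_n_components(X, y, 0.5, 5), 1L)
  # noise-free rank-1 signal needs one component
  x <- rnorm(12)
  expect_identical(select_n_components(cbind(x, 2 * x), 1 + x, 0.95, 5), 1L)
  # pure-noise response: threshold unreachable at the cap, warning + cap
  set.seed(3)
  Xn <- matrix(rnorm(40 * 4), 40, 4)
  yn <- rnorm(40)
  expect_warning(k <- select_n_components(Xn, yn, 0.999, 3), "cap")
  expect_identical(k, 3L)
})

test_that("group map flags planted polarity and handles degenerate voxels", {
  mk <- function(coefs) structure(list(coefficients = coefs, intercept = 0,
                                       n_components = 1, r2 = 1,
                                       individual_id = "x"),
                                  class = "plsr_model")
  set.seed(9)
  # voxel 1: strong consistent positive; voxel 2: consistent negative;
  # voxel 3: identical nonzero (zero variance); voxel 4: null noise
  C <- cbind(rnorm(12, 5, 0.5), rnorm(12, -5, 0.5), rep(2, 12), rnorm(12))
  models <- lapply(seq_len(12), function(i) mk(C[i, ]))
  expect_message(gm <- group_predictive_map(models, alpha = 0.05),
                 "zero across-individual variance")
  expect_true(gm$significant[1])
  expect_true(gm$significant[2])
  expect_identical(gm$polarity[1], "positive")
  expect_identical(gm$polarity[2], "negative")
  expect_false(gm$significant[3])  # degenerate voxel excluded
  expect_true(gm$excluded[3])
  expect_equal(gm$p_value[3], 0)
  expect_false(gm$significant[4])
  expect_true(all(gm$p_value >= 0 & gm$p_value <= 1))
  expect_error(group_predictive_map(models[1:2]), "at least 3")
})
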