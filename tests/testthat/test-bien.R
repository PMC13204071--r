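test_that("candidate generation covers the shrinkage limits", {
  X <- random_design(100, 6, seed = 1)
  y <- 3 + 2 * X[, 1] + rnorm(100)
  # penalty beyond lambda_max shrinks everything away
  expect_length(generate_candidate_set(X, y, alpha = 1, lambda = 1e6), 0L)
  # the unpenalized limit selects every non-constant column
  expect_setequal(generate_candidate_set(X, y, alpha = 0.5, lambda = 0),
                  colnames(X))
  expect_error(generate_candidate_set(X, c(y[-1], NA), 1, 1), "non-finite")
})

test_that("lasso selection matches soft-thresholding on an orthonormal design", {
  # columns centred, orthogonal, scaled so the 1/n variance is exactly 1:
  # the lasso keeps column j iff |x_j' y| / n > lambda
  n <- 64L
  set.seed(20)
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]  # orthonormal, mean 0
  X <- base * sqrt(n)
  colnames(X) <- c("a", "b", "c")
  y <- as.vector(X %*% c(5, 1, 0))
  g <- abs(crossprod(X, y)) / n  # univariate effects: 5, 1, 0
  expect_equal(as.vector(g), c(5, 1, 0), tolerance = 1e-8)
  expect_equal(generate_candidate_set(X, y, alpha = 1, lambda = 3), "a")
  expect_setequal(generate_candidate_set(X, y, alpha = 1, lambda = 0.5),
                  c("a", "b"))
})

test_that("maximum-likelihood refits agree with the normal-equations oracle", {
  for (seed in c(3, 4, 5)) {
    X <- random_design(50, 3, seed = seed)
    set.seed(seed + 100)
    y <- 1 + X %*% c(2, -1, 0.5) + rnorm(50)
    fit <- refit_mle(X, y, c("x1", "x2", "x3"))
    oracle <- ols_normal_equations(X, y, c("x1", "x2", "x3"))
    expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)
  }
  # empty subset: intercept is the mean, RSS the total sum of squares
  X <- random_design(30, 2, seed = 6); y <- rnorm(30, 5)
  f0 <- refit_mle(X, y, character())
  expect_equal(unname(f0$coefficients), mean(y))
  expect_equal(f0$rss, sum((y - mean(y))^2))
  # exact linear dependence is recovered to numerical precision
  yx <- 2 + 3 * X[, 1]
  f1 <- refit_mle(X, yx, "x1")
  expect_equal(unname(f1$coefficients["x1"]), 3, tolerance = 1e-10)
  expect_lt(f1$rss, 1e-16)
  # rank-deficient submatrices are discarded, not fatal
  Xd <- cbind(X, x3 = X[, 1])
  expect_s3_class(refit_mle(Xd, y, c("x1", "x3")), "discarded_candidate")
})

test_that("BIC scoring follows the formula with k counting the error variance", {
  X <- random_design(100, 2, seed = 7)
  y <- rnorm(100, 50, 5)
  f0 <- refit_mle(X, y, character())
  # hand arithmetic for the intercept-only Gaussian model
  sigma2 <- sum((y - mean(y))^2) / 100
  ll <- -100 / 2 * (log(2 * pi * sigma2) + 1)
  expect_equal(f0$bic, -2 * ll + 2 * log(100))
  # identical fit, one extra parameter: BIC differs by exactly log(n)
  m <- list(loglik = ll, k = 3L, n = 100L)
  expect_equal(score_bic(m) - f0$bic, log(100))
  # a better fit at equal complexity scores strictly lower
  f1 <- refit_mle(X, y, "x1")
  f2 <- refit_mle(X, y, "x2")
  better <- if (f1$rss < f2$rss) c(f1$bic, f2$bic) else c(f2$bic, f1$bic)
  expect_lt(better[1L], better[2L])
  expect_error(score_bic(list(loglik = 0, k = 2L, n = 1L)), "n > 1")
})

test_that("infinite patience reproduces an exhaustive grid evaluation", {
  X <- random_design(120, 6, seed = 8)
  set.seed(9)
  y <- 2 + 4 * X[, 2] - 3 * X[, 5] + rnorm(120)
  grid <- grid_spec(alpha = c(0.5, 1), nlambda = 12, patience = Inf)
  got <- truncated_grid_search(X, y, grid)
  # independent exhaustive evaluation over the same grid
  best_bic <- refit_mle(X, y, character())$bic
  best_sub <- character()
  for (a in grid$alpha) {
    lp <- symtraj:::.lambda_path(X, y, a, grid)
    for (l in lp) {
      s <- generate_candidate_set(X, y, a, l)
      f <- refit_mle(X, y, s)
      if (!inherits(f, "discarded_candidate") && f$bic < best_bic - 1e-9) {
        best_bic <- f$bic; best_sub <- s
      }
    }
  }
  expect_equal(got$bic, best_bic, tolerance = 1e-8)
  expect_setequal(got$subset, best_sub)
})

test_that("a strong single predictor wins the grid search", {
  X <- random_design(200, 10, seed = 10)
  set.seed(11)
  y <- 50 + 10 * X[, 4] + rnorm(200)
  best <- truncated_grid_search(X, y, grid_spec())
  expect_equal(best$subset, "x4")
})

test_that("pruning removes noise, keeps signal, and fixes points", {
  X <- random_design(500, 4, seed = 12)
  set.seed(13)
  y <- 5 + 6 * X[, 1] + rnorm(500)
  start <- refit_mle(X, y, c("x1", "x3"))  # x3 is pure noise
  pruned <- prune(start, X, y, threshold = 0.05)
  expect_equal(pruned$subset, "x1")
  expect_true(all(pruned$p_values <= 0.05))
  # already-significant models are a fixed point
  again <- prune(refit_mle(X, y, pruned$subset), X, y, 0.05)
  expect_equal(again$subset, pruned$subset)
  expect_equal(unname(again$coefficients), unname(pruned$coefficients))
  # the intercept-only model passes through unchanged
  p0 <- prune(refit_mle(X, y, character()), X, y, 0.05)
  expect_length(p0$subset, 0L)
  expect_equal(p0$intercept, mean(y))
})

test_that("the full fit is deterministic and never beats the null by less", {
  X <- random_design(150, 8, seed = 14)
  set.seed(15)
  y <- 10 + 3 * X[, 2] + rnorm(150)
  f1 <- bien_fit(X, y)
  f2 <- bien_fit(X, y)
  expect_identical(f1$subset, f2$subset)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$bic, f2$bic)
  null_bic <- refit_mle(X, y, character())$bic
  expect_lte(f1$bic, null_bic)
})

test_that("selection is equivariant to predictor rescaling", {
  X <- random_design(200, 5, seed = 16)
  set.seed(17)
  y <- 4 * X[, 3] - 2 * X[, 1] + rnorm(200)
  f <- bien_fit(X, y)
  X2 <- X; X2[, 3] <- X2[, 3] * 50
  f2 <- bien_fit(X2, y)
  expect_setequal(f2$subset, f$subset)
  expect_equal(unname(f2$coefficients["x3"]),
               unname(f$coefficients["x3"]) / 50, tolerance = 1e-6)
})

test_that("constant and duplicate columns are set aside before fitting", {
  X <- random_design(100, 3, seed = 18)
  X <- cbind(X, const = rep(2, 100), x1_copy = X[, 1])
  set.seed(19)
  y <- 3 * X[, "x1"] + rnorm(100)
  f <- bien_fit(X, y)
  expect_setequal(f$removed_columns$column, c("const", "x1_copy"))
  expect_false(any(c("const", "x1_copy") %in% f$subset))
})

test_that("pure-noise outcomes rarely admit predictors under BIC", {
  hits <- sapply(1:20, function(s) {
    X <- random_design(300, 10, seed = 200 + s)
    set.seed(400 + s)
    y <- rnorm(300, 50, 10)
    length(bien_fit(X, y)$subset)
  })
  expect_lt(mean(hits >= 1), 0.5)
  expect_lt(mean(hits), 1)
})
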