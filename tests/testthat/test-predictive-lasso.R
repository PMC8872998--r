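test_that("full shrinkage, orthonormal soft-threshold and OLS limits hold", {
  set.seed(1)
  n <- 40; p <- 5
  y <- rnorm(n)
  # lambda >= lambda_max: all zero, intercept = mean(y)
  X <- matrix(rnorm(n * p), n, p)
  lmax <- max(abs(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))) / n
  f <- lasso_fit(X, y, lmax * 1.0001)
  expect_true(all(f$coef == 0))
  expect_equal(f$intercept, mean(y))

  # orthonormal design: coefficients equal soft-thresholded OLS
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1] * sqrt(n)
  expect_equal(crossprod(Q) / n, diag(p), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (lam in c(0.02, 0.1, 0.3)) {
    fo <- lasso_fit(Q, y, lam)
    ols <- drop(crossprod(Q, y - mean(y))) / n
    soft <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_lt(max(abs(fo$coef - soft)), 1e-8)
  }

  # lambda = 0 equals least squares (normal-equations oracle)
  X2 <- matrix(rnorm(20 * 5), 20, 5)
  y2 <- rnorm(20)
  f0 <- lasso_fit(X2, y2, 0)
  bo <- solve(crossprod(cbind(1, X2)), crossprod(cbind(1, X2), y2))
  expect_lt(max(abs(c(f0$intercept, f0$coef) - bo) / max(abs(bo))), 1e-6)

  X2[, 3] <- 7
  expect_error(lasso_fit(X2, y2, 0.1), "zero-variance")
})

test_that("homotopy and coordinate descent agree across random designs", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(15:50, 1); p <- sample(3:60, 1)
    X <- matrix(rnorm(n * p), n, p)
    if (p > 2) X[, 1] <- X[, 2] + rnorm(n, 0, 0.05)
    y <- rnorm(n)
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    lmax <- max(abs(crossprod(Xc, yc))) / n
    g <- exp(seq(log(lmax), log(lmax * 0.001), length.out = 40))
    bh <- slopekit:::.lasso_homotopy_path(Xc, yc, g)
    bc <- slopekit:::.cd_lasso_path(Xc, yc, g, 1e-9, 300000L, FALSE)$beta
    # where they differ the homotopy objective must not be worse
    obj <- function(b, lam) sum((yc - Xc %*% b)^2) / (2 * n) + lam * sum(abs(b))
    for (l in seq_along(g)) {
      d <- max(abs(bh[, l] - bc[, l]))
      if (d > 1e-6)
        expect_lte(obj(bh[, l], g[l]), obj(bc[, l], g[l]) + 1e-10)
      else expect_lt(d, 1e-6)
    }
  }
})

test_that("coordinate-descent objective is non-increasing across sweeps", {
  set.seed(3)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rnorm(30)
  tr <- slopekit:::lasso_path_coefs(X, y, lambda_grid(X, y, 20),
                                    trace_objective = TRUE)$objective
  for (o in tr) if (length(o) > 1) expect_true(all(diff(o) <= 1e-12))
})

test_that("sparsity is monotone in lambda on orthogonal designs", {
  set.seed(4)
  n <- 64
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 10), n, 10))))[, -1] * sqrt(n)
  y <- drop(Q[, 1:3] %*% c(3, -2, 1)) + rnorm(n)
  g <- lambda_grid(Q, y)
  b <- slopekit:::lasso_path_coefs(Q, y, g)$beta
  nnz <- colSums(b != 0)
  expect_true(all(diff(nnz) >= 0))   # grid is decreasing in lambda
})

test_that("inner CV selection matches a brute-force fold-by-grid oracle", {
  set.seed(5)
  n <- 40; p <- 8
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- drop(X[, 1] * 2) + rnorm(n)
  g <- lambda_grid(X, y, n_lambda = 25)
  sel <- inner_cv_lambda(X, y, k = 5, grid = g, seed = 11)
  # oracle: refit every fold x grid cell with lasso_fit (the CD solver)
  cvm <- sapply(g, function(lam) {
    mean(vapply(1:5, function(f) {
      tr <- sel$foldid != f
      fit <- lasso_fit(X[tr, ], y[tr], lam)
      mean((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
    }, numeric(1)))
  })
  expect_equal(sel$lambda, g[which.min(cvm)])
  expect_lt(max(abs(sel$cv_mse - cvm)), 1e-6)
  # single-element grid returns that element
  expect_equal(inner_cv_lambda(X, y, k = 5, grid = 0.3, seed = 1)$lambda, 0.3)
  expect_error(inner_cv_lambda(X, y, k = 5, grid = numeric(0)), "empty")
})

test_that("a strong predictor survives selection and prioritization", {
  hits_cv <- hits_pri <- logical(100)
  for (s in 1:100) {
    set.seed(300 + s)
    n <- 100; p <- 21
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- 5 * X[, 1] + rnorm(n)
    sel <- inner_cv_lambda(X, y, k = 10, seed = s)
    fit <- lasso_fit(X, y, sel$lambda)
    hits_cv[s] <- fit$coef["f1"] != 0
    pri <- prioritize_features(X, y, seed = s)
    hits_pri[s] <- "f1" %in% pri$features
  }
  expect_gte(mean(hits_cv), 0.95)
  expect_gte(mean(hits_pri), 0.95)
})

test_that("noiseless recoverable signal gives near-perfect LOOCV", {
  set.seed(6)
  n <- 24; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:2] %*% c(2, -1))
  g <- lambda_grid(X, y, n_lambda = 60, min_ratio = 1e-6)
  cv <- loocv_predict(X, y, grid = g, k_inner = 8, seed = 1)
  expect_lt(cv$mse, 1e-4 * var(y))
  expect_gt(cv$r2, 0.99)
})

test_that("the held-out subject's outcome never leaks into its prediction", {
  set.seed(7)
  n <- 20; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  cov <- balanced_covariates(n, seed = 7)
  y <- drop(X[, 1]) + rnorm(n)
  cv1 <- loocv_predict(X, y, covariates = cov, k_inner = 5, seed = 3)
  for (i in c(1, 11)) {
    y2 <- y
    y2[i] <- 1e3   # absurd outcome for the held-out subject
    cv2 <- loocv_predict(X, y2, covariates = cov, k_inner = 5, seed = 3)
    expect_equal(cv2$predictions[i], cv1$predictions[i], tolerance = 1e-10)
  }
})

test_that("fused LOOCV equals the plain-R fold-by-fold recomputation", {
  set.seed(8)
  n <- 16; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  cov <- balanced_covariates(n, seed = 8)
  y <- drop(X[, 2]) + rnorm(n)
  cv_c <- loocv_predict(X, y, covariates = cov, k_inner = 4, seed = 5)
  # R-route oracle replicating per-fold grids, selection and fitting
  preds <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ff <- slopekit:::fold_features(X, cov, tr, i)
    gi <- lambda_grid(ff$train, y[tr])
    sel <- inner_cv_lambda(ff$train, y[tr], k = 4, grid = gi, seed = 5 + i)
    upto <- seq_len(which(gi == sel$lambda)[1])
    b <- slopekit:::lasso_path_coefs(ff$train, y[tr], gi[upto])$beta[, length(upto)]
    b0 <- mean(y[tr]) - sum(colMeans(ff$train) * b)
    preds[i] <- b0 + sum(ff$test[1, ] * b)
  }
  expect_equal(cv_c$predictions, preds, tolerance = 1e-8)
})

test_that("permuted outcomes destroy cross-validated skill", {
  r2 <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 30; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, 1]) + rnorm(n, 0, 0.5)
    yp <- y[sample.int(n)]
    loocv_predict(X, yp, k_inner = 5, seed = s)$r2
  }, numeric(1))
  expect_lte(median(r2), 0.05)
})

test_that("squared-correlation R2 option is wired through", {
  set.seed(11)
  n <- 14; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1]) + rnorm(n, 0, 0.2)
  a <- loocv_predict(X, y, k_inner = 5, seed = 2)
  b <- loocv_predict(X, y, k_inner = 5, seed = 2, r2_method = "cor2")
  expect_identical(a$predictions, b$predictions)
  expect_equal(b$r2, cor(y, b$predictions)^2)
})

test_that("loocv input contracts", {
  X <- matrix(rnorm(50), 5, 10)
  expect_error(loocv_predict(X, rnorm(5)), "n >= 10")
  X2 <- matrix(rnorm(120), 12, 10)
  expect_error(loocv_predict(X2, rep(1, 12)), "constant outcome")
})

test_that("permutation null respects its defining identity and seeds", {
  set.seed(9)
  n <- 14; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  pm <- permutation_test_mse(X, y, B = 30, k_inner = 5, seed = 6)
  expect_equal(pm$p, (1 + sum(pm$null_mses <= pm$observed_mse)) / (pm$B + 1))
  expect_gt(pm$p, 0)
  expect_lte(pm$p, 1)
  pm2 <- permutation_test_mse(X, y, B = 30, k_inner = 5, seed = 6)
  expect_identical(pm$null_mses, pm2$null_mses)
  expect_error(permutation_test_mse(X, y, B = 0), "B >= 1")
  # maximal p when the observed statistic is worst-case
  expect_equal(slopekit:::perm_pvalue(5, c(1, 2, 3), larger_is_extreme = FALSE),
               1)
})

test_that("prioritization at lambda_max returns the empty set", {
  set.seed(10)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  Xs <- scale(X)
  lmax <- max(abs(crossprod(sweep(Xs, 2, colMeans(Xs)), y - mean(y)))) / 30
  pri <- prioritize_features(X, y, grid = lmax * 1.001, k = 5, seed = 1)
  expect_length(pri$features, 0)
})
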