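#' Lambda grid for a LASSO path
#'
#' Log-spaced sequence of `n_lambda` penalties from `lambda_max` (the
#' smallest penalty at which every coefficient is exactly zero,
#' `max_j |x_j' (y - mean(y))| / n` after column centering) down to
#' `min_ratio * lambda_max`.
#'
#' @param X n x p feature matrix.
#' @param y outcome vector.
#' @param n_lambda grid length (default 100).
#' @param min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.001).
#' @return decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, n_lambda = 100, min_ratio = 0.001) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xc, yc))) / n
  if (!is.finite(lmax) || lmax <= 0)
    stop("lambda_max is not positive; features carry no signal at all")
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit a LASSO model at a fixed penalty
#'
#' Minimizes `(1/2n) * sum((y - b0 - X b)^2) + lambda * sum(|b|)` by cyclic
#' coordinate descent with an unpenalized intercept, converged when the
#' largest coefficient change in a sweep drops below `tol`. At
#' `lambda >= lambda_max` every coefficient is exactly zero and the
#' intercept is `mean(y)`.
#'
#' @param X n x p feature matrix; columns must have positive variance
#'   (standardize beforehand if coefficients should be comparable).
#' @param y outcome vector.
#' @param lambda penalty weight, `>= 0`.
#' @param tol coordinate-descent convergence tolerance (default 1e-7).
#' @param maxit maximum sweeps per penalty.
#' @return object of class `lasso_model`: `lambda`, `intercept`, `coef`
#'   (named, sparse in the sense that most entries are exactly 0).
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-7, maxit = 100000L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(lambda) == 1, lambda >= 0)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature column(s): ",
         paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  yc <- y - mean(y)
  fit <- .cd_lasso_path(Xc, yc, as.numeric(lambda), tol, as.integer(maxit),
                        FALSE)
  b <- drop(fit$beta)
  names(b) <- colnames(X)
  structure(list(lambda = lambda, intercept = mean(y) - sum(ctr * b),
                 coef = b),
            class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  drop(object$intercept + newx %*% object$coef)
}

#' @export
print.lasso_model <- function(x, ...) {
  cat("lasso_model: lambda =", signif(x$lambda, 4), ";",
      sum(x$coef != 0), "of", length(x$coef), "nonzero coefficients\n")
  invisible(x)
}

# exact path via lambda-homotopy; returns list(beta = p x L matrix).
# trace_objective switches to the coordinate-descent solver, which records
# its objective after every sweep (used by the monotonicity checks).
lasso_path_coefs <- function(X, y, lambda, tol = 1e-7, maxit = 100000L,
                             trace_objective = FALSE) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  yc <- y - mean(y)
  lambda <- as.numeric(lambda)
  if (trace_objective)
    return(.cd_lasso_path(Xc, yc, lambda, tol, as.integer(maxit), TRUE))
  list(beta = .lasso_homotopy_path(Xc, yc, lambda, tol, as.integer(maxit)))
}

#' Select the penalty by k-fold cross-validation
#'
#' Splits the samples into `k` seeded folds, fits the full penalty path on
#' each training part, and returns the grid value minimizing the mean
#' held-out squared error across folds (ties broken toward the larger
#' penalty).
#'
#' @param X n x p feature matrix (already on its final scale).
#' @param y outcome vector.
#' @param k number of folds (default 10).
#' @param grid decreasing penalty sequence; defaults to [lambda_grid()].
#' @param seed integer seed for the fold assignment.
#' @param tol,maxit passed to the coordinate-descent solver.
#' @return list: `lambda` (chosen), `cv_mse` (per grid value), `grid`,
#'   `foldid`.
#' @export
inner_cv_lambda <- function(X, y, k = 10, grid = NULL, seed = 1L,
                            tol = 1e-7, maxit = 100000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= k, k >= 2)
  if (is.null(grid)) grid <- lambda_grid(X, y)
  if (!length(grid)) stop("empty lambda grid")
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  set.seed(seed)
  foldid <- sample(rep(seq_len(k), length.out = n))
  fold_mse <- .cd_lasso_cv_mse(X, y, as.integer(foldid), as.integer(k),
                               grid, tol, as.integer(maxit))
  cv_mse <- colMeans(fold_mse)
  list(lambda = grid[which.min(cv_mse)], cv_mse = cv_mse, grid = grid,
       foldid = foldid)
}

# standardize columns by train statistics; drop (near-)constant columns
standardize_train <- function(Xtr, Xte = NULL) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  keep <- which(scl > 1e-12)
  Xtr_s <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, ctr[keep]), 2,
                 scl[keep], "/")
  out <- list(train = Xtr_s, keep = keep, center = ctr, scale = scl)
  if (!is.null(Xte))
    out$test <- sweep(sweep(Xte[, keep, drop = FALSE], 2, ctr[keep]), 2,
                      scl[keep], "/")
  out
}

# per-fold preprocessing: residualize on train, apply to test, standardize
fold_features <- function(X, covariates, train, test) {
  Xtr <- X[train, , drop = FALSE]
  Xte <- X[test, , drop = FALSE]
  if (!is.null(covariates)) {
    res <- residualize_covariates(t(Xtr), covariates[train, , drop = FALSE],
                                  t(Xte), covariates[test, , drop = FALSE])
    Xtr <- t(res$train)
    Xte <- t(res$test)
  }
  standardize_train(Xtr, Xte)
}

#' Leave-one-out cross-validated LASSO prediction of treatment slopes
#'
#' For each subject i: nuisance covariates (batch, sex, RIN) are
#' residualized out of the features with a model fit on the other n-1
#' subjects only, features are standardized on those subjects, the penalty
#' is chosen by an inner k-fold cross-validation, a LASSO is fit, and
#' subject i is predicted. Nothing about subject i's outcome or covariates
#' touches the model that predicts it.
#'
#' @param X n x p feature matrix (subjects in rows; raw scale).
#' @param y numeric outcome (treatment slopes).
#' @param covariates optional data.frame (rows = subjects) with `batch`,
#'   `sex`, `rin` columns for in-fold residualization; `NULL` skips it.
#' @param grid fixed penalty sequence; `NULL` (default) recomputes
#'   [lambda_grid()] on every training fold.
#' @param n_lambda,lambda_min_ratio grid shape when `grid` is `NULL`.
#' @param k_inner inner CV folds (default 10).
#' @param seed master seed; fold i's inner CV uses `seed + i`.
#' @param r2_method `"one_minus_sse"` (default; `1 - SSE/SST`, may be
#'   negative) or `"cor2"` (squared Pearson correlation).
#' @return object of class `cv_result`: `predictions`, `per_fold_lambda`,
#'   `mse`, `r2`, `r2_method`, `seed`.
#' @export
loocv_predict <- function(X, y, covariates = NULL, grid = NULL,
                          n_lambda = 100, lambda_min_ratio = 0.001,
                          k_inner = 10, seed = 1L,
                          r2_method = c("one_minus_sse", "cor2")) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 10)
  r2_method <- match.arg(r2_method)
  if (stats::sd(y) == 0)
    stop("constant outcome: cross-validated R^2 is undefined")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  if (!is.null(grid))
    return(loocv_predict_r(X, y, covariates, grid, k_inner, seed,
                           r2_method))
  D <- if (is.null(covariates)) matrix(numeric(0), n, 0)
       else covariate_design(covariates)
  # inner fold assignments, one column per outer fold, seeded at seed + i
  foldids <- vapply(seq_len(n), function(i) {
    set.seed(seed + i)
    sample(rep(seq_len(k_inner), length.out = n - 1))
  }, integer(n - 1))
  res <- .loocv_lasso(X, y, D, foldids, as.integer(k_inner),
                      as.integer(n_lambda), lambda_min_ratio)
  preds <- res$predictions
  lam <- res$per_fold_lambda
  mse <- mean((y - preds)^2)
  r2 <- if (r2_method == "one_minus_sse")
    1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  else suppressWarnings(stats::cor(y, preds))^2
  if (!is.finite(r2)) r2 <- 0
  structure(list(predictions = preds, per_fold_lambda = lam, mse = mse,
                 r2 = r2, r2_method = r2_method, seed = seed),
            class = "cv_result")
}

# plain-R outer loop, used when the caller pins the lambda grid; fold
# mechanics identical to the fused C++ route
loocv_predict_r <- function(X, y, covariates, grid, k_inner, seed,
                            r2_method) {
  n <- nrow(X)
  g <- sort(as.numeric(grid), decreasing = TRUE)
  preds <- numeric(n)
  lam <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    ff <- fold_features(X, covariates, train, i)
    ytr <- y[train]
    sel <- inner_cv_lambda(ff$train, ytr, k = k_inner, grid = g,
                           seed = seed + i)
    upto <- seq_len(which(g == sel$lambda)[1])
    beta <- lasso_path_coefs(ff$train, ytr, g[upto])$beta
    b <- beta[, length(upto)]
    b0 <- mean(ytr) - sum(colMeans(ff$train) * b)
    preds[i] <- b0 + sum(ff$test[1, ] * b)
    lam[i] <- sel$lambda
  }
  mse <- mean((y - preds)^2)
  r2 <- if (r2_method == "one_minus_sse")
    1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  else suppressWarnings(stats::cor(y, preds))^2
  if (!is.finite(r2)) r2 <- 0
  structure(list(predictions = preds, per_fold_lambda = lam, mse = mse,
                 r2 = r2, r2_method = r2_method, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (LOOCV): n =", length(x$predictions),
      "; MSE =", signif(x$mse, 4), "; R^2 =", signif(x$r2, 3), "\n")
  invisible(x)
}

#' Permutation-null significance of the cross-validated MSE
#'
#' Reruns the complete leave-one-out pipeline — in-fold residualization,
#' standardization, inner penalty selection, fitting, prediction — on `B`
#' label-shuffled copies of the outcome and compares the observed MSE with
#' the null distribution:
#' `p = (1 + #\{null MSE <= observed MSE\}) / (B + 1)`. When the observed
#' model beats every one of B = 1000 nulls, p attains its floor
#' 1/1001 = 9.99e-4. Shuffling happens on the raw outcome before any
#' fitting, so the null replicates see exactly the pipeline the observed
#' statistic saw.
#'
#' @inheritParams loocv_predict
#' @param B number of permutations (default 1000).
#' @return object of class `permutation_null`: `observed_mse`, `null_mses`,
#'   `p`, `B`, `seed`, plus the observed `cv_result` as `observed_fit`.
#' @export
permutation_test_mse <- function(X, y, covariates = NULL, grid = NULL,
                                 B = 1000, seed = 1L, ...) {
  stopifnot(B >= 1)
  obs <- loocv_predict(X, y, covariates = covariates, grid = grid,
                       seed = seed, ...)
  n <- length(y)
  set.seed(seed)
  perms <- replicate(B, sample.int(n))
  null_mses <- vapply(seq_len(B), function(b) {
    loocv_predict(X, y[perms[, b]], covariates = covariates, grid = grid,
                  seed = seed + b, ...)$mse
  }, numeric(1))
  structure(list(observed_mse = obs$mse, null_mses = null_mses,
                 p = perm_pvalue(obs$mse, null_mses,
                                 larger_is_extreme = FALSE),
                 B = B, seed = seed, observed_fit = obs),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null: observed MSE =", signif(x$observed_mse, 4),
      "; p =", signif(x$p, 4), "(B =", x$B, ")\n")
  invisible(x)
}

#' Prioritize predictive features with a full-data LASSO refit
#'
#' Residualizes nuisance covariates and standardizes features on ALL
#' subjects, selects the penalty by k-fold cross-validation, fits once,
#' and returns the features with nonzero coefficients — the "treatment
#' relevant" set. As a diagnostic, also reports how often each returned
#' feature was selected across the leave-one-out refits when
#' `loo_frequency = TRUE`.
#'
#' @inheritParams loocv_predict
#' @param k folds for the penalty selection (default 10).
#' @param loo_frequency also compute per-feature selection frequency over
#'   leave-one-out refits (slower; default FALSE).
#' @return object of class `prioritized_set`: `features` (ids), `weights`
#'   (standardized-scale coefficients), `lambda`, optionally
#'   `loo_frequency`.
#' @export
prioritize_features <- function(X, y, covariates = NULL, grid = NULL,
                                k = 10, seed = 1L, loo_frequency = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  all_i <- seq_len(n)
  ff <- fold_features(X, covariates, all_i, all_i)
  g <- if (is.null(grid)) lambda_grid(ff$train, y)
       else sort(as.numeric(grid), decreasing = TRUE)
  sel <- inner_cv_lambda(ff$train, y, k = k, grid = g, seed = seed)
  upto <- seq_len(which(g == sel$lambda)[1])
  beta <- lasso_path_coefs(ff$train, y, g[upto])$beta
  b <- beta[, length(upto)]
  names(b) <- colnames(ff$train)
  nz <- which(b != 0)
  freq <- NULL
  if (loo_frequency) {
    cnt <- integer(ncol(X))
    names(cnt) <- colnames(X)
    for (i in all_i) {
      tr <- setdiff(all_i, i)
      ffi <- fold_features(X, covariates, tr, i)
      gi <- if (is.null(grid)) lambda_grid(ffi$train, y[tr])
            else g
      si <- inner_cv_lambda(ffi$train, y[tr], k = k, grid = gi,
                            seed = seed + i)
      ui <- seq_len(which(gi == si$lambda)[1])
      bi <- lasso_path_coefs(ffi$train, y[tr], gi[ui])$beta[, length(ui)]
      cnt[colnames(ffi$train)[bi != 0]] <-
        cnt[colnames(ffi$train)[bi != 0]] + 1L
    }
    freq <- cnt / n
  }
  structure(list(features = names(b)[nz], weights = b[nz],
                 lambda = sel$lambda, loo_frequency = freq),
            class = "prioritized_set")
}

#' @export
print.prioritized_set <- function(x, ...) {
  cat("prioritized_set:", length(x$features),
      "features with nonzero weight at lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}
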