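#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same distribution: the
#' reference distribution is the across-sample mean of the sorted columns,
#' and each column's values are replaced by the reference value at their
#' rank. Ties receive the average of the reference values across the tied
#' ranks, so the operation is idempotent.
#'
#' @param m numeric matrix, probes x samples (log2 intensities).
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1) stop("need at least one sample")
  if (any(!is.finite(m))) stop("expression matrix must be finite")
  ref <- rowMeans(matrix(apply(m, 2, sort), nrow(m), ncol(m)))
  out <- matrix(apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  }), nrow(m), ncol(m))
  dimnames(out) <- dimnames(m)
  out
}

#' Keep the most variable probes
#'
#' Retains the `ceiling(keep_fraction * n_probes)` probes with the highest
#' row variance (denominator n-1), preserving the original probe order
#' among survivors. With the conventional 50% filter a 20,194-probe matrix
#' keeps exactly 10,097 probes.
#'
#' @param m numeric matrix, probes x samples.
#' @param keep_fraction proportion of probes to keep, in (0, 1].
#' @return the filtered matrix.
#' @export
variance_filter <- function(m, keep_fraction = 0.5) {
  m <- as.matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix")
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must lie in (0, 1]")
  k <- ceiling(keep_fraction * nrow(m))
  v <- apply(m, 1, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(k)])
  m[keep, , drop = FALSE]
}

#' Remove batch, sex and RIN variance with a train-fit / test-apply model
#'
#' For every probe, fits expression ~ intercept + batch + sex + RIN by least
#' squares on the TRAINING samples only, then subtracts the fitted values
#' from both training and test samples. No information from the test set
#' influences the fit, so the operation is safe inside cross-validation
#' folds. Training residuals are exactly orthogonal to the training design.
#'
#' @param train probes x training-samples matrix.
#' @param train_cov data.frame with rows aligned to `train` columns;
#'   columns `batch`, `sex` (categorical) and `rin` (numeric); any subset
#'   of these is accepted.
#' @param test optional probes x test-samples matrix (same probes).
#' @param test_cov covariates for `test`, same columns as `train_cov`;
#'   categorical levels must already occur in training.
#' @return list with `train` and (if given) `test` residual matrices.
#' @export
residualize_covariates <- function(train, train_cov, test = NULL,
                                   test_cov = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train_cov) == ncol(train))
  des <- covariate_design(train_cov)
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (is.null(test_cov) || nrow(test_cov) != ncol(test))
      stop("test covariates must align with test samples")
    for (v in intersect(c("batch", "sex"), names(train_cov))) {
      bad <- setdiff(unique(as.character(test_cov[[v]])),
                     unique(as.character(train_cov[[v]])))
      if (length(bad))
        stop("test ", v, " level(s) unseen in training: ",
             paste(bad, collapse = ", "))
    }
    des_test <- covariate_design(test_cov, levels_from = train_cov)
  }
  q <- qr(des)
  if (q$rank < ncol(des))
    stop("covariate design is rank deficient on training samples")
  # coefficients for all probes at once: (probes x q) via QR on the design
  coefs <- t(qr.coef(q, t(train)))
  train_resid <- train - coefs %*% t(des)
  out <- list(train = train_resid)
  if (!is.null(test)) out$test <- test - coefs %*% t(des_test)
  out
}

# intercept + batch dummies + sex dummy + rin, with training-anchored levels
covariate_design <- function(cov, levels_from = NULL) {
  n <- nrow(cov)
  des <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  anchor <- if (is.null(levels_from)) cov else levels_from
  for (v in intersect(c("batch", "sex"), names(cov))) {
    lev <- sort(unique(as.character(anchor[[v]])))
    f <- factor(as.character(cov[[v]]), levels = lev)
    if (length(lev) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, lev[-1])
      des <- cbind(des, mm)
    }
  }
  if ("rin" %in% names(cov)) {
    if (any(cov$rin < 0)) stop("rin must be non-negative")
    des <- cbind(des, rin = as.numeric(cov$rin))
  }
  des
}
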