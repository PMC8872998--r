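#' Fit a random-intercept / random-slope linear mixed model
#'
#' Fits `outcome ~ <fixed terms> + (slope_var | subject)` by REML and returns
#' the pieces downstream stages need: fixed effects, the unstructured 2x2
#' random-effect covariance, residual variance, per-subject BLUP deviations
#' (computed from Henderson's mixed-model equations at the estimates),
#' Wald F tests per fixed term with containment denominator degrees of
#' freedom, and the REML log-likelihood.
#'
#' Variance components may instead be supplied through `vc`, in which case no
#' REML optimization is run: `vc = list(G = <2x2>, sigma2 = <scalar>)` fixes
#' both and the fixed effects are the exact generalized-least-squares
#' solution; `vc = list(G = <2x2>, sigma2 = NULL)` interprets `G` relative to
#' the residual variance (marginal covariance `sigma2 * (Z G Z' + I)`), so
#' the GLS coefficients are scale-free and `sigma2` is estimated by the
#' REML-type quotient with `N - p` degrees of freedom. With `G = 0` this
#' reproduces ordinary least squares.
#'
#' @param data data.frame with one row per visit.
#' @param fixed fixed-effects formula, e.g. `outcome ~ age`.
#' @param subject name of the subject-id column.
#' @param slope_var name of the visit-level variable carrying the random
#'   slope (default `"age"`); must appear in `data`.
#' @param vc optional fixed variance components (see Details).
#' @return object of class `lmm_fit` with elements `beta`, `G`, `sigma2`,
#'   `blups` (subjects x 2 matrix of intercept/slope deviations),
#'   `reml_loglik`, `fixed_tests` (data.frame: term, F, df1, df2, p),
#'   `vcov_beta`, `slope_var`, `subjects`, `converged`.
#' @export
fit_lmm <- function(data, fixed = outcome ~ age, subject = "subject_id",
                    slope_var = "age", vc = NULL) {
  stopifnot(is.data.frame(data), subject %in% names(data),
            slope_var %in% names(data))
  yvar <- all.vars(fixed)[1]
  if (!yvar %in% names(data)) stop("outcome variable not found in data")
  if (any(!is.finite(data[[slope_var]])))
    stop("slope variable must be finite")
  sid <- as.character(data[[subject]])
  usub <- unique(sid)
  if (length(usub) < 2) stop("need >= 2 subjects")

  X <- stats::model.matrix(fixed, data)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient")
  y <- data[[yvar]]
  idx <- split(seq_along(y), factor(sid, levels = usub))

  if (is.null(vc)) {
    f <- stats::as.formula(paste(paste(deparse(fixed), collapse = " "),
                                 "+ (", slope_var, "| .subj.)"))
    d2 <- data
    d2$.subj. <- sid
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(f, data = d2, REML = TRUE,
                          control = lme4::lmerControl(calc.derivs = FALSE)),
               error = function(e) stop("mixed-model fit failed: ",
                                        conditionMessage(e), call. = FALSE)),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
    vcl <- lme4::VarCorr(fit)
    G <- as.matrix(vcl$.subj.)[1:2, 1:2]
    dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
    sigma2 <- stats::sigma(fit)^2
    beta <- lme4::fixef(fit)
    reml_ll <- as.numeric(stats::logLik(fit))
    converged <- TRUE
  } else {
    G <- as.matrix(vc$G)
    stopifnot(nrow(G) == 2, ncol(G) == 2)
    dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
    if (is.null(vc$sigma2)) {
      gls <- lmm_gls(X, y, data[[slope_var]], idx, G, 1)
      p <- ncol(X)
      sigma2 <- gls$quad / (length(y) - p)
      beta <- gls$beta
      reml_ll <- NA_real_
    } else {
      sigma2 <- vc$sigma2
      gls <- lmm_gls(X, y, data[[slope_var]], idx, G, sigma2)
      beta <- gls$beta
      reml_ll <- NA_real_
    }
    converged <- TRUE
  }

  # BLUPs and beta covariance from own per-subject GLS/Henderson pass
  gls <- lmm_gls(X, y, data[[slope_var]], idx, G, sigma2, beta = beta)
  blups <- gls$blups
  rownames(blups) <- usub
  colnames(blups) <- c("intercept", "slope")
  vb <- gls$vcov_beta
  dimnames(vb) <- list(colnames(X), colnames(X))

  ft <- wald_fixed_tests(X, beta, vb, fixed, data, sid)

  structure(list(beta = beta, G = G, sigma2 = sigma2, blups = blups,
                 reml_loglik = reml_ll, fixed_tests = ft, vcov_beta = vb,
                 slope_var = slope_var, subjects = usub,
                 converged = converged),
            class = "lmm_fit")
}

# Per-subject GLS accumulation and Henderson BLUPs.
# V_i = Z_i G Z_i' + sigma2 I with Z_i = [1, t_i]. Returns beta (unless
# given), its covariance, BLUPs b_i = G Z_i' V_i^-1 (y_i - X_i beta), and
# the GLS quadratic form of residuals.
lmm_gls <- function(X, y, tvar, idx, G, sigma2, beta = NULL) {
  p <- ncol(X)
  A <- matrix(0, p, p); bvec <- numeric(p)
  Vinv_list <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    Z <- cbind(1, tvar[i])
    V <- Z %*% G %*% t(Z) + diag(sigma2, length(i))
    Vi <- solve(V)
    Vinv_list[[k]] <- Vi
    A <- A + crossprod(X[i, , drop = FALSE], Vi %*% X[i, , drop = FALSE])
    bvec <- bvec + crossprod(X[i, , drop = FALSE], Vi %*% y[i])
  }
  vcov_beta <- solve(A)
  if (is.null(beta)) beta <- drop(vcov_beta %*% bvec)
  names(beta) <- colnames(X)
  blups <- matrix(0, length(idx), 2)
  quad <- 0
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    Z <- cbind(1, tvar[i])
    r <- y[i] - X[i, , drop = FALSE] %*% beta
    blups[k, ] <- drop(G %*% t(Z) %*% Vinv_list[[k]] %*% r)
    quad <- quad + drop(crossprod(r, Vinv_list[[k]] %*% r))
  }
  list(beta = beta, vcov_beta = vcov_beta, blups = blups, quad = quad)
}

# Wald F per fixed-effect term with containment denominator df:
# terms constant within subject get n_subjects - 1 - n_between columns,
# visit-varying terms get N - n_subjects - n_within columns.
wald_fixed_tests <- function(X, beta, vcov_beta, fixed, data, sid) {
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fixed), "term.labels")
  if (!length(labels)) {
    return(data.frame(term = character(), F = numeric(), df1 = numeric(),
                      df2 = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  nsub <- length(unique(sid))
  N <- nrow(X)
  col_between <- vapply(seq_len(ncol(X)), function(j) {
    all(tapply(X[, j], sid, function(v) max(v) - min(v)) <= 1e-12)
  }, logical(1))
  term_between <- vapply(seq_along(labels), function(t)
    all(col_between[asgn == t]), logical(1))
  n_bet <- sum(col_between & asgn > 0)
  n_wit <- sum(!col_between & asgn > 0)
  df2_between <- max(1, nsub - 1 - n_bet)
  df2_within <- max(1, N - nsub - n_wit)
  rows <- lapply(seq_along(labels), function(t) {
    j <- which(asgn == t)
    Lb <- beta[j]
    Fi <- drop(crossprod(Lb, solve(vcov_beta[j, j, drop = FALSE], Lb))) /
      length(j)
    df2 <- if (term_between[t]) df2_between else df2_within
    data.frame(term = labels[t], F = Fi, df1 = length(j), df2 = df2,
               p = stats::pf(Fi, length(j), df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit:", length(x$subjects), "subjects; sigma2 =",
      signif(x$sigma2, 4), "\n")
  cat("fixed effects:\n"); print(signif(x$beta, 5))
  cat("random-effect SDs:", signif(sqrt(diag(x$G)), 4), "\n")
  if (nrow(x$fixed_tests)) { cat("Wald F tests:\n"); print(x$fixed_tests) }
  invisible(x)
}

#' Extract per-subject treatment slopes from a mixed-model fit
#'
#' Treatment slope of subject i is the fixed slope coefficient plus the
#' subject's BLUP slope deviation — a total growth rate (units/month), not a
#' deviation from the population mean.
#'
#' @param fit an [fit_lmm()] result.
#' @return data.frame with columns `subject_id`, `slope`.
#' @export
extract_treatment_slopes <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  fx <- fit$beta[fit$slope_var]
  if (is.na(fx)) stop("no fixed coefficient named '", fit$slope_var, "'")
  data.frame(subject_id = fit$subjects,
             slope = as.numeric(fx) + fit$blups[, "slope"],
             stringsAsFactors = FALSE)
}

#' Fit the early-vs-late treatment-start group model
#'
#' Models the outcome as a function of treatment-start group (early = start
#' before `cutoff` months), age, their interaction, days in treatment,
#' weekly treatment hours and (when available) the pre-treatment Mullen
#' Early Learning Composite, with subject-specific random intercepts and age
#' slopes. Age is centered at `cutoff` months for numerical conditioning;
#' this changes no test statistic.
#'
#' @param visits data.frame: `subject_id`, `age`, `outcome`.
#' @param subjects data.frame with `subject_id`, `age_start`, and optionally
#'   `days_in_treatment`, `hours_week`.
#' @param clinical optional data.frame with `subject_id` and `msel_elc`.
#' @param cutoff months defining the early/late split (default 24).
#' @param vc optional fixed variance components, passed to [fit_lmm()].
#' @return an `lmm_fit`; `fixed_tests` includes the group main effect and
#'   the age-by-group interaction.
#' @export
fit_group_model <- function(visits, subjects, clinical = NULL, cutoff = 24,
                            vc = NULL) {
  d <- merge(visits, subjects, by = "subject_id")
  if (!is.null(clinical))
    d <- merge(d, clinical[, intersect(c("subject_id", "msel_elc"),
                                       names(clinical)), drop = FALSE],
               by = "subject_id")
  d$group <- factor(ifelse(d$age_start < cutoff, "early", "late"),
                    levels = c("early", "late"))
  if (length(unique(d$group)) < 2)
    stop("both start groups must be non-empty")
  d$age_c <- d$age - cutoff
  extra <- intersect(c("days_in_treatment", "hours_week", "msel_elc"),
                     names(d))
  f <- stats::as.formula(paste("outcome ~ group * age_c",
                               paste(c("", extra), collapse = " + ")))
  fit_lmm(d, fixed = f, subject = "subject_id", slope_var = "age_c", vc = vc)
}

#' Permutation test for a group difference in slope variability
#'
#' Tests whether treatment slopes are more variable among late starters than
#' early starters. The observed statistic is `SD(late) - SD(early)`; the
#' null distribution is built by permuting group labels over subjects while
#' holding group sizes fixed, and the p-value uses add-one smoothing,
#' `p = (1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param slopes numeric vector of per-subject treatment slopes, or the
#'   data.frame from [extract_treatment_slopes()].
#' @param group vector of group labels aligned with `slopes`.
#' @param late label identifying the late-start group (default `"late"`).
#' @param B number of permutations (default 10000).
#' @param seed integer seed.
#' @return object of class `variance_diff_test`: `sd_early`, `sd_late`,
#'   `observed_diff`, `null_diffs`, `p`, `B`, `seed`.
#' @export
sd_difference_test <- function(slopes, group, late = "late", B = 10000,
                               seed = 1L) {
  if (is.data.frame(slopes)) slopes <- slopes$slope
  stopifnot(length(slopes) == length(group), B >= 1)
  if (any(!is.finite(slopes))) stop("slopes must be finite")
  is_late <- group == late
  n_late <- sum(is_late); n_early <- sum(!is_late)
  if (n_late < 2 || n_early < 2)
    stop("both groups need >= 2 members")
  sd_late <- stats::sd(slopes[is_late])
  sd_early <- stats::sd(slopes[!is_late])
  observed <- sd_late - sd_early
  set.seed(seed)
  n <- length(slopes)
  null_diffs <- vapply(seq_len(B), function(b) {
    lab <- sample.int(n, n_late)
    stats::sd(slopes[lab]) - stats::sd(slopes[-lab])
  }, numeric(1))
  p <- perm_pvalue(observed, null_diffs, larger_is_extreme = TRUE)
  structure(list(sd_early = sd_early, sd_late = sd_late,
                 observed_diff = observed, null_diffs = null_diffs,
                 p = p, B = B, seed = seed),
            class = "variance_diff_test")
}

#' @export
print.variance_diff_test <- function(x, ...) {
  cat("SD-difference permutation test: SD(late) =", signif(x$sd_late, 4),
      ", SD(early) =", signif(x$sd_early, 4), "\n")
  cat("observed diff =", signif(x$observed_diff, 4), "; p =",
      signif(x$p, 4), "(B =", x$B, ")\n")
  invisible(x)
}

# add-one permutation p-value; convention shared by every permutation test
# in the package: p = (1 + #{null at least as extreme}) / (B + 1)
perm_pvalue <- function(observed, nulls, larger_is_extreme = TRUE) {
  b <- if (larger_is_extreme) sum(nulls >= observed) else sum(nulls <= observed)
  (1 + b) / (length(nulls) + 1)
}
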