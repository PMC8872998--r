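test_that("zero-noise data collapses to the generating line", {
  v <- data.frame(subject_id = rep(c("A", "B"), each = 4),
                  age = c(1:4, 2:5))
  v$outcome <- 2 + 3 * v$age
  f <- fit_lmm(v)
  expect_equal(unname(f$beta), c(2, 3), tolerance = 1e-8)
  expect_lt(f$G["slope", "slope"], 1e-6)
  expect_lt(max(abs(f$blups)), 1e-6)
  sl <- extract_treatment_slopes(f)
  expect_equal(sl$slope, c(3, 3), tolerance = 1e-8)
})

test_that("input contracts are enforced", {
  v <- data.frame(subject_id = rep("A", 3), age = 1:3, outcome = rnorm(3))
  expect_error(fit_lmm(v), ">= 2 subjects")
  v2 <- data.frame(subject_id = rep(c("A", "B"), each = 3),
                   age = rep(1:3, 2), outcome = rnorm(6))
  v2$dup <- v2$age * 2   # collinear with age
  expect_error(fit_lmm(v2, fixed = outcome ~ age + dup), "rank deficient")
  coh <- simulate_cohort(quiet_cfg(n_subjects = 10, seed = 3))
  one <- coh$subjects
  one$age_start <- 15   # everyone early
  expect_error(fit_group_model(coh$visits, one), "non-empty")
})

test_that("REML recovers generating variance components at n = 100", {
  # intercept SD is estimated at age 0, well outside the visit ages, so a
  # single realization carries ~10% sampling error; the 15% accuracy check
  # uses the mean over three fixed seeds
  sds <- sapply(1:3, function(s) {
    coh <- simulate_cohort(quiet_cfg(n_subjects = 100, sd_rand_intercept = 5,
                                     sd_rand_slope = 2, sd_residual = 1,
                                     group_gain_effect = 0,
                                     late_slope_sd_inflation = 1, seed = s))
    sqrt(diag(fit_lmm(coh$visits)$G))
  })
  expect_lt(abs(mean(sds["intercept", ]) / 5 - 1), 0.15)
  expect_lt(abs(mean(sds["slope", ]) / 2 - 1), 0.15)

  coh <- simulate_cohort(quiet_cfg(n_subjects = 100, sd_rand_intercept = 5,
                                   sd_rand_slope = 2, sd_residual = 1,
                                   group_gain_effect = 0,
                                   late_slope_sd_inflation = 1, seed = 1))
  f <- fit_lmm(coh$visits)
  se_slope <- sqrt(f$vcov_beta[2, 2])
  expect_lt(abs(f$beta["age"] - coh$truth$config$fixed_slope), 2 * se_slope)
  # extracted slopes track the truth closely at low residual noise
  sl <- extract_treatment_slopes(f)
  expect_gt(cor(sl$slope, coh$truth$true_slope[sl$subject_id]), 0.9)
})

test_that("estimates sit at a local REML maximum", {
  coh <- simulate_cohort(quiet_cfg(n_subjects = 30, seed = 8))
  f <- fit_lmm(coh$visits)
  ll_hat <- reml_loglik_oracle(coh$visits, f$G, f$sigma2)
  for (mult in c(0.8, 1.25)) {
    expect_gt(ll_hat, reml_loglik_oracle(coh$visits, f$G * mult, f$sigma2))
    expect_gt(ll_hat, reml_loglik_oracle(coh$visits, f$G, f$sigma2 * mult))
  }
})

test_that("fixed variance components reproduce the dense GLS oracle", {
  coh <- simulate_cohort(quiet_cfg(n_subjects = 15, seed = 4))
  G <- matrix(c(4, 0.5, 0.5, 1), 2)
  f <- fit_lmm(coh$visits, vc = list(G = G, sigma2 = 2))
  o <- gls_oracle(coh$visits, G, 2)
  expect_lt(max(abs((f$beta - o$beta) / o$beta)), 1e-8)
})

test_that("BLUPs match the dense mixed-model oracle, single-visit included", {
  set.seed(9)
  nv <- c(1, rep(5, 11))
  v <- data.frame(subject_id = rep(sprintf("S%02d", 1:12), times = nv))
  v$age <- unlist(lapply(nv, seq_len)) * 3 + 10
  v$outcome <- 20 + 2 * v$age + rnorm(nrow(v), 0, 2)
  f <- fit_lmm(v)
  o <- gls_oracle(v, f$G, f$sigma2)
  for (nm in c("S01", "S05")) {
    i <- o$idx[[nm]]
    Z <- cbind(1, v$age[i])
    b <- f$G %*% t(Z) %*% solve(o$V[i, i, drop = FALSE],
                                o$y[i] - o$X[i, , drop = FALSE] %*% o$beta)
    expect_equal(unname(f$blups[nm, ]), unname(drop(b)), tolerance = 1e-6)
  }
  # mean of BLUP deviations is ~0 and slopes shift-invariant
  expect_lt(abs(mean(f$blups[, "slope"])), 0.1)
  v2 <- v
  v2$outcome <- v$outcome + 100
  f2 <- fit_lmm(v2)
  expect_equal(extract_treatment_slopes(f2)$slope,
               extract_treatment_slopes(f)$slope, tolerance = 1e-4)
})

test_that("group model: degenerate random effects reduce to OLS F values", {
  coh <- simulate_cohort(quiet_cfg(n_subjects = 15, seed = 4))
  gm <- fit_group_model(coh$visits, coh$subjects, coh$clinical,
                        vc = list(G = matrix(0, 2, 2), sigma2 = NULL))
  d <- merge(merge(coh$visits, coh$subjects),
             coh$clinical[, c("subject_id", "msel_elc")])
  d$group <- factor(ifelse(d$age_start < 24, "early", "late"))
  d$age_c <- d$age - 24
  ols <- lm(outcome ~ group * age_c + days_in_treatment + hours_week +
              msel_elc, d)
  tt <- summary(ols)$coefficients[-1, 3]
  # every 1-df Wald F must equal the matching OLS t^2 (order-free match)
  expect_equal(sort(gm$fixed_tests$F), sort(unname(tt^2)), tolerance = 1e-6)
})

test_that("group test is calibrated under the null and powered under gain", {
  ps_null <- vapply(1:200, function(s) {
    coh <- simulate_cohort(quiet_cfg(group_gain_effect = 0,
                                     late_slope_sd_inflation = 1,
                                     seed = 1000 + s))
    gm <- fit_group_model(coh$visits, coh$subjects, coh$clinical)
    gm$fixed_tests$p[gm$fixed_tests$term == "group"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps_null, punif)$p.value, 0.01)

  ps_alt <- vapply(1:100, function(s) {
    coh <- simulate_cohort(quiet_cfg(group_gain_effect = 50,
                                     sd_rand_slope = 1, sd_rand_intercept = 5,
                                     late_slope_sd_inflation = 1,
                                     seed = 2000 + s))
    gm <- fit_group_model(coh$visits, coh$subjects, coh$clinical)
    gm$fixed_tests$p[gm$fixed_tests$term == "group"]
  }, numeric(1))
  expect_gte(mean(ps_alt < 0.001), 0.95)
})

test_that("sd_difference_test matches exhaustive enumeration and edge cases", {
  # all slopes identical
  r <- sd_difference_test(rep(2, 8), rep(c("early", "late"), 4), B = 200,
                          seed = 1)
  expect_equal(r$observed_diff, 0)
  expect_equal(r$p, 1)
  # 2+2 subjects: exact p by enumerating all 6 labelings
  sl <- c(1, 2, 0, 10)
  grp <- c("early", "early", "late", "late")
  combs <- combn(4, 2)
  exact_diffs <- apply(combs, 2, function(k) sd(sl[k]) - sd(sl[-k]))
  obs <- sd(sl[3:4]) - sd(sl[1:2])
  p_exact <- mean(exact_diffs >= obs)
  r2 <- sd_difference_test(sl, grp, B = 4000, seed = 2)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(r2$p - p_exact), 3 * mc_se + 1 / 4001)
  # label-swap symmetry: swapping which group is late flips the tail
  r3 <- sd_difference_test(sl, grp, late = "early", B = 4000, seed = 2)
  expect_equal(r3$observed_diff, -r2$observed_diff)
  # reproducibility and the defining identity of p
  r4 <- sd_difference_test(sl, grp, B = 4000, seed = 2)
  expect_identical(r2$null_diffs, r4$null_diffs)
  expect_equal(r2$p, (1 + sum(r2$null_diffs >= r2$observed_diff)) /
                 (r2$B + 1))
  expect_error(sd_difference_test(c(1, 2, 3), c("early", "late", "late"),
                                  B = 10), ">= 2 members")
})
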