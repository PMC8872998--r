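test_that("config validation rejects contradictory settings", {
  expect_error(cohort_config(target_r2 = 1.2), "target_r2")
  expect_error(cohort_config(sd_residual = -1), "SDs")
  expect_error(cohort_config(n_causal = 50, n_probes = 10), "n_causal")
  expect_error(cohort_config(sd_rand_slope = 0, target_r2 = 0.1),
               "sd_rand_slope")
  expect_error(cohort_config(age_start_mean = NaN), "non-finite")
  expect_error(cohort_config(age_start_sd = 12), "too large")
  # cohort-wide R2 infeasible under strong late inflation
  expect_error(cohort_config(target_r2 = 0.5, late_slope_sd_inflation = 4),
               "late_slope_sd_inflation")
})

test_that("identical config and seed give byte-identical cohorts", {
  a <- simulate_cohort(cohort_config(n_subjects = 15, n_probes = 40,
                                     n_causal = 5, seed = 42))
  b <- simulate_cohort(cohort_config(n_subjects = 15, n_probes = 40,
                                     n_causal = 5, seed = 42))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(n_subjects = 15, n_probes = 40,
                                     n_causal = 5, seed = 43))
  expect_false(identical(a$expression, c$expression))
})

test_that("cohort internal consistency invariants hold", {
  coh <- simulate_cohort(cohort_config(n_subjects = 25, n_probes = 60,
                                       n_causal = 8, seed = 7))
  expect_true(all(coh$visits$subject_id %in% coh$subjects$subject_id))
  expect_identical(colnames(coh$expression), coh$subjects$subject_id)
  expect_false(anyNA(coh$visits$outcome))
  expect_false(any(!is.finite(coh$expression)))
  expect_true(all(coh$truth$causal_probe_ids %in% rownames(coh$expression)))
  expect_length(coh$truth$true_slope, 25)
  # visit schedule: first visit at start age, strictly increasing by 3
  one <- coh$visits[coh$visits$subject_id == coh$subjects$subject_id[1], ]
  expect_equal(one$age[1], coh$subjects$age_start[1])
  expect_true(all(diff(one$age) == 3))
  expect_true(max(one$age) <= 36)
  nodes <- unique(c(coh$network$from, coh$network$to))
  expect_true(all(nodes %in% rownames(coh$expression)))
})

test_that("zero-noise cohort puts every outcome exactly on its line", {
  cfg <- quiet_cfg(n_subjects = 8, sd_rand_slope = 0, sd_residual = 0,
                   sd_rand_intercept = 0, group_gain_effect = 0,
                   late_slope_sd_inflation = 1, seed = 5)
  coh <- simulate_cohort(cfg)
  # per-subject OLS recovers the fixed slope exactly
  sl <- vapply(split(coh$visits, coh$visits$subject_id), function(d)
    unname(coef(lm(outcome ~ age, d))[2]), numeric(1))
  expect_equal(unname(sl), rep(cfg$fixed_slope, 8), tolerance = 1e-10)
  expect_equal(unname(coh$truth$true_slope), rep(cfg$fixed_slope, 8))
})

test_that("start-age moments match the stated cohort at large n", {
  coh <- simulate_cohort(quiet_cfg(n_subjects = 10000, seed = 12))
  expect_equal(mean(coh$subjects$age_start), 22.77, tolerance = 0.1 / 22.77)
  expect_lt(abs(sd(coh$subjects$age_start) - 4.08), 0.1)
  expect_true(all(coh$subjects$age_start >= 13 &
                    coh$subjects$age_start <= 27))
})

test_that("causal predictor hits the target R2 and random-effect moments", {
  r2 <- vapply(1:5, function(s) {
    coh <- simulate_cohort(cohort_config(n_subjects = 500, target_r2 = 0.3,
                                         n_probes = 100, n_causal = 20,
                                         seed = s))
    cor(coh$truth$causal_predictor, coh$truth$true_slope)^2
  }, numeric(1))
  # single-seed spread at n=500 is ~0.035 SD, so average five seeds
  expect_gt(mean(r2), 0.25)
  expect_lt(mean(r2), 0.35)

  coh <- simulate_cohort(cohort_config(n_subjects = 5000, n_probes = 20,
                                       n_causal = 4, target_r2 = 0,
                                       late_slope_sd_inflation = 1,
                                       group_gain_effect = 0, seed = 3))
  # recover random-effect SDs from the truth record at large n
  expect_lt(abs(sd(coh$truth$true_slope) / 4 - 1), 0.05)
  # per-group slope SDs under inflation
  coh2 <- simulate_cohort(cohort_config(n_subjects = 5000, n_probes = 20,
                                        n_causal = 4, target_r2 = 0,
                                        late_slope_sd_inflation = 2,
                                        seed = 4))
  g <- coh2$subjects$start_group
  expect_lt(abs(sd(coh2$truth$true_slope[g == "early"]) / 4 - 1), 0.05)
  expect_lt(abs(sd(coh2$truth$true_slope[g == "late"]) / 8 - 1), 0.05)
})

test_that("clinical scores correlate with slopes as loaded", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2000, n_probes = 10,
                                       n_causal = 2, seed = 21))
  loads <- coh$truth$config$clinical_loading
  for (m in names(loads)) {
    r <- cor(coh$clinical[[m]], coh$truth$true_slope)
    expect_lt(abs(r - loads[[m]]), 0.08)
  }
  # scales sit on instrument-like means
  defs <- clinical_measure_defaults()
  expect_lt(abs(mean(coh$clinical$msel_elc) -
                  defs$mean[defs$measure == "msel_elc"]), 2)
})

test_that("written cohort round-trips through the plain-text formats", {
  coh <- simulate_cohort(cohort_config(n_subjects = 10, n_probes = 30,
                                       n_causal = 5, seed = 9))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  v <- read_visits(file.path(d, "visits.tsv"))
  expect_equal(nrow(v), nrow(coh$visits))
  expect_equal(v$outcome, coh$visits$outcome, tolerance = 1e-12)
  m <- read_expression_matrix(file.path(d, "expression.tsv"))
  expect_equal(dim(m), dim(coh$expression))
  expect_equal(unname(m), unname(coh$expression), tolerance = 1e-12)
  gs <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_identical(gs$causal, coh$gene_sets$causal)
  ed <- read_edge_list(file.path(d, "network.tsv"))
  expect_equal(nrow(ed), nrow(coh$network))
})
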