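#' Configuration for a synthetic early-intervention cohort
#'
#' Builds and validates the parameter set that [simulate_cohort()] consumes.
#' Defaults describe a cohort of toddlers entering a standardized early
#' intervention: ~41 subjects, age at treatment start on \[13, 27\] months
#' with mean 22.77 and SD 4.08 (a moment-matched scaled Beta, so mean, SD
#' and range are reproduced exactly), outcome assessed at
#' intake and every 3 months until 36 months of age, subject-specific random
#' intercepts and slopes, an additive outcome gain for subjects starting
#' before 24 months, inflated slope variability for late starters, and a
#' probes-by-subjects log2 expression matrix in which a sparse causal probe
#' set carries a linear signal for the true treatment slope calibrated to a
#' target predictive R-squared.
#'
#' @param n_subjects number of subjects.
#' @param male_fraction proportion of males.
#' @param age_start_mean,age_start_sd mean and SD (months) of the
#'   age-at-start distribution (matched exactly on the stated range).
#' @param age_start_range attainable start-age range in months.
#' @param early_cutoff months; subjects with start age below this are the
#'   "early" group.
#' @param visit_interval months between assessments.
#' @param final_age months; last possible assessment age.
#' @param fixed_intercept,fixed_slope population outcome intercept (units)
#'   and growth rate (units/month).
#' @param sd_rand_intercept,sd_rand_slope,sd_residual SDs of the random
#'   intercept, random slope (early-group scale) and visit-level residual.
#' @param group_gain_effect additive outcome gain (units) for early starters.
#' @param late_slope_sd_inflation multiplier (>= 1) applied to the random
#'   slope SD for subjects starting at or after `early_cutoff`.
#' @param n_probes,n_causal expression matrix size and causal probe count.
#' @param causal_cor pairwise correlation among causal probes (a shared
#'   co-expression module factor); 0 gives independent causal probes.
#' @param target_r2 population R-squared of the causal-probe linear predictor
#'   for the true slope, defined cohort-wide (see Details).
#' @param n_batches number of processing batches.
#' @param batch_prob batch assignment probabilities (recycled/normalized).
#' @param batch_effect_sd,sex_effect_sd,rin_effect_sd SDs of per-probe
#'   nuisance effects on the log2 scale.
#' @param rin_range range of the uniform RIN distribution.
#' @param hours_week_mean,hours_week_sd treatment intensity distribution.
#' @param clinical_loading named vector of target correlations between
#'   clinical measures and the true slope; names select rows of
#'   [clinical_measure_defaults()] where available.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   cohorts.
#'
#' @details The cohort-wide slope variance is
#' `sd_rand_slope^2 * E[m^2]` where `m` is 1 for early starters and
#' `late_slope_sd_inflation` for late starters, the expectation taken under
#' the truncated-normal start-age distribution. The causal signal variance is
#' `target_r2` times that total, so the population squared correlation
#' between the causal linear predictor and true slopes equals `target_r2`
#' regardless of the inflation factor, while the per-group slope SDs remain
#' `sd_rand_slope` and `sd_rand_slope * late_slope_sd_inflation`. This
#' requires `target_r2 * E[m^2] <= 1`; contradictory settings are rejected.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_subjects = 41,
                          male_fraction = 33 / 41,
                          age_start_mean = 22.77,
                          age_start_sd = 4.08,
                          age_start_range = c(13, 27),
                          early_cutoff = 24,
                          visit_interval = 3,
                          final_age = 36,
                          fixed_intercept = 30,
                          fixed_slope = 4,
                          sd_rand_intercept = 8,
                          sd_rand_slope = 4,
                          sd_residual = 4,
                          group_gain_effect = 10,
                          late_slope_sd_inflation = 2,
                          n_probes = 2000,
                          n_causal = 50,
                          causal_cor = 0.5,
                          target_r2 = 0.13,
                          n_batches = 3,
                          batch_prob = NULL,
                          batch_effect_sd = 0.3,
                          sex_effect_sd = 0.1,
                          rin_effect_sd = 0.1,
                          rin_range = c(7, 10),
                          hours_week_mean = 9,
                          hours_week_sd = 1.5,
                          clinical_loading = c(msel_elc = 0.5, msel_el = 0.45,
                                               vabs_abc = 0.45, vabs_comm = 0.4,
                                               ados_total = -0.4, ados_rrb = -0.3),
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              male_fraction = male_fraction,
              age_start_mean = age_start_mean, age_start_sd = age_start_sd,
              age_start_range = as.numeric(age_start_range),
              early_cutoff = early_cutoff, visit_interval = visit_interval,
              final_age = final_age,
              fixed_intercept = fixed_intercept, fixed_slope = fixed_slope,
              sd_rand_intercept = sd_rand_intercept,
              sd_rand_slope = sd_rand_slope, sd_residual = sd_residual,
              group_gain_effect = group_gain_effect,
              late_slope_sd_inflation = late_slope_sd_inflation,
              n_probes = as.integer(n_probes), n_causal = as.integer(n_causal),
              causal_cor = causal_cor,
              target_r2 = target_r2, n_batches = as.integer(n_batches),
              batch_prob = batch_prob,
              batch_effect_sd = batch_effect_sd, sex_effect_sd = sex_effect_sd,
              rin_effect_sd = rin_effect_sd, rin_range = as.numeric(rin_range),
              hours_week_mean = hours_week_mean, hours_week_sd = hours_week_sd,
              clinical_loading = clinical_loading,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  num <- unlist(cfg[c("male_fraction", "age_start_mean", "age_start_sd",
                      "age_start_range", "early_cutoff", "visit_interval",
                      "final_age", "fixed_intercept", "fixed_slope",
                      "sd_rand_intercept", "sd_rand_slope", "sd_residual",
                      "group_gain_effect", "late_slope_sd_inflation",
                      "target_r2", "batch_effect_sd", "sex_effect_sd",
                      "rin_effect_sd", "rin_range", "hours_week_mean",
                      "hours_week_sd")])
  if (any(!is.finite(num)))
    stop("cohort_config: non-finite parameter value", call. = FALSE)
  stopifnot(cfg$n_subjects >= 1L, cfg$n_probes >= 1L,
            cfg$n_causal >= 0L, cfg$n_batches >= 1L)
  if (cfg$n_causal > cfg$n_probes)
    stop("n_causal must not exceed n_probes", call. = FALSE)
  sds <- c(cfg$sd_rand_intercept, cfg$sd_rand_slope, cfg$sd_residual,
           cfg$batch_effect_sd, cfg$sex_effect_sd, cfg$rin_effect_sd,
           cfg$age_start_sd, cfg$hours_week_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (cfg$target_r2 < 0 || cfg$target_r2 >= 1)
    stop("target_r2 must lie in [0, 1)", call. = FALSE)
  if (cfg$causal_cor < 0 || cfg$causal_cor >= 1)
    stop("causal_cor must lie in [0, 1)", call. = FALSE)
  if (cfg$late_slope_sd_inflation < 1)
    stop("late_slope_sd_inflation must be >= 1", call. = FALSE)
  if (cfg$visit_interval <= 0)
    stop("visit_interval must be positive", call. = FALSE)
  if (cfg$age_start_range[1] >= cfg$age_start_range[2])
    stop("age_start_range must be increasing", call. = FALSE)
  if (cfg$age_start_sd > 0) start_age_shapes(cfg)  # feasibility check
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1)
    stop("male_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$target_r2 > 0 && cfg$sd_rand_slope == 0)
    stop("target_r2 > 0 requires sd_rand_slope > 0", call. = FALSE)
  if (cfg$target_r2 > 0 && cfg$n_causal == 0)
    stop("target_r2 > 0 requires n_causal > 0", call. = FALSE)
  m2 <- mean_sq_inflation(cfg)
  if (cfg$target_r2 * m2 > 1)
    stop("target_r2 too large for the requested late_slope_sd_inflation: ",
         "needs target_r2 <= ", signif(1 / m2, 4), call. = FALSE)
  if (is.null(cfg$batch_prob)) cfg$batch_prob <- rep(1, cfg$n_batches)
  if (length(cfg$batch_prob) != cfg$n_batches || any(cfg$batch_prob < 0) ||
      sum(cfg$batch_prob) <= 0)
    stop("batch_prob must be ", cfg$n_batches, " non-negative weights",
         call. = FALSE)
  cfg$batch_prob <- cfg$batch_prob / sum(cfg$batch_prob)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config:", x$n_subjects, "subjects,", x$n_probes, "probes (",
      x$n_causal, "causal ), target_r2 =", x$target_r2, "\n")
  cat("  start age mean", x$age_start_mean, "SD", x$age_start_sd,
      "on [", x$age_start_range[1], ",", x$age_start_range[2],
      "], early cutoff", x$early_cutoff, "mo\n")
  invisible(x)
}

# Start ages follow a scaled Beta on the stated range with shape parameters
# moment-matched to (age_start_mean, age_start_sd); this reproduces mean, SD
# and range exactly (a truncated normal on the same range cannot reach the
# required SD at that mean).
start_age_shapes <- function(cfg) {
  lo <- cfg$age_start_range[1]; hi <- cfg$age_start_range[2]
  m <- (cfg$age_start_mean - lo) / (hi - lo)
  v <- (cfg$age_start_sd / (hi - lo))^2
  if (m <= 0 || m >= 1)
    stop("age_start_mean must lie strictly inside age_start_range")
  if (v >= m * (1 - m))
    stop("age_start_sd too large for the stated range/mean")
  k <- m * (1 - m) / v - 1
  c(alpha = m * k, beta = (1 - m) * k)
}

# P(start >= early_cutoff) under the start-age law
prob_late_start <- function(cfg) {
  lo <- cfg$age_start_range[1]; hi <- cfg$age_start_range[2]
  if (cfg$age_start_sd == 0)
    return(as.numeric(cfg$age_start_mean >= cfg$early_cutoff))
  sh <- start_age_shapes(cfg)
  cut <- min(max((cfg$early_cutoff - lo) / (hi - lo), 0), 1)
  stats::pbeta(cut, sh[1], sh[2], lower.tail = FALSE)
}

# E[m^2] where m = 1 (early) or late_slope_sd_inflation (late)
mean_sq_inflation <- function(cfg) {
  p <- prob_late_start(cfg)
  (1 - p) + p * cfg$late_slope_sd_inflation^2
}

r_start_age <- function(n, cfg) {
  if (cfg$age_start_sd == 0) return(rep(cfg$age_start_mean, n))
  lo <- cfg$age_start_range[1]; hi <- cfg$age_start_range[2]
  sh <- start_age_shapes(cfg)
  lo + (hi - lo) * stats::rbeta(n, sh[1], sh[2])
}

#' Reference means and SDs for simulated pre-treatment clinical measures
#'
#' Location/scale used to place simulated clinical scores on familiar
#' instrument scales (ADOS symptom totals, Mullen T-score composites,
#' Vineland standard scores). Measures not listed here are simulated with
#' mean 50, SD 10.
#'
#' @return data.frame with columns `measure`, `mean`, `sd`.
#' @export
clinical_measure_defaults <- function() {
  data.frame(
    measure = c("ados_total", "ados_sc", "ados_rrb",
                "msel_el", "msel_rl", "msel_vr", "msel_fm", "msel_elc",
                "vabs_comm", "vabs_soc", "vabs_dl", "vabs_motor", "vabs_abc"),
    mean = c(14.27, 12.17, 6.17, 31.39, 29.10, 41.29, 41.63, 73.83,
             77.12, 85.51, 89.05, 94.83, 84.27),
    sd = c(6.02, 5.41, 2.11, 10.62, 11.22, 9.65, 11.38, 15.31,
           14.38, 12.52, 11.99, 11.98, 12.34),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic early-intervention cohort
#'
#' Generates longitudinal outcome records, subject covariates, pre-treatment
#' clinical scores, a log2 expression matrix with batch/sex/RIN nuisance
#' structure and a sparse causal signal for the true treatment slope, gene
#' sets, an interaction network, and a truth record — everything the
#' downstream trajectory-modelling and prediction stages consume.
#'
#' Per-visit outcome for subject i at age a:
#' `fixed_intercept + gain*I(early_i) + b0_i + (fixed_slope + b1_i)*a + e`,
#' with `b0_i ~ N(0, sd_rand_intercept^2)`,
#' `b1_i = signal_i + noise_i` where `signal_i` is the scaled causal-probe
#' linear predictor and `noise_i` has SD `sd_rand_slope` (early) times
#' `late_slope_sd_inflation` (late), net of the signal variance, and
#' `e ~ N(0, sd_residual^2)`. Visits run from the start age every
#' `visit_interval` months up to `final_age`.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_data`: list with `visits`, `subjects`,
#'   `clinical`, `expression` (probes x subjects), `gene_sets`, `network`
#'   (two-column data.frame of undirected edges) and `truth`
#'   (`true_slope`, `causal_probe_ids`, `causal_weights`,
#'   `causal_predictor` — the scaled causal-probe linear signal per
#'   subject — and the generating `config`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 12, n_probes = 100,
#'                                      n_causal = 10, seed = 7))
#' head(coh$visits)
#' @export
simulate_cohort <- function(config) {
  cfg <- if (inherits(config, "cohort_config")) config
         else validate_cohort_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  sid <- sprintf("S%03d", seq_len(n))

  start_age <- r_start_age(n, cfg)
  early <- start_age < cfg$early_cutoff
  male <- stats::runif(n) < cfg$male_fraction
  batch <- paste0("B", sample.int(cfg$n_batches, n, replace = TRUE,
                                  prob = cfg$batch_prob))
  rin <- stats::runif(n, cfg$rin_range[1], cfg$rin_range[2])
  hours_week <- stats::rnorm(n, cfg$hours_week_mean, cfg$hours_week_sd)
  # days in treatment: span from start to final age, ~30.44 days per month
  days_in_treatment <- pmax(0, (cfg$final_age - start_age)) * 30.44 +
    stats::rnorm(n, 0, 10)

  # expression: per-probe baseline + standard-normal subject scores + nuisance
  pid <- sprintf("P%05d", seq_len(cfg$n_probes))
  mu_g <- stats::rnorm(cfg$n_probes, 8, 1.5)
  z <- matrix(stats::rnorm(cfg$n_probes * n), cfg$n_probes, n,
              dimnames = list(pid, sid))
  causal <- sort(sample.int(cfg$n_probes, cfg$n_causal))
  # under module correlation the members are co-regulated and contribute
  # with a common direction (half-normal weights); independent causal
  # probes get signed weights
  w <- stats::rnorm(cfg$n_causal)
  if (cfg$causal_cor > 0) w <- abs(w)
  # causal probes form a co-expressed module: shared factor with pairwise
  # correlation causal_cor, unit marginal variance preserved
  if (cfg$n_causal > 0 && cfg$causal_cor > 0) {
    f <- stats::rnorm(n)
    z[causal, ] <- sqrt(cfg$causal_cor) * rep(f, each = cfg$n_causal) +
      sqrt(1 - cfg$causal_cor) * z[causal, , drop = FALSE]
  }

  # slope deviations: causal signal scaled to cohort-wide target_r2;
  # Var(w'z) under the module correlation is w'Rw with
  # R = (1-rho) I + rho 11'
  m2 <- mean_sq_inflation(cfg)
  v_total <- cfg$sd_rand_slope^2 * m2       # cohort-wide slope-deviation var
  s_var <- cfg$target_r2 * v_total
  if (cfg$n_causal > 0 && s_var > 0) {
    wRw <- (1 - cfg$causal_cor) * sum(w^2) + cfg$causal_cor * sum(w)^2
    cvec <- sqrt(s_var / wRw) * w
    signal <- drop(crossprod(z[causal, , drop = FALSE], cvec))
  } else {
    cvec <- numeric(cfg$n_causal)
    signal <- numeric(n)
  }
  noise_sd_early <- sqrt(max(0, cfg$sd_rand_slope^2 - s_var))
  noise_sd_late <- sqrt(max(0, (cfg$sd_rand_slope *
                                  cfg$late_slope_sd_inflation)^2 - s_var))
  b1 <- signal + stats::rnorm(n) * ifelse(early, noise_sd_early, noise_sd_late)
  b0 <- stats::rnorm(n, 0, cfg$sd_rand_intercept)
  true_slope <- cfg$fixed_slope + b1

  # nuisance structure on the log2 scale
  be <- matrix(stats::rnorm(cfg$n_probes * cfg$n_batches, 0, cfg$batch_effect_sd),
               cfg$n_probes, cfg$n_batches)
  se <- stats::rnorm(cfg$n_probes, 0, cfg$sex_effect_sd)
  re <- stats::rnorm(cfg$n_probes, 0, cfg$rin_effect_sd)
  bidx <- as.integer(sub("^B", "", batch))
  expr <- mu_g + z + be[, bidx, drop = FALSE] +
    outer(se, as.numeric(male)) +
    outer(re, rin - mean(cfg$rin_range))
  dimnames(expr) <- list(pid, sid)

  # longitudinal visits
  nv <- floor((cfg$final_age - start_age) / cfg$visit_interval) + 1
  nv <- pmax(nv, 1L)
  vsub <- rep(seq_len(n), nv)
  age <- unlist(lapply(seq_len(n), function(i)
    start_age[i] + cfg$visit_interval * (seq_len(nv[i]) - 1)))
  outcome <- cfg$fixed_intercept + cfg$group_gain_effect * early[vsub] +
    b0[vsub] + (cfg$fixed_slope + b1[vsub]) * age +
    stats::rnorm(length(age), 0, cfg$sd_residual)
  visits <- data.frame(subject_id = sid[vsub], age = age, outcome = outcome,
                       stringsAsFactors = FALSE)

  subjects <- data.frame(
    subject_id = sid,
    sex = ifelse(male, "M", "F"),
    batch = batch,
    rin = rin,
    age_start = start_age,
    start_group = ifelse(early, "early", "late"),
    days_in_treatment = days_in_treatment,
    hours_week = hours_week,
    stringsAsFactors = FALSE
  )

  # clinical scores: loading * standardized true slope + noise, then placed
  # on instrument-like scales
  loads <- cfg$clinical_loading
  defs <- clinical_measure_defaults()
  slope_std <- (true_slope - cfg$fixed_slope) / sqrt(v_total)
  clin <- vapply(seq_along(loads), function(j) {
    r <- loads[j]
    zc <- r * slope_std + sqrt(1 - r^2) * stats::rnorm(n)
    k <- match(names(loads)[j], defs$measure)
    if (is.na(k)) 50 + 10 * zc else defs$mean[k] + defs$sd[k] * zc
  }, numeric(n))
  colnames(clin) <- names(loads)
  clinical <- data.frame(subject_id = sid, clin, stringsAsFactors = FALSE)

  gene_sets <- c(list(causal = pid[causal]),
                 lapply(stats::setNames(1:3, paste0("random_set_", 1:3)),
                        function(k) sort(sample(pid, min(50, cfg$n_probes)))))

  network <- simulate_probe_network(pid, causal)

  out <- list(visits = visits, subjects = subjects, clinical = clinical,
              expression = expr, gene_sets = gene_sets, network = network,
              truth = list(true_slope = stats::setNames(true_slope, sid),
                           causal_probe_ids = pid[causal],
                           causal_weights = stats::setNames(cvec, pid[causal]),
                           causal_predictor = stats::setNames(signal, sid),
                           config = cfg))
  class(out) <- "cohort_data"
  out
}

# sparse random interaction network (mean degree ~4) with 5x denser wiring
# among causal probes, mimicking a functionally coherent module
simulate_probe_network <- function(pid, causal_idx) {
  np <- length(pid)
  if (np < 2)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  p_base <- min(1, 4 / (np - 1))
  sample_pairs <- function(m, ids) {
    # m distinct unordered pairs from ids, by redraw-until-unique
    from <- integer(0); to <- integer(0)
    while (length(from) < m) {
      need <- m - length(from)
      a <- sample(ids, 2 * need + 8, replace = TRUE)
      b <- sample(ids, 2 * need + 8, replace = TRUE)
      ok <- a != b
      i <- pmin(a[ok], b[ok]); j <- pmax(a[ok], b[ok])
      from <- c(from, i); to <- c(to, j)
      dup <- duplicated(paste(from, to))
      from <- from[!dup]; to <- to[!dup]
    }
    list(from = from[seq_len(m)], to = to[seq_len(m)])
  }
  m_base <- stats::rbinom(1, np * (np - 1) / 2, p_base)
  nc <- length(causal_idx)
  m_causal <- if (nc >= 2)
    stats::rbinom(1, nc * (nc - 1) / 2, min(1, 5 * p_base)) else 0L
  e1 <- sample_pairs(m_base, seq_len(np))
  e2 <- if (m_causal > 0) sample_pairs(m_causal, causal_idx)
        else list(from = integer(0), to = integer(0))
  from <- c(e1$from, e2$from); to <- c(e1$to, e2$to)
  dup <- duplicated(paste(from, to))
  data.frame(from = pid[from[!dup]], to = pid[to[!dup]],
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", nrow(x$subjects), "subjects,", nrow(x$visits),
      "visits,", nrow(x$expression), "probes,",
      length(x$truth$causal_probe_ids), "causal\n")
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes `visits.tsv`, `subjects.tsv`, `clinical.tsv`, `expression.tsv`
#' (probe-id first column), `gene_sets.gmt` and `network.tsv` under `dir`.
#'
#' @param cohort a `cohort_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("visits.tsv", "subjects.tsv", "clinical.tsv",
                            "expression.tsv", "gene_sets.gmt", "network.tsv"))
  utils::write.table(cohort$visits, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$subjects, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression_matrix(cohort$expression, paths[4])
  write_gmt(cohort$gene_sets, paths[5])
  utils::write.table(cohort$network, paths[6], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
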