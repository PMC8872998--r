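# small configs and oracle helpers shared across test files

quiet_cfg <- function(...) {
  # tiny expressionless cohort for trajectory-only tests
  cohort_config(n_probes = 2, n_causal = 0, target_r2 = 0, ...)
}

# dense-matrix GLS oracle: beta from the full N x N marginal covariance
gls_oracle <- function(visits, G, sigma2) {
  X <- cbind(1, visits$age)
  y <- visits$outcome
  sid <- visits$subject_id
  idx <- split(seq_len(nrow(visits)), factor(sid, levels = unique(sid)))
  V <- matrix(0, nrow(visits), nrow(visits))
  for (i in idx) {
    Z <- cbind(1, visits$age[i])
    V[i, i] <- Z %*% G %*% t(Z) + diag(sigma2, length(i))
  }
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  list(beta = drop(beta), V = V, X = X, y = y, idx = idx)
}

# REML log-likelihood (up to a constant) at given variance components;
# used to probe local maximality of the fitted estimates
reml_loglik_oracle <- function(visits, G, sigma2) {
  o <- gls_oracle(visits, G, sigma2)
  r <- o$y - o$X %*% o$beta
  -0.5 * (determinant(o$V, logarithm = TRUE)$modulus +
            determinant(t(o$X) %*% solve(o$V, o$X),
                        logarithm = TRUE)$modulus +
            drop(t(r) %*% solve(o$V, r)))
}

# deterministic LOO-safe covariates for small-n pipeline tests
balanced_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(batch = rep_len(c("B1", "B2", "B3"), n),
             sex = rep_len(c("M", "F"), n),
             rin = runif(n, 7, 10))
}
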