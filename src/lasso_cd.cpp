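// LASSO solvers for the prediction pipeline.
//
// Objective: (1/2n) * ||y - X b||^2 + lambda * ||b||_1, intercept handled
// by the callers through centering.
//
// Two routes:
//  * cyclic coordinate descent (cd_*): the reference solver; converged when
//    the largest absolute coefficient change in a sweep drops below tol.
//  * exact lambda-homotopy (LARS-lasso with drops): piecewise-linear path
//    in lambda; used by the path/CV/LOOCV engines because it is exact and
//    orders of magnitude faster in the p > n small-lambda regime. Falls
//    back to warm-started coordinate descent on numerically degenerate
//    Gram segments.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double soft(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// ----------------------------------------------------------------------
// coordinate descent
// ----------------------------------------------------------------------

static void cd_solve(const double* X, int n, int p, std::vector<double>& r,
                     std::vector<double>& b, const std::vector<double>& a,
                     double lambda, double tol, int maxit,
                     std::vector<double>* obj_trace) {
  for (int it = 0; it < maxit; ++it) {
    double maxdelta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (a[j] <= 0.0) continue;
      const double* xj = X + static_cast<size_t>(j) * n;
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
      rho = rho / n + a[j] * b[j];
      double bnew = soft(rho, lambda) / a[j];
      double d = bnew - b[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        b[j] = bnew;
        double ad = std::abs(d);
        if (ad > maxdelta) maxdelta = ad;
      }
    }
    if (obj_trace) {
      double rss = 0.0, l1 = 0.0;
      for (int i = 0; i < n; ++i) rss += r[i] * r[i];
      for (int j = 0; j < p; ++j) l1 += std::abs(b[j]);
      obj_trace->push_back(rss / (2.0 * n) + lambda * l1);
    }
    if (maxdelta < tol) break;
  }
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                   double tol = 1e-7, int maxit = 100000,
                   bool trace_objective = false) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  if (y.size() != n) stop("length(y) != nrow(X)");
  const double* xp = REAL(X);
  std::vector<double> a(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = xp + static_cast<size_t>(j) * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    a[j] = s / n;
  }
  std::vector<double> r(y.begin(), y.end());
  std::vector<double> b(p, 0.0);
  NumericMatrix beta(p, L);
  List traces(L);
  for (int l = 0; l < L; ++l) {
    std::vector<double> tr;
    cd_solve(xp, n, p, r, b, a, lambda[l], tol, maxit,
             trace_objective ? &tr : nullptr);
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
    if (trace_objective) traces[l] = wrap(tr);
  }
  List out = List::create(_["beta"] = beta);
  if (trace_objective) out["objective"] = traces;
  return out;
}

// ----------------------------------------------------------------------
// exact lambda-homotopy
// ----------------------------------------------------------------------

// Cholesky of the active Gram matrix G_AA = X_A'X_A / n (lower triangle,
// row-major q x q). `G` optionally holds the full precomputed p x p Gram.
// Returns false if a pivot degenerates (dependent set).
static bool chol_gram(const double* X, int n, const std::vector<int>& A,
                      std::vector<double>& Lmat, int stride, const double* G,
                      int p) {
  const int q = A.size();
  for (int i = 0; i < q; ++i) {
    const double* xi = X + static_cast<size_t>(A[i]) * n;
    for (int j = 0; j <= i; ++j) {
      double g;
      if (G) {
        g = G[static_cast<size_t>(A[i]) * p + A[j]];
      } else {
        const double* xj = X + static_cast<size_t>(A[j]) * n;
        double s = 0.0;
        for (int t = 0; t < n; ++t) s += xi[t] * xj[t];
        g = s / n;
      }
      for (int k = 0; k < j; ++k)
        g -= Lmat[static_cast<size_t>(i) * stride + k] *
             Lmat[static_cast<size_t>(j) * stride + k];
      if (i == j) {
        if (g < 1e-10) return false;
        Lmat[static_cast<size_t>(i) * stride + i] = std::sqrt(g);
      } else {
        Lmat[static_cast<size_t>(i) * stride + j] =
          g / Lmat[static_cast<size_t>(j) * stride + j];
      }
    }
  }
  return true;
}

static void chol_solve(const std::vector<double>& Lmat, int q, int stride,
                       const std::vector<double>& rhs,
                       std::vector<double>& out) {
  out.assign(rhs.begin(), rhs.begin() + q);
  for (int i = 0; i < q; ++i) {
    const double* Li = &Lmat[static_cast<size_t>(i) * stride];
    for (int k = 0; k < i; ++k) out[i] -= Li[k] * out[k];
    out[i] /= Li[i];
  }
  for (int i = q - 1; i >= 0; --i) {
    for (int k = i + 1; k < q; ++k)
      out[i] -= Lmat[static_cast<size_t>(k) * stride + i] * out[k];
    out[i] /= Lmat[static_cast<size_t>(i) * stride + i];
  }
}

// Exact lasso solutions at the grid lambdas (decreasing). X, y centered.
// beta: p x L column-major output, assumed zero-initialized.
static void homotopy_path(const double* X, int n, int p, const double* y,
                          const double* lam, int L, double* beta,
                          double cd_tol, int cd_maxit) {
  std::vector<double> q(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = X + static_cast<size_t>(j) * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * y[i];
    q[j] = s / n;
  }
  int j0 = 0;
  double lmax = 0.0;
  for (int j = 0; j < p; ++j)
    if (std::abs(q[j]) > lmax) { lmax = std::abs(q[j]); j0 = j; }
  int gi = 0;
  while (gi < L && lam[gi] >= lmax) ++gi;   // all-zero solutions
  if (gi >= L || lmax <= 0.0) return;

  std::vector<int> A(1, j0);
  std::vector<double> s(1, q[j0] > 0 ? 1.0 : -1.0);
  std::vector<char> active(p, 0);
  active[j0] = 1;
  double lam_cur = lmax;

  std::vector<double> Lmat, u, v, qA, t1(n), t2(n);
  const int max_events = 40 * std::min(n, p) + 1000;

  // precompute the full Gram when small enough to be worth the memory;
  // otherwise fall back to on-the-fly X products per segment
  std::vector<double> Gfull;
  const double* G = nullptr;
  if (p <= 600) {
    Gfull.resize(static_cast<size_t>(p) * p);
    for (int a = 0; a < p; ++a) {
      const double* xa = X + static_cast<size_t>(a) * n;
      for (int b = 0; b <= a; ++b) {
        const double* xb = X + static_cast<size_t>(b) * n;
        double s = 0.0;
        for (int t = 0; t < n; ++t) s += xa[t] * xb[t];
        s /= n;
        Gfull[static_cast<size_t>(a) * p + b] = s;
        Gfull[static_cast<size_t>(b) * p + a] = s;
      }
    }
    G = Gfull.data();
  }

  auto fallback_cd = [&](int from_gi) {
    // warm-started coordinate descent for the remaining grid lambdas
    std::vector<double> a(p), b(p, 0.0), r(y, y + n);
    for (int j = 0; j < p; ++j) {
      const double* xj = X + static_cast<size_t>(j) * n;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += xj[i] * xj[i];
      a[j] = ss / n;
    }
    if (from_gi > 0) {
      for (size_t k = 0; k < A.size(); ++k) {
        int j = A[k];
        b[j] = beta[static_cast<size_t>(from_gi - 1) * p + j];
        if (b[j] != 0.0) {
          const double* xj = X + static_cast<size_t>(j) * n;
          for (int i = 0; i < n; ++i) r[i] -= b[j] * xj[i];
        }
      }
    }
    for (int l = from_gi; l < L; ++l) {
      cd_solve(X, n, p, r, b, a, lam[l], cd_tol, cd_maxit, nullptr);
      for (int j = 0; j < p; ++j) beta[static_cast<size_t>(l) * p + j] = b[j];
    }
  };

  // incremental Cholesky with fixed row stride S: valid for the current A
  // throughout the loop; appended in place on entries, rebuilt after drops
  const int S = std::min(n, p) + 2;
  Lmat.assign(static_cast<size_t>(S) * S, 0.0);
  std::vector<double> sA(S), gbuf(S);
  if (!chol_gram(X, n, A, Lmat, S, G, p)) { fallback_cd(gi); return; }
  // Gram entry helper for the append step when no full Gram is cached
  auto gram_entry = [&](int a, int b) -> double {
    if (G) return G[static_cast<size_t>(a) * p + b];
    const double* xa = X + static_cast<size_t>(a) * n;
    const double* xb = X + static_cast<size_t>(b) * n;
    double sacc = 0.0;
    for (int t = 0; t < n; ++t) sacc += xa[t] * xb[t];
    return sacc / n;
  };
  // remove active index k from the Cholesky by Givens re-triangularization
  // (O(q^2), replaces a full O(q^3) rebuild on drops)
  auto chol_delete = [&](int k) {
    const int qn = A.size();   // size before deletion
    for (int i = k + 1; i < qn; ++i)
      for (int c2 = 0; c2 < i + 1; ++c2)
        Lmat[static_cast<size_t>(i - 1) * S + c2] =
          Lmat[static_cast<size_t>(i) * S + c2];
    const int m = qn - 1;      // rows remaining
    for (int j = k; j < m; ++j) {
      double a = Lmat[static_cast<size_t>(j) * S + j];
      double b = Lmat[static_cast<size_t>(j) * S + j + 1];
      double r = std::hypot(a, b);
      if (r <= 0.0) continue;
      const double c = a / r, sn = b / r;
      for (int i = j; i < m; ++i) {
        double t1 = Lmat[static_cast<size_t>(i) * S + j];
        double t2 = Lmat[static_cast<size_t>(i) * S + j + 1];
        Lmat[static_cast<size_t>(i) * S + j] = c * t1 + sn * t2;
        Lmat[static_cast<size_t>(i) * S + j + 1] = -sn * t1 + c * t2;
      }
    }
  };

  // append row for feature j to the Cholesky of G_AA; false if dependent
  auto chol_append = [&](int j) -> bool {
    const int qn = A.size();
    if (qn + 1 >= S) return false;   // rank saturation
    for (int k = 0; k < qn; ++k) gbuf[k] = gram_entry(A[k], j);
    double pivot = gram_entry(j, j);
    double* Lrow = &Lmat[static_cast<size_t>(qn) * S];
    for (int i = 0; i < qn; ++i) {
      double val = gbuf[i];
      for (int k2 = 0; k2 < i; ++k2)
        val -= Lrow[k2] * Lmat[static_cast<size_t>(i) * S + k2];
      Lrow[i] = val / Lmat[static_cast<size_t>(i) * S + i];
      pivot -= Lrow[i] * Lrow[i];
    }
    if (pivot < 1e-10) return false;
    Lrow[qn] = std::sqrt(pivot);
    return true;
  };

  for (int ev = 0; ev < max_events; ++ev) {
    const int qn = A.size();
    qA.resize(qn);
    for (int k = 0; k < qn; ++k) { qA[k] = q[A[k]]; sA[k] = s[k]; }
    chol_solve(Lmat, qn, S, qA, u);
    chol_solve(Lmat, qn, S, sA, v);
    if (!G) {
      // t1 = X_A u, t2 = X_A v for the on-the-fly correlation updates
      std::fill(t1.begin(), t1.end(), 0.0);
      std::fill(t2.begin(), t2.end(), 0.0);
      for (int k = 0; k < qn; ++k) {
        const double* xj = X + static_cast<size_t>(A[k]) * n;
        const double uk = u[k], vk = v[k];
        for (int i = 0; i < n; ++i) {
          t1[i] += uk * xj[i];
          t2[i] += vk * xj[i];
        }
      }
    }
    // next entering event
    const double hi = lam_cur * (1.0 - 1e-9);
    double lam_enter = -1.0; int j_enter = -1; double s_enter = 0.0;
    for (int j = 0; j < p; ++j) {
      if (active[j]) continue;
      double g1 = 0.0, g2 = 0.0;
      if (G) {
        const double* Gj = G + static_cast<size_t>(j) * p;
        for (int k = 0; k < qn; ++k) {
          g1 += Gj[A[k]] * u[k];
          g2 += Gj[A[k]] * v[k];
        }
      } else {
        const double* xj = X + static_cast<size_t>(j) * n;
        double a1 = 0.0, a2 = 0.0;
        for (int i = 0; i < n; ++i) { a1 += xj[i] * t1[i]; a2 += xj[i] * t2[i]; }
        g1 = a1 / n; g2 = a2 / n;
      }
      const double qt = q[j] - g1, w = g2;
      for (int sg = -1; sg <= 1; sg += 2) {
        const double den = sg - w;
        if (std::abs(den) < 1e-9) continue;
        const double lc = qt / den;
        if (lc > 0.0 && lc < hi && lc > lam_enter) {
          lam_enter = lc; j_enter = j; s_enter = sg;
        }
      }
    }
    // next drop event
    double lam_drop = -1.0; int k_drop = -1;
    for (int k = 0; k < qn; ++k) {
      if (v[k] == 0.0) continue;
      const double ld = u[k] / v[k];
      if (ld > 0.0 && ld < hi && ld > lam_drop) { lam_drop = ld; k_drop = k; }
    }
    double lam_next = std::max(lam_enter, lam_drop);
    if (lam_next < 0.0) lam_next = 0.0;
    // emit grid solutions inside this segment
    while (gi < L && lam[gi] >= lam_next) {
      double* bcol = beta + static_cast<size_t>(gi) * p;
      for (int k = 0; k < qn; ++k) bcol[A[k]] = u[k] - lam[gi] * v[k];
      ++gi;
    }
    if (gi >= L) return;
    if (lam_next <= 0.0) return;   // nothing left to emit
    lam_cur = lam_next;
    if (lam_drop >= lam_enter) {
      chol_delete(k_drop);
      active[A[k_drop]] = 0;
      A.erase(A.begin() + k_drop);
      s.erase(s.begin() + k_drop);
    } else {
      // append entrant; a degenerate pivot means the candidate is linearly
      // dependent on the active set and rides the boundary with zero
      // coefficient — rare enough that CD finishes the path
      if (!chol_append(j_enter)) { fallback_cd(gi); return; }
      A.push_back(j_enter);
      s.push_back(s_enter);
      active[j_enter] = 1;
    }
  }
  fallback_cd(gi);   // event budget exceeded; finish with CD
}

// [[Rcpp::export(name = ".lasso_homotopy_path")]]
NumericMatrix lasso_homotopy_path(NumericMatrix X, NumericVector y,
                                  NumericVector lambda, double cd_tol = 1e-7,
                                  int cd_maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  if (y.size() != n) stop("length(y) != nrow(X)");
  for (int l = 1; l < L; ++l)
    if (lambda[l] > lambda[l - 1]) stop("lambda must be decreasing");
  NumericMatrix beta(p, L);
  homotopy_path(REAL(X), n, p, REAL(y), REAL(lambda), L, REAL(beta),
                cd_tol, cd_maxit);
  return beta;
}

// Mean held-out squared error per (fold, lambda); each fold re-centers its
// training columns/outcome (unpenalized intercept) and solves the exact
// path. Shared by inner_cv_lambda and the fused LOOCV below.
static void cv_mse_fill(const double* X, const double* y, int n, int p,
                        const int* foldid, int k, const double* lam, int L,
                        double* mse /* k x L col-major */, double cd_tol,
                        int cd_maxit) {
  std::vector<double> Xtr, ytr, xbar(p), beta;
  std::vector<int> tr_idx, te_idx;
  for (int f = 1; f <= k; ++f) {
    tr_idx.clear(); te_idx.clear();
    for (int i = 0; i < n; ++i)
      (foldid[i] == f ? te_idx : tr_idx).push_back(i);
    const int ntr = tr_idx.size(), nte = te_idx.size();
    if (ntr < 2 || nte < 1) stop("degenerate CV fold");
    Xtr.assign(static_cast<size_t>(ntr) * p, 0.0);
    ytr.assign(ntr, 0.0);
    double ybar = 0.0;
    for (int t = 0; t < ntr; ++t) ybar += y[tr_idx[t]];
    ybar /= ntr;
    for (int t = 0; t < ntr; ++t) ytr[t] = y[tr_idx[t]] - ybar;
    for (int j = 0; j < p; ++j) {
      const double* xj = X + static_cast<size_t>(j) * n;
      double m = 0.0;
      for (int t = 0; t < ntr; ++t) m += xj[tr_idx[t]];
      m /= ntr;
      xbar[j] = m;
      double* cj = &Xtr[static_cast<size_t>(j) * ntr];
      for (int t = 0; t < ntr; ++t) cj[t] = xj[tr_idx[t]] - m;
    }
    beta.assign(static_cast<size_t>(p) * L, 0.0);
    homotopy_path(Xtr.data(), ntr, p, ytr.data(), lam, L, beta.data(),
                  cd_tol, cd_maxit);
    for (int l = 0; l < L; ++l) {
      const double* b = &beta[static_cast<size_t>(l) * p];
      double se = 0.0;
      for (int t = 0; t < nte; ++t) {
        const int i = te_idx[t];
        double yhat = ybar;
        for (int j = 0; j < p; ++j)
          if (b[j] != 0.0)
            yhat += b[j] * (X[static_cast<size_t>(j) * n + i] - xbar[j]);
        const double d = y[i] - yhat;
        se += d * d;
      }
      mse[static_cast<size_t>(l) * k + (f - 1)] = se / nte;
    }
  }
}

// [[Rcpp::export(name = ".cd_lasso_cv_mse")]]
NumericMatrix cd_lasso_cv_mse(NumericMatrix X, NumericVector y,
                              IntegerVector foldid, int k,
                              NumericVector lambda, double tol = 1e-7,
                              int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  if (foldid.size() != n) stop("foldid length mismatch");
  NumericMatrix mse(k, L);
  cv_mse_fill(REAL(X), REAL(y), n, p, INTEGER(foldid), k, REAL(lambda), L,
              REAL(mse), tol, maxit);
  return mse;
}

// ----------------------------------------------------------------------
// fused leave-one-out pipeline
// ----------------------------------------------------------------------

// Ordinary least squares of each feature column on the covariate design D
// (training rows only), residualizing train and the single test row.
static void residualize_fold(const double* X, const double* D, int n, int p,
                             int qd, const std::vector<int>& tr, int te,
                             std::vector<double>& Xtr,
                             std::vector<double>& xte) {
  const int ntr = tr.size();
  // normal equations A = D_tr'D_tr, factor once
  std::vector<double> A(static_cast<size_t>(qd) * qd, 0.0), Lm;
  for (int a = 0; a < qd; ++a) {
    const double* da = D + static_cast<size_t>(a) * n;
    for (int b = 0; b <= a; ++b) {
      const double* db = D + static_cast<size_t>(b) * n;
      double sacc = 0.0;
      for (int t = 0; t < ntr; ++t) sacc += da[tr[t]] * db[tr[t]];
      A[a * qd + b] = sacc;
      A[b * qd + a] = sacc;
    }
  }
  Lm.assign(static_cast<size_t>(qd) * qd, 0.0);
  for (int i = 0; i < qd; ++i) {
    for (int j = 0; j <= i; ++j) {
      double g = A[i * qd + j];
      for (int kk = 0; kk < j; ++kk) g -= Lm[i * qd + kk] * Lm[j * qd + kk];
      if (i == j) {
        if (g <= 1e-10) stop("covariate design rank deficient in a fold");
        Lm[i * qd + i] = std::sqrt(g);
      } else Lm[i * qd + j] = g / Lm[j * qd + j];
    }
  }
  std::vector<double> rhs(qd), coef(qd);
  for (int j = 0; j < p; ++j) {
    const double* xj = X + static_cast<size_t>(j) * n;
    for (int a = 0; a < qd; ++a) {
      const double* da = D + static_cast<size_t>(a) * n;
      double sacc = 0.0;
      for (int t = 0; t < ntr; ++t) sacc += da[tr[t]] * xj[tr[t]];
      rhs[a] = sacc;
    }
    chol_solve(Lm, qd, qd, rhs, coef);
    double* cj = &Xtr[static_cast<size_t>(j) * ntr];
    for (int t = 0; t < ntr; ++t) {
      double fit = 0.0;
      for (int a = 0; a < qd; ++a)
        fit += coef[a] * D[static_cast<size_t>(a) * n + tr[t]];
      cj[t] = xj[tr[t]] - fit;
    }
    double fit_te = 0.0;
    for (int a = 0; a < qd; ++a)
      fit_te += coef[a] * D[static_cast<size_t>(a) * n + te];
    xte[j] = xj[te] - fit_te;
  }
}

// Full LOOCV: per held-out subject, residualize covariates (if any),
// standardize on the training subjects, build the lambda grid on the
// training fold, pick lambda by inner k-fold CV (fold ids supplied), fit at
// the chosen lambda and predict the held-out subject.
// foldid_mat: (n-1) x n, column i = inner fold assignment for outer fold i.
// [[Rcpp::export(name = ".loocv_lasso")]]
List loocv_lasso(NumericMatrix X, NumericVector y, NumericMatrix D,
                 IntegerMatrix foldid_mat, int k_inner, int n_lambda,
                 double min_ratio, double cd_tol = 1e-7,
                 int cd_maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), qd = D.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (foldid_mat.nrow() != n - 1 || foldid_mat.ncol() != n)
    stop("foldid_mat must be (n-1) x n");
  const double* xp = REAL(X);
  const double* dp = REAL(D);
  NumericVector pred(n), lam_sel(n);
  std::vector<int> tr(n - 1);
  std::vector<double> Xtr(static_cast<size_t>(n - 1) * p), xte(p);
  std::vector<double> ytr(n - 1), grid(n_lambda), mse, beta, cvm;
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int t = 0; t < n; ++t) if (t != i) tr[c++] = t;
    const int ntr = n - 1;
    if (qd > 0) {
      residualize_fold(xp, dp, n, p, qd, tr, i, Xtr, xte);
    } else {
      for (int j = 0; j < p; ++j) {
        const double* xj = xp + static_cast<size_t>(j) * n;
        double* cj = &Xtr[static_cast<size_t>(j) * ntr];
        for (int t = 0; t < ntr; ++t) cj[t] = xj[tr[t]];
        xte[j] = xj[i];
      }
    }
    // standardize on training subjects; dead columns zeroed out
    for (int j = 0; j < p; ++j) {
      double* cj = &Xtr[static_cast<size_t>(j) * ntr];
      double m = 0.0;
      for (int t = 0; t < ntr; ++t) m += cj[t];
      m /= ntr;
      double ss = 0.0;
      for (int t = 0; t < ntr; ++t) { cj[t] -= m; ss += cj[t] * cj[t]; }
      const double sd = std::sqrt(ss / (ntr - 1));
      if (sd < 1e-12) {
        for (int t = 0; t < ntr; ++t) cj[t] = 0.0;
        xte[j] = 0.0;
      } else {
        for (int t = 0; t < ntr; ++t) cj[t] /= sd;
        xte[j] = (xte[j] - m) / sd;
      }
    }
    double ybar = 0.0;
    for (int t = 0; t < ntr; ++t) ybar += y[tr[t]];
    ybar /= ntr;
    for (int t = 0; t < ntr; ++t) ytr[t] = y[tr[t]] - ybar;
    // lambda grid on this training fold
    double lmax = 0.0;
    for (int j = 0; j < p; ++j) {
      const double* cj = &Xtr[static_cast<size_t>(j) * ntr];
      double sacc = 0.0;
      for (int t = 0; t < ntr; ++t) sacc += cj[t] * ytr[t];
      sacc = std::abs(sacc) / ntr;
      if (sacc > lmax) lmax = sacc;
    }
    if (lmax <= 0.0) { pred[i] = ybar; lam_sel[i] = 0.0; continue; }
    const double lstep = std::log(min_ratio) / (n_lambda - 1);
    for (int l = 0; l < n_lambda; ++l)
      grid[l] = lmax * std::exp(lstep * l);
    // inner CV on the (already standardized) training fold
    mse.assign(static_cast<size_t>(k_inner) * n_lambda, 0.0);
    cv_mse_fill(Xtr.data(), ytr.data(), ntr, p,
                &foldid_mat(0, i), k_inner, grid.data(), n_lambda,
                mse.data(), cd_tol, cd_maxit);
    cvm.assign(n_lambda, 0.0);
    for (int l = 0; l < n_lambda; ++l) {
      double sacc = 0.0;
      for (int f = 0; f < k_inner; ++f)
        sacc += mse[static_cast<size_t>(l) * k_inner + f];
      cvm[l] = sacc / k_inner;
    }
    int lbest = 0;
    for (int l = 1; l < n_lambda; ++l) if (cvm[l] < cvm[lbest]) lbest = l;
    // final fit on the full training fold at the chosen lambda
    beta.assign(static_cast<size_t>(p) * (lbest + 1), 0.0);
    homotopy_path(Xtr.data(), ntr, p, ytr.data(), grid.data(), lbest + 1,
                  beta.data(), cd_tol, cd_maxit);
    const double* b = &beta[static_cast<size_t>(lbest) * p];
    double yhat = ybar;
    for (int j = 0; j < p; ++j)
      if (b[j] != 0.0) yhat += b[j] * xte[j];
    pred[i] = yhat;
    lam_sel[i] = grid[lbest];
  }
  return List::create(_["predictions"] = pred,
                      _["per_fold_lambda"] = lam_sel);
}
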