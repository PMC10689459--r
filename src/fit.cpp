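// Multi-start bounded least-squares fitting of the 4-parameter log-logistic
// model. Uses R's internal L-BFGS-B implementation (R_ext/Applic.h) with
// analytic gradients so that screens with 10^4..10^6 curves stay fast.
//
// Parameter vector: (pEC50, slope, front, back)
// Model: yhat = back + (front - back) / (1 + 10^(slope * (x + pEC50)))

#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cfloat>

using namespace Rcpp;

namespace {

const double LN10 = 2.302585092994045684;

struct CurveEnv {
  int n;
  const double *x;
  const double *y;
  const double *w;
};

// logistic factor s = 1 / (1 + 10^u), computed overflow-safely
inline double sig10(double u) {
  if (u > 300.0) return 0.0;
  if (u < -300.0) return 1.0;
  return 1.0 / (1.0 + std::pow(10.0, u));
}

double sse_fn(int npar, double *par, void *ex) {
  (void)npar;
  CurveEnv *env = static_cast<CurveEnv *>(ex);
  const double pec50 = par[0], slope = par[1], front = par[2], back = par[3];
  double sse = 0.0;
  for (int i = 0; i < env->n; ++i) {
    const double s = sig10(slope * (env->x[i] + pec50));
    const double r = env->y[i] - (back + (front - back) * s);
    sse += env->w[i] * r * r;
  }
  if (!std::isfinite(sse)) sse = DBL_MAX;
  return sse;
}

void sse_gr(int npar, double *par, double *gr, void *ex) {
  (void)npar;
  CurveEnv *env = static_cast<CurveEnv *>(ex);
  const double pec50 = par[0], slope = par[1], front = par[2], back = par[3];
  double g0 = 0.0, g1 = 0.0, g2 = 0.0, g3 = 0.0;
  for (int i = 0; i < env->n; ++i) {
    const double z = env->x[i] + pec50;
    const double s = sig10(slope * z);
    const double ss1 = s * (1.0 - s);
    const double r = env->y[i] - (back + (front - back) * s);
    const double wr2 = -2.0 * env->w[i] * r;
    // dyhat/dtheta
    const double d_pec = -(front - back) * LN10 * slope * ss1;
    const double d_slp = -(front - back) * LN10 * z * ss1;
    g0 += wr2 * d_pec;
    g1 += wr2 * d_slp;
    g2 += wr2 * s;
    g3 += wr2 * (1.0 - s);
  }
  gr[0] = g0; gr[1] = g1; gr[2] = g2; gr[3] = g3;
}

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Box-projected Levenberg-Marquardt on the weighted SSE. Allocation-free
// (fixed 4-parameter arrays), used to screen the many starts cheaply; the
// winning candidate is polished with L-BFGS-B afterwards.
double lm_fit(const CurveEnv &env, double *par, const double *l,
              const double *u, int maxit, double tol) {
  double sse = sse_fn(4, par, const_cast<CurveEnv *>(&env));
  double lambda = 1e-3;
  for (int it = 0; it < maxit; ++it) {
    // build normal equations A = J'J, b = J'r with J = dyhat/dtheta * sqrt(w)
    double A[4][4] = {{0}}, b[4] = {0};
    const double pec50 = par[0], slope = par[1], front = par[2], back = par[3];
    for (int i = 0; i < env.n; ++i) {
      const double z = env.x[i] + pec50;
      const double s = sig10(slope * z);
      const double ss1 = s * (1.0 - s);
      const double r = env.y[i] - (back + (front - back) * s);
      const double J[4] = {-(front - back) * LN10 * slope * ss1,
                           -(front - back) * LN10 * z * ss1,
                           s, 1.0 - s};
      const double wi = env.w[i];
      for (int a = 0; a < 4; ++a) {
        b[a] += wi * J[a] * r;
        for (int c = a; c < 4; ++c) A[a][c] += wi * J[a] * J[c];
      }
    }
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < a; ++c) A[a][c] = A[c][a];

    bool stepped = false;
    for (int tries = 0; tries < 30; ++tries) {
      // damped system M = A + lambda * diag(A); solve M delta = b (Cholesky)
      double M[4][4];
      for (int a = 0; a < 4; ++a)
        for (int c = 0; c < 4; ++c)
          M[a][c] = A[a][c] + (a == c ? lambda * (A[a][a] > 0 ? A[a][a] : 1e-12)
                                        + 1e-300
                                      : 0.0);
      double L[4][4] = {{0}};
      bool ok = true;
      for (int a = 0; a < 4 && ok; ++a) {
        double d = M[a][a];
        for (int c = 0; c < a; ++c) d -= L[a][c] * L[a][c];
        if (d <= 0 || !std::isfinite(d)) { ok = false; break; }
        L[a][a] = std::sqrt(d);
        for (int rr = a + 1; rr < 4; ++rr) {
          double v = M[rr][a];
          for (int c = 0; c < a; ++c) v -= L[rr][c] * L[a][c];
          L[rr][a] = v / L[a][a];
        }
      }
      if (!ok) { lambda *= 10.0; continue; }
      double ytmp[4], delta[4];
      for (int a = 0; a < 4; ++a) {
        double v = b[a];
        for (int c = 0; c < a; ++c) v -= L[a][c] * ytmp[c];
        ytmp[a] = v / L[a][a];
      }
      for (int a = 3; a >= 0; --a) {
        double v = ytmp[a];
        for (int c = a + 1; c < 4; ++c) v -= L[c][a] * delta[c];
        delta[a] = v / L[a][a];
      }
      double cand[4];
      for (int a = 0; a < 4; ++a) cand[a] = clampd(par[a] + delta[a], l[a], u[a]);
      double sse_new = sse_fn(4, cand, const_cast<CurveEnv *>(&env));
      if (sse_new < sse) {
        const double gain = sse - sse_new;
        for (int a = 0; a < 4; ++a) par[a] = cand[a];
        sse = sse_new;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (gain <= tol * (sse + tol)) return sse; // converged
        break;
      }
      lambda *= 10.0;
      if (lambda > 1e14) return sse; // stuck (often at an active bound)
    }
    if (!stepped) return sse;
  }
  return sse;
}

} // namespace

// Fit one curve from a matrix of starting points (n_starts x 4), returning the
// lowest-SSE bounded solution over all starts.
// [[Rcpp::export]]
List cc_fit_ols(NumericVector x, NumericVector y, NumericVector w,
                NumericMatrix starts, NumericVector lower, NumericVector upper,
                double factr, double pgtol, int maxit) {
  const int n = x.size();
  if (y.size() != n || w.size() != n)
    stop("x, y, w must have equal length");
  if (starts.ncol() != 4)
    stop("starts must have 4 columns (pEC50, slope, front, back)");

  CurveEnv env;
  env.n = n;
  env.x = REAL(x);
  env.y = REAL(y);
  env.w = REAL(w);

  double l[4], u[4];
  int nbd[4];
  for (int j = 0; j < 4; ++j) {
    l[j] = lower[j];
    u[j] = upper[j];
    nbd[j] = 2; // both bounds
  }

  const int nstarts = starts.nrow();
  std::vector<double> cand_par(4 * nstarts);
  std::vector<double> cand_sse(nstarts, R_PosInf);
  int n_ok = 0;

  // stage 1: coarse Levenberg-Marquardt basin search from every start
  for (int srow = 0; srow < nstarts; ++srow) {
    double *par = &cand_par[4 * srow];
    for (int j = 0; j < 4; ++j) par[j] = clampd(starts(srow, j), l[j], u[j]);
    const double sse = lm_fit(env, par, l, u, 80, 1e-10);
    if (!std::isfinite(sse)) continue;
    ++n_ok;
    cand_sse[srow] = sse;
  }

  // stage 2: polish distinct basins near the coarse optimum with bounded
  // L-BFGS-B. Candidates within a relative SSE margin of the coarse best
  // are considered; duplicates (starts that fell into an already-selected
  // basin) are skipped, so near-tied basins are all resolved at full
  // precision and the winner does not depend on ulp-level input noise.
  std::vector<int> ord(nstarts);
  for (int i = 0; i < nstarts; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return cand_sse[a] < cand_sse[b]; });
  const double coarse_best = cand_sse[ord[0]];
  const double margin = coarse_best * 1.01 + 1e-300;
  const int max_polish = 12;
  std::vector<int> selected;
  for (int pi = 0; pi < nstarts && (int)selected.size() < max_polish; ++pi) {
    const int srow = ord[pi];
    if (!std::isfinite(cand_sse[srow])) break;
    if (cand_sse[srow] > margin && !selected.empty()) break;
    bool dup = false;
    for (int sj : selected) {
      bool close = true;
      for (int j = 0; j < 4; ++j) {
        const double a = cand_par[4 * srow + j], bb = cand_par[4 * sj + j];
        if (std::fabs(a - bb) > 1e-4 * (1.0 + std::fabs(bb))) { close = false; break; }
      }
      if (close) { dup = true; break; }
    }
    if (!dup) selected.push_back(srow);
  }

  double best_par[4] = {NA_REAL, NA_REAL, NA_REAL, NA_REAL};
  double best_sse = R_PosInf;
  int best_start = NA_INTEGER;
  bool best_conv = false;
  char msg[256];
  for (int srow : selected) {
    double par[4];
    for (int j = 0; j < 4; ++j) par[j] = cand_par[4 * srow + j];
    double fmin = cand_sse[srow];
    int fail = 0, fncount = 0, grcount = 0;
    lbfgsb(4, 5, par, l, u, nbd, &fmin, sse_fn, sse_gr, &fail, &env,
           factr, pgtol, &fncount, &grcount, maxit, msg, 0, 10);
    // if the polish cannot improve the candidate it was already at a
    // numerical optimum: keep it and count it as converged even when the
    // line search gave up at machine precision
    bool conv = (fail == 0);
    if (!std::isfinite(fmin) || fmin >= cand_sse[srow]) {
      fmin = cand_sse[srow];
      for (int j = 0; j < 4; ++j) par[j] = cand_par[4 * srow + j];
      conv = true;
    }
    if (fmin < best_sse) {
      best_sse = fmin;
      for (int j = 0; j < 4; ++j) best_par[j] = par[j];
      best_start = srow + 1;
      best_conv = conv;
    }
  }

  return List::create(
      _["par"] = NumericVector::create(_["pEC50"] = best_par[0],
                                       _["slope"] = best_par[1],
                                       _["front"] = best_par[2],
                                       _["back"] = best_par[3]),
      _["sse"] = best_sse,
      _["converged"] = best_conv,
      _["n_starts"] = nstarts,
      _["n_converged"] = n_ok,
      _["best_start"] = best_start);
}

// Weighted SSE of the log-logistic model at fixed parameters (used for the
// global-fit property and by callers that only need the objective).
// [[Rcpp::export]]
double cc_sse_loglogistic(NumericVector x, NumericVector y, NumericVector w,
                          NumericVector par) {
  const int n = x.size();
  if (y.size() != n || w.size() != n) stop("x, y, w must have equal length");
  if (par.size() != 4) stop("par must have length 4");
  CurveEnv env;
  env.n = n;
  env.x = REAL(x);
  env.y = REAL(y);
  env.w = REAL(w);
  double p[4] = {par[0], par[1], par[2], par[3]};
  return sse_fn(4, p, &env);
}
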