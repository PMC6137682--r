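// Kernel-weighted marginal ML estimation of ICC slope/intercept curves at
// focal points of the residual log response time.
//
// The weighted item log-likelihood for item i at focal point j is
//   sum_p ln sum_q gw_q * exp(rest_pq) * Psi(alpha*th_q + beta, x_pi)^{w_pj}
// where rest_pq is the log-likelihood of person p's responses to all other
// items at quadrature node q under the current response-specific
// parameters.  Each (item, focal point) problem is solved by a damped
// Newton ascent in (alpha, beta) inside a box, started from the previous
// sweep's value.

#include <Rcpp.h>
using namespace Rcpp;

static const double CLIP = 8.0;

// log Phi(e) via erfc: exact to machine precision on the clipped range
// |e| <= 8 (erfc(8/sqrt(2)) ~ 1.2e-15 is far above double underflow).
static inline double log_phi_fast(double e) {
  return std::log(0.5 * std::erfc(-e * M_SQRT1_2));
}

// log Psi(eta, x) and its first/second derivative helpers
static inline double log_psi1(double eta, int x) {
  double e = eta > CLIP ? CLIP : (eta < -CLIP ? -CLIP : eta);
  return log_phi_fast(x ? e : -e);
}

// Tabulated log Phi on [-8, 8] (step 1e-3, linear interpolation, max error
// ~3e-7 in log space) for the bulk per-sweep rebuild loops, where that
// error is negligible against the 1e-3 sweep tolerance.  The Newton
// optimizer and the exported likelihood oracle keep the exact version.
static std::vector<double> LPHI_TAB;
static const int TAB_N = 16001;
static const double TAB_STEP = 1e-3;
static void init_lphi_tab() {
  if (!LPHI_TAB.empty()) return;
  LPHI_TAB.resize(TAB_N);
  for (int i = 0; i < TAB_N; ++i)
    LPHI_TAB[i] = log_phi_fast(-CLIP + i * TAB_STEP);
}
static inline double log_psi1_tab(double eta, int x) {
  double e = x ? eta : -eta;
  if (e <= -CLIP) return LPHI_TAB[0];
  if (e >= CLIP) return LPHI_TAB[TAB_N - 1];
  double u = (e + CLIP) / TAB_STEP;
  int i = (int)u;
  double fr = u - i;
  return LPHI_TAB[i] + fr * (LPHI_TAB[i + 1] - LPHI_TAB[i]);
}

// u = d log Psi / d eta ; returns u, and via ref du = du/deta = -eta*u - u^2
static inline double dlog_psi(double eta, int x, double &du) {
  double e = eta > CLIP ? CLIP : (eta < -CLIP ? -CLIP : eta);
  double lphi = -0.5 * e * e - 0.9189385332046727;   // log standard normal pdf
  double u;
  if (x) u = std::exp(lphi - log_phi_fast(e));
  else   u = -std::exp(lphi - log_phi_fast(-e));
  du = -e * u - u * u;
  return u;
}

struct FocalProblem {
  int N, Q;                   // N = number of ACTIVE persons
  const int *idx;             // active person indices into the full arrays
  const int *x;               // responses to the target item (full length)
  const double *w;            // kernel weights (full length)
  const double *cmat;         // full-N x Q matrix exp(log_gw + rest - rowmax)
  const int *nact;            // per full person: number of active nodes
  const int *qidx;            // per full person: active node indices (Q stride)
  int Nfull;
  const double *th;           // quadrature nodes, length Q
  double base;                // constant: sum over inactive persons of ln s_p
};

// objective, gradient, Hessian at (a, b).  The probit pieces depend only on
// the node, so all tail evaluations are O(Q); the person x node loop is
// pure arithmetic over the active sets.
static double fgh(const FocalProblem &P, double a, double b,
                  double *grad, double *hess) {
  double f = P.base;
  bool wantg = grad != NULL, wanth = hess != NULL;
  if (wantg) { grad[0] = grad[1] = 0.0; }
  if (wanth) { hess[0] = hess[1] = hess[2] = 0.0; }
  std::vector<double> lp0(P.Q), lp1(P.Q), u0(P.Q), u1(P.Q), du0(P.Q), du1(P.Q);
  for (int q = 0; q < P.Q; ++q) {
    double eta = a * P.th[q] + b;
    lp1[q] = log_psi1(eta, 1);
    lp0[q] = log_psi1(eta, 0);
    if (wantg) {
      u1[q] = dlog_psi(eta, 1, du1[q]);
      u0[q] = dlog_psi(eta, 0, du0[q]);
    }
  }
  for (int pi = 0; pi < P.N; ++pi) {
    int p = P.idx[pi];
    int xp = P.x[p];
    double wp = P.w[p];
    const double *lp = xp ? &lp1[0] : &lp0[0];
    const double *uu = xp ? &u1[0] : &u0[0];
    const double *dd = xp ? &du1[0] : &du0[0];
    double s = 0.0, g0 = 0.0, g1 = 0.0, h00 = 0.0, h01 = 0.0, h11 = 0.0;
    const double *crow = P.cmat + (size_t)p;   // column-major stride Nfull
    const int *qa = P.qidx + (size_t)p * P.Q;
    int nq = P.nact[p];
    for (int qq = 0; qq < nq; ++qq) {
      int q = qa[qq];
      double c = crow[(size_t)q * P.Nfull];
      double t = c * std::exp(wp * lp[q]);
      s += t;
      if (!wantg) continue;
      double A = wp * uu[q];
      double tq = t * A;
      g0 += tq * P.th[q];
      g1 += tq;
      if (wanth) {
        double B = A * A + wp * dd[q];
        double tb = t * B;
        h00 += tb * P.th[q] * P.th[q];
        h01 += tb * P.th[q];
        h11 += tb;
      }
    }
    if (s <= 0.0 || !R_finite(s)) return -std::numeric_limits<double>::infinity();
    f += std::log(s);
    if (wantg) {
      double G0 = g0 / s, G1 = g1 / s;
      grad[0] += G0; grad[1] += G1;
      if (wanth) {
        hess[0] += h00 / s - G0 * G0;
        hess[1] += h01 / s - G0 * G1;
        hess[2] += h11 / s - G1 * G1;
      }
    }
  }
  return f;
}

// Damped projected Newton ascent inside [alo,ahi] x [blo,bhi].
static void solve_focal(const FocalProblem &P, double &a, double &b,
                        double alo, double ahi, double blo, double bhi,
                        bool &ok) {
  double grad[2], hess[3], gn2[2], hn2[3];
  double f = fgh(P, a, b, grad, hess);
  ok = R_finite(f);
  if (!ok) return;
  for (int it = 0; it < 60; ++it) {
    // ascent direction: Newton if -H is positive definite, else gradient
    double da, db;
    double det = hess[0] * hess[2] - hess[1] * hess[1];
    if (hess[0] < 0 && det > 0) {
      da = -( hess[2] * grad[0] - hess[1] * grad[1]) / det;
      db = -(-hess[1] * grad[0] + hess[0] * grad[1]) / det;
    } else {
      double gn = std::sqrt(grad[0] * grad[0] + grad[1] * grad[1]) + 1e-12;
      da = grad[0] / gn * 0.25; db = grad[1] / gn * 0.25;
    }
    // limit step length for stability
    double sn = std::sqrt(da * da + db * db);
    if (sn > 2.0) { da *= 2.0 / sn; db *= 2.0 / sn; }
    double an = std::min(std::max(a + da, alo), ahi);
    double bn = std::min(std::max(b + db, blo), bhi);
    // already converged (common in later sweeps): no further evaluation
    if (std::max(std::fabs(an - a), std::fabs(bn - b)) < 1e-6) break;
    // full step with derivatives; backtrack with cheap evaluations only if
    // it fails to ascend
    double fnew = fgh(P, an, bn, gn2, hn2);
    if (!(fnew >= f - 1e-12)) {
      double step = 0.5;
      for (int ls = 0; ls < 11; ++ls) {
        an = std::min(std::max(a + step * da, alo), ahi);
        bn = std::min(std::max(b + step * db, blo), bhi);
        fnew = fgh(P, an, bn, NULL, NULL);
        if (fnew >= f - 1e-12) break;
        step *= 0.5;
      }
      fnew = fgh(P, an, bn, gn2, hn2);
    }
    double move = std::max(std::fabs(an - a), std::fabs(bn - b));
    a = an; b = bn; f = fnew;
    grad[0] = gn2[0]; grad[1] = gn2[1];
    hess[0] = hn2[0]; hess[1] = hn2[1]; hess[2] = hn2[2];
    if (!R_finite(f)) { ok = false; return; }
    if (move < 1e-6) break;
  }
}

// [[Rcpp::export]]
List cpp_estimate_curves(IntegerMatrix X, NumericMatrix Zhat,
                         NumericVector focal, double h,
                         NumericVector alpha_init, NumericVector beta_init,
                         NumericVector theta_nodes, NumericVector gh_weights,
                         double tol, int max_sweeps,
                         double alpha_lo, double alpha_hi,
                         double beta_lo, double beta_hi,
                         double min_sum_w) {
  const int N = X.nrow(), K = X.ncol(), J = focal.size(), Q = theta_nodes.size();
  const double bw = h * std::pow((double)N, -0.2);
  const double inv2bw2 = 1.0 / (2.0 * bw * bw);

  NumericMatrix alpha_curve(K, J), beta_curve(K, J), sum_w(K, J);
  NumericMatrix alpha_star(N, K), beta_star(N, K);
  std::vector<double> log_gw(Q);
  for (int q = 0; q < Q; ++q) log_gw[q] = std::log(gh_weights[q]);

  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < J; ++j) {
      alpha_curve(i, j) = alpha_init[i];
      beta_curve(i, j) = beta_init[i];
    }
    for (int p = 0; p < N; ++p) {
      alpha_star(p, i) = alpha_init[i];
      beta_star(p, i) = beta_init[i];
    }
  }

  // total_pq = sum_k log Psi(alpha*_pk th_q + beta*_pk, x_pk)
  init_lphi_tab();
  NumericMatrix total(N, Q);
  for (int p = 0; p < N; ++p)
    for (int q = 0; q < Q; ++q) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += log_psi1_tab(alpha_star(p, k) * theta_nodes[q] + beta_star(p, k), X(p, k));
      total(p, q) = s;
    }

  NumericMatrix cmat(N, Q);
  std::vector<double> rest_log((size_t)N * Q);
  std::vector<double> wvec(N);
  std::vector<int> xcol(N), nact(N), qidx((size_t)N * Q), pact(N);
  int sweeps_done = 0;
  bool converged = false;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_change = 0.0;
    for (int i = 0; i < K; ++i) {
      // rest = total - own contribution; shift by row max, exponentiate.
      // Nodes with negligible posterior mass (< 1e-14 of the row maximum)
      // are dropped from the optimization loops.
      for (int p = 0; p < N; ++p) {
        xcol[p] = X(p, i);
        double own_a = alpha_star(p, i), own_b = beta_star(p, i);
        double mx = -INFINITY;
        for (int q = 0; q < Q; ++q) {
          double r = total(p, q) -
            log_psi1_tab(own_a * theta_nodes[q] + own_b, xcol[p]);
          rest_log[(size_t)p * Q + q] = r;
          r += log_gw[q];
          cmat(p, q) = r;
          if (r > mx) mx = r;
        }
        int na = 0;
        for (int q = 0; q < Q; ++q) {
          double c = std::exp(cmat(p, q) - mx);
          cmat(p, q) = c;
          if (c >= 1e-14) qidx[(size_t)p * Q + na++] = q;
        }
        nact[p] = na;
      }
      FocalProblem P;
      P.Nfull = N; P.Q = Q; P.x = &xcol[0]; P.cmat = REAL(cmat);
      P.th = REAL(theta_nodes);
      P.nact = &nact[0]; P.qidx = &qidx[0];
      P.base = 0.0;
      for (int j = 0; j < J; ++j) {
        double Fj = focal[j], sw = 0.0;
        int np = 0;
        for (int p = 0; p < N; ++p) {
          double d = Zhat(p, i) - Fj;
          wvec[p] = std::exp(-d * d * inv2bw2);
          sw += wvec[p];
          // persons with negligible weight contribute an (a,b)-constant
          // term; drop them from the optimization
          if (wvec[p] >= 1e-9) pact[np++] = p;
        }
        sum_w(i, j) = sw;
        P.w = &wvec[0];
        P.idx = &pact[0];
        P.N = np;
        double a = alpha_curve(i, j), b = beta_curve(i, j);
        bool ok = true;
        solve_focal(P, a, b, alpha_lo, alpha_hi, beta_lo, beta_hi, ok);
        if (!ok || !R_finite(a) || !R_finite(b))
          stop("optimizer failure at item %d, focal point %d", i + 1, j + 1);
        max_change = std::max(max_change,
          std::max(std::fabs(a - alpha_curve(i, j)),
                   std::fabs(b - beta_curve(i, j))));
        alpha_curve(i, j) = a;
        beta_curve(i, j) = b;
      }
      // update response-specific parameters by piecewise-linear interpolation
      for (int p = 0; p < N; ++p) {
        double zp = Zhat(p, i), anew, bnew;
        if (zp <= focal[0]) { anew = alpha_curve(i, 0); bnew = beta_curve(i, 0); }
        else if (zp >= focal[J - 1]) { anew = alpha_curve(i, J - 1); bnew = beta_curve(i, J - 1); }
        else {
          int j = 0;
          while (j < J - 2 && focal[j + 1] < zp) ++j;
          double t = (zp - focal[j]) / (focal[j + 1] - focal[j]);
          anew = alpha_curve(i, j) + t * (alpha_curve(i, j + 1) - alpha_curve(i, j));
          bnew = beta_curve(i, j) + t * (beta_curve(i, j + 1) - beta_curve(i, j));
        }
        // refresh total with the new own contribution (rest was cached
        // during the cmat build)
        for (int q = 0; q < Q; ++q) {
          total(p, q) = rest_log[(size_t)p * Q + q] +
            log_psi1_tab(anew * theta_nodes[q] + bnew, xcol[p]);
        }
        alpha_star(p, i) = anew;
        beta_star(p, i) = bnew;
      }
    }
    sweeps_done = sweep + 1;
    if (max_change < tol) { converged = true; break; }
  }

  LogicalMatrix low_info(K, J);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < J; ++j) low_info(i, j) = sum_w(i, j) < min_sum_w;

  return List::create(
    _["alpha_curve"] = alpha_curve, _["beta_curve"] = beta_curve,
    _["alpha_star"] = alpha_star, _["beta_star"] = beta_star,
    _["sum_weights"] = sum_w, _["low_info"] = low_info,
    _["n_sweeps"] = sweeps_done, _["converged"] = converged);
}

// Weighted item log-likelihood (exported for cross-checking the R oracle):
// same objective as solved above, WITHOUT the row-max shift removed.
// [[Rcpp::export]]
double cpp_weighted_loglik(double alpha, double beta, IntegerVector x,
                           NumericVector w, NumericMatrix rest_log,
                           NumericVector theta_nodes, NumericVector gh_weights) {
  int N = x.size(), Q = theta_nodes.size();
  double f = 0.0;
  for (int p = 0; p < N; ++p) {
    double mx = -INFINITY;
    std::vector<double> v(Q);
    for (int q = 0; q < Q; ++q) {
      v[q] = std::log(gh_weights[q]) + rest_log(p, q) +
        w[p] * log_psi1(alpha * theta_nodes[q] + beta, x[p]);
      if (v[q] > mx) mx = v[q];
    }
    double s = 0.0;
    for (int q = 0; q < Q; ++q) s += std::exp(v[q] - mx);
    f += mx + std::log(s);
  }
  return f;
}

// One-pass joint log-likelihood pieces for the Gibbs sampler: residual z,
// probit argument eta, accuracy log Psi and log-normal time log-density.
// model codes: 0 = ci, 1 = linear, 2 = quadratic, 3 = multicat.
// [[Rcpp::export]]
List cpp_joint_loglik(NumericMatrix lnT, IntegerMatrix X,
                      NumericVector theta, NumericVector tau,
                      NumericVector xi, NumericVector sigma,
                      NumericMatrix A, NumericMatrix C,
                      int model, NumericVector thresholds, int baseline,
                      bool want_eta) {
  const int N = lnT.nrow(), K = lnT.ncol();
  const int M = thresholds.size() + 1;
  NumericMatrix acc(N, K), rt(N, K);
  NumericMatrix eta_out = want_eta ? NumericMatrix(N, K) : NumericMatrix(0, 0);
  const double LN_SQRT_2PI = 0.9189385332046727;
  for (int i = 0; i < K; ++i) {
    const double xii = xi[i], sigi = sigma[i];
    const double lsig = std::log(sigi);
    for (int p = 0; p < N; ++p) {
      const double mu = xii - tau[p];
      const double e = (lnT(p, i) - mu) / sigi;
      double s, t;
      switch (model) {
      case 0: s = A(i, 0); t = C(i, 0); break;
      case 1: s = A(i, 0) + A(i, 1) * e; t = C(i, 0) + C(i, 1) * e; break;
      case 2: s = A(i, 0) + (A(i, 1) + A(i, 2) * e) * e;
              t = C(i, 0) + (C(i, 1) + C(i, 2) * e) * e; break;
      default: {
        int cat = 1;
        while (cat < M && e >= thresholds[cat - 1]) ++cat;
        s = A(i, 0); t = C(i, 0);
        if (cat != baseline) {
          int col = cat < baseline ? cat : cat - 1;
          s += A(i, col); t += C(i, col);
        }
      }
      }
      const double eta = s * theta[p] + t;
      acc(p, i) = log_psi1(eta, X(p, i));
      rt(p, i) = -LN_SQRT_2PI - lsig - 0.5 * e * e;
      if (want_eta) eta_out(p, i) = eta;
    }
  }
  return List::create(_["acc"] = acc, _["rt"] = rt, _["eta"] = eta_out);
}

// E-step work matrix for the plain 2PNO EM: lp(p,q) = log gw_q +
// sum_k log Psi(alpha_k th_q + beta_k, x_pk).
// [[Rcpp::export]]
NumericMatrix cpp_2pno_estep(IntegerMatrix X, NumericVector alpha,
                             NumericVector beta, NumericVector theta_nodes,
                             NumericVector log_gw) {
  const int N = X.nrow(), K = X.ncol(), Q = theta_nodes.size();
  init_lphi_tab();
  NumericMatrix lp(N, Q);
  for (int q = 0; q < Q; ++q) {
    double lg = log_gw[q];
    for (int p = 0; p < N; ++p) lp(p, q) = lg;
  }
  for (int k = 0; k < K; ++k) {
    std::vector<double> l1(Q), l0(Q);
    for (int q = 0; q < Q; ++q) {
      double eta = alpha[k] * theta_nodes[q] + beta[k];
      l1[q] = log_psi1(eta, 1);
      l0[q] = log_psi1(eta, 0);
    }
    for (int q = 0; q < Q; ++q) {
      double a1 = l1[q], a0 = l0[q];
      for (int p = 0; p < N; ++p) lp(p, q) += X(p, k) ? a1 : a0;
    }
  }
  return lp;
}
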