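// Marginal likelihood (and analytic gradient) of the three-level
// random-intercept logistic model by nested adaptive Gauss-Hermite
// quadrature.
//
// Data layout: rows sorted by state then county; county_ptr holds row
// offsets of the nC county blocks, state_ptr holds county offsets of the
// nS state blocks. eta0 = X beta is precomputed on the R side. vwarm /
// uwarm carry posterior-mode warm starts across likelihood evaluations
// (updated in place; they only affect Newton starting points, never the
// converged value).
//
// The gradient treats the adaptive centres and scales as fixed at their
// converged values (the standard AGQ score approximation); with respect
// to beta it is returned as the vector of posterior-mean residuals
// E[y_i - p_i], to be contracted with X on the R side; with respect to
// the log standard deviations it uses d log phi(u; s)/d log s = u^2/s^2 - 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log(1 + e^eta) and p = logistic(eta) from a single exponential
static inline void logistic_terms(double eta, double& log1pe, double& p) {
  if (eta > 0) {
    double e = std::exp(-eta);
    log1pe = eta + std::log1p(e);
    p = 1.0 / (1.0 + e);
  } else {
    double e = std::exp(eta);
    log1pe = std::log1p(e);
    p = e / (1.0 + e);
  }
}

static inline double dnorm_log(double x, double sd) {
  double z = x / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727417803297;
}

// Bernoulli-logit log-likelihood of rows [lo, hi) at common added offset,
// with gradient and curvature with respect to that offset.
static inline void block_llk(const double* eta0, const double* y,
                             int lo, int hi, double add,
                             double& ll, double& gr, double& he) {
  ll = 0.0; gr = 0.0; he = 0.0;
  for (int i = lo; i < hi; ++i) {
    double log1pe, p;
    logistic_terms(eta0[i] + add, log1pe, p);
    ll += y[i] * (eta0[i] + add) - log1pe;
    gr += y[i] - p;
    he -= p * (1.0 - p);
  }
}

// Penalized posterior mode of one county intercept (damped Newton on a
// strictly concave objective).
static inline double county_mode(const double* eta0, const double* y,
                                 int lo, int hi, double v, double isu2,
                                 double start, double& he_out) {
  double u = start, ll, gr, he;
  for (int it = 0; it < 60; ++it) {
    block_llk(eta0, y, lo, hi, v + u, ll, gr, he);
    double step = -(gr - u * isu2) / (he - isu2);
    if (step > 5.0) step = 5.0; else if (step < -5.0) step = -5.0;
    u += step;
    if (std::fabs(step) < 1e-9 * (1.0 + std::fabs(u))) {
      block_llk(eta0, y, lo, hi, v + u, ll, gr, he);
      break;
    }
  }
  he_out = he - isu2;
  return u;
}

// log M_j(v) = log \int p(y_j | v + u) phi(u; su) du by adaptive GH
// quadrature centred on the posterior mode. Optionally:
//   dv      — accumulates d log M_j / dv (posterior-averaged score), and
//   racc    — accumulates Wq * E[y_i - p_i] into racc[lo..hi) together
//             with Wq * E[u^2/su^2 - 1] into acc_lsu.
static double county_logM(const double* eta0, const double* y, int lo, int hi,
                          double v, double sig_u,
                          const double* a, const double* lw, int nq,
                          double& uwarm, double* dv,
                          double Wq = 0.0, double* racc = nullptr,
                          double* acc_lsu = nullptr) {
  double ll, gr, he;
  if (sig_u <= 0.0) {
    block_llk(eta0, y, lo, hi, v, ll, gr, he);
    if (dv) *dv += gr;
    if (racc)
      for (int i = lo; i < hi; ++i) {
        double log1pe, p;
        logistic_terms(eta0[i] + v, log1pe, p);
        racc[i] += Wq * (y[i] - p);
      }
    return ll;
  }
  const int len = hi - lo;
  double isu2 = 1.0 / (sig_u * sig_u);
  double he_pen;
  double uhat = county_mode(eta0, y, lo, hi, v, isu2, uwarm, he_pen);
  uwarm = uhat;
  double tau = 1.0 / std::sqrt(-he_pen);
  static thread_local std::vector<double> resid;
  if (racc && (int) resid.size() < nq * len) resid.resize(nq * len);
  std::vector<double> term(nq), sc(nq), uval(nq);
  double m = -INFINITY;
  for (int t = 0; t < nq; ++t) {
    double u = uhat + M_SQRT2 * tau * a[t];
    uval[t] = u;
    double llt = 0.0, grt = 0.0;
    double* rt = racc ? resid.data() + t * len : nullptr;
    for (int i = lo; i < hi; ++i) {
      double log1pe, p;
      logistic_terms(eta0[i] + v + u, log1pe, p);
      llt += y[i] * (eta0[i] + v + u) - log1pe;
      grt += y[i] - p;
      if (rt) rt[i - lo] = y[i] - p;
    }
    term[t] = lw[t] + a[t] * a[t] + llt + dnorm_log(u, sig_u);
    sc[t] = grt;
    if (term[t] > m) m = term[t];
  }
  double s = 0.0, sg = 0.0;
  for (int t = 0; t < nq; ++t) {
    term[t] = std::exp(term[t] - m);
    s += term[t]; sg += term[t] * sc[t];
  }
  if (dv) *dv += sg / s;
  if (racc) {
    double a_ls = 0.0;
    for (int t = 0; t < nq; ++t) {
      double w = Wq * term[t] / s;
      const double* rt = resid.data() + t * len;
      for (int i = 0; i < len; ++i) racc[lo + i] += w * rt[i];
      double zu = uval[t] / sig_u;
      a_ls += w * (zu * zu - 1.0);
    }
    *acc_lsu += a_ls;
  }
  return m + std::log(s) + std::log(M_SQRT2 * tau);
}

struct StateBlock {
  const double* eta0; const double* y;
  const int* county_ptr; int c0, c1;
  double sig_u, sig_v;
  const double* a; const double* lw; int nq;
  double* uwarm;

  // G(v) = sum_j log M_j(v) + log phi(v; sig_v); optional d/dv; optional
  // gradient accumulation with outer posterior weight Wq.
  double G(double v, double* grad, double Wq = 0.0, double* racc = nullptr,
           double* acc_lsu = nullptr) const {
    double out = 0.0, g = 0.0;
    for (int c = c0; c < c1; ++c)
      out += county_logM(eta0, y, county_ptr[c], county_ptr[c + 1], v,
                         sig_u, a, lw, nq, uwarm[c],
                         grad ? &g : (double*) nullptr, Wq, racc, acc_lsu);
    if (sig_v > 0.0) {
      out += dnorm_log(v, sig_v);
      g -= v / (sig_v * sig_v);
    }
    if (grad) *grad = g;
    return out;
  }

  // Maximize G by Newton on the analytic gradient with secant curvature.
  double mode(double start, double& hess) const {
    double v = start, g;
    G(v, &g);
    double h0 = 1e-4 * (1.0 + std::fabs(v));
    double g2;
    G(v + h0, &g2);
    hess = (g2 - g) / h0;
    if (hess >= -1e-8) hess = -1.0;
    double v_prev = v, g_prev = g;
    for (int it = 0; it < 40; ++it) {
      double step = -g / hess;
      if (step > 2.0) step = 2.0; else if (step < -2.0) step = -2.0;
      v_prev = v; g_prev = g;
      v += step;
      if (std::fabs(step) < 1e-8 * (1.0 + std::fabs(v))) break;
      G(v, &g);
      if (std::fabs(v - v_prev) > 1e-12) {
        double h2 = (g - g_prev) / (v - v_prev);
        if (h2 < -1e-8) hess = h2;
      }
      if (std::fabs(g) < 1e-10) break;
    }
    return v;
  }
};

// [[Rcpp::export]]
List agq_nll_grad(NumericVector eta0, NumericVector y,
                  IntegerVector county_ptr, IntegerVector state_ptr,
                  double sig_u, double sig_v,
                  NumericVector gh_nodes, NumericVector gh_logw,
                  NumericVector vwarm, NumericVector uwarm,
                  bool want_grad) {
  const int nS = state_ptr.size() - 1;
  const int n = eta0.size();
  const int nq = gh_nodes.size();
  double total = 0.0, g_lsu = 0.0, g_lsv = 0.0;
  NumericVector racc(want_grad ? n : 0);
  double* rp = want_grad ? racc.begin() : nullptr;
  double dummy_lsu = 0.0;
  for (int s = 0; s < nS; ++s) {
    StateBlock blk{eta0.begin(), y.begin(), county_ptr.begin(),
                   state_ptr[s], state_ptr[s + 1], sig_u, sig_v,
                   gh_nodes.begin(), gh_logw.begin(), nq, uwarm.begin()};
    if (sig_v <= 0.0) {
      if (want_grad)
        total += blk.G(0.0, nullptr, 1.0, rp, &g_lsu);
      else
        total += blk.G(0.0, nullptr);
      continue;
    }
    double hess;
    double vhat = blk.mode(vwarm[s], hess);
    vwarm[s] = vhat;
    double tauv = 1.0 / std::sqrt(-hess);
    std::vector<double> term(nq), vq(nq);
    double m = -INFINITY;
    for (int q = 0; q < nq; ++q) {
      vq[q] = vhat + M_SQRT2 * tauv * gh_nodes[q];
      term[q] = gh_logw[q] + gh_nodes[q] * gh_nodes[q] + blk.G(vq[q], nullptr);
      if (term[q] > m) m = term[q];
    }
    double ssum = 0.0;
    for (int q = 0; q < nq; ++q) {
      term[q] = std::exp(term[q] - m);
      ssum += term[q];
    }
    total += m + std::log(ssum) + std::log(M_SQRT2 * tauv);
    if (want_grad) {
      for (int q = 0; q < nq; ++q) {
        double Wq = term[q] / ssum;
        blk.G(vq[q], nullptr, Wq, rp, sig_u > 0 ? &g_lsu : &dummy_lsu);
        double zv = vq[q] / sig_v;
        g_lsv += Wq * (zv * zv - 1.0);
      }
    }
  }
  return List::create(Named("nll") = -total, Named("resid") = racc,
                      Named("g_lsu") = g_lsu, Named("g_lsv") = g_lsv);
}

// Empirical-Bayes posterior modes at fixed parameters: state modes of the
// county-integrated posterior, then county modes conditional on them.
// [[Rcpp::export]]
List agq_modes(NumericVector eta0, NumericVector y,
               IntegerVector county_ptr, IntegerVector state_ptr,
               double sig_u, double sig_v,
               NumericVector gh_nodes, NumericVector gh_logw) {
  const int nS = state_ptr.size() - 1;
  const int nC = county_ptr.size() - 1;
  const int nq = gh_nodes.size();
  NumericVector vhat(nS), uhat(nC);
  std::vector<double> uw(nC, 0.0);
  for (int s = 0; s < nS; ++s) {
    StateBlock blk{eta0.begin(), y.begin(), county_ptr.begin(),
                   state_ptr[s], state_ptr[s + 1], sig_u, sig_v,
                   gh_nodes.begin(), gh_logw.begin(), nq, uw.data()};
    double v = 0.0;
    if (sig_v > 0.0) {
      double hess;
      v = blk.mode(0.0, hess);
    }
    vhat[s] = v;
    if (sig_u > 0.0) {
      double isu2 = 1.0 / (sig_u * sig_u), he;
      for (int c = state_ptr[s]; c < state_ptr[s + 1]; ++c)
        uhat[c] = county_mode(eta0.begin(), y.begin(), county_ptr[c],
                              county_ptr[c + 1], v, isu2, uw[c], he);
    }
  }
  return List::create(Named("v") = vhat, Named("u") = uhat);
}
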