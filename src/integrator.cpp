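// Adaptive Dormand-Prince 5(4) integration of the package's model classes
// and benchmark systems. Parameter vectors are packed by the R wrappers:
//   model 1 (S-system):  J, K, alpha[J], beta[J], g[J*(J+K)], h[J*(J+K)]
//   model 2 (sigmoidal): J, K, tau[J], theta[J+K], W[J*(J+K)]
//   model 3 (gravity):   ell, mu                      (state: r, v)
//   model 4 (phospho):   n_states, n_trans, then per transition
//                        (from0, to0, V, K, input_flag)
//   model 5 (glycolysis): 16 constants, fixed order (see R/benchmarks.R)
// Matrices are row-major; inputs enter as constant pseudo-variables.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Status { ST_OK = 0, ST_POSITIVITY = 1, ST_BLOWUP = 2, ST_FAILURE = 3 };

static inline double sigmoid_c(double y) {
  // 1/(1+e^y), stable for large |y|
  if (y > 0) {
    double e = std::exp(-y);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(y));
}

struct Model {
  int code;
  int J;                       // dynamical dimension
  const double *p;             // packed parameters (after any header)
  const double *inputs;
  int K;
  mutable bool nonpos = false; // last rhs failure hit a non-positive state

  // writes dx[0..J)
  bool rhs(const double *x, double *dx, long *n_eval) const {
    ++*n_eval;
    nonpos = false;
    switch (code) {
    case 1: { // S-system
      int JK = J + K;
      const double *alpha = p, *beta = p + J;
      const double *g = p + 2 * J, *h = p + 2 * J + J * JK;
      for (int i = 0; i < J; ++i) {
        double prod = alpha[i], deg = beta[i];
        for (int j = 0; j < JK; ++j) {
          double xj = (j < J) ? x[j] : inputs[j - J];
          if (xj <= 0.0) { if (j < J) nonpos = true; return false; }
          double gij = g[i * JK + j], hij = h[i * JK + j];
          if (gij != 0.0 && prod != 0.0) prod *= std::pow(xj, gij);
          if (hij != 0.0 && deg != 0.0) deg *= std::pow(xj, hij);
        }
        dx[i] = prod - deg;
        if (!std::isfinite(dx[i])) return false;
      }
      return true;
    }
    case 2: { // sigmoidal (CTRNN convention)
      int JK = J + K;
      const double *tau = p, *theta = p + J, *W = p + J + JK;
      for (int i = 0; i < J; ++i) {
        double s = -x[i] / tau[i];
        for (int j = 0; j < JK; ++j) {
          double wij = W[i * JK + j];
          if (wij != 0.0) {
            double xj = (j < J) ? x[j] : inputs[j - J];
            s += wij * sigmoid_c(theta[j] - xj);
          }
        }
        dx[i] = s;
        if (!std::isfinite(dx[i])) return false;
      }
      return true;
    }
    case 3: { // reduced radial two-body problem
      double ell = p[0], mu = p[1];
      double r = x[0];
      if (r <= 0.0) return false;
      dx[0] = x[1];
      dx[1] = ell * ell / (r * r * r) - mu / (r * r);
      return true;
    }
    case 4: { // microstate phosphorylation network
      int n_states = (int) p[0], n_trans = (int) p[1];
      for (int i = 0; i < n_states; ++i) dx[i] = 0.0;
      const double *tr = p + 2;
      for (int t = 0; t < n_trans; ++t) {
        int from = (int) tr[5 * t], to = (int) tr[5 * t + 1];
        double V = tr[5 * t + 2], Km = tr[5 * t + 3];
        if (tr[5 * t + 4] != 0.0) V = inputs[0];
        double xf = x[from];
        double rate = V * xf / (Km + xf);
        dx[from] -= rate;
        dx[to] += rate;
      }
      for (int i = 0; i < n_states; ++i)
        if (!std::isfinite(dx[i])) return false;
      return true;
    }
    case 5: { // yeast glycolysis oscillator, 7 species
      const double *c = p;
      double J0 = c[0], k1 = c[1], K1 = c[2], q = c[3], k2 = c[4], k3 = c[5],
             k4 = c[6], k5 = c[7], k6 = c[8], kk = c[9], kappa = c[10],
             psi = c[11], Ntot = c[12], Atot = c[13], n_tri = c[14],
             n_atp = c[15];
      double S1 = x[0], S2 = x[1], S3 = x[2], S4 = x[3], S5 = x[4],
             S6 = x[5], S7 = x[6];
      double v1 = k1 * S1 * S6 / (1.0 + std::pow(S6 / K1, q));
      double v2 = k2 * S2 * (Ntot - S5);
      double v3 = k3 * S3 * (Atot - S6);
      dx[0] = J0 - v1;
      dx[1] = n_tri * v1 - v2 - k6 * S2 * S5;
      dx[2] = v2 - v3;
      dx[3] = v3 - k4 * S4 * S5 - kappa * (S4 - S7);
      dx[4] = v2 - k4 * S4 * S5 - k6 * S2 * S5;
      dx[5] = -n_atp * v1 + n_atp * v3 - k5 * S6;
      dx[6] = psi * kappa * (S4 - S7) - kk * S7;
      for (int i = 0; i < 7; ++i)
        if (!std::isfinite(dx[i])) return false;
      return true;
    }
    }
    return false;
  }
};

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// [[Rcpp::export]]
List cpp_integrate(int model, NumericVector pars, NumericVector x0,
                   NumericVector inputs, NumericVector times, double rtol,
                   double atol, bool positivity, double blowup, int maxsteps) {
  int J = x0.size();
  Model m;
  m.code = model;
  m.inputs = inputs.begin();
  m.K = inputs.size();
  if (model == 1 || model == 2) {
    m.J = (int) pars[0];
    m.p = pars.begin() + 2; // skip J, K header
  } else {
    m.J = J;
    m.p = pars.begin();
  }

  int nt = times.size();
  NumericMatrix states(nt, J);
  long n_eval = 0;
  int status = ST_OK;
  int last_ok = 0;

  std::vector<double> x(x0.begin(), x0.end()), xnew(J), xerr(J);
  std::vector<double> k1(J), k2v(J), k3v(J), k4v(J), k5v(J), k6v(J), k7(J),
      xtmp(J);

  for (int i = 0; i < J; ++i) states(0, i) = x[i];

  double t = times[0];
  bool have_k1 = false;
  double h = 0.0;
  int nstep = 0;

  for (int it = 1; it < nt && status == ST_OK; ++it) {
    double tend = times[it];
    if (h <= 0.0) h = (tend - t) / 100.0;
    while (t < tend && status == ST_OK) {
      if (++nstep > maxsteps) { status = ST_FAILURE; break; }
      // land exactly on the output time without letting the clamped step
      // pollute the controller's step size
      bool clamped = false;
      double hs = h;
      if (hs >= tend - t) { hs = tend - t; clamped = true; }
      if (hs < 1e-14 * std::max(1.0, std::fabs(t))) {
        status = (positivity && m.nonpos) ? ST_POSITIVITY : ST_FAILURE;
        break;
      }
      if (!have_k1) {
        if (!m.rhs(x.data(), k1.data(), &n_eval)) { status = ST_FAILURE; break; }
        have_k1 = true;
      }
      bool ok = true;
      for (int i = 0; i < J; ++i) xtmp[i] = x[i] + hs * a21 * k1[i];
      ok = m.rhs(xtmp.data(), k2v.data(), &n_eval);
      if (ok) {
        for (int i = 0; i < J; ++i)
          xtmp[i] = x[i] + hs * (a31 * k1[i] + a32 * k2v[i]);
        ok = m.rhs(xtmp.data(), k3v.data(), &n_eval);
      }
      if (ok) {
        for (int i = 0; i < J; ++i)
          xtmp[i] = x[i] + hs * (a41 * k1[i] + a42 * k2v[i] + a43 * k3v[i]);
        ok = m.rhs(xtmp.data(), k4v.data(), &n_eval);
      }
      if (ok) {
        for (int i = 0; i < J; ++i)
          xtmp[i] = x[i] + hs * (a51 * k1[i] + a52 * k2v[i] + a53 * k3v[i] +
                                 a54 * k4v[i]);
        ok = m.rhs(xtmp.data(), k5v.data(), &n_eval);
      }
      if (ok) {
        for (int i = 0; i < J; ++i)
          xtmp[i] = x[i] + hs * (a61 * k1[i] + a62 * k2v[i] + a63 * k3v[i] +
                                 a64 * k4v[i] + a65 * k5v[i]);
        ok = m.rhs(xtmp.data(), k6v.data(), &n_eval);
      }
      if (ok) {
        for (int i = 0; i < J; ++i)
          xnew[i] = x[i] + hs * (b1 * k1[i] + b3 * k3v[i] + b4 * k4v[i] +
                                 b5 * k5v[i] + b6 * k6v[i]);
        ok = m.rhs(xnew.data(), k7.data(), &n_eval);
      }
      if (!ok) { // rhs failed inside the step: shrink and retry
        h = 0.25 * hs;
        continue;
      }
      double err = 0.0;
      for (int i = 0; i < J; ++i) {
        double x4 = x[i] + hs * (e1 * k1[i] + e3 * k3v[i] + e4 * k4v[i] +
                                 e5 * k5v[i] + e6 * k6v[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xnew[i]));
        double d = (xnew[i] - x4) / sc;
        err += d * d;
      }
      err = std::sqrt(err / J);
      if (err <= 1.0) { // accept
        t = clamped ? tend : t + hs;
        x = xnew;
        k1 = k7; // FSAL
        double bad = 0.0;
        for (int i = 0; i < J; ++i) bad = std::max(bad, std::fabs(x[i]));
        if (bad > blowup) { status = ST_BLOWUP; break; }
        if (positivity) {
          for (int i = 0; i < J; ++i)
            if (x[i] <= 0.0) { status = ST_POSITIVITY; break; }
          if (status != ST_OK) break;
        }
        double fac = (err == 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
        fac = std::min(5.0, std::max(0.2, fac));
        // grow the controller step from the attempted step; a clamped step
        // must not shrink it
        h = clamped ? std::max(h, hs * fac) : hs * fac;
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        h = hs * std::max(0.1, fac);
      }
    }
    if (status == ST_OK) {
      for (int i = 0; i < J; ++i) states(it, i) = x[i];
      last_ok = it;
    }
  }
  if (status != ST_OK) {
    for (int it = last_ok + 1; it < nt; ++it)
      for (int i = 0; i < J; ++i) states(it, i) = NA_REAL;
  }
  return List::create(_["states"] = states, _["status"] = status,
                      _["n_rhs"] = (double) n_eval,
                      _["last_ok_index"] = last_ok + 1);
}

// [[Rcpp::export]]
NumericVector cpp_rhs(int model, NumericVector pars, NumericVector x,
                      NumericVector inputs) {
  Model m;
  m.code = model;
  m.inputs = inputs.begin();
  m.K = inputs.size();
  if (model == 1 || model == 2) {
    m.J = (int) pars[0];
    m.p = pars.begin() + 2;
  } else {
    m.J = x.size();
    m.p = pars.begin();
  }
  NumericVector dx(x.size());
  long n = 0;
  if (!m.rhs(x.begin(), dx.begin(), &n))
    stop("right-hand side evaluation failed (non-finite or domain violation)");
  return dx;
}

// Batched prediction over conditions: one call integrates the same model
// from many initial states/inputs over per-condition time grids. Fails fast:
// returns early when any condition's integration does not finish cleanly.
// [[Rcpp::export]]
List cpp_predict_batch(int model, NumericVector pars, NumericMatrix x0s,
                       NumericMatrix inputs, List times, double rtol,
                       double atol, bool positivity, double blowup,
                       int maxsteps) {
  int n_cond = x0s.nrow();
  List out(n_cond);
  double n_rhs = 0.0;
  int status = ST_OK;
  for (int c = 0; c < n_cond; ++c) {
    NumericVector x0 = x0s(c, _);
    NumericVector I = (inputs.ncol() > 0) ? (NumericVector) inputs(c, _)
                                          : NumericVector(0);
    NumericVector tt = times[c];
    List res = cpp_integrate(model, pars, x0, I, tt, rtol, atol, positivity,
                             blowup, maxsteps);
    n_rhs += as<double>(res["n_rhs"]);
    status = as<int>(res["status"]);
    out[c] = res["states"];
    if (status != ST_OK) {
      return List::create(_["states"] = out, _["status"] = status,
                          _["n_rhs"] = n_rhs, _["n_done"] = c + 1);
    }
  }
  return List::create(_["states"] = out, _["status"] = status,
                      _["n_rhs"] = n_rhs, _["n_done"] = n_cond);
}
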