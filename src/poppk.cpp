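// Core numerics: closed-form two-compartment disposition under
// piecewise-constant infusion, and the per-subject marginal-likelihood
// machinery (inner empirical-Bayes optimization, FOCE-I / Laplace OFV).
// Parameter order throughout: CL, VC, Q, VT.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Disp {
  double CL, VC, Q, VT;
  int ncomp;
  double k10, k12, k21;
  double l1, l2;      // eigenvalue magnitudes, l1 >= l2 > 0
  double c1, c2;      // partial-fraction coefficients, both >= 0
  bool degen;         // near-equal eigenvalues: series/limit branch
};

static Disp make_disp(double CL, double VC, double Q, double VT, int ncomp) {
  Disp d;
  d.CL = CL; d.VC = VC; d.Q = Q; d.VT = VT; d.ncomp = ncomp;
  d.k10 = CL / VC;
  if (ncomp == 1) {
    d.k12 = d.k21 = 0.0;
    d.l1 = d.k10; d.l2 = d.k10; d.c1 = 1.0; d.c2 = 0.0; d.degen = false;
    return d;
  }
  d.k12 = Q / VC;
  d.k21 = Q / VT;
  const double s = d.k10 + d.k12 + d.k21;
  const double p = d.k10 * d.k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;           // round-off guard; disc >= 4*k12*k21 in exact arithmetic
  const double rt = std::sqrt(disc);
  d.l1 = 0.5 * (s + rt);
  d.l2 = p / d.l1;                      // product identity: avoids cancellation for l2
  d.degen = (rt < 1e-9 * s);
  if (!d.degen) {
    // eigenvalues interlace the micro-constant: l2 <= k21 <= l1, so both
    // coefficients are non-negative and the washout form has no cancellation
    d.c1 = (d.l1 - d.k21) / (d.l1 - d.l2);
    d.c2 = (d.k21 - d.l2) / (d.l1 - d.l2);
  } else {
    d.c1 = d.c2 = 0.0;
  }
  return d;
}

// unit-rate step response of central concentration, tau >= 0
static double step_resp(const Disp& d, double tau) {
  if (tau <= 0.0) return 0.0;
  if (d.ncomp == 1)
    return -std::expm1(-d.k10 * tau) / d.CL;
  if (d.degen) {
    const double l = 0.5 * (d.l1 + d.l2);
    const double e = std::exp(-l * tau);
    const double om = -std::expm1(-l * tau);       // 1 - e^{-l tau}
    return (om / l + (d.k21 - l) * (om - l * tau * e) / (l * l)) / d.VC;
  }
  return (d.c1 * (-std::expm1(-d.l1 * tau)) / d.l1 +
          d.c2 * (-std::expm1(-d.l2 * tau)) / d.l2) / d.VC;
}

// contribution of one constant-rate segment [a, b) at time t
static double seg_conc(const Disp& d, double R, double a, double b, double t) {
  if (R == 0.0 || t <= a) return 0.0;
  if (t <= b) return R * step_resp(d, t - a);
  if (d.ncomp == 1) {
    const double w = -std::expm1(-d.k10 * (b - a));
    return R * w * std::exp(-d.k10 * (t - b)) / d.CL;
  }
  if (d.degen) return R * (step_resp(d, t - a) - step_resp(d, t - b));
  // washout: difference of step responses rearranged so every term is
  // non-negative -- keeps relative accuracy when the concentration is tiny
  const double w1 = -std::expm1(-d.l1 * (b - a));
  const double w2 = -std::expm1(-d.l2 * (b - a));
  return R * (d.c1 * w1 * std::exp(-d.l1 * (t - b)) / d.l1 +
              d.c2 * w2 * std::exp(-d.l2 * (t - b)) / d.l2) / d.VC;
}

static arma::vec profile_core(double CL, double VC, double Q, double VT,
                              int ncomp, const arma::mat& segs,
                              const arma::vec& times) {
  const Disp d = make_disp(CL, VC, Q, VT, ncomp);
  arma::vec out(times.n_elem, arma::fill::zeros);
  for (arma::uword j = 0; j < segs.n_rows; ++j) {
    const double a = segs(j, 0), b = segs(j, 1), R = segs(j, 2);
    for (arma::uword i = 0; i < times.n_elem; ++i)
      out(i) += seg_conc(d, R, a, b, times(i));
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_profile")]]
arma::vec cpp_profile(arma::vec pars, int ncomp, arma::mat segs, arma::vec times) {
  return profile_core(pars(0), pars(1), ncomp == 2 ? pars(2) : 0.0,
                      ncomp == 2 ? pars(3) : 1.0, ncomp, segs, times);
}

// eigenvalue magnitudes of the disposition matrix (hybrid rate constants)
// [[Rcpp::export(name = "cpp_lambdas")]]
arma::vec cpp_lambdas(arma::vec pars) {
  const Disp d = make_disp(pars(0), pars(1), pars(2), pars(3), 2);
  arma::vec out(2);
  out(0) = d.l1; out(1) = d.l2;
  return out;
}

// ---------------------------------------------------------------------------
// NLME machinery

struct Subject {
  arma::mat segs;
  arma::vec times;
  arma::vec dv;
};

struct ModelCtx {
  int ncomp;
  bool prop_error;   // proportional (Var = sigma2*f^2) vs additive (Var = sigma2)
  double sigma2;
  arma::vec omega2;  // length 4; <= 0 means eta pinned at 0
  arma::uvec free_;  // indices of free etas
};

static const double LOG2PI = 1.8378770664093454836;
static const double BIG = 1e10;

static arma::vec subj_pred(const ModelCtx& m, const arma::vec& theta_i,
                           const arma::vec& eta, const Subject& s) {
  arma::vec p = theta_i % arma::exp(eta);   // lognormal IIV
  return profile_core(p(0), p(1), m.ncomp == 2 ? p(2) : 0.0,
                      m.ncomp == 2 ? p(3) : 1.0, m.ncomp, s.segs, s.times);
}

// -2*(log p(dv|eta) + log p(eta)), up to nothing: full constants included
static double joint_neg2(const ModelCtx& m, const arma::vec& theta_i,
                         const arma::vec& eta, const Subject& s, bool* ok) {
  arma::vec f = subj_pred(m, theta_i, eta, s);
  double g = 0.0;
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    double V = m.prop_error ? m.sigma2 * f(j) * f(j) : m.sigma2;
    if (m.prop_error && f(j) < 1e-12) { if (ok) *ok = false; return BIG; }
    const double r = s.dv(j) - f(j);
    g += LOG2PI + std::log(V) + r * r / V;
  }
  for (arma::uword k = 0; k < m.free_.n_elem; ++k) {
    const arma::uword i = m.free_(k);
    g += LOG2PI + std::log(m.omega2(i)) + eta(i) * eta(i) / m.omega2(i);
  }
  if (!std::isfinite(g)) { if (ok) *ok = false; return BIG; }
  if (ok) *ok = true;
  return g;
}

// Jacobian of predictions wrt free etas (central differences)
static arma::mat pred_jac(const ModelCtx& m, const arma::vec& theta_i,
                          const arma::vec& eta, const Subject& s,
                          arma::vec& f0) {
  const double h = 1e-5;
  f0 = subj_pred(m, theta_i, eta, s);
  arma::mat A(f0.n_elem, m.free_.n_elem);
  for (arma::uword k = 0; k < m.free_.n_elem; ++k) {
    arma::vec ep = eta, em = eta;
    ep(m.free_(k)) += h; em(m.free_(k)) -= h;
    A.col(k) = (subj_pred(m, theta_i, ep, s) - subj_pred(m, theta_i, em, s)) / (2.0 * h);
  }
  return A;
}

// analytic gradient of joint_neg2 wrt free etas given predictions + Jacobian
static arma::vec joint_grad(const ModelCtx& m, const arma::vec& eta,
                            const Subject& s, const arma::vec& f,
                            const arma::mat& A) {
  arma::vec gr(m.free_.n_elem, arma::fill::zeros);
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    const double V = m.prop_error ? m.sigma2 * f(j) * f(j) : m.sigma2;
    const double r = s.dv(j) - f(j);
    for (arma::uword k = 0; k < m.free_.n_elem; ++k) {
      double t = -2.0 * r * A(j, k) / V;
      if (m.prop_error)
        t += (2.0 * A(j, k) / f(j)) * (1.0 - r * r / V);
      gr(k) += t;
    }
  }
  for (arma::uword k = 0; k < m.free_.n_elem; ++k)
    gr(k) += 2.0 * eta(m.free_(k)) / m.omega2(m.free_(k));
  return gr;
}

// Fisher-scoring Hessian of joint_neg2 (expected information, always PD)
static arma::mat joint_fisher(const ModelCtx& m, const arma::vec& f,
                              const arma::mat& A) {
  arma::mat H(m.free_.n_elem, m.free_.n_elem, arma::fill::zeros);
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    const double V = m.prop_error ? m.sigma2 * f(j) * f(j) : m.sigma2;
    double w = 2.0 / V;
    if (m.prop_error) w += 4.0 / (f(j) * f(j));  // variance-gradient information
    H += w * (A.row(j).t() * A.row(j));
  }
  for (arma::uword k = 0; k < m.free_.n_elem; ++k)
    H(k, k) += 2.0 / m.omega2(m.free_(k));
  return H;
}

// exact Hessian of joint_neg2 by central second differences (Laplace term)
static arma::mat joint_hess_fd(const ModelCtx& m, const arma::vec& theta_i,
                               const arma::vec& eta, const Subject& s) {
  const double h = 1e-4;
  const arma::uword d = m.free_.n_elem;
  arma::mat H(d, d);
  const double g0 = joint_neg2(m, theta_i, eta, s, nullptr);
  for (arma::uword k = 0; k < d; ++k) {
    arma::vec ep = eta, em = eta;
    ep(m.free_(k)) += h; em(m.free_(k)) -= h;
    const double gp = joint_neg2(m, theta_i, ep, s, nullptr);
    const double gm = joint_neg2(m, theta_i, em, s, nullptr);
    H(k, k) = (gp - 2.0 * g0 + gm) / (h * h);
    for (arma::uword l = k + 1; l < d; ++l) {
      arma::vec epp = eta, epm = eta, emp = eta, emm = eta;
      epp(m.free_(k)) += h; epp(m.free_(l)) += h;
      epm(m.free_(k)) += h; epm(m.free_(l)) -= h;
      emp(m.free_(k)) -= h; emp(m.free_(l)) += h;
      emm(m.free_(k)) -= h; emm(m.free_(l)) -= h;
      H(k, l) = H(l, k) =
        (joint_neg2(m, theta_i, epp, s, nullptr) - joint_neg2(m, theta_i, epm, s, nullptr)
         - joint_neg2(m, theta_i, emp, s, nullptr) + joint_neg2(m, theta_i, emm, s, nullptr))
        / (4.0 * h * h);
    }
  }
  return H;
}

// inner empirical-Bayes optimization: Fisher-scoring Newton with backtracking
static bool inner_opt(const ModelCtx& m, const arma::vec& theta_i,
                      const Subject& s, arma::vec& eta,
                      double inner_tol, int max_iter, double* g_out) {
  bool ok;
  double g = joint_neg2(m, theta_i, eta, s, &ok);
  if (!ok) { eta.zeros(); g = joint_neg2(m, theta_i, eta, s, &ok); if (!ok) return false; }
  for (int it = 0; it < max_iter; ++it) {
    arma::vec f;
    arma::mat A = pred_jac(m, theta_i, eta, s, f);
    arma::vec gr = joint_grad(m, eta, s, f, A);
    if (gr.has_nan()) return false;
    if (arma::norm(gr, "inf") < inner_tol * (1.0 + std::fabs(g))) break;
    arma::mat H = joint_fisher(m, f, A);
    arma::vec step;
    if (!arma::solve(step, H, gr, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx))
      step = gr / (arma::norm(H, "inf") + 1.0);
    const double snorm = arma::norm(step, 2);
    if (snorm > 4.0) step *= 4.0 / snorm;   // trust-region-style step cap
    double alpha = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 25; ++ls) {
      arma::vec cand = eta;
      for (arma::uword k = 0; k < m.free_.n_elem; ++k)
        cand(m.free_(k)) -= alpha * step(k);
      bool cok;
      const double gc = joint_neg2(m, theta_i, cand, s, &cok);
      if (cok && gc <= g) {
        const bool converged_move = std::fabs(g - gc) < 1e-12 * (1.0 + std::fabs(g));
        eta = cand; g = gc; improved = true;
        if (converged_move) { *g_out = g; return true; }
        break;
      }
      alpha *= 0.5;
    }
    if (!improved) break;  // at a (numerical) minimum
  }
  // polish with exact-Hessian Newton steps: drives the mode to machine
  // accuracy so the outer objective is a smooth function of the population
  // parameters (the FOCE/Laplace values are sensitive to the mode)
  for (int pol = 0; pol < 3; ++pol) {
    arma::vec f;
    arma::mat A = pred_jac(m, theta_i, eta, s, f);
    arma::vec gr = joint_grad(m, eta, s, f, A);
    if (gr.has_nan() || arma::norm(gr, "inf") < 1e-11 * (1.0 + std::fabs(g))) break;
    arma::mat H = joint_hess_fd(m, theta_i, eta, s);
    H = 0.5 * (H + H.t());
    arma::vec step;
    if (!arma::solve(step, H, gr, arma::solve_opts::no_approx)) break;
    arma::vec cand = eta;
    for (arma::uword k = 0; k < m.free_.n_elem; ++k)
      cand(m.free_(k)) -= step(k);
    bool cok;
    const double gc = joint_neg2(m, theta_i, cand, s, &cok);
    if (!cok || gc > g + 1e-9 * (1.0 + std::fabs(g))) break;
    eta = cand; g = gc;
  }
  *g_out = g;
  return std::isfinite(g) && g < BIG;
}

// -2 log marginal likelihood contribution of one subject
static double subj_neg2ll(const ModelCtx& m, const arma::vec& theta_i,
                          const Subject& s, arma::vec& eta, int method,
                          double inner_tol, int max_inner, bool* ok) {
  const arma::uword d = m.free_.n_elem;
  if (d == 0) {            // degenerate prior: fixed-effects likelihood, eta = 0
    eta.zeros();
    return joint_neg2(m, theta_i, eta, s, ok);
  }
  double g;
  if (!inner_opt(m, theta_i, s, eta, inner_tol, max_inner, &g)) {
    // retry cold from zero before giving up
    eta.zeros();
    if (!inner_opt(m, theta_i, s, eta, inner_tol, max_inner, &g)) { *ok = false; return BIG; }
  }
  arma::vec f;
  arma::mat A = pred_jac(m, theta_i, eta, s, f);
  if (m.prop_error && f.min() < 1e-12) { *ok = false; return BIG; }

  if (method == 1) {       // Laplace: exact Hessian of the joint at the mode
    arma::mat H = joint_hess_fd(m, theta_i, eta, s);
    arma::mat Hh = 0.5 * (H + H.t()) * 0.5;        // symmetrize, then H/2
    double ridge = 0.0;
    for (int tries = 0; tries < 8; ++tries) {
      arma::mat R;
      if (arma::chol(R, Hh + ridge * arma::eye(d, d))) {
        double ld = 2.0 * arma::sum(arma::log(R.diag()));
        const double v = g - d * LOG2PI + ld;
        *ok = std::isfinite(v);
        return *ok ? v : BIG;
      }
      ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
    }
    *ok = false;
    return BIG;
  }

  // FOCE-I: linearize predictions about the conditional mode; observation
  // covariance uses the mode-evaluated residual variance (the interaction)
  arma::vec V(f.n_elem);
  for (arma::uword j = 0; j < f.n_elem; ++j)
    V(j) = m.prop_error ? m.sigma2 * f(j) * f(j) : m.sigma2;
  arma::vec etaf(d);
  arma::vec w2(d);
  for (arma::uword k = 0; k < d; ++k) {
    etaf(k) = eta(m.free_(k));
    w2(k) = m.omega2(m.free_(k));
  }
  arma::mat Sy = A * arma::diagmat(w2) * A.t() + arma::diagmat(V);
  arma::vec res = s.dv - f + A * etaf;
  arma::mat R;
  if (!arma::chol(R, Sy)) { *ok = false; return BIG; }
  arma::vec z = arma::solve(arma::trimatl(R.t()), res);
  const double v = f.n_elem * LOG2PI + 2.0 * arma::sum(arma::log(R.diag())) + arma::dot(z, z);
  *ok = std::isfinite(v);
  return *ok ? v : BIG;
}

static Subject as_subject(const List& s) {
  Subject out;
  out.segs = as<arma::mat>(s["segs"]);
  out.times = as<arma::vec>(s["times"]);
  out.dv = as<arma::vec>(s["dv"]);
  return out;
}

// Population OFV. theta_i: 4 x nsub individual typical values (covariates
// already applied); etas: 4 x nsub warm starts, updated in the returned copy.
// [[Rcpp::export(name = "cpp_ofv")]]
List cpp_ofv(arma::mat theta_i, arma::vec omega2, double sigma2,
             bool prop_error, int ncomp, List subjects, int method,
             arma::mat etas, double inner_tol = 1e-8, int max_inner = 60) {
  ModelCtx m;
  m.ncomp = ncomp;
  m.prop_error = prop_error;
  m.sigma2 = sigma2;
  m.omega2 = omega2;
  m.free_ = arma::find(omega2 > 1e-12);
  const int n = subjects.size();
  arma::vec ofv_i(n);
  LogicalVector ok(n);
  bool all_ok = true;
  for (int i = 0; i < n; ++i) {
    Subject s = as_subject(subjects[i]);
    arma::vec eta = etas.col(i);
    bool oki = true;
    ofv_i(i) = subj_neg2ll(m, theta_i.col(i), s, eta, method, inner_tol, max_inner, &oki);
    etas.col(i) = eta;
    ok[i] = oki;
    all_ok = all_ok && oki;
  }
  return List::create(_["ofv"] = arma::sum(ofv_i), _["ofv_i"] = ofv_i,
                      _["etas"] = etas, _["ok"] = ok, _["all_ok"] = all_ok);
}
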