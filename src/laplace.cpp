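// Marginal-likelihood core: per-subject conditional log-likelihood for the
// count-model ladder, inner Newton maximization over the (<=2) random
// effects, Laplace correction and adaptive Gauss-Hermite quadrature.
//
// Parameter slot order in `fe`:
//   0 lam0, 1 lam2, 2 th_pdv, 3 th_ppdv, 4 th_pppdv,
//   5 ovdp, 6 delta, 7 p0, 8 pm, 9 ster_s (steroid-month replacement value)
// `spec` codes:
//   0 family: 0 PS, 1 ZIP, 2 GP, 3 NB, 4 ZINB, 5 PMIX
//   1 markov: 0 none, 1 MAK1, 2/3/4 MAK2 order 1/2/3
//   2 steroid target: 0 none, 1 lam0, 2 ovdp, 3 th_pdv, 4 th_ppdv
//   3,4 random-effect targets re1, re2: 0 none, 1 lam0, 2 lam2, 3 th_pdv,
//       4 ovdp
#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Subj {
  IntegerVector y, pdv, ppdv, pppdv, ind, ster, use;
  int T;
};

struct Par {
  double lam0, lam2, th_pdv, th_ppdv, th_pppdv, ovdp, delta, p0, pm, ster_s;
  int family, markov, ster_target, re1, re2, q;
  double omega[2];
};

static inline double logpmf(int fam, int y, double lam, double ovdp,
                            double delta, double p0, double pm, double lam2) {
  switch (fam) {
  case 0: { // PS
    if (lam <= 0) return NEG_INF;
    return y * std::log(lam) - lam - std::lgamma(y + 1.0);
  }
  case 1: { // ZIP
    if (lam <= 0) return NEG_INF;
    double base = y * std::log(lam) - lam - std::lgamma(y + 1.0);
    if (p0 <= 0) return base;
    if (y == 0) return std::log(p0 + (1.0 - p0) * std::exp(base));
    return std::log1p(-p0) + base;
  }
  case 2: { // GP, Consul-Jain
    if (lam <= 0) return NEG_INF;
    double mu = lam + y * delta;
    if (mu <= 0) return NEG_INF;
    return std::log(lam) + (y - 1.0) * std::log(mu) - mu -
           std::lgamma(y + 1.0);
  }
  case 3: { // NB (NB2)
    if (lam <= 0 || ovdp < 0) return NEG_INF;
    if (ovdp < 1e-12)
      return y * std::log(lam) - lam - std::lgamma(y + 1.0);
    double r = 1.0 / ovdp;
    return std::lgamma(y + r) - std::lgamma(r) - std::lgamma(y + 1.0) +
           r * std::log(r / (r + lam)) + y * std::log(lam / (r + lam));
  }
  case 4: { // ZINB
    double base = logpmf(3, y, lam, ovdp, 0, 0, 0, 0);
    if (p0 <= 0) return base;
    if (y == 0) return std::log(p0 + (1.0 - p0) * std::exp(base));
    return std::log1p(-p0) + base;
  }
  case 5: { // PMIX: two-component Poisson mixture
    if (lam <= 0 || lam2 <= 0) return NEG_INF;
    double a = std::log(pm) + y * std::log(lam) - lam - std::lgamma(y + 1.0);
    double b = std::log1p(-pm) + y * std::log(lam2) - lam2 -
               std::lgamma(y + 1.0);
    double m = std::max(a, b);
    if (m == NEG_INF) return NEG_INF;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
  }
  }
  return NEG_INF;
}

// conditional log-likelihood of one subject given eta (length q)
static double subj_cll(const Subj &s, const Par &p, const double *eta) {
  double m_lam0 = 1, m_lam2 = 1, m_pdv = 1, m_ovdp = 1;
  const int tg[2] = {p.re1, p.re2};
  for (int j = 0; j < p.q; j++) {
    double e = std::exp(eta[j]);
    if (tg[j] == 1) m_lam0 = e;
    else if (tg[j] == 2) m_lam2 = e;
    else if (tg[j] == 3) m_pdv = e;
    else if (tg[j] == 4) m_ovdp = e;
  }
  double ll = 0.0;
  for (int t = 0; t < s.T; t++) {
    if (!s.use[t]) continue;
    bool st = s.ster[t] == 1;
    double lam0 = (st && p.ster_target == 1 ? p.ster_s : p.lam0) * m_lam0;
    double thp  = (st && p.ster_target == 3 ? p.ster_s : p.th_pdv) * m_pdv;
    double thpp = (st && p.ster_target == 4 ? p.ster_s : p.th_ppdv);
    double ov   = (st && p.ster_target == 2 ? p.ster_s : p.ovdp) * m_ovdp;
    double lam;
    switch (p.markov) {
    case 0: lam = lam0; break;
    case 1: lam = s.ind[t] ? p.lam2 : lam0; break;
    default:
      lam = lam0 + thp * s.pdv[t];
      if (p.markov >= 3) lam += thpp * s.ppdv[t];
      if (p.markov >= 4) lam += p.th_pppdv * s.pppdv[t];
    }
    double lam2 = p.lam2 * m_lam2;
    double l = logpmf(p.family, s.y[t], lam, ov, p.delta, p.p0, p.pm, lam2);
    if (l == NEG_INF) return NEG_INF;
    ll += l;
  }
  return ll;
}

// first and second derivatives of the log pmf with respect to lam for the
// single-rate families (PS, ZIP, GP, NB, ZINB); assumes lam > 0 and, for
// GP, lam + y*delta > 0
static inline void dlogpmf_dlam(int fam, int y, double lam, double ovdp,
                                double delta, double p0,
                                double &d1, double &d2) {
  switch (fam) {
  case 0:
    d1 = y / lam - 1.0;
    d2 = -y / (lam * lam);
    return;
  case 1: {
    if (y == 0 && p0 > 0) {
      double P = p0 + (1.0 - p0) * std::exp(-lam);
      double w = (1.0 - p0) * std::exp(-lam) / P;
      d1 = -w;
      d2 = w * (1.0 - w);
    } else {
      d1 = y / lam - 1.0;
      d2 = -y / (lam * lam);
    }
    return;
  }
  case 2: {
    double mu = lam + y * delta;
    d1 = 1.0 / lam + (y - 1.0) / mu - 1.0;
    d2 = -1.0 / (lam * lam) - (y - 1.0) / (mu * mu);
    return;
  }
  case 3: {
    if (ovdp < 1e-12) { // Poisson limit
      d1 = y / lam - 1.0;
      d2 = -y / (lam * lam);
      return;
    }
    double r = 1.0 / ovdp;
    d1 = y / lam - (y + r) / (r + lam);
    d2 = -y / (lam * lam) + (y + r) / ((r + lam) * (r + lam));
    return;
  }
  case 4: {
    if (y == 0 && p0 > 0 && ovdp >= 1e-12) {
      double r = 1.0 / ovdp;
      double q = std::exp(r * std::log(r / (r + lam)));
      double P = p0 + (1.0 - p0) * q;
      double q1 = -r * q / (r + lam);
      double q2 = r * q * (r + 1.0) / ((r + lam) * (r + lam));
      d1 = (1.0 - p0) * q1 / P;
      d2 = (1.0 - p0) * q2 / P - d1 * d1;
    } else {
      dlogpmf_dlam(ovdp < 1e-12 ? (p0 > 0 ? 1 : 0) : 3, y, lam, ovdp, delta,
                   p0, d1, d2);
      if (ovdp < 1e-12 && p0 > 0) return; // ZIP handled the y==0 case
    }
    return;
  }
  }
}

// analytic gradient / Hessian of h(eta) for single-rate families with
// random effects on lam0 and/or th_pdv; returns false when not applicable
static bool an_grad_hess(const Subj &s, const Par &p, const double *eta,
                         double *g, double *H) {
  if (p.family == 5) return false;
  const int tg[2] = {p.re1, p.re2};
  for (int j = 0; j < p.q; j++)
    if (tg[j] != 1 && tg[j] != 3) return false;
  double m_lam0 = 1, m_pdv = 1;
  for (int j = 0; j < p.q; j++) {
    double e = std::exp(eta[j]);
    if (tg[j] == 1) m_lam0 = e;
    else m_pdv = e;
  }
  double G[2] = {0, 0}, h11 = 0, h22 = 0, h12 = 0;
  for (int t = 0; t < s.T; t++) {
    if (!s.use[t]) continue;
    bool st = s.ster[t] == 1;
    double lam0 = (st && p.ster_target == 1 ? p.ster_s : p.lam0) * m_lam0;
    double thp  = (st && p.ster_target == 3 ? p.ster_s : p.th_pdv) * m_pdv;
    double thpp = (st && p.ster_target == 4 ? p.ster_s : p.th_ppdv);
    double ov   = (st && p.ster_target == 2 ? p.ster_s : p.ovdp);
    double lam, pdvterm = thp * s.pdv[t];
    switch (p.markov) {
    case 0: lam = lam0; break;
    case 1:
      lam = s.ind[t] ? p.lam2 : lam0;
      if (s.ind[t]) lam0 = 0; // no eta sensitivity in the lam2 branch
      break;
    default:
      lam = lam0 + pdvterm;
      if (p.markov >= 3) lam += thpp * s.ppdv[t];
      if (p.markov >= 4) lam += p.th_pppdv * s.pppdv[t];
    }
    if (lam <= 0) return false;
    if (p.family == 2 && lam + s.y[t] * p.delta <= 0) return false;
    double d1, d2;
    dlogpmf_dlam(p.family, s.y[t], lam, ov, p.delta, p.p0, d1, d2);
    double a[2];
    for (int j = 0; j < p.q; j++)
      a[j] = (tg[j] == 1) ? lam0 : pdvterm;
    for (int j = 0; j < p.q; j++) G[j] += d1 * a[j];
    h11 += d2 * a[0] * a[0] + d1 * a[0];
    if (p.q > 1) {
      h22 += d2 * a[1] * a[1] + d1 * a[1];
      h12 += d2 * a[0] * a[1];
    }
  }
  for (int j = 0; j < p.q; j++) G[j] -= eta[j] / p.omega[j];
  h11 -= 1.0 / p.omega[0];
  if (p.q > 1) h22 -= 1.0 / p.omega[1];
  g[0] = G[0];
  H[0] = h11;
  if (p.q > 1) {
    g[1] = G[1];
    H[1] = H[2] = h12;
    H[3] = h22;
  }
  return true;
}

// joint log density h(eta) = cll + log-normal prior on eta
static double h_joint(const Subj &s, const Par &p, const double *eta) {
  double h = subj_cll(s, p, eta);
  if (h == NEG_INF) return NEG_INF;
  for (int j = 0; j < p.q; j++)
    h += -0.5 * eta[j] * eta[j] / p.omega[j] -
         0.5 * std::log(2.0 * M_PI * p.omega[j]);
  return h;
}

// gradient / Hessian of h at eta: analytic where available, otherwise
// central differences
static void num_grad_hess(const Subj &s, const Par &p, const double *eta,
                          double *g, double *H) {
  const double hs = 1e-4;
  int q = p.q;
  double e[2], fc = h_joint(s, p, eta);
  for (int j = 0; j < q; j++) {
    e[0] = eta[0]; e[1] = (q > 1) ? eta[1] : 0.0;
    e[j] = eta[j] + hs; double fp = h_joint(s, p, e);
    e[j] = eta[j] - hs; double fm = h_joint(s, p, e);
    g[j] = (fp - fm) / (2 * hs);
    H[j * q + j] = (fp - 2 * fc + fm) / (hs * hs);
  }
  if (q == 2) {
    double epp[2] = {eta[0] + hs, eta[1] + hs};
    double epm[2] = {eta[0] + hs, eta[1] - hs};
    double emp[2] = {eta[0] - hs, eta[1] + hs};
    double emm[2] = {eta[0] - hs, eta[1] - hs};
    double o = (h_joint(s, p, epp) - h_joint(s, p, epm) -
                h_joint(s, p, emp) + h_joint(s, p, emm)) / (4 * hs * hs);
    H[1] = H[2] = o;
  }
}

static void grad_hess(const Subj &s, const Par &p, const double *eta,
                      double *g, double *H) {
  if (!an_grad_hess(s, p, eta, g, H)) num_grad_hess(s, p, eta, g, H);
}

// solve (A) x = b for q<=2 symmetric A; returns false if not solvable
static bool solve_q(int q, const double *A, const double *b, double *x) {
  if (q == 1) {
    if (A[0] == 0) return false;
    x[0] = b[0] / A[0];
    return true;
  }
  double det = A[0] * A[3] - A[1] * A[2];
  if (det == 0) return false;
  x[0] = (A[3] * b[0] - A[1] * b[1]) / det;
  x[1] = (A[0] * b[1] - A[2] * b[0]) / det;
  return true;
}

// Newton ascent of h(eta) with safeguarded halving line search.
// On exit: eta = mode, H = Hessian of h there. Returns h(mode); sets
// ok=false on non-convergence.
static double inner_newton(const Subj &s, const Par &p, double *eta,
                           double *H, bool &ok) {
  int q = p.q;
  double g[2], d[2], A[4], cur = h_joint(s, p, eta);
  if (cur == NEG_INF) { // fall back to the prior mode
    eta[0] = 0; if (q > 1) eta[1] = 0;
    cur = h_joint(s, p, eta);
  }
  ok = false;
  for (int it = 0; it < 200; it++) {
    grad_hess(s, p, eta, g, H);
    double gmax = std::abs(g[0]);
    if (q > 1) gmax = std::max(gmax, std::abs(g[1]));
    // absolute gradient tolerance: the mode must be resolved far below the
    // outer optimizer's finite-difference step or the OFV surface looks
    // noisy to it
    if (gmax < 1e-8) { ok = true; break; }
    // Newton direction from -H, ridged until positive definite
    double ridge = 0.0;
    for (int tries = 0; tries < 40; tries++) {
      for (int k = 0; k < q * q; k++) A[k] = -H[k];
      for (int j = 0; j < q; j++) A[j * q + j] += ridge;
      bool pd = (q == 1) ? A[0] > 0
                         : (A[0] > 0 && A[0] * A[3] - A[1] * A[2] > 0);
      if (pd && solve_q(q, A, g, d)) break;
      ridge = (ridge == 0.0) ? 1e-4 : ridge * 10;
      d[0] = g[0]; if (q > 1) d[1] = g[1]; // gradient fallback
    }
    double step = 1.0, e[2], best = cur;
    bool moved = false;
    for (int ls = 0; ls < 30; ls++) {
      e[0] = eta[0] + step * d[0];
      e[1] = (q > 1) ? eta[1] + step * d[1] : 0.0;
      double f = h_joint(s, p, e);
      if (f > best) {
        eta[0] = e[0]; if (q > 1) eta[1] = e[1];
        cur = f; moved = true; break;
      }
      step *= 0.5;
    }
    if (!moved) { ok = gmax < 1e-4; break; }
  }
  grad_hess(s, p, eta, g, H);
  return cur;
}

static Par make_par(const NumericVector &fe, const IntegerVector &spec,
                    const NumericVector &omega) {
  Par p;
  p.lam0 = fe[0]; p.lam2 = fe[1]; p.th_pdv = fe[2]; p.th_ppdv = fe[3];
  p.th_pppdv = fe[4]; p.ovdp = fe[5]; p.delta = fe[6]; p.p0 = fe[7];
  p.pm = fe[8]; p.ster_s = fe[9];
  p.family = spec[0]; p.markov = spec[1]; p.ster_target = spec[2];
  p.re1 = spec[3]; p.re2 = spec[4];
  p.q = (p.re1 > 0) + (p.re2 > 0);
  p.omega[0] = omega.size() > 0 ? omega[0] : 0.0;
  p.omega[1] = omega.size() > 1 ? omega[1] : 0.0;
  return p;
}

static Subj make_subj(const List &sl) {
  Subj s;
  s.y = sl["y"]; s.pdv = sl["pdv"]; s.ppdv = sl["ppdv"];
  s.pppdv = sl["pppdv"]; s.ind = sl["ind"]; s.ster = sl["ster"];
  s.use = sl["use"];
  s.T = s.y.size();
  return s;
}

// Marginal -2 log-likelihood (OFV). nodes = 1 gives the Laplace
// approximation; nodes > 1 adaptive Gauss-Hermite centered and scaled at
// the per-subject mode. eta_warm (q x nsub) is filled with the per-subject
// modes (empirical-Bayes estimates).
// [[Rcpp::export(name = ".marginal_ofv_cpp")]]
List marginal_ofv_cpp(List subjects, NumericVector fe, IntegerVector spec,
                      NumericVector omega, NumericMatrix eta_warm,
                      int nodes, NumericVector gh_x, NumericVector gh_w) {
  Par p = make_par(fe, spec, omega);
  int n = subjects.size(), q = p.q;
  double ofv = 0.0;
  LogicalVector conv(n, true);
  for (int i = 0; i < n; i++) {
    Subj s = make_subj(List(subjects[i]));
    if (q == 0) {
      double eta0[2] = {0, 0};
      double ll = subj_cll(s, p, eta0);
      if (ll == NEG_INF) { ofv += 1e10; conv[i] = false; continue; }
      ofv += -2.0 * ll;
      continue;
    }
    // Deterministic multi-start: the joint density can be multi-modal for
    // some subjects, and a history-dependent warm start would make the OFV
    // a non-deterministic (and non-smooth) function of the parameters.
    // Candidates: the prior mode, a moment-matched start on any lam0
    // random effect, and +/- one prior sd on each dimension.
    double ybar = 0.0; int nuse = 0;
    for (int t = 0; t < s.T; t++) if (s.use[t]) { ybar += s.y[t]; nuse++; }
    ybar = nuse ? ybar / nuse : 0.0;
    const int tg[2] = {p.re1, p.re2};
    double mstart[2] = {0, 0};
    for (int j = 0; j < q; j++) {
      if (tg[j] == 1 && p.lam0 > 0) {
        double sd = std::sqrt(p.omega[j]);
        double v = std::log((ybar + 0.25) / p.lam0);
        mstart[j] = std::max(-3.0 * sd, std::min(3.0 * sd, v));
      }
    }
    double cand[6][2] = {{0, 0},
                         {mstart[0], mstart[1]},
                         {std::sqrt(p.omega[0]), 0},
                         {-std::sqrt(p.omega[0]), 0},
                         {mstart[0], q > 1 ? std::sqrt(p.omega[1]) : 0},
                         {mstart[0], q > 1 ? -std::sqrt(p.omega[1]) : 0}};
    int ncand = (q > 1) ? 6 : 4;
    // screen candidates by joint density, run Newton from the best two
    double hc0[6];
    for (int c = 0; c < ncand; c++) hc0[c] = h_joint(s, p, cand[c]);
    int c1 = 0, c2 = -1;
    for (int c = 1; c < ncand; c++) if (hc0[c] > hc0[c1]) c1 = c;
    for (int c = 0; c < ncand; c++)
      if (c != c1 && (c2 < 0 || hc0[c] > hc0[c2])) c2 = c;
    double eta[2] = {0, 0}, H[4] = {0, 0, 0, 0};
    double hstar = NEG_INF;
    bool ok = false;
    int starts[2] = {c1, c2};
    for (int ci = 0; ci < 2; ci++) {
      int c = starts[ci];
      if (c < 0 || hc0[c] == NEG_INF) continue;
      double e[2] = {cand[c][0], cand[c][1]};
      double Hc[4] = {0, 0, 0, 0};
      bool okc;
      double hc = inner_newton(s, p, e, Hc, okc);
      if (hc > hstar + 1e-10) {
        hstar = hc; ok = okc;
        eta[0] = e[0]; eta[1] = e[1];
        for (int k = 0; k < 4; k++) H[k] = Hc[k];
      }
    }
    if (hstar == NEG_INF) { // all candidates invalid: one rescue from 0
      double e[2] = {0, 0}, Hc[4] = {0, 0, 0, 0};
      bool okc;
      hstar = inner_newton(s, p, e, Hc, okc);
      ok = okc;
      eta[0] = e[0]; eta[1] = e[1];
      for (int k = 0; k < 4; k++) H[k] = Hc[k];
    }
    if (!R_finite(hstar)) { ofv += 1e10; conv[i] = false; continue; }
    conv[i] = ok;
    eta_warm(0, i) = eta[0];
    if (q > 1) eta_warm(1, i) = eta[1];
    // negative Hessian, ridged to PD if needed
    double A[4];
    for (int k = 0; k < q * q; k++) A[k] = -H[k];
    double ridge = 0.0;
    while (true) {
      bool pd = (q == 1) ? A[0] > 0
                         : (A[0] > 0 && A[0] * A[3] - A[1] * A[2] > 0);
      if (pd) break;
      ridge = (ridge == 0.0) ? 1e-6 : ridge * 10;
      for (int k = 0; k < q * q; k++) A[k] = -H[k];
      for (int j = 0; j < q; j++) A[j * q + j] += ridge;
      conv[i] = false;
      if (ridge > 1e6) break;
    }
    // Cholesky of Sigma = A^{-1}: L such that L L' = A^{-1}
    double logdetA, L[4] = {0, 0, 0, 0};
    if (q == 1) {
      logdetA = std::log(A[0]);
      L[0] = 1.0 / std::sqrt(A[0]);
    } else {
      double det = A[0] * A[3] - A[1] * A[2];
      logdetA = std::log(det);
      // chol of inv(A) = [A3,-A1;-A2,A0]/det
      double S0 = A[3] / det, S1 = -A[1] / det, S3 = A[0] / det;
      L[0] = std::sqrt(S0);
      L[2] = S1 / L[0];
      L[3] = std::sqrt(std::max(S3 - L[2] * L[2], 1e-300));
    }
    double logmarg;
    if (nodes <= 1) {
      logmarg = hstar + 0.5 * q * std::log(2.0 * M_PI) - 0.5 * logdetA;
    } else {
      // AGQ centered at the mode: eta = mode + sqrt(2) L z
      double acc = 0.0;
      if (q == 1) {
        for (int a = 0; a < nodes; a++) {
          double e[2] = {eta[0] + M_SQRT2 * L[0] * gh_x[a], 0.0};
          double f = h_joint(s, p, e);
          if (f == NEG_INF) continue;
          acc += gh_w[a] * std::exp(gh_x[a] * gh_x[a] + f - hstar);
        }
        logmarg = hstar + 0.5 * std::log(2.0) - 0.5 * logdetA + std::log(acc);
      } else {
        for (int a = 0; a < nodes; a++)
          for (int b = 0; b < nodes; b++) {
            double z1 = gh_x[a], z2 = gh_x[b];
            double e[2] = {eta[0] + M_SQRT2 * L[0] * z1,
                           eta[1] + M_SQRT2 * (L[2] * z1 + L[3] * z2)};
            double f = h_joint(s, p, e);
            if (f == NEG_INF) continue;
            acc += gh_w[a] * gh_w[b] * std::exp(z1 * z1 + z2 * z2 + f - hstar);
          }
        logmarg = hstar + std::log(2.0) - 0.5 * logdetA + std::log(acc);
      }
      if (!R_finite(logmarg)) { ofv += 1e10; conv[i] = false; continue; }
    }
    ofv += -2.0 * logmarg;
  }
  return List::create(_["ofv"] = ofv, _["converged"] = conv,
                      _["eta"] = eta_warm);
}
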