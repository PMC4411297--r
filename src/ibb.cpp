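#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Beta-binomial log density with mean pi and intra-class correlation rho:
// a = pi(1-rho)/rho, b = (1-pi)(1-rho)/rho.
static double lbb(double v, double n, double pi, double rho) {
  if (pi < 1e-12) pi = 1e-12;
  if (pi > 1 - 1e-12) pi = 1 - 1e-12;
  if (rho < 1e-9) {
    return Rf_lchoose(n, v) + v * std::log(pi) + (n - v) * std::log1p(-pi);
  }
  double s = (1 - rho) / rho, a = pi * s, b = (1 - pi) * s;
  return Rf_lchoose(n, v) + Rf_lbeta(v + a, n - v + b) - Rf_lbeta(a, b);
}

// first and second derivatives of lbb w.r.t. pi
static void dlbb(double v, double n, double pi, double rho,
                 double &d1, double &d2) {
  if (pi < 1e-12) pi = 1e-12;
  if (pi > 1 - 1e-12) pi = 1 - 1e-12;
  if (rho < 1e-9) {
    d1 = v / pi - (n - v) / (1 - pi);
    d2 = -v / (pi * pi) - (n - v) / ((1 - pi) * (1 - pi));
    return;
  }
  double s = (1 - rho) / rho, a = pi * s, b = (1 - pi) * s;
  d1 = s * (Rf_digamma(v + a) - Rf_digamma(a)
            - Rf_digamma(n - v + b) + Rf_digamma(b));
  d2 = s * s * (Rf_trigamma(v + a) - Rf_trigamma(a)
                + Rf_trigamma(n - v + b) - Rf_trigamma(b));
}

// log-likelihood of one pair at latent baseline logit lp, with derivatives
// in lp (test member mean is plogis(lp + lb))
static void pair_ll(double vc, double nc, double vt, double nt,
                    double lp, double lb, double rho,
                    double &ll, double &g1, double &g2) {
  double pc = 1.0 / (1.0 + std::exp(-lp));
  double pt = 1.0 / (1.0 + std::exp(-(lp + lb)));
  double d1c, d2c, d1t, d2t;
  dlbb(vc, nc, pc, rho, d1c, d2c);
  dlbb(vt, nt, pt, rho, d1t, d2t);
  double wc = pc * (1 - pc), wt = pt * (1 - pt);
  ll = lbb(vc, nc, pc, rho) + lbb(vt, nt, pt, rho);
  g1 = d1c * wc + d1t * wt;
  g2 = d2c * wc * wc + d1c * wc * (1 - 2 * pc)
     + d2t * wt * wt + d1t * wt * (1 - 2 * pt);
}

// profile out the pair's baseline by safeguarded Newton; returns the
// maximized log-likelihood and the curvature (-d2) at the optimum
static void profile_pair(double vc, double nc, double vt, double nt,
                         double lb, double rho,
                         double &ll, double &curv) {
  const double LO = -18, HI = 18;
  double p0 = (vc + vt + 0.5) / (nc + nt + 1.0);
  double lp = std::log(p0 / (1 - p0)) - lb / 2;
  if (lp < LO) lp = LO;
  if (lp > HI) lp = HI;
  double lo = LO, hi = HI, g1, g2;
  for (int it = 0; it < 60; ++it) {
    pair_ll(vc, nc, vt, nt, lp, lb, rho, ll, g1, g2);
    if (std::fabs(g1) < 1e-10) break;
    if (g1 > 0) lo = lp; else hi = lp;
    double step = (g2 < -1e-12) ? lp - g1 / g2 : (lo + hi) / 2;
    if (step <= lo || step >= hi) step = (lo + hi) / 2;
    if (std::fabs(step - lp) < 1e-12) { lp = step; break; }
    lp = step;
  }
  pair_ll(vc, nc, vt, nt, lp, lb, rho, ll, g1, g2);
  curv = -g2;
  if (curv < 1e-8) curv = 1e-8;
}

// Cox-Reid adjusted profile negative log-likelihood of (log fold change,
// logit overdispersion), with the per-pair latent baselines profiled out
// and the adjustment -1/2 log det of their information.
// [[Rcpp::export(name = ".cr_profile_nll")]]
double cr_profile_nll(double lb, double lr,
                      NumericVector vt, NumericVector nt,
                      NumericVector vc, NumericVector nc,
                      bool adjust = true) {
  double rho = 1.0 / (1.0 + std::exp(-lr));
  double tot = 0;
  for (int i = 0; i < vt.size(); ++i) {
    double ll, curv;
    profile_pair(vc[i], nc[i], vt[i], nt[i], lb, rho, ll, curv);
    tot += ll;
    if (adjust) tot -= 0.5 * std::log(curv);
  }
  return -tot;
}
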