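#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal likelihood machinery for the 4PL model with a Gaussian random
// effect on the midpoint, one scalar effect per cell line:
//
//   y_ij = right + (left - right) / (1 + exp((xmid + b_i - x_ij)/scale)) + e_ij
//   b_i ~ N(0, sb^2),  e_ij ~ N(0, se^2)
//
// The random effect is integrated out per line by the Laplace approximation
// (default) or adaptive Gauss-Hermite quadrature centred at the conditional
// mode.  Observations must arrive sorted by line (0-based `line` index).

// p = 1/(1 + exp(u)) without overflow
static inline double inv_logit_neg(double u) {
  if (u > 0.0) {
    double e = std::exp(-u);
    return e / (1.0 + e);
  }
  double e = std::exp(u);
  return 1.0 / (1.0 + e);
}

struct PenFit {
  double g;        // penalised half-deviance at b
  double gp;       // d g / d b
  double h_gn;     // Gauss-Newton curvature (always > 0)
  double h_full;   // full curvature (may be indefinite away from the mode)
};

// penalised objective for one line:
//   g(b) = RSS(b)/(2 se^2) + b^2/(2 sb^2)
static PenFit pen_objective(double b, const double* x, const double* y, int n,
                            double L, double R, double m, double s,
                            double inv_se2, double inv_sb2) {
  PenFit out;
  out.g = 0.5 * b * b * inv_sb2;
  out.gp = b * inv_sb2;
  out.h_gn = inv_sb2;
  out.h_full = inv_sb2;
  double d = L - R;
  for (int j = 0; j < n; ++j) {
    double u = (m + b - x[j]) / s;
    double p = inv_logit_neg(u);
    double f = R + d * p;
    double r = y[j] - f;
    double fp = -d * p * (1.0 - p) / s;                    // df/db
    double fpp = d * (1.0 - 2.0 * p) * p * (1.0 - p) / (s * s);
    out.g += 0.5 * r * r * inv_se2;
    out.gp += -r * fp * inv_se2;
    out.h_gn += fp * fp * inv_se2;
    out.h_full += (fp * fp - r * fpp) * inv_se2;
  }
  return out;
}

// Newton search (Gauss-Newton curvature, backtracking) for the conditional
// mode of one line's random effect.
static double find_mode(const double* x, const double* y, int n,
                        double L, double R, double m, double s,
                        double inv_se2, double inv_sb2, double b0) {
  double b = std::isfinite(b0) ? b0 : 0.0;
  PenFit cur = pen_objective(b, x, y, n, L, R, m, s, inv_se2, inv_sb2);
  for (int it = 0; it < 100; ++it) {
    double step = -cur.gp / cur.h_gn;
    if (!std::isfinite(step)) break;
    double bn = b + step;
    PenFit nxt = pen_objective(bn, x, y, n, L, R, m, s, inv_se2, inv_sb2);
    int halv = 0;
    while (nxt.g > cur.g && halv < 40) {
      step *= 0.5;
      bn = b + step;
      nxt = pen_objective(bn, x, y, n, L, R, m, s, inv_se2, inv_sb2);
      ++halv;
    }
    if (nxt.g > cur.g) break;  // cannot improve
    b = bn;
    cur = nxt;
    // tight tolerance: the outer optimiser differences this objective, so
    // the mode must be found to well below finite-difference resolution
    // regardless of the warm start used
    if (std::fabs(cur.gp) < 1e-12 * (1.0 + std::fabs(cur.g)) ||
        std::fabs(step) < 1e-13)
      break;
  }
  return b;
}

// starts[i] .. starts[i+1]-1 give line i's observations
static std::vector<int> line_starts(const IntegerVector& line, int n_lines) {
  int n = line.size();
  std::vector<int> starts(n_lines + 1, 0);
  for (int j = 0; j < n; ++j) {
    int g = line[j];
    if (g < 0 || g >= n_lines) stop("line index out of range");
    starts[g + 1]++;
  }
  for (int i = 0; i < n_lines; ++i) starts[i + 1] += starts[i];
  // verify sortedness
  for (int j = 1; j < n; ++j)
    if (line[j] < line[j - 1]) stop("observations must be sorted by line");
  return starts;
}

// Negative marginal log-likelihood.
// par = (left, right, xmid, scale, log sd_b, log sd_e); nagq <= 1 -> Laplace.
// b_cache, when of length n_lines, provides warm starts for the inner mode
// search and is updated in place with the modes found.
// [[Rcpp::export]]
double nlme4pl_nll(NumericVector par, NumericVector x, NumericVector y,
                   IntegerVector line, int n_lines, int nagq,
                   NumericVector ghz, NumericVector ghw,
                   NumericVector b_cache) {
  const double BIG = 1e10;
  for (int k = 0; k < par.size(); ++k)
    if (!std::isfinite(par[k])) return BIG;
  double L = par[0], R = par[1], m = par[2], s = par[3];
  double sb = std::exp(par[4]), se = std::exp(par[5]);
  if (s == 0.0 || !std::isfinite(sb) || !std::isfinite(se) || se <= 0.0)
    return BIG;
  double inv_se2 = 1.0 / (se * se);
  double inv_sb2 = 1.0 / (sb * sb);
  std::vector<int> starts = line_starts(line, n_lines);
  const double* xp = x.begin();
  const double* yp = y.begin();
  double ll = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (int i = 0; i < n_lines; ++i) {
    int a = starts[i], nI = starts[i + 1] - a;
    if (nI == 0) continue;
    bool warm = b_cache.size() == n_lines;
    double bhat = find_mode(xp + a, yp + a, nI, L, R, m, s, inv_se2,
                            inv_sb2, warm ? b_cache[i] : 0.0);
    if (warm) b_cache[i] = bhat;
    PenFit at = pen_objective(bhat, xp + a, yp + a, nI, L, R, m, s,
                              inv_se2, inv_sb2);
    double h = at.h_full > 0.0 ? at.h_full : at.h_gn;
    if (nagq <= 1) {
      // -0.5*log(sb^2 * h) written via sb2*h = 1 + sb^2*(data part), stable
      // as sb -> 0
      double sb2h = (sb * sb) * h;
      ll += -0.5 * nI * (l2pi + 2.0 * std::log(se)) - at.g -
            0.5 * std::log(sb2h);
    } else {
      double tau = 1.0 / std::sqrt(h);
      double acc = 0.0;
      for (int k = 0; k < nagq; ++k) {
        double bk = bhat + M_SQRT2 * tau * ghz[k];
        PenFit pk = pen_objective(bk, xp + a, yp + a, nI, L, R, m, s,
                                  inv_se2, inv_sb2);
        acc += ghw[k] * std::exp(ghz[k] * ghz[k] - (pk.g - at.g));
      }
      double logI = -at.g + 0.5 * std::log(2.0) + std::log(tau) +
                    std::log(acc);
      ll += -0.5 * nI * (l2pi + 2.0 * std::log(se)) -
            0.5 * (l2pi + 2.0 * std::log(sb)) + logI;
    }
    if (!std::isfinite(ll)) return BIG;
  }
  return -ll;
}

// Conditional modes of the per-line random effects at given parameters.
// [[Rcpp::export]]
NumericVector nlme4pl_modes(NumericVector par, NumericVector x,
                            NumericVector y, IntegerVector line,
                            int n_lines) {
  double L = par[0], R = par[1], m = par[2], s = par[3];
  double sb = std::exp(par[4]), se = std::exp(par[5]);
  double inv_se2 = 1.0 / (se * se);
  double inv_sb2 = 1.0 / (sb * sb);
  std::vector<int> starts = line_starts(line, n_lines);
  const double* xp = x.begin();
  const double* yp = y.begin();
  NumericVector b(n_lines);
  for (int i = 0; i < n_lines; ++i) {
    int a = starts[i], nI = starts[i + 1] - a;
    b[i] = nI == 0 ? 0.0
                   : find_mode(xp + a, yp + a, nI, L, R, m, s, inv_se2,
                               inv_sb2, 0.0);
  }
  return b;
}

// Laplace negative log-likelihood together with its analytic gradient with
// respect to (left, right, xmid, scale, log sd_b, log sd_e).
//
// Writing g(b, th) for the penalised half-deviance of one line and bhat(th)
// for its minimiser, the line's contribution is
//   (n/2) log(2 pi se^2) + g(bhat, th) + 0.5 log(sb^2 * h),  h = g_bb(bhat).
// d/dth g(bhat(th), th) = direct partial only (envelope, g_b(bhat) = 0);
// the log-det term needs dh/dth = h_th + g_bbb * dbhat/dth with
// dbhat/dth = -g_bth / h.
// [[Rcpp::export]]
NumericVector nlme4pl_nll_grad(NumericVector par, NumericVector x,
                               NumericVector y, IntegerVector line,
                               int n_lines, NumericVector b_cache) {
  NumericVector out(7);
  const double BIG = 1e10;
  for (int k = 0; k < par.size(); ++k)
    if (!std::isfinite(par[k])) { out[0] = BIG; return out; }
  double L = par[0], R = par[1], m = par[2], s = par[3];
  double sb = std::exp(par[4]), se = std::exp(par[5]);
  if (s == 0.0 || !std::isfinite(sb) || !std::isfinite(se) || se <= 0.0) {
    out[0] = BIG; return out;
  }
  double inv_se2 = 1.0 / (se * se);
  double inv_sb2 = 1.0 / (sb * sb);
  double d = L - R;
  std::vector<int> starts = line_starts(line, n_lines);
  const double* xp = x.begin();
  const double* yp = y.begin();
  const double l2pi = std::log(2.0 * M_PI);
  bool warm = b_cache.size() == n_lines;
  double nll = 0.0;
  double grad[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < n_lines; ++i) {
    int a = starts[i], nI = starts[i + 1] - a;
    if (nI == 0) continue;
    double bhat = find_mode(xp + a, yp + a, nI, L, R, m, s, inv_se2,
                            inv_sb2, warm ? b_cache[i] : 0.0);
    if (warm) b_cache[i] = bhat;
    // single pass over this line's wells accumulating every sum needed
    double rr = 0, A_f2 = 0, A_rfbb = 0, Sg3 = 0;
    double S_rf[4] = {0, 0, 0, 0};    // sum r * f_phi
    double S_gb[4] = {0, 0, 0, 0};    // sum (f_phi f_b - r f_bphi)
    double S_h[4] = {0, 0, 0, 0};     // sum (2 f_b f_bphi + f_phi f_bb - r f_bbphi)
    for (int j = a; j < a + nI; ++j) {
      double u = (m + bhat - xp[j]) / s;
      double p = inv_logit_neg(u);
      double q = p * (1.0 - p);
      double omp = 1.0 - 2.0 * p;
      double f = R + d * p;
      double r = yp[j] - f;
      double fb = -d * q / s;
      double fbb = d * omp * q / (s * s);
      double w3 = 2.0 * q - omp * omp;
      double fbbb = d * q * w3 / (s * s * s);
      double fphi[4] = {p, 1.0 - p, fb, d * q * u / s};
      double fbphi[4] = {-q / s, q / s, fbb,
                         -d * q * (omp * u - 1.0) / (s * s)};
      double fbbphi[4] = {omp * q / (s * s), -omp * q / (s * s), fbbb,
                          -d * q * (w3 * u + 2.0 * omp) / (s * s * s)};
      rr += r * r;
      A_f2 += fb * fb;
      A_rfbb += r * fbb;
      Sg3 += 3.0 * fb * fbb - r * fbbb;
      for (int k = 0; k < 4; ++k) {
        S_rf[k] += r * fphi[k];
        S_gb[k] += fphi[k] * fb - r * fbphi[k];
        S_h[k] += 2.0 * fb * fbphi[k] + fphi[k] * fbb - r * fbbphi[k];
      }
    }
    double h = (A_f2 - A_rfbb) * inv_se2 + inv_sb2;
    if (h <= 0.0) h = A_f2 * inv_se2 + inv_sb2;  // Gauss-Newton fallback
    double g_at = 0.5 * rr * inv_se2 + 0.5 * bhat * bhat * inv_sb2;
    double sb2h = (sb * sb) * h;
    nll += 0.5 * nI * (l2pi + 2.0 * std::log(se)) + g_at +
           0.5 * std::log(sb2h);
    double g_bbb = Sg3 * inv_se2;
    // curve parameters (left, right, xmid, scale)
    for (int k = 0; k < 4; ++k) {
      double g_phi = -S_rf[k] * inv_se2;
      double g_bphi = S_gb[k] * inv_se2;
      double h_phi = S_h[k] * inv_se2;
      grad[k] += g_phi + 0.5 * (h_phi - g_bbb * g_bphi / h) / h;
    }
    // log sd_b: d(0.5 log sb^2)/dlsb = 1; g_lsb = -bhat^2/sb^2;
    // h_lsb = -2/sb^2; g_{b,lsb} = -2 bhat/sb^2
    grad[4] += 1.0 - bhat * bhat * inv_sb2 +
               0.5 * (-2.0 * inv_sb2 +
                      g_bbb * 2.0 * bhat * inv_sb2 / h) / h;
    // log sd_e: direct nI; g_lse = -rr/se^2; h_lse = -2(h - 1/sb^2);
    // g_{b,lse} = 2 bhat/sb^2 (using the mode equation)
    grad[5] += nI - rr * inv_se2 +
               0.5 * (-2.0 * (h - inv_sb2) -
                      g_bbb * 2.0 * bhat * inv_sb2 / h) / h;
    if (!std::isfinite(nll)) { out[0] = BIG; return out; }
  }
  out[0] = nll;
  for (int k = 0; k < 6; ++k) out[k + 1] = grad[k];
  return out;
}
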