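// Poisson maximum-likelihood event positioning.
//
// The likelihood of the charges q_i over the M_rec used pixels, given a
// trial position (x, y), assigns each pixel the Poisson rate
// lam_i = f_i(x, y) * (sum q) / (sum f), with f_i the fitted bell-shaped
// light-response function.  Minimised quantity is the negative log
// likelihood up to q-only constants: sum_i [lam_i - q_i log lam_i].
// A 2-D Nelder-Mead search starts at the centroid of the maximum-charge
// pixel, constrained to a disc of radius r_rec around it.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double bell(const double* p, double x, double y) {
  // p = {a, b, c, d, e}
  double dx = x - p[3], dy = y - p[4];
  double r2 = (dx * dx + dy * dy) / (p[1] * p[1]);
  return p[0] / (1.0 + std::pow(r2, p[2]));
}

struct NllCtx {
  const double* P;       // params, G x 5 column-major
  int G;
  const int* use;        // 0-based group indices
  int m;
  const double* q;       // charges of used pixels
  double sq;             // sum of charges
  double cx, cy, rrec;   // constraint disc
};

static double nll_at(const NllCtx& c, double x, double y) {
  double sf = 0.0;
  std::vector<double> f(c.m);
  for (int k = 0; k < c.m; ++k) {
    const int g = c.use[k];
    double pk[5] = {c.P[g], c.P[c.G + g], c.P[2 * c.G + g],
                    c.P[3 * c.G + g], c.P[4 * c.G + g]};
    f[k] = bell(pk, x, y);
    sf += f[k];
  }
  if (sf <= 1e-12 || c.sq <= 0.0) return 1e30;
  double s = 0.0;
  for (int k = 0; k < c.m; ++k) {
    double lam = f[k] * c.sq / sf;
    if (lam < 1e-12) lam = 1e-12;
    s += lam - c.q[k] * std::log(lam);
  }
  return s;
}

static double penalised(const NllCtx& c, double x, double y) {
  double dx = x - c.cx, dy = y - c.cy;
  double d = std::sqrt(dx * dx + dy * dy);
  double pen = 0.0;
  if (d > c.rrec) {
    // project back onto the disc for evaluation, quadratic penalty outside
    double s = c.rrec / d;
    x = c.cx + dx * s;
    y = c.cy + dy * s;
    pen = 1e3 * (d - c.rrec) * (d - c.rrec);
  }
  return nll_at(c, x, y) + pen;
}

// Nelder-Mead in 2-D; returns best point and value, records convergence.
static bool nelder_mead(const NllCtx& c, double x0, double y0, double step,
                        double tol, int maxit, double& bx, double& by,
                        double& bv) {
  double px[3] = {x0, x0 + step, x0};
  double py[3] = {y0, y0, y0 + step};
  double pv[3];
  for (int i = 0; i < 3; ++i) pv[i] = penalised(c, px[i], py[i]);
  int it = 0;
  for (; it < maxit; ++it) {
    // order: lo, mid, hi
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (pv[i] < pv[lo]) lo = i;
      if (pv[i] > pv[hi]) hi = i;
    }
    int mid = 3 - lo - hi;
    if (lo == hi) mid = (lo + 1) % 3;
    double simplex_size = std::max(
      std::hypot(px[lo] - px[hi], py[lo] - py[hi]),
      std::hypot(px[lo] - px[mid], py[lo] - py[mid]));
    if (simplex_size < tol) {
      bx = px[lo]; by = py[lo]; bv = pv[lo];
      return true;
    }
    double ox = (px[lo] + px[mid]) / 2.0, oy = (py[lo] + py[mid]) / 2.0;
    double rx = ox + (ox - px[hi]), ry = oy + (oy - py[hi]);
    double rv = penalised(c, rx, ry);
    if (rv < pv[lo]) {
      double ex = ox + 2.0 * (ox - px[hi]), ey = oy + 2.0 * (oy - py[hi]);
      double ev = penalised(c, ex, ey);
      if (ev < rv) { px[hi] = ex; py[hi] = ey; pv[hi] = ev; }
      else { px[hi] = rx; py[hi] = ry; pv[hi] = rv; }
    } else if (rv < pv[mid]) {
      px[hi] = rx; py[hi] = ry; pv[hi] = rv;
    } else {
      double kx = ox + 0.5 * (px[hi] - ox), ky = oy + 0.5 * (py[hi] - oy);
      double kv = penalised(c, kx, ky);
      if (kv < pv[hi]) { px[hi] = kx; py[hi] = ky; pv[hi] = kv; }
      else {  // shrink towards lo
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
          py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
          pv[i] = penalised(c, px[i], py[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (pv[i] < pv[lo]) lo = i;
  bx = px[lo]; by = py[lo]; bv = pv[lo];
  return false;
}

// [[Rcpp::export(name = ".cpp_bell_eval")]]
NumericVector cpp_bell_eval(NumericVector par, NumericVector x,
                            NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  double p[5] = {par[0], par[1], par[2], par[3], par[4]};
  for (int i = 0; i < n; ++i) out[i] = bell(p, x[i], y[i]);
  return out;
}

// [[Rcpp::export(name = ".cpp_nll")]]
double cpp_nll(NumericVector q, NumericMatrix params, IntegerVector use,
               double x, double y) {
  std::vector<int> u(use.size());
  for (int k = 0; k < use.size(); ++k) u[k] = use[k] - 1;
  double sq = 0.0;
  for (int k = 0; k < q.size(); ++k) sq += q[k];
  NllCtx c{REAL(params), params.nrow(), u.data(), (int)u.size(),
           REAL(q), sq, 0.0, 0.0, 1e9};
  return nll_at(c, x, y);
}

// [[Rcpp::export(name = ".cpp_reconstruct")]]
NumericMatrix cpp_reconstruct(NumericMatrix Q, NumericMatrix params,
                              NumericVector cx, NumericVector cy,
                              IntegerMatrix nb, LogicalVector usable,
                              double r_rec, double step, double tol,
                              int maxit) {
  const int n = Q.nrow(), G = Q.ncol(), M = nb.ncol();
  NumericMatrix out(n, 5);  // x, y, nll, seed gid, converged
  colnames(out) = CharacterVector::create("x", "y", "nll", "seed",
                                          "converged");
  std::vector<int> use(M);
  std::vector<double> q(M);
  for (int i = 0; i < n; ++i) {
    int seed = -1;
    double qmax = -1.0;
    for (int g = 0; g < G; ++g)
      if (usable[g] && Q(i, g) > qmax) { qmax = Q(i, g); seed = g; }
    if (seed < 0 || qmax <= 0.0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = NA_REAL; out(i, 4) = 0;
      continue;
    }
    double sq = 0.0;
    for (int k = 0; k < M; ++k) {
      use[k] = nb(seed, k) - 1;
      q[k] = Q(i, use[k]);
      sq += q[k];
    }
    NllCtx c{REAL(params), G, use.data(), M, q.data(), sq,
             cx[seed], cy[seed], r_rec};
    double bx, by, bv;
    bool conv = nelder_mead(c, cx[seed], cy[seed], step, tol, maxit,
                            bx, by, bv);
    if (!conv) {
      // restarts from perturbed seeds
      for (int rsx = -1; rsx <= 1 && !conv; rsx += 2)
        for (int rsy = -1; rsy <= 1 && !conv; rsy += 2) {
          double tx, ty, tv;
          conv = nelder_mead(c, cx[seed] + rsx * step / 2.0,
                             cy[seed] + rsy * step / 2.0, step, tol,
                             maxit, tx, ty, tv);
          if (tv < bv) { bx = tx; by = ty; bv = tv; }
        }
    }
    // never worse than the seed position
    double sv = nll_at(c, cx[seed], cy[seed]);
    if (sv < bv) { bx = cx[seed]; by = cy[seed]; bv = sv; }
    if (!conv) {
      // fall back to the charge centroid of the used pixels
      double wx = 0.0, wy = 0.0, w = 0.0;
      for (int k = 0; k < M; ++k) {
        wx += q[k] * cx[use[k]];
        wy += q[k] * cy[use[k]];
        w += q[k];
      }
      if (w > 0) { bx = wx / w; by = wy / w; bv = nll_at(c, bx, by); }
    }
    out(i, 0) = bx; out(i, 1) = by; out(i, 2) = bv;
    out(i, 3) = seed + 1; out(i, 4) = conv ? 1 : 0;
  }
  return out;
}
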