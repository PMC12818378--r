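#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Hartigan & Hartigan's dip statistic: the minimal sup-norm distance between
// the empirical CDF and any unimodal CDF (convex on (-inf, m], concave on
// [m, inf), with an atom permitted at the mode m).
//
// Computed by bisection on the tube half-width t.  Feasibility of "some
// unimodal CDF lies within t of the ECDF everywhere" is checked by a linear
// sweep that propagates, for each prefix of the sorted unique values, the
// convex region of achievable (value, arrival-slope) states of a convex
// nondecreasing chain constrained to the tube boxes
//   c_j - t <= G(v_j) <= cprev_j + t  (intersected with [0, 1]).
// The region's lower/upper boundaries are piecewise-linear convex/concave
// curves in the arrival slope; transitions are running-min/max (slope can
// only grow), a shear by the gap width, and box clipping.  The concave
// suffix chain is the mirror image of the same computation.  A mode in the
// open gap after v_k is feasible iff both chains are feasible and the
// minimal left endpoint does not exceed the maximal right start; a mode
// with an atom at v_k replaces the box at v_k by its one-sided halves.

namespace {

const double FEAS_EPS = 1e-12;

struct Curve {
  std::vector<double> s, y;  // breakpoints, piecewise linear between
};

double curve_eval(const Curve &c, double sv) {
  const std::vector<double> &s = c.s;
  if (sv <= s.front()) return c.y.front();
  if (sv >= s.back()) return c.y.back();
  size_t lo = 0, hi = s.size() - 1;
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (s[mid] <= sv) lo = mid; else hi = mid;
  }
  if (s[hi] == s[lo]) return std::min(c.y[lo], c.y[hi]);
  double w = (sv - s[lo]) / (s[hi] - s[lo]);
  return c.y[lo] + w * (c.y[hi] - c.y[lo]);
}

double curve_min(const Curve &c) {
  return *std::min_element(c.y.begin(), c.y.end());
}

// f convex: running minimum over s' <= s, flat extension to smax
void running_min_extend(Curve &f, double smax) {
  size_t am = 0;
  for (size_t i = 1; i < f.y.size(); ++i) if (f.y[i] < f.y[am]) am = i;
  f.s.resize(am + 1); f.y.resize(am + 1);
  if (f.s.back() < smax) { f.s.push_back(smax); f.y.push_back(f.y[am]); }
}

// g concave: running maximum, flat extension
void running_max_extend(Curve &g, double smax) {
  size_t am = 0;
  for (size_t i = 1; i < g.y.size(); ++i) if (g.y[i] > g.y[am]) am = i;
  g.s.resize(am + 1); g.y.resize(am + 1);
  if (g.s.back() < smax) { g.s.push_back(smax); g.y.push_back(g.y[am]); }
}

void shear(Curve &c, double delta) {
  for (size_t i = 0; i < c.s.size(); ++i) c.y[i] += c.s[i] * delta;
}

void clip_low(Curve &f, double lo) {  // f := max(f, lo)
  std::vector<double> ns, ny;
  size_t n = f.s.size();
  ns.reserve(n + 2); ny.reserve(n + 2);
  for (size_t i = 0; i < n; ++i) {
    if (i > 0) {
      double y0 = f.y[i - 1], y1 = f.y[i];
      if ((y0 - lo) * (y1 - lo) < 0) {
        double w = (lo - y0) / (y1 - y0);
        ns.push_back(f.s[i - 1] + w * (f.s[i] - f.s[i - 1]));
        ny.push_back(lo);
      }
    }
    ns.push_back(f.s[i]); ny.push_back(std::max(f.y[i], lo));
  }
  f.s.swap(ns); f.y.swap(ny);
}

void clip_high(Curve &g, double hi) {  // g := min(g, hi)
  std::vector<double> ns, ny;
  size_t n = g.s.size();
  ns.reserve(n + 2); ny.reserve(n + 2);
  for (size_t i = 0; i < n; ++i) {
    if (i > 0) {
      double y0 = g.y[i - 1], y1 = g.y[i];
      if ((y0 - hi) * (y1 - hi) < 0) {
        double w = (hi - y0) / (y1 - y0);
        ns.push_back(g.s[i - 1] + w * (g.s[i] - g.s[i - 1]));
        ny.push_back(hi);
      }
    }
    ns.push_back(g.s[i]); ny.push_back(std::min(g.y[i], hi));
  }
  g.s.swap(ns); g.y.swap(ny);
}

// restrict both curves to the slope interval where f <= g; false if empty
bool restrict_domain(Curve &f, Curve &g) {
  std::vector<double> gr;
  gr.reserve(f.s.size() + g.s.size());
  std::merge(f.s.begin(), f.s.end(), g.s.begin(), g.s.end(),
             std::back_inserter(gr));
  gr.erase(std::unique(gr.begin(), gr.end()), gr.end());
  size_t m = gr.size();
  std::vector<double> h(m);
  for (size_t i = 0; i < m; ++i) h[i] = curve_eval(f, gr[i]) - curve_eval(g, gr[i]);
  // h is convex; the region h <= tol is one interval
  const double tol = FEAS_EPS;
  int iL = -1, iR = -1;
  for (size_t i = 0; i < m; ++i) if (h[i] <= tol) { iL = (int)i; break; }
  if (iL < 0) return false;
  for (int i = (int)m - 1; i >= 0; --i) if (h[i] <= tol) { iR = i; break; }
  double sL = gr[iL], sR = gr[iR];
  if (iL > 0 && h[iL - 1] > tol) {  // interpolate crossing
    double w = (tol - h[iL - 1]) / (h[iL] - h[iL - 1]);
    sL = gr[iL - 1] + w * (gr[iL] - gr[iL - 1]);
  }
  if (iR + 1 < (int)m && h[iR + 1] > tol) {
    double w = (tol - h[iR + 1]) / (h[iR] - h[iR + 1]);
    sR = gr[iR + 1] + w * (gr[iR] - gr[iR + 1]);
  }
  if (sR < sL) sR = sL;
  Curve nf, ng;
  nf.s.push_back(sL); nf.y.push_back(curve_eval(f, sL));
  for (size_t i = 0; i < f.s.size(); ++i)
    if (f.s[i] > sL && f.s[i] < sR) { nf.s.push_back(f.s[i]); nf.y.push_back(f.y[i]); }
  if (sR > sL) { nf.s.push_back(sR); nf.y.push_back(curve_eval(f, sR)); }
  ng.s.push_back(sL); ng.y.push_back(curve_eval(g, sL));
  for (size_t i = 0; i < g.s.size(); ++i)
    if (g.s[i] > sL && g.s[i] < sR) { ng.s.push_back(g.s[i]); ng.y.push_back(g.y[i]); }
  if (sR > sL) { ng.s.push_back(sR); ng.y.push_back(curve_eval(g, sR)); }
  f = nf; g = ng;
  return true;
}

struct SweepOut {
  std::vector<char> prefOK, atomOK;  // index 1..K
  std::vector<double> A, AL;
};

// clo[j] = ECDF at v_j (lower box corner is clo - t)
// chi[j] = ECDF just below v_j (upper box corner is chi + t)
void sweep(const std::vector<double> &v, const std::vector<double> &clo,
           const std::vector<double> &chi, double t, double smax,
           SweepOut &out) {
  int K = (int)v.size();
  out.prefOK.assign(K + 1, 0); out.atomOK.assign(K + 1, 0);
  out.A.assign(K + 1, 0.0); out.AL.assign(K + 1, 0.0);
  out.AL[1] = 0.0; out.atomOK[1] = 1;  // empty prefix: L can sit at 0
  double lo1 = std::max(0.0, clo[0] - t), hi1 = std::min(1.0, chi[0] + t);
  if (lo1 > hi1 + FEAS_EPS) return;
  Curve f, g;
  f.s.assign({0.0, smax}); f.y.assign({lo1, lo1});
  g.s.assign({0.0, smax}); g.y.assign({hi1, hi1});
  out.prefOK[1] = 1; out.A[1] = lo1;
  for (int j = 2; j <= K; ++j) {
    double delta = v[j - 1] - v[j - 2];
    running_min_extend(f, smax);
    running_max_extend(g, smax);
    shear(f, delta);
    shear(g, delta);
    double AL = std::max(0.0, curve_min(f));
    if (AL <= chi[j - 1] + t + FEAS_EPS) { out.AL[j] = AL; out.atomOK[j] = 1; }
    double lo = std::max(0.0, clo[j - 1] - t), hi = std::min(1.0, chi[j - 1] + t);
    if (lo > hi + FEAS_EPS) return;
    clip_low(f, lo);
    clip_high(g, hi);
    if (!restrict_domain(f, g)) return;
    out.prefOK[j] = 1;
    out.A[j] = curve_min(f);
  }
}

bool feasible(const std::vector<double> &v, const std::vector<double> &c,
              const std::vector<double> &cp, const std::vector<double> &vm,
              const std::vector<double> &cm, const std::vector<double> &cpm,
              double t, double smax, SweepOut &L, SweepOut &R) {
  int K = (int)v.size();
  sweep(v, c, cp, t, smax, L);
  sweep(vm, cm, cpm, t, smax, R);
  for (int k = 0; k <= K; ++k) {  // mode in the open gap after v_k
    bool okl = (k == 0) || L.prefOK[k];
    bool okr = (k == K) || R.prefOK[K - k];
    if (!okl || !okr) continue;
    if (k > 0 && k < K) {
      double A = L.A[k], B = 1.0 - R.A[K - k];
      if (A > B + FEAS_EPS) continue;
    }
    return true;
  }
  for (int k = 1; k <= K; ++k) {  // mode with an atom at v_k
    if (!L.atomOK[k] || !R.atomOK[K + 1 - k]) continue;
    double A = L.AL[k], B = 1.0 - R.AL[K + 1 - k];
    if (A > B + FEAS_EPS) continue;
    return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
double dip_stat_cpp(Rcpp::NumericVector x, double tol = 1e-14) {
  int n = x.size();
  if (n < 1) Rcpp::stop("empty sample");
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  std::vector<double> v; std::vector<int> cnt;
  for (int i = 0; i < n; ++i) {
    if (v.empty() || xs[i] != v.back()) { v.push_back(xs[i]); cnt.push_back(1); }
    else cnt.back()++;
  }
  int K = (int)v.size();
  if (K == 1) return 0.0;
  double v0 = v.front(), v1 = v.back();
  double mingap = v1 - v0;
  for (int j = 0; j + 1 < K; ++j) mingap = std::min(mingap, v[j + 1] - v[j]);
  for (int j = 0; j < K; ++j) v[j] = (v[j] - v0) / (v1 - v0);
  mingap /= (v1 - v0);
  double smax = 1.0 / mingap + 1.0;
  std::vector<double> c(K), cp(K);
  int run = 0;
  for (int j = 0; j < K; ++j) {
    cp[j] = (double)run / n;
    run += cnt[j];
    c[j] = (double)run / n;
  }
  std::vector<double> vm(K), cm(K), cpm(K);
  for (int j = 0; j < K; ++j) {
    vm[j] = 1.0 - v[K - 1 - j];
    cm[j] = 1.0 - cp[K - 1 - j];
    cpm[j] = 1.0 - c[K - 1 - j];
  }
  SweepOut L, R;
  double lo = 0.0, hi = 0.26;
  if (!feasible(v, c, cp, vm, cm, cpm, hi, smax, L, R)) hi = 0.51;
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    if (feasible(v, c, cp, vm, cm, cpm, mid, smax, L, R)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}
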