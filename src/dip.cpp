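// Hartigan's dip statistic: the minimum over unimodal distribution
// functions of the maximum absolute distance to the empirical CDF.
//
// Exact computation by enumerating candidate mode placements: at every
// distinct value (where the unimodal class allows an atom) and inside
// every gap between consecutive distinct values (mode position optimized;
// feasibility is jointly convex in position and band half-width d).  For
// a candidate d, the convex side is feasible iff the greatest convex
// minorant of its upper constraints dominates its lower constraints
// (mirrored for the concave side), and the two sides must join: the
// minimal extrapolated left limit at the mode may not exceed the band
// ceiling there nor the maximal achievable start of the concave side.
// Each configuration is solved by bisection on d; the dip is the minimum
// over configurations.  Validated against an LP oracle over piecewise
// linear unimodal CDFs (see the test suite).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

namespace {

struct DipWork {
  std::vector<double> u, Fk, Fp;   // distinct values, ecdf at / below
  int m;
  std::vector<double> U, L, h, uu, neg;
  std::vector<int> hull;

  double Lv(int k, double d) const { return std::max(Fk[k] - d, 0.0); }
  double Uv(int k, double d) const { return std::min(Fp[k] + d, 1.0); }

  // lower convex hull of (xs, ys), values interpolated at every xs
  void lower_hull_vals(const std::vector<double>& xs,
                       const std::vector<double>& ys,
                       std::vector<double>& out) {
    const int k = (int) xs.size();
    out.resize(k);
    if (k <= 2) { out = ys; return; }
    hull.clear();
    hull.push_back(0); hull.push_back(1);
    for (int i = 2; i < k; ++i) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        if ((ys[b] - ys[a]) * (xs[i] - xs[a]) >=
            (ys[i] - ys[a]) * (xs[b] - xs[a]))
          hull.pop_back();
        else break;
      }
      hull.push_back(i);
    }
    int seg = 0;
    for (int j = 0; j < k; ++j) {
      while (seg + 2 < (int) hull.size() && xs[hull[seg + 1]] <= xs[j]) ++seg;
      int a = hull[seg], b = hull[seg + 1];
      out[j] = (xs[b] == xs[a]) ? ys[a]
        : ys[a] + (ys[b] - ys[a]) * (xs[j] - xs[a]) / (xs[b] - xs[a]);
    }
  }

  // convex side bracket feasibility on points 0..s-1
  bool left_ok(int s, double d) {
    if (s <= 0) return true;
    U.resize(s); L.resize(s); uu.assign(u.begin(), u.begin() + s);
    for (int k = 0; k < s; ++k) { U[k] = Uv(k, d); L[k] = Lv(k, d); }
    lower_hull_vals(uu, U, h);
    for (int k = 0; k < s; ++k) if (h[k] < L[k] - 1e-14) return false;
    return true;
  }

  // concave side bracket feasibility on points t..m-1
  bool right_ok(int t, double d, bool relax) {
    if (t >= m) return true;
    int len = m - t;
    U.resize(len); L.resize(len); neg.resize(len);
    uu.assign(u.begin() + t, u.end());
    for (int k = 0; k < len; ++k) {
      U[k] = Uv(t + k, d); L[k] = Lv(t + k, d); neg[k] = -L[k];
    }
    if (relax) U[0] = std::min(Fk[t] + d, 1.0);
    lower_hull_vals(uu, neg, h);
    for (int k = 0; k < len; ++k) if (-h[k] > U[k] + 1e-14) return false;
    return true;
  }

  // per-point steepest entry slopes for the convex side 0..s-1:
  // sl[i] = max_{j<i} (L_i - U_j)/(u_i - u_j); the minimal achievable
  // value at mu >= u_i along a feasible convex chain through point i is
  // L_i + sl[i] * (mu - u_i)
  std::vector<double> slA, slB;
  void prep_a(int s, double d) {
    slA.assign(s, -1e300);
    for (int i = 1; i < s; ++i) {
      double Li = Lv(i, d);
      for (int j = 0; j < i; ++j) {
        double v = (Li - Uv(j, d)) / (u[i] - u[j]);
        if (v > slA[i]) slA[i] = v;
      }
    }
  }
  double a_min(int s, double mu, double d) {
    if (s <= 0) return 0.0;
    double best = Lv(s - 1, d);
    for (int i = 1; i < s; ++i) {
      if (slA[i] <= 0) continue;
      double v = Lv(i, d) + slA[i] * (mu - u[i]);
      if (v > best) best = v;
    }
    return std::max(best, 0.0);
  }

  // mirrored for the concave side t..m-1: sr[p] = max_{q>p} of the chord
  // slope (L_q - U_p)/(u_q - u_p); the maximal achievable value at
  // mu <= u_p is U_p + sr[p] * (mu - u_p)
  double U0r;
  void prep_b(int t, double d, bool relax) {
    U0r = relax ? std::min(Fk[t] + d, 1.0) : Uv(t, d);
    slB.assign(m, -1e300);
    for (int p = t; p < m - 1; ++p) {
      double Up = (p == t) ? U0r : Uv(p, d);
      for (int q = p + 1; q < m; ++q) {
        double v = (Lv(q, d) - Up) / (u[q] - u[p]);
        if (v > slB[p]) slB[p] = v;
      }
    }
  }
  double b_max(int t, double mu, double d) {
    if (t >= m) return 1.0;
    double best = U0r;
    for (int p = t; p < m - 1; ++p) {
      if (slB[p] <= 0) continue;
      double Up = (p == t) ? U0r : Uv(p, d);
      double v = Up + slB[p] * (mu - u[p]);
      if (v < best) best = v;
    }
    return std::min(best, 1.0);
  }

  // mode at point t (0-based)
  bool feas_atom(int t, double d) {
    if (!left_ok(t, d)) return false;
    if (!right_ok(t, d, true)) return false;
    prep_a(t, d);
    double am = a_min(t, u[t], d);
    double ceilA = (t > 0) ? std::min(Fp[t] + d, 1.0) : d;
    if (am > ceilA + 1e-14) return false;
    prep_b(t, d, true);
    return am <= b_max(t, u[t], d) + 1e-14;
  }

  // mode inside gap (u[s-1], u[s]) in 0-based points, s = 1..m-1:
  // left covers 0..s-1, right covers s..m-1
  bool feas_gap(int s, double d) {
    if (!left_ok(s, d)) return false;
    if (!right_ok(s, d, false)) return false;
    prep_a(s, d);
    prep_b(s, d, false);
    double floor_c = Fk[s - 1] - d, ceil_c = Fk[s - 1] + d;
    double lo = u[s - 1], hi = u[s];
    auto psi = [&](double mu) {
      double a = std::max(a_min(s, mu, d), floor_c);
      double b = std::min(b_max(s, mu, d), ceil_c);
      return a - b;
    };
    for (int it = 0; it < 120 && (hi - lo) > 1e-13 * (u[m - 1] - u[0] + 1.0);
         ++it) {
      double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
      if (psi(m1) <= psi(m2)) hi = m2; else lo = m1;
    }
    double v = std::min(psi(lo), std::min(psi(hi), psi(0.5 * (lo + hi))));
    return v <= 1e-14;
  }
};

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector x, double tol = 1e-10) {
  const int n = x.size();
  if (n < 2) return 0.0;
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  DipWork w;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    w.u.push_back(xs[i]);
    w.Fk.push_back((double) j / n);
    i = j;
  }
  w.m = (int) w.u.size();
  if (w.m == 1) return 0.0;
  w.Fp.resize(w.m);
  w.Fp[0] = 0.0;
  for (int k = 1; k < w.m; ++k) w.Fp[k] = w.Fk[k - 1];

  double best = 0.5;
  auto solve = [&](auto&& feas) {
    if (!feas(best)) return;
    double lo = 0.0, hi = best;
    while (hi - lo > tol) {
      double mid = 0.5 * (lo + hi);
      if (feas(mid)) hi = mid; else lo = mid;
    }
    best = hi;
  };
  for (int t = 0; t < w.m; ++t)
    solve([&](double d) { return w.feas_atom(t, d); });
  for (int s = 1; s < w.m; ++s)
    solve([&](double d) { return w.feas_gap(s, d); });
  return best;
}

// dip of each column of a matrix (used by the Monte-Carlo null)
// [[Rcpp::export(name = ".dip_stat_cols_cpp")]]
Rcpp::NumericVector dip_stat_cols_cpp(Rcpp::NumericMatrix xs,
                                      double tol = 1e-10) {
  Rcpp::NumericVector out(xs.ncol());
  for (int j = 0; j < xs.ncol(); ++j)
    out[j] = dip_stat_cpp(xs.column(j), tol);
  return out;
}
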