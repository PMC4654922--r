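// Fast kernels for the MB-MDR pairwise statistic and the permutation engine.
//
// Genotypes are integer codes 0/1/2 with NA_INTEGER for missing; subjects
// missing either genotype of a pair are dropped from that pair's analysis.
// The statistic is max(T_H, T_L) where H/L pool the two-locus cells whose
// one-vs-rest association test is significant at alpha_cell in the
// corresponding direction; an all-O table yields an exact 0.0.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Pearson chi-squared on a 2x2 table without continuity correction.
// Returns NA if any margin is empty (test incomputable).
static inline double chi2_2x2(double a, double b, double c, double d) {
  double r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d;
  if (r1 <= 0 || r2 <= 0 || c1 <= 0 || c2 <= 0) return NA_REAL;
  double n = r1 + r2;
  double det = a * d - b * c;
  return n * det * det / (r1 * r2 * c1 * c2);
}

// Pooled-variance two-sample t from sufficient statistics; NA if
// incomputable.  Pooling the variance keeps the squared statistic on a
// chi-squared(1)-like scale even for tiny groups, which the gamma tail
// model relies on (an unpooled Welch t on a 2-subject group is unbounded).
static inline double pooled_t(double n1, double s1, double ss1,
                              double n2, double s2, double ss2,
                              double *df_out) {
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return NA_REAL;
  double m1 = s1 / n1, m2 = s2 / n2;
  double v = (ss1 - n1 * m1 * m1) + (ss2 - n2 * m2 * m2);
  double df = n1 + n2 - 2;
  double sp2 = v / df;
  if (sp2 < 0) sp2 = 0;
  double se2 = sp2 * (1 / n1 + 1 / n2);
  if (se2 <= 0) return NA_REAL;
  *df_out = df;
  return (m1 - m2) / std::sqrt(se2);
}

// Binary-trait statistic from per-cell case/control counts.
static double stat_binary(const double ca[9], const double co[9],
                          double totca, double totco, double chi_crit,
                          double min_cell) {
  int lab[9];
  for (int c = 0; c < 9; ++c) {
    lab[c] = 0;
    double a = ca[c], b = co[c];
    if (a + b < min_cell || a + b <= 0) continue;
    double cc = totca - a, d = totco - b;
    double chi = chi2_2x2(a, b, cc, d);
    if (ISNAN(chi) || !(chi > chi_crit)) continue;
    double p1 = a / (a + b);
    double p2 = cc / (cc + d);       // cc + d > 0 whenever chi is finite
    lab[c] = (p1 > p2) ? 1 : -1;
  }
  double T = 0.0;
  double ha = 0, hb = 0, la = 0, lb = 0;
  bool anyH = false, anyL = false;
  for (int c = 0; c < 9; ++c) {
    if (lab[c] == 1)  { anyH = true; ha += ca[c]; hb += co[c]; }
    if (lab[c] == -1) { anyL = true; la += ca[c]; lb += co[c]; }
  }
  if (anyH) {
    double chi = chi2_2x2(ha, hb, totca - ha, totco - hb);
    if (!ISNAN(chi) && chi > T) T = chi;
  }
  if (anyL) {
    double chi = chi2_2x2(la, lb, totca - la, totco - lb);
    if (!ISNAN(chi) && chi > T) T = chi;
  }
  return T;
}

// Continuous-trait statistic from per-cell n / sum / sum-of-squares.
static double stat_continuous(const double cn[9], const double cs[9],
                              const double css[9], double tn, double ts,
                              double tss, double alpha_cell,
                              double min_cell) {
  int lab[9];
  // the pooled df of every one-vs-rest test is tn - 2, so one critical
  // value serves all nine cells (two-sided at alpha_cell)
  double t_crit = (tn >= 3) ? R::qt(1.0 - alpha_cell / 2.0, tn - 2.0, 1, 0)
                            : R_PosInf;
  for (int c = 0; c < 9; ++c) {
    lab[c] = 0;
    if (cn[c] < min_cell || cn[c] <= 0) continue;
    double df;
    double t = pooled_t(cn[c], cs[c], css[c],
                       tn - cn[c], ts - cs[c], tss - css[c], &df);
    if (ISNAN(t)) continue;
    if (!(std::fabs(t) > t_crit)) continue;
    lab[c] = (t > 0) ? 1 : -1;
  }
  double T = 0.0;
  double hn = 0, hs = 0, hss = 0, ln_ = 0, ls = 0, lss = 0;
  bool anyH = false, anyL = false;
  for (int c = 0; c < 9; ++c) {
    if (lab[c] == 1)  { anyH = true; hn += cn[c]; hs += cs[c]; hss += css[c]; }
    if (lab[c] == -1) { anyL = true; ln_ += cn[c]; ls += cs[c]; lss += css[c]; }
  }
  if (anyH) {
    double df;
    double t = pooled_t(hn, hs, hss, tn - hn, ts - hs, tss - hss, &df);
    if (!ISNAN(t) && t * t > T) T = t * t;
  }
  if (anyL) {
    double df;
    double t = pooled_t(ln_, ls, lss, tn - ln_, ts - ls, tss - lss, &df);
    if (!ISNAN(t) && t * t > T) T = t * t;
  }
  return T;
}

struct StatContext {
  bool binary;
  double chi_crit;     // qchisq(1 - alpha_cell, 1), binary stage-1 threshold
  double alpha_cell;   // continuous stage-1 significance level
  double min_cell;     // cells smaller than this are never labelled H/L
  bool adjust;         // residualize trait on the pair's codominant dummies
};

// Closed-form pair-local codominant correction.  The OLS fit of the trait
// on [intercept, g1==1, g1==2, g2==1, g2==2] is constant within each of
// the nine two-locus cells, so it can be computed from the per-cell
// counts and sums alone: solve the 5x5 weighted normal equations built
// from the cell margins (dropping rank-deficient columns), then turn the
// raw cell sums into residual sums.  O(1) per pair after the counting
// pass, against O(n_individuals) for an explicit residual vector.
static void residualize_cells(const double cn[9], const double cs[9],
                              const double css[9], double rn[9],
                              double rs[9], double rss[9]) {
  // design row of cell c = 3*g1 + g2
  double X[9][5];
  for (int c = 0; c < 9; ++c) {
    int g1 = c / 3, g2 = c % 3;
    X[c][0] = 1.0;
    X[c][1] = (g1 == 1); X[c][2] = (g1 == 2);
    X[c][3] = (g2 == 1); X[c][4] = (g2 == 2);
  }
  double A[5][5] = {{0}}, b[5] = {0};
  double tot = 0;
  for (int c = 0; c < 9; ++c) {
    tot += cn[c];
    if (cn[c] <= 0) continue;
    for (int j = 0; j < 5; ++j) {
      b[j] += X[c][j] * cs[c];
      for (int k = j; k < 5; ++k) A[j][k] += cn[c] * X[c][j] * X[c][k];
    }
  }
  for (int j = 0; j < 5; ++j)
    for (int k = 0; k < j; ++k) A[j][k] = A[k][j];
  // Gauss-Jordan with tiny-pivot column dropping (fitted values are
  // invariant to which dependent column is dropped)
  double tol = 1e-9 * (tot > 1 ? tot : 1.0);
  int use[5];
  for (int j = 0; j < 5; ++j) {
    if (A[j][j] > tol) {
      use[j] = 1;
      double piv = A[j][j];
      for (int k = 0; k < 5; ++k) A[j][k] /= piv;
      b[j] /= piv;
      for (int i = 0; i < 5; ++i) {
        if (i == j) continue;
        double f = A[i][j];
        if (f == 0) continue;
        for (int k = 0; k < 5; ++k) A[i][k] -= f * A[j][k];
        b[i] -= f * b[j];
      }
    } else {
      use[j] = 0;
      for (int k = 0; k < 5; ++k) { A[j][k] = 0; A[k][j] = 0; }
      b[j] = 0;
    }
  }
  for (int c = 0; c < 9; ++c) {
    double fit = 0;
    for (int j = 0; j < 5; ++j) if (use[j]) fit += X[c][j] * b[j];
    rn[c] = cn[c];
    rs[c] = cs[c] - cn[c] * fit;
    rss[c] = css[c] - 2.0 * fit * cs[c] + cn[c] * fit * fit;
  }
}

// Statistic for one SNP pair given genotype column pointers.
static double pair_stat(const int *g1, const int *g2, const double *y,
                        int nind, StatContext &ctx) {
  if (ctx.binary && !ctx.adjust) {
    double ca[9] = {0}, co[9] = {0};
    double totca = 0, totco = 0;
    for (int i = 0; i < nind; ++i) {
      int a = g1[i], b = g2[i];
      if (a == NA_INTEGER || b == NA_INTEGER) continue;
      int c = 3 * a + b;
      if (y[i] > 0.5) { ca[c] += 1; totca += 1; } else { co[c] += 1; totco += 1; }
    }
    return stat_binary(ca, co, totca, totco, ctx.chi_crit, ctx.min_cell);
  }
  // continuous path (native continuous trait, or residualized)
  double cn[9] = {0}, cs[9] = {0}, css[9] = {0};
  double tn = 0, ts = 0, tss = 0;
  for (int i = 0; i < nind; ++i) {
    int a = g1[i], b = g2[i];
    if (a == NA_INTEGER || b == NA_INTEGER) continue;
    int c = 3 * a + b;
    double v = y[i];
    cn[c] += 1; cs[c] += v; css[c] += v * v;
    tn += 1; ts += v; tss += v * v;
  }
  if (tn == 0) return 0.0;
  if (ctx.adjust) {
    double rn[9], rs[9], rss[9];
    residualize_cells(cn, cs, css, rn, rs, rss);
    double ts_ = 0, tss_ = 0;
    for (int c = 0; c < 9; ++c) { ts_ += rs[c]; tss_ += rss[c]; }
    return stat_continuous(rn, rs, rss, tn, ts_, tss_, ctx.alpha_cell,
                           ctx.min_cell);
  }
  return stat_continuous(cn, cs, css, tn, ts, tss, ctx.alpha_cell, ctx.min_cell);
}

static StatContext make_ctx(bool binary, double alpha_cell, bool adjust,
                            double min_cell) {
  StatContext ctx;
  ctx.binary = binary;
  ctx.alpha_cell = alpha_cell;
  ctx.chi_crit = R::qchisq(1.0 - alpha_cell, 1.0, 1, 0);
  ctx.adjust = adjust;
  ctx.min_cell = min_cell;
  return ctx;
}

static inline const int *col_ptr(const IntegerMatrix &G, int j) {
  return &G[(R_xlen_t)j * G.nrow()];
}

// lexicographic linear index of pair (a, b), 0-based, a < b
static inline double pair_lin(double a, double b, double s) {
  return a * s - a * (a + 1) / 2.0 + (b - a - 1);
}

// [[Rcpp::export]]
NumericVector cpp_all_stats(IntegerMatrix G, NumericVector y, bool binary,
                            double alpha_cell, bool adjust,
                            double min_cell) {
  int s = G.ncol(), nind = G.nrow();
  R_xlen_t m = (R_xlen_t)s * (s - 1) / 2;
  NumericVector out(m);
  StatContext ctx = make_ctx(binary, alpha_cell, adjust, min_cell);
  R_xlen_t k = 0;
  for (int a = 0; a < s - 1; ++a) {
    const int *ga = col_ptr(G, a);
    for (int b = a + 1; b < s; ++b) {
      out[k++] = pair_stat(ga, col_ptr(G, b), REAL(y), nind, ctx);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stats_pairs(IntegerMatrix G, NumericVector y,
                              IntegerVector a, IntegerVector b, bool binary,
                              double alpha_cell, bool adjust,
                              double min_cell) {
  int nind = G.nrow();
  R_xlen_t np = a.size();
  NumericVector out(np);
  StatContext ctx = make_ctx(binary, alpha_cell, adjust, min_cell);
  for (R_xlen_t k = 0; k < np; ++k) {
    out[k] = pair_stat(col_ptr(G, a[k] - 1), col_ptr(G, b[k] - 1),
                       REAL(y), nind, ctx);
  }
  return out;
}

struct TopEntry {
  double stat;
  double lin;  // linear pair index, used as the deterministic tie-break
  int a, b;
};

// "worse" ordering: smaller stat first, larger pair index first among ties
struct TopWorse {
  bool operator()(const TopEntry &x, const TopEntry &y) const {
    if (x.stat != y.stat) return x.stat > y.stat;
    return x.lin < y.lin;
  }
};

// [[Rcpp::export]]
List cpp_scan_top(IntegerMatrix G, NumericVector y, bool binary,
                  double alpha_cell, bool adjust, double min_cell, int n) {
  int s = G.ncol(), nind = G.nrow();
  StatContext ctx = make_ctx(binary, alpha_cell, adjust, min_cell);
  std::priority_queue<TopEntry, std::vector<TopEntry>, TopWorse> heap;
  for (int a = 0; a < s - 1; ++a) {
    const int *ga = col_ptr(G, a);
    for (int b = a + 1; b < s; ++b) {
      double t = pair_stat(ga, col_ptr(G, b), REAL(y), nind, ctx);
      TopEntry e;
      e.stat = t;
      e.lin = pair_lin(a, b, s);
      e.a = a + 1; e.b = b + 1;
      if ((int)heap.size() < n) {
        heap.push(e);
      } else {
        const TopEntry &w = heap.top();
        if (t > w.stat || (t == w.stat && e.lin < w.lin)) {
          heap.pop();
          heap.push(e);
        }
      }
    }
  }
  int k = heap.size();
  IntegerVector ra(k), rb(k);
  NumericVector rs(k);
  for (int i = k - 1; i >= 0; --i) {
    const TopEntry &e = heap.top();
    ra[i] = e.a; rb[i] = e.b; rs[i] = e.stat;
    heap.pop();
  }
  return List::create(_["snp_a"] = ra, _["snp_b"] = rb, _["statistic"] = rs);
}

// Statistics on a stored pair list plus the exact maximum over every other
// pair, in one pass over the upper triangle.
// [[Rcpp::export]]
List cpp_perm_exact(IntegerMatrix G, NumericVector y, IntegerVector topA,
                    IntegerVector topB, bool binary, double alpha_cell,
                    bool adjust, double min_cell) {
  int s = G.ncol(), nind = G.nrow();
  StatContext ctx = make_ctx(binary, alpha_cell, adjust, min_cell);
  std::unordered_map<double, int> pos;
  for (int k = 0; k < topA.size(); ++k)
    pos[pair_lin(topA[k] - 1, topB[k] - 1, s)] = k;
  NumericVector stats(topA.size());
  double M = 0.0;
  bool any_rest = false;
  for (int a = 0; a < s - 1; ++a) {
    const int *ga = col_ptr(G, a);
    for (int b = a + 1; b < s; ++b) {
      double t = pair_stat(ga, col_ptr(G, b), REAL(y), nind, ctx);
      std::unordered_map<double, int>::iterator it =
        pos.find(pair_lin(a, b, s));
      if (it != pos.end()) {
        stats[it->second] = t;
      } else {
        any_rest = true;
        if (t > M) M = t;
      }
    }
  }
  return List::create(_["stats"] = stats, _["max_rest"] = M,
                      _["any_rest"] = any_rest);
}

// Sample statistics of randomly drawn non-stored pairs until `S` strictly
// positive values are collected; zeros are counted in `z`.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_sample_tail(IntegerMatrix G, NumericVector y,
                     NumericVector excluded_sorted, int S, double max_draws,
                     bool binary, double alpha_cell, bool adjust,
                     double min_cell) {
  int s = G.ncol(), nind = G.nrow();
  double m = (double)s * (s - 1) / 2.0;
  StatContext ctx = make_ctx(binary, alpha_cell, adjust, min_cell);
  NumericVector v(S);
  double z = 0, draws = 0;
  int filled = 0;
  std::unordered_map<double, double> cache;
  while (filled < S) {
    double r = std::floor(unif_rand() * m);
    if (r >= m) r = m - 1;
    if (std::binary_search(excluded_sorted.begin(), excluded_sorted.end(), r))
      continue;
    draws += 1;
    if (draws > max_draws)
      stop("degenerate null (all zeros): no positive statistics after %.0f draws",
           max_draws);
    // invert linear index: find a with offset(a) <= r < offset(a+1),
    // offset(a) = a*s - a*(a+1)/2
    double a = std::floor(s - 0.5 - std::sqrt((s - 0.5) * (s - 0.5) - 2.0 * r));
    if (a < 0) a = 0;
    if (a > s - 2) a = s - 2;
    while (a > 0 && r < pair_lin(a, a + 1, s)) a -= 1;
    while (a < s - 2 && r >= pair_lin(a + 1, a + 2, s)) a += 1;
    double b = a + 1 + (r - pair_lin(a, a + 1, s));
    // with-replacement draws revisit pairs often; the statistic is
    // deterministic given the permuted trait, so cache it per pair
    double t;
    std::unordered_map<double, double>::const_iterator hit = cache.find(r);
    if (hit != cache.end()) {
      t = hit->second;
    } else {
      t = pair_stat(col_ptr(G, (int)a), col_ptr(G, (int)b),
                    REAL(y), nind, ctx);
      cache[r] = t;
    }
    if (t > 0) v[filled++] = t; else z += 1;
  }
  return List::create(_["v"] = v, _["z"] = z, _["draws"] = draws);
}
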