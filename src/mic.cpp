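// Maximal information coefficient (MIC) engine.
//
// Two routes to the same statistic:
//   * mic_approx_cpp: the standard MINE approximation -- equipartition the
//     row axis, collapse the column axis to clumps/superclumps, then a
//     dynamic program finds the optimal column partition for every column
//     count l with l * ny <= B.  Both axis orientations are scored and the
//     maximum normalized mutual information is returned.
//   * mic_exact_cpp: exhaustive enumeration of every row partition (cuts
//     between distinct values) combined with the exact column DP.  Feasible
//     only for small n; used as the default for n <= 30 and exercised by the
//     brute-force oracle tests.
//
// All grids with nx * ny <= B, nx >= 2, ny >= 2 are considered; the score of
// a grid is I(X;Y) / log2(min(nx, ny)).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -1e300;

static std::vector<int> order_idx(const std::vector<double> &v) {
  std::vector<int> idx(v.size());
  for (size_t i = 0; i < v.size(); ++i) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Equipartition sorted values into ~ny rows keeping ties together.
static void equipartition(const std::vector<double> &ys, int ny,
                          std::vector<int> &rows, int &q) {
  int n = (int)ys.size();
  rows.assign(n, 0);
  double rowsize = (double)n / (double)ny;
  int i = 0, h = 0, curr = 0;
  while (i < n) {
    int s = 1;
    for (int j = i + 1; j < n; ++j) {
      if (ys[j] == ys[i]) ++s; else break;
    }
    double t1 = std::fabs((double)h + (double)s - rowsize);
    double t2 = std::fabs((double)h - rowsize);
    if (h != 0 && t1 >= t2) {
      ++curr;
      h = 0;
      rowsize = (double)(n - i) / (double)(ny - curr);
    }
    for (int j = 0; j < s; ++j) rows[i + j] = curr;
    i += s;
    h += s;
  }
  q = curr + 1;
}

// Clump partition of the x-sorted points: x-ties stay together, and maximal
// runs of points falling in the same row are merged (an optimal column
// partition never cuts inside such a run).
static void clumps_partition(const std::vector<double> &xs,
                             const std::vector<int> &Qx,
                             std::vector<int> &Pm, int &p) {
  int n = (int)xs.size();
  std::vector<long> Qt(Qx.begin(), Qx.end());
  long c = -1;
  int i = 0;
  while (i < n) {
    int s = 1;
    bool flag = false;
    for (int j = i + 1; j < n; ++j) {
      if (xs[j] == xs[i]) {
        if (Qt[j] != Qt[i]) flag = true;
        ++s;
      } else break;
    }
    if (s > 1 && flag) {
      for (int j = 0; j < s; ++j) Qt[i + j] = c;
      --c;
    }
    i += s;
  }
  Pm.assign(n, 0);
  int k = 0;
  for (int j = 1; j < n; ++j) {
    if (Qt[j] != Qt[j - 1]) ++k;
    Pm[j] = k;
  }
  p = k + 1;
}

// Cap the number of clumps at khat by equipartitioning the clump ids.
static void superclumps(std::vector<int> &Pm, int &p, int khat) {
  if (p <= khat) return;
  int n = (int)Pm.size();
  std::vector<double> dp(n);
  for (int i = 0; i < n; ++i) dp[i] = (double)Pm[i];
  std::vector<int> rows;
  int q;
  equipartition(dp, khat, rows, q);
  for (int i = 0; i < n; ++i) Pm[i] = rows[i];
  p = q;
}

// k * log2(k) lookup for integer counts, shared by the DP and entropies.
static const std::vector<double> &xlog2_table(int n) {
  static std::vector<double> tab;
  if ((int)tab.size() < n + 1) {
    int old = (int)tab.size();
    tab.resize(n + 1);
    if (old == 0) { tab[0] = 0.0; old = 1; }
    for (int k = old; k <= n; ++k) tab[k] = k * std::log2((double)k);
  }
  return tab;
}

// For fixed rows Qx (in x order) and clumps Pm, return for each column count
// l (index l of the result) the maximum over column partitions of
// sum_{col,row} n_cr * log2(n_cr / n_c).  MI(l) = H(rows) + G[l] / n.
static std::vector<double> optimize_x(const std::vector<int> &Pm, int p,
                                      const std::vector<int> &Qx, int q,
                                      int lmax) {
  int n = (int)Qx.size();
  const std::vector<double> &L = xlog2_table(n);
  // row composition of each clump (CSR); clumps are usually single-row
  std::vector<int> comp_start(p + 1, 0), comp_row, comp_cnt;
  comp_row.reserve(n);
  comp_cnt.reserve(n);
  {
    int i = 0;
    for (int cl = 0; cl < p; ++cl) {
      comp_start[cl] = (int)comp_row.size();
      while (i < n && Pm[i] == cl) {
        int r = Qx[i], c = 0;
        while (i < n && Pm[i] == cl && Qx[i] == r) { ++c; ++i; }
        // merge with an earlier entry for the same row within this clump
        bool merged = false;
        for (int k = comp_start[cl]; k < (int)comp_row.size(); ++k)
          if (comp_row[k] == r) { comp_cnt[k] += c; merged = true; break; }
        if (!merged) { comp_row.push_back(r); comp_cnt.push_back(c); }
      }
    }
    comp_start[p] = (int)comp_row.size();
  }
  // term(s, t) = sum_r n_cr log2 n_cr - n_c log2 n_c for the column made of
  // clumps s..t-1, tabulated by an incremental sweep (O(1) per clump).
  std::vector<double> T((size_t)(p + 1) * (p + 1), 0.0);
  std::vector<int> cnt(q, 0);
  for (int t = 1; t <= p; ++t) {
    std::fill(cnt.begin(), cnt.end(), 0);
    double sumL = 0.0;
    int tt = 0;
    for (int s = t - 1; s >= 0; --s) {
      for (int k = comp_start[s]; k < comp_start[s + 1]; ++k) {
        int r = comp_row[k], c = comp_cnt[k];
        sumL -= L[cnt[r]];
        cnt[r] += c;
        sumL += L[cnt[r]];
        tt += c;
      }
      T[(size_t)s * (p + 1) + t] = sumL - L[tt];
    }
  }
  int Lmax = std::min(lmax, p);
  std::vector<double> out(Lmax + 1, NEG_INF);
  std::vector<double> prev(p + 1, NEG_INF), curr(p + 1, NEG_INF);
  for (int t = 1; t <= p; ++t) prev[t] = T[t];
  out[1] = prev[p];
  for (int l = 2; l <= Lmax; ++l) {
    std::fill(curr.begin(), curr.end(), NEG_INF);
    for (int t = l; t <= p; ++t) {
      double best = NEG_INF;
      const size_t stride = (size_t)(p + 1);
      for (int s = l - 1; s < t; ++s) {
        double v = prev[s] + T[(size_t)s * stride + t];
        if (v > best) best = v;
      }
      curr[t] = best;
    }
    out[l] = curr[p];
    std::swap(prev, curr);
  }
  return out;
}

static double entropy_rows(const std::vector<int> &rows, int q, int n) {
  const std::vector<double> &L = xlog2_table(n);
  std::vector<int> nr(q, 0);
  for (int i = 0; i < n; ++i) nr[rows[i]] += 1;
  double H = L[n];
  for (int r = 0; r < q; ++r) H -= L[nr[r]];
  return H / n;
}

// One orientation of the MINE approximation (rows from yv, columns from xv).
static double mic_one_orientation(const std::vector<double> &xv,
                                  const std::vector<double> &yv,
                                  double B, int c) {
  int n = (int)xv.size();
  std::vector<int> yord = order_idx(yv);
  std::vector<int> xord = order_idx(xv);
  std::vector<double> ys(n), xs(n);
  for (int i = 0; i < n; ++i) ys[i] = yv[yord[i]];
  for (int i = 0; i < n; ++i) xs[i] = xv[xord[i]];
  int maxy = (int)std::floor(B / 2.0);
  double best = 0.0;
  std::vector<int> rowSorted, rowOrig(n), Qx(n), Pm;
  for (int ny = 2; ny <= maxy; ++ny) {
    int lmax = (int)std::floor(B / (double)ny);
    if (lmax < 2) break;
    int q;
    equipartition(ys, ny, rowSorted, q);
    if (q < 2) continue;
    for (int i = 0; i < n; ++i) rowOrig[yord[i]] = rowSorted[i];
    for (int i = 0; i < n; ++i) Qx[i] = rowOrig[xord[i]];
    int p;
    clumps_partition(xs, Qx, Pm, p);
    int khat = std::max(1, (int)((double)c * lmax));
    superclumps(Pm, p, khat);
    if (p < 2) continue;
    double Hq = entropy_rows(Qx, q, n);
    std::vector<double> G = optimize_x(Pm, p, Qx, q, lmax);
    for (int l = 2; l < (int)G.size(); ++l) {
      if (G[l] < NEG_INF / 2) continue;
      double mi = Hq + G[l] / (double)n;
      double v = mi / std::log2((double)std::min(l, ny));
      if (v > best) best = v;
    }
  }
  if (best > 1.0) best = 1.0;
  return best;
}

// [[Rcpp::export]]
double mic_approx_cpp(NumericVector x, NumericVector y, double B, int c) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double a = mic_one_orientation(xv, yv, B, c);
  double b = mic_one_orientation(yv, xv, B, c);
  return std::max(a, b);
}

// [[Rcpp::export]]
double mic_exact_cpp(NumericVector x, NumericVector y, double B) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<int> yord = order_idx(yv);
  std::vector<int> xord = order_idx(xv);
  std::vector<double> ys(n), xs(n);
  for (int i = 0; i < n; ++i) ys[i] = yv[yord[i]];
  for (int i = 0; i < n; ++i) xs[i] = xv[xord[i]];
  // allowed cut positions: before index i where the sorted y value changes
  std::vector<int> gapPos;
  for (int i = 1; i < n; ++i)
    if (ys[i] > ys[i - 1]) gapPos.push_back(i);
  int m = (int)gapPos.size();
  int maxy = (int)std::floor(B / 2.0);
  double best = 0.0;
  std::vector<int> rowSorted(n), rowOrig(n), Qx(n), Pm;
  for (int ny = 2; ny <= maxy; ++ny) {
    int lmax = (int)std::floor(B / (double)ny);
    if (lmax < 2) break;
    int k = ny - 1;
    if (m < k) continue;
    std::vector<int> comb(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    while (true) {
      int r = 0, nextCut = 0;
      for (int i = 0; i < n; ++i) {
        if (nextCut < k && i == gapPos[comb[nextCut]]) { ++r; ++nextCut; }
        rowSorted[i] = r;
      }
      for (int i = 0; i < n; ++i) rowOrig[yord[i]] = rowSorted[i];
      for (int i = 0; i < n; ++i) Qx[i] = rowOrig[xord[i]];
      int p;
      clumps_partition(xs, Qx, Pm, p);
      if (p >= 2) {
        double Hq = entropy_rows(rowSorted, ny, n);
        std::vector<double> G = optimize_x(Pm, p, Qx, ny, lmax);
        for (int l = 2; l < (int)G.size(); ++l) {
          if (G[l] < NEG_INF / 2) continue;
          double mi = Hq + G[l] / (double)n;
          double v = mi / std::log2((double)std::min(l, ny));
          if (v > best) best = v;
        }
      }
      int idx = k - 1;
      while (idx >= 0 && comb[idx] == m - k + idx) --idx;
      if (idx < 0) break;
      ++comb[idx];
      for (int j = idx + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
  }
  if (best > 1.0) best = 1.0;
  return best;
}

// Null distribution of the approximate MIC under permutation of y.
// Uses R's RNG, so set.seed() on the R side makes it reproducible.
// [[Rcpp::export]]
NumericVector mic_perm_cpp(NumericVector x, NumericVector y, double B, int c,
                           int nperm) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yp(y.begin(), y.end());
  NumericVector out(nperm);
  for (int b = 0; b < nperm; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    double a1 = mic_one_orientation(xv, yp, B, c);
    double a2 = mic_one_orientation(yp, xv, B, c);
    out[b] = std::max(a1, a2);
  }
  return out;
}
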