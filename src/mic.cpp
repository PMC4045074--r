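// Maximal information coefficient (MIC).
//
// MIC(x,y) = max over axis-aligned grids (a columns x b rows, a*b <= B(n),
// a,b >= 2) of I(grid) / log min(a,b).  B(n) = max(4, floor(n^alpha)); the
// floor keeps the smallest legal grid (2x2) admissible for small n.
//
// mic_cpp: the ApproxMaxMI heuristic — equipartition one axis into b rows,
// dynamic programming over clump boundaries to optimize the other axis,
// both orientations, elementwise max.
// mic_exhaustive_cpp: brute force over every admissible grid (n <= 12),
// used as the small-n oracle mode.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e300;

static inline double xlogx(double p) { return p > 0 ? p * std::log(p) : 0.0; }

static std::vector<int> order_idx(const NumericVector& v) {
  std::vector<int> idx(v.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Equipartition v into at most b rows, never splitting ties.
// row[i] gets the 0-based row of point i; returns rows actually used.
static int equipartition(const NumericVector& v, int b, std::vector<int>& row) {
  int n = v.size();
  std::vector<int> idx = order_idx(v);
  row.assign(n, 0);
  int i = 0, curr = 0, rowsize = 0, assigned = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[idx[j]] == v[idx[i]]) ++j;
    int s = j - i;
    double desired = (double)(n - assigned + rowsize) / (b - curr);
    if (rowsize != 0 && curr < b - 1 &&
        std::fabs(rowsize + s - desired) >= std::fabs(rowsize - desired)) {
      ++curr;
      rowsize = 0;
    }
    for (int t = i; t < j; ++t) row[idx[t]] = curr;
    rowsize += s;
    assigned += s;
    i = j;
  }
  return curr + 1;
}

// DP over clump boundaries: bestG[l] (l = 1..amax) = max over partitions of
// all points into exactly l columns of sum_col [ -(m/n)log(m/n)
// + sum_q (m_q/n)log(m_q/n) ]  (= H(P) - H(P,Q)); NEG_INF when impossible.
static void optimize_axis(const NumericVector& x, const std::vector<int>& row,
                          int b, int amax, int cap,
                          std::vector<double>& bestG) {
  int n = x.size();
  std::vector<int> idx = order_idx(x);

  // clumps: identical x stays together; consecutive points in the same row
  // merge; a tie-group spanning several rows is a clump of its own
  std::vector<int> clump(n);
  int k = -1, prev_row = -2;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[idx[j]] == x[idx[i]]) ++j;
    int r0 = row[idx[i]];
    bool pure = true;
    for (int t = i + 1; t < j; ++t)
      if (row[idx[t]] != r0) { pure = false; break; }
    int grow = pure ? r0 : -1;
    if (k < 0 || grow == -1 || grow != prev_row) ++k;
    for (int t = i; t < j; ++t) clump[t] = k;  // position in sorted order
    prev_row = grow;
    i = j;
  }
  int nclump = k + 1;

  // superclumps: cap candidate boundaries for speed (clump factor heuristic)
  if (nclump > cap) {
    std::vector<int> size(nclump, 0);
    for (int t = 0; t < n; ++t) size[clump[t]]++;
    std::vector<int> remap(nclump);
    int curr = 0, rowsize = 0, assigned = 0;
    for (int c = 0; c < nclump; ++c) {
      double desired = (double)(n - assigned + rowsize) / (cap - curr);
      if (rowsize != 0 && curr < cap - 1 &&
          std::fabs(rowsize + size[c] - desired) >= std::fabs(rowsize - desired)) {
        ++curr;
        rowsize = 0;
      }
      remap[c] = curr;
      rowsize += size[c];
      assigned += size[c];
    }
    for (int t = 0; t < n; ++t) clump[t] = remap[clump[t]];
    nclump = curr + 1;
  }

  // cumulative per-row counts over clump prefixes
  std::vector<std::vector<int>> cum(nclump + 1, std::vector<int>(b, 0));
  std::vector<int> cumn(nclump + 1, 0);
  {
    int t = 0;
    for (int c = 0; c < nclump; ++c) {
      cum[c + 1] = cum[c];
      cumn[c + 1] = cumn[c];
      while (t < n && clump[t] == c) {
        cum[c + 1][row[idx[t]]]++;
        cumn[c + 1]++;
        ++t;
      }
    }
  }
  auto seg_w = [&](int j, int i2) {
    int m = cumn[i2] - cumn[j];
    if (m == 0) return 0.0;
    double w = -xlogx((double)m / n);
    for (int q = 0; q < b; ++q)
      w += xlogx((double)(cum[i2][q] - cum[j][q]) / n);
    return w;
  };

  bestG.assign(amax + 1, NEG_INF);
  std::vector<std::vector<double>> G(amax + 1,
                                     std::vector<double>(nclump + 1, NEG_INF));
  for (int i2 = 1; i2 <= nclump; ++i2) G[1][i2] = seg_w(0, i2);
  for (int l = 2; l <= amax; ++l)
    for (int i2 = l; i2 <= nclump; ++i2) {
      double best = NEG_INF;
      for (int j = l - 1; j < i2; ++j) {
        if (G[l - 1][j] == NEG_INF) continue;
        double v = G[l - 1][j] + seg_w(j, i2);
        if (v > best) best = v;
      }
      G[l][i2] = best;
    }
  for (int l = 1; l <= amax; ++l) bestG[l] = G[l][nclump];
}

static int grid_budget(int n, double alpha) {
  int B = (int)std::floor(std::pow((double)n, alpha));
  return B < 4 ? 4 : B;
}

// [[Rcpp::export]]
double mic_cpp(NumericVector x, NumericVector y, double alpha = 0.6,
               int clump_c = 15) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  int B = grid_budget(n, alpha);
  double best = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    const NumericVector& xx = orient ? y : x;
    const NumericVector& yy = orient ? x : y;
    for (int b = 2; b <= B / 2; ++b) {
      int amax = B / b;
      if (amax < 2) break;
      std::vector<int> row;
      int bused = equipartition(yy, b, row);
      if (bused < 2) continue;
      std::vector<int> cnt(bused, 0);
      for (int t = 0; t < n; ++t) cnt[row[t]]++;
      double HQ = 0.0;
      for (int q = 0; q < bused; ++q) HQ -= xlogx((double)cnt[q] / n);
      std::vector<double> bestG;
      optimize_axis(xx, row, bused, amax, clump_c * amax, bestG);
      double run = NEG_INF;
      for (int l = 2; l <= amax; ++l) {
        if (bestG[l] > run) run = bestG[l];
        if (run == NEG_INF) continue;
        double denom = std::log((double)std::min(l, bused));
        double val = (HQ + run) / denom;
        if (val > best) best = val;
      }
    }
  }
  return best > 1.0 ? 1.0 : best;
}

// recursive enumeration over cut subsets for the exhaustive oracle
static void enum_cuts(int ngap, int need, int start, std::vector<int>& cuts,
                      const std::function<void(const std::vector<int>&)>& fn) {
  if (need == 0) {
    fn(cuts);
    return;
  }
  for (int c = start; c <= ngap - need + 1; ++c) {
    cuts.push_back(c);
    enum_cuts(ngap, need - 1, c + 1, cuts, fn);
    cuts.pop_back();
  }
}

// dense rank of distinct values (block id per point) and block count
static int blocks(const NumericVector& v, std::vector<int>& blk) {
  int n = v.size();
  std::vector<int> idx = order_idx(v);
  blk.assign(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && v[idx[i]] != v[idx[i - 1]]) ++k;
    blk[idx[i]] = k;
  }
  return k + 1;
}

// [[Rcpp::export]]
double mic_exhaustive_cpp(NumericVector x, NumericVector y, double alpha = 0.6) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  if (n > 12) stop("exhaustive MIC limited to n <= 12");
  int B = grid_budget(n, alpha);
  std::vector<int> bx, by;
  int dx = blocks(x, bx), dy = blocks(y, by);
  double best = 0.0;
  for (int a = 2; a * 2 <= B; ++a) {
    if (a > dx) break;
    for (int b = 2; a * b <= B; ++b) {
      if (b - 1 > dy - 1) continue;
      std::vector<int> cx;
      enum_cuts(dx - 1, a - 1, 1, cx, [&](const std::vector<int>& cutx) {
        // column of block g = #cuts <= g
        std::vector<int> colof(dx, 0);
        for (int g = 0; g < dx; ++g) {
          int c = 0;
          for (int u : cutx)
            if (u <= g) ++c;
          colof[g] = c;
        }
        std::vector<int> cy;
        enum_cuts(dy - 1, b - 1, 1, cy, [&](const std::vector<int>& cuty) {
          std::vector<int> rowof(dy, 0);
          for (int g = 0; g < dy; ++g) {
            int c = 0;
            for (int u : cuty)
              if (u <= g) ++c;
            rowof[g] = c;
          }
          std::vector<int> joint(a * b, 0), mc(a, 0), mr(b, 0);
          for (int t = 0; t < n; ++t) {
            int cc = colof[bx[t]], rr = rowof[by[t]];
            joint[cc * b + rr]++;
            mc[cc]++;
            mr[rr]++;
          }
          double I = 0.0;
          for (int cc = 0; cc < a; ++cc)
            for (int rr = 0; rr < b; ++rr) {
              double pj = (double)joint[cc * b + rr] / n;
              if (pj > 0)
                I += pj * std::log(pj * n * n / ((double)mc[cc] * mr[rr]));
            }
          double val = I / std::log((double)std::min(a, b));
          if (val > best) best = val;
        });
      });
    }
  }
  return best > 1.0 ? 1.0 : best;
}
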