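// Maximal information coefficient via the MINE approximation:
// for each grid shape (p columns x q rows) with p * q <= B(n) = n^alpha,
// the y axis is mass-equipartitioned into q rows and the x-axis cut points
// are optimized by dynamic programming over clump boundaries (clump count
// capped at c * p "superclumps"); the roles of x and y are then swapped and
// the larger normalized mutual information is kept.  MIC is the maximum of
// I / ln(min(p, q)) over all admissible shapes.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Mass equipartition of a sorted vector into at most q bins, keeping ties
// together.  Returns bin index per sorted position; bins are 0..(used-1).
static std::vector<int> equipartition_sorted(const std::vector<double> &ys,
                                             int q) {
  int n = ys.size();
  std::vector<int> row(n);
  double rowsize = (double)n / q;
  int i = 0, h = 0, curr = 0;
  while (i < n) {
    int s = 1;
    while (i + s < n && ys[i + s] == ys[i]) ++s;
    double t1 = std::fabs((double)h + s - rowsize);
    double t2 = std::fabs((double)h - rowsize);
    if (h != 0 && curr < q - 1 && t1 >= t2) {
      ++curr;
      h = 0;
      int remaining = q - curr;
      rowsize = (double)(n - i) / remaining;
    }
    for (int j = i; j < i + s; ++j) row[j] = curr;
    i += s;
    h += s;
  }
  return row;
}

static double entropy_counts(const std::vector<int> &cnt, int total) {
  double hh = 0.0;
  for (size_t r = 0; r < cnt.size(); ++r)
    if (cnt[r] > 0) {
      double p = (double)cnt[r] / total;
      hh -= p * std::log(p);
    }
  return hh;
}

// One orientation: rows from y, optimized cuts on x.  Updates `best` with
// max over l in [2, pmax], q of I(l, q) / ln(min(l, q)).
static void optimize_axis(const std::vector<double> &x,
                          const std::vector<double> &y, int B, double cpar,
                          double &best) {
  int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  std::vector<double> ysorted(y);
  std::sort(ysorted.begin(), ysorted.end());

  for (int q = 2; q <= B / 2; ++q) {
    int pmax = B / q;
    if (pmax < 2) break;
    std::vector<int> rowOfSorted = equipartition_sorted(ysorted, q);
    // map each point's y value to its row (ties share a row by construction)
    std::vector<int> rowOf(n);
    for (int i = 0; i < n; ++i) {
      int lo = std::lower_bound(ysorted.begin(), ysorted.end(), y[i]) -
               ysorted.begin();
      rowOf[i] = rowOfSorted[lo];
    }
    std::vector<int> rowTotal(q, 0);
    for (int i = 0; i < n; ++i) rowTotal[rowOf[i]]++;
    double HR = entropy_counts(rowTotal, n);
    if (HR <= 0.0) continue;  // constant y: MI is 0 for every grid

    // clumps: maximal runs in x order of points sharing one row; points with
    // tied x stay together
    std::vector<std::vector<int> > clumpCnt;  // per clump, counts per row
    {
      int i = 0;
      while (i < n) {
        int s = 1;
        while (i + s < n && x[ord[i + s]] == x[ord[i]]) ++s;
        bool pure = true;
        for (int j = 1; j < s; ++j)
          if (rowOf[ord[i + j]] != rowOf[ord[i]]) { pure = false; break; }
        int r0 = rowOf[ord[i]];
        bool mergePrev = false;
        if (pure && !clumpCnt.empty()) {
          // previous clump pure in the same row?
          const std::vector<int> &pc = clumpCnt.back();
          int nz = 0, rprev = -1;
          for (int r = 0; r < q; ++r)
            if (pc[r] > 0) { ++nz; rprev = r; }
          if (nz == 1 && rprev == r0) mergePrev = true;
        }
        if (!mergePrev) clumpCnt.push_back(std::vector<int>(q, 0));
        for (int j = 0; j < s; ++j) clumpCnt.back()[rowOf[ord[i + j]]]++;
        i += s;
      }
    }
    int m = clumpCnt.size();
    int kmax = std::max(2, (int)(cpar * pmax));
    if (m > kmax) {
      // superclumps: equipartition the clump sequence by point mass
      std::vector<std::vector<int> > sc;
      double target = (double)n / kmax;
      int assigned = 0, usedBins = 0, h = 0;
      for (int t = 0; t < m; ++t) {
        int sz = 0;
        for (int r = 0; r < q; ++r) sz += clumpCnt[t][r];
        double t1 = std::fabs((double)h + sz - target);
        double t2 = std::fabs((double)h - target);
        if (h != 0 && usedBins < kmax - 1 && t1 >= t2) {
          ++usedBins;
          h = 0;
          target = (double)(n - assigned) / (kmax - usedBins);
        }
        if (h == 0) sc.push_back(std::vector<int>(q, 0));
        for (int r = 0; r < q; ++r) sc.back()[r] += clumpCnt[t][r];
        h += sz;
        assigned += sz;
      }
      clumpCnt.swap(sc);
      m = clumpCnt.size();
    }
    if (m < 2) continue;

    // prefix counts: cum[r][t] over first t clumps; cnt[t] total points
    std::vector<std::vector<int> > cum(q, std::vector<int>(m + 1, 0));
    std::vector<int> cnt(m + 1, 0);
    for (int t = 1; t <= m; ++t) {
      cnt[t] = cnt[t - 1];
      for (int r = 0; r < q; ++r) {
        cum[r][t] = cum[r][t - 1] + clumpCnt[t - 1][r];
        cnt[t] += clumpCnt[t - 1][r];
      }
    }
    // H(rows | column spanning clumps (s, t]), precomputed for all s < t
    std::vector<double> HC((m + 1) * (m + 1), 0.0);
    for (int s = 0; s < m; ++s) {
      for (int t = s + 1; t <= m; ++t) {
        int np = cnt[t] - cnt[s];
        double hh = 0.0;
        for (int r = 0; r < q; ++r) {
          int d = cum[r][t] - cum[r][s];
          if (d > 0) {
            double p = (double)d / np;
            hh -= p * std::log(p);
          }
        }
        HC[s * (m + 1) + t] = hh;
      }
    }
    auto Hcol = [&](int s, int t) { return HC[s * (m + 1) + t]; };

    int L = std::min(pmax, m);
    // G[t][l] = max over partitions of first t clumps into l columns of
    // -H(rows | columns), probabilities within the first t clumps
    std::vector<std::vector<double> > G(m + 1,
                                        std::vector<double>(L + 1, -1e300));
    for (int t = 1; t <= m; ++t) G[t][1] = -Hcol(0, t);
    for (int l = 2; l <= L; ++l) {
      for (int t = l; t <= m; ++t) {
        double bestv = -1e300;
        for (int s = l - 1; s < t; ++s) {
          double v = ((double)cnt[s] / cnt[t]) * G[s][l - 1] -
                     ((double)(cnt[t] - cnt[s]) / cnt[t]) * Hcol(s, t);
          if (v > bestv) bestv = v;
        }
        G[t][l] = bestv;
      }
    }
    for (int l = 2; l <= L; ++l) {
      double I = HR + G[m][l];
      if (I < 0) I = 0;
      double norm = std::log((double)std::min(l, q));
      if (norm > 0) {
        double v = I / norm;
        if (v > 1.0) v = 1.0;  // floating-point guard
        if (v > best) best = v;
      }
    }
  }
}

// [[Rcpp::export]]
double mic_cpp(NumericVector xr, NumericVector yr, double alpha, double c) {
  int n = xr.size();
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  int B = std::max(4, (int)std::floor(std::pow((double)n, alpha)));
  double best = 0.0;
  optimize_axis(x, y, B, c, best);
  optimize_axis(y, x, B, c, best);
  return best;
}

// Pairwise MIC for the columns of X (symmetric matrix, unit diagonal).
// [[Rcpp::export]]
NumericMatrix mic_matrix_cpp(NumericMatrix X, double alpha, double c) {
  int p = X.ncol();
  NumericMatrix M(p, p);
  for (int i = 0; i < p; ++i) M(i, i) = 1.0;
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double v = mic_cpp(X(_, i), X(_, j), alpha, c);
      M(i, j) = v;
      M(j, i) = v;
    }
  }
  return M;
}
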