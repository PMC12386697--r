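#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Six co-occurrence metrics from a merged, normalized pair list.
// codes are i*ng + j with i, j in [0, ng); w sums to 1.
static void metrics_from_pairs(const std::vector<std::pair<int, double> > &pr,
                               int ng, double *out) {
  std::vector<double> pi(ng, 0.0), pj(ng, 0.0);
  double homog = 0.0, contrast = 0.0, dissim = 0.0, entropy = 0.0, asm2 = 0.0;
  for (size_t k = 0; k < pr.size(); ++k) {
    int i = pr[k].first / ng, j = pr[k].first % ng;
    double g = pr[k].second;
    int d = i - j;
    homog += g / (1.0 + d * d);
    contrast += g * d * d;
    dissim += g * std::abs(d);
    if (g > 0) entropy -= g * std::log(g);
    asm2 += g * g;
    pi[i] += g;
    pj[j] += g;
  }
  double mui = 0.0, muj = 0.0;
  for (int i = 0; i < ng; ++i) { mui += i * pi[i]; muj += i * pj[i]; }
  double vi = 0.0, vj = 0.0;
  for (int i = 0; i < ng; ++i) {
    vi += (i - mui) * (i - mui) * pi[i];
    vj += (i - muj) * (i - muj) * pj[i];
  }
  double corr;
  if (vi <= 1e-12 || vj <= 1e-12) {
    corr = 1.0;  // degenerate (constant window) convention
  } else {
    corr = 0.0;
    for (size_t k = 0; k < pr.size(); ++k) {
      int i = pr[k].first / ng, j = pr[k].first % ng;
      corr += (i - mui) * (j - muj) * pr[k].second;
    }
    corr /= std::sqrt(vi * vj);
  }
  out[0] = homog; out[1] = contrast; out[2] = dissim;
  out[3] = entropy; out[4] = asm2; out[5] = corr;
}

// Sliding-window GLCM texture planes for one quantized band.
// q: integer matrix (values in [0, ng) where valid), valid: logical matrix.
// offsets: k x 2 integer matrix of (dx, dy) = (column, row) displacements.
// Each offset's co-occurrence matrix is normalized separately, then the
// matrices are averaged; metrics are evaluated on the average.
// Pixels whose window leaves the grid or touches an invalid pixel get NA.
// [[Rcpp::export]]
List glcm_planes_cpp(IntegerMatrix q, LogicalMatrix valid, int ng,
                     IntegerMatrix offsets, int window, bool symmetric) {
  int nr = q.nrow(), nc = q.ncol(), h = window / 2, noff = offsets.nrow();
  NumericMatrix homog(nr, nc), contrast(nr, nc), dissim(nr, nc),
      entropy(nr, nc), asm2(nr, nc), corr(nr, nc);
  std::fill(homog.begin(), homog.end(), NA_REAL);
  std::fill(contrast.begin(), contrast.end(), NA_REAL);
  std::fill(dissim.begin(), dissim.end(), NA_REAL);
  std::fill(entropy.begin(), entropy.end(), NA_REAL);
  std::fill(asm2.begin(), asm2.end(), NA_REAL);
  std::fill(corr.begin(), corr.end(), NA_REAL);

  std::vector<std::pair<int, double> > pairs, merged, off_codes;
  double out[6];
  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      bool ok = true;
      for (int i = r - h; i <= r + h && ok; ++i)
        for (int j = c - h; j <= c + h; ++j)
          if (!valid(i, j)) { ok = false; break; }
      if (!ok) continue;
      pairs.clear();
      int used_offsets = 0;
      for (int o = 0; o < noff; ++o) {
        int dx = offsets(o, 0), dy = offsets(o, 1);
        off_codes.clear();
        for (int i = r - h; i <= r + h; ++i) {
          int i2 = i + dy;
          if (i2 < r - h || i2 > r + h) continue;
          for (int j = c - h; j <= c + h; ++j) {
            int j2 = j + dx;
            if (j2 < c - h || j2 > c + h) continue;
            int a = q(i, j), b = q(i2, j2);
            off_codes.push_back(std::make_pair(a * ng + b, 1.0));
            if (symmetric)
              off_codes.push_back(std::make_pair(b * ng + a, 1.0));
          }
        }
        if (off_codes.empty()) continue;
        ++used_offsets;
        double w = 1.0 / off_codes.size();
        for (size_t k = 0; k < off_codes.size(); ++k)
          pairs.push_back(std::make_pair(off_codes[k].first, w));
      }
      if (used_offsets == 0) continue;
      double scale = 1.0 / used_offsets;
      std::sort(pairs.begin(), pairs.end());
      merged.clear();
      for (size_t k = 0; k < pairs.size(); ++k) {
        if (!merged.empty() && merged.back().first == pairs[k].first)
          merged.back().second += pairs[k].second * scale;
        else
          merged.push_back(
              std::make_pair(pairs[k].first, pairs[k].second * scale));
      }
      metrics_from_pairs(merged, ng, out);
      homog(r, c) = out[0]; contrast(r, c) = out[1]; dissim(r, c) = out[2];
      entropy(r, c) = out[3]; asm2(r, c) = out[4]; corr(r, c) = out[5];
    }
  }
  return List::create(
      _["homogeneity"] = homog, _["contrast"] = contrast,
      _["dissimilarity"] = dissim, _["entropy"] = entropy,
      _["second_moment"] = asm2, _["correlation"] = corr);
}
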