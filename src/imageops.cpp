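#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labelling of a binary matrix (8- or 4-connectivity).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (connectivity == 4 && di != 0 && dj != 0) continue;
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Binary dilation (grow = true) or erosion (grow = false) by a disk of
// the given radius in pixels (Euclidean, centre included).
// [[Rcpp::export]]
LogicalMatrix cpp_morph_disk(LogicalMatrix mask, double radius, bool grow) {
  const int H = mask.nrow(), W = mask.ncol();
  const int r = (int)std::floor(radius);
  std::vector<std::pair<int, int> > se;
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      if (di * di + dj * dj <= radius * radius)
        se.push_back(std::make_pair(di, dj));
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      bool hit = false, all = true;
      for (size_t k = 0; k < se.size(); ++k) {
        const int ni = i + se[k].first, nj = j + se[k].second;
        const bool v = (ni >= 0 && ni < H && nj >= 0 && nj < W)
                           ? (bool)mask(ni, nj)
                           : false;
        if (v) hit = true; else all = false;
      }
      out(i, j) = grow ? hit : all;
    }
  }
  return out;
}

// Classical non-local means with a Gaussian-weighted patch distance.
// search and patch are full (odd) window widths; h is the smoothing
// bandwidth applied to the per-pixel mean squared patch difference.
// [[Rcpp::export]]
NumericMatrix cpp_nlm(NumericMatrix img, int search, int patch, double h) {
  const int H = img.nrow(), W = img.ncol();
  const int sr = search / 2, pr = patch / 2;
  NumericMatrix out(H, W);
  // Gaussian patch kernel, sigma = patch radius / 2 (clamped >= 0.5)
  const double sig = std::max(0.5, pr / 2.0);
  std::vector<double> kern((2 * pr + 1) * (2 * pr + 1));
  double ks = 0;
  for (int dj = -pr; dj <= pr; ++dj)
    for (int di = -pr; di <= pr; ++di) {
      const double v = std::exp(-(di * di + dj * dj) / (2 * sig * sig));
      kern[(di + pr) + (2 * pr + 1) * (dj + pr)] = v;
      ks += v;
    }
  for (size_t k = 0; k < kern.size(); ++k) kern[k] /= ks;
  const double h2 = h * h;
  // replicate-pad lookup
  #define PIX(a, b) img(std::min(std::max((a), 0), H - 1), \
                        std::min(std::max((b), 0), W - 1))
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0, wsum = 0, wmax = 0;
      for (int sj = -sr; sj <= sr; ++sj) {
        for (int si = -sr; si <= sr; ++si) {
          if (si == 0 && sj == 0) continue;
          const int ci = i + si, cj = j + sj;
          if (ci < 0 || ci >= H || cj < 0 || cj >= W) continue;
          double d2 = 0;
          for (int dj = -pr; dj <= pr; ++dj)
            for (int di = -pr; di <= pr; ++di) {
              const double diff = PIX(i + di, j + dj) - PIX(ci + di, cj + dj);
              d2 += kern[(di + pr) + (2 * pr + 1) * (dj + pr)] * diff * diff;
            }
          const double w = std::exp(-d2 / h2);
          if (w > wmax) wmax = w;
          acc += w * img(ci, cj);
          wsum += w;
        }
      }
      // centre pixel gets the maximum neighbour weight (standard trick)
      const double wc = wmax > 0 ? wmax : 1.0;
      acc += wc * img(i, j);
      wsum += wc;
      out(i, j) = acc / wsum;
    }
  }
  #undef PIX
  return out;
}
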