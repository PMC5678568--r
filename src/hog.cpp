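#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unsigned gradient orientation histograms, hard binning into [0, pi).
// Gradients are central differences with edge replication; the border
// divisor stays 2 so the descriptor is a pure function of the pixel lattice.
static void pixel_gradients(const NumericMatrix& img, int nbins,
                            std::vector<int>& bin, std::vector<double>& mag) {
  int nr = img.nrow(), nc = img.ncol();
  bin.assign((size_t)nr * nc, 0);
  mag.assign((size_t)nr * nc, 0.0);
  double binw = M_PI / nbins;
  for (int c = 0; c < nc; ++c) {
    int cm = c > 0 ? c - 1 : 0, cp = c < nc - 1 ? c + 1 : nc - 1;
    for (int r = 0; r < nr; ++r) {
      int rm = r > 0 ? r - 1 : 0, rp = r < nr - 1 ? r + 1 : nr - 1;
      double gy = (img(rp, c) - img(rm, c)) / 2.0;
      double gx = (img(r, cp) - img(r, cm)) / 2.0;
      double m = std::sqrt(gx * gx + gy * gy);
      size_t k = (size_t)c * nr + r;
      mag[k] = m;
      if (m > 0) {
        double th = std::atan2(gy, gx);
        if (th < 0) th += M_PI;
        if (th >= M_PI) th -= M_PI;
        int b = (int)(th / binw);
        if (b >= nbins) b = nbins - 1;
        bin[k] = b;
      }
    }
  }
}

// Accumulate cell histograms for a window whose top-left pixel is (r0, c0).
static void window_cells(const std::vector<int>& bin, const std::vector<double>& mag,
                         int nr, int r0, int c0, int wcells, int cell, int nbins,
                         std::vector<double>& hist) {
  hist.assign((size_t)wcells * wcells * nbins, 0.0);
  for (int cy = 0; cy < wcells; ++cy) {
    for (int cx = 0; cx < wcells; ++cx) {
      double* h = &hist[((size_t)cy * wcells + cx) * nbins];
      for (int dc = 0; dc < cell; ++dc) {
        size_t col0 = (size_t)(c0 + cx * cell + dc) * nr + (r0 + cy * cell);
        for (int dr = 0; dr < cell; ++dr) {
          size_t k = col0 + dr;
          h[bin[k]] += mag[k];
        }
      }
    }
  }
}

// Block-normalized descriptor from a window's cell-histogram grid.
// Block layout: blocks row-major, cells within block row-major, then bins.
static void block_descriptor(const std::vector<double>& hist, int wcells,
                             int bcells, int nbins, double eps,
                             std::vector<double>& out) {
  int nb = wcells - bcells + 1;
  out.resize((size_t)nb * nb * bcells * bcells * nbins);
  size_t k = 0;
  for (int by = 0; by < nb; ++by) {
    for (int bx = 0; bx < nb; ++bx) {
      size_t start = k;
      double ss = 0.0;
      for (int i = 0; i < bcells; ++i) {
        for (int j = 0; j < bcells; ++j) {
          const double* h = &hist[((size_t)(by + i) * wcells + (bx + j)) * nbins];
          for (int b = 0; b < nbins; ++b) {
            out[k++] = h[b];
            ss += h[b] * h[b];
          }
        }
      }
      double nrm = std::sqrt(ss + eps * eps);
      for (size_t t = start; t < k; ++t) out[t] /= nrm;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_hog(NumericMatrix patch, int cell, int bcells, int nbins,
                      double eps) {
  std::vector<int> bin;
  std::vector<double> mag, hist, desc;
  pixel_gradients(patch, nbins, bin, mag);
  int wcells = patch.nrow() / cell;
  window_cells(bin, mag, patch.nrow(), 0, 0, wcells, cell, nbins, hist);
  block_descriptor(hist, wcells, bcells, nbins, eps, desc);
  return NumericVector(desc.begin(), desc.end());
}

struct FlatStage {
  std::vector<int> feat;
  std::vector<double> thr, pol, wt;
  double threshold;
};

static void flatten_stages(const List& stages, std::vector<FlatStage>& out) {
  out.clear();
  for (int s = 0; s < stages.size(); ++s) {
    List st = stages[s];
    NumericMatrix L = st["learners"];
    FlatStage f;
    f.threshold = as<double>(st["threshold"]);
    for (int i = 0; i < L.nrow(); ++i) {
      f.feat.push_back((int)L(i, 0) - 1);  // 1-based in the model
      f.thr.push_back(L(i, 1));
      f.pol.push_back(L(i, 2));
      f.wt.push_back(L(i, 3));
    }
    out.push_back(f);
  }
}

// Per-orientation-bin integral images of gradient magnitude, so any cell sum
// is four lookups. Layout: integ[b][(size_t)c * (nr + 1) + r], (nr+1) x (nc+1).
struct HOGField {
  int nr, nc, cell, bcells, nbins, wcells, nblockside;
  double eps;
  std::vector<std::vector<double> > integ;

  void build(const NumericMatrix& img, int cell_, int bcells_, int nbins_,
             int window_px, double eps_) {
    nr = img.nrow(); nc = img.ncol();
    cell = cell_; bcells = bcells_; nbins = nbins_; eps = eps_;
    wcells = window_px / cell;
    nblockside = wcells - bcells + 1;
    std::vector<int> bin;
    std::vector<double> mag;
    pixel_gradients(img, nbins, bin, mag);
    integ.assign(nbins, std::vector<double>((size_t)(nr + 1) * (nc + 1), 0.0));
    std::vector<double> colsum(nbins);
    for (int c = 0; c < nc; ++c) {
      std::fill(colsum.begin(), colsum.end(), 0.0);
      for (int r = 0; r < nr; ++r) {
        size_t k = (size_t)c * nr + r;
        colsum[bin[k]] += mag[k];
        for (int b = 0; b < nbins; ++b)
          integ[b][(size_t)(c + 1) * (nr + 1) + (r + 1)] =
            integ[b][(size_t)c * (nr + 1) + (r + 1)] + colsum[b];
      }
    }
  }

  inline double cellSum(int b, int r0, int c0) const {
    const std::vector<double>& I = integ[b];
    size_t s = nr + 1;
    return I[(size_t)(c0 + cell) * s + (r0 + cell)] -
           I[(size_t)c0 * s + (r0 + cell)] -
           I[(size_t)(c0 + cell) * s + r0] + I[(size_t)c0 * s + r0];
  }

  inline double blockNorm(int wr0, int wc0, int by, int bx) const {
    double ss = 0.0;
    for (int i = 0; i < bcells; ++i)
      for (int j = 0; j < bcells; ++j) {
        int r0 = wr0 + (by + i) * cell, c0 = wc0 + (bx + j) * cell;
        for (int b = 0; b < nbins; ++b) {
          double v = cellSum(b, r0, c0);
          ss += v * v;
        }
      }
    return std::sqrt(ss + eps * eps);
  }

  // Lazily evaluate descriptor component `f` for the window at (wr0, wc0).
  inline double feature(int f, int wr0, int wc0,
                        std::vector<double>& normCache) const {
    int perBlock = bcells * bcells * nbins;
    int bi = f / perBlock, wi = f % perBlock;
    int ci = wi / nbins, b = wi % nbins;
    int by = bi / nblockside, bx = bi % nblockside;
    int cy = by + ci / bcells, cx = bx + ci % bcells;
    if (normCache[bi] < 0) normCache[bi] = blockNorm(wr0, wc0, by, bx);
    return cellSum(b, wr0 + cy * cell, wc0 + cx * cell) / normCache[bi];
  }
};

// Slide the cascade over an image. Returns one row per window:
// (r0, c0, score, accepted, stages_evaluated), coordinates 0-based.
// early_exit = false evaluates every stage regardless of rejection.
// [[Rcpp::export]]
NumericMatrix cpp_scan(NumericMatrix img, int cell, int bcells, int nbins,
                       double eps, int window_px, int stride_px, List stages,
                       bool early_exit) {
  std::vector<FlatStage> fs;
  flatten_stages(stages, fs);
  HOGField F;
  F.build(img, cell, bcells, nbins, window_px, eps);
  int nblocks = F.nblockside * F.nblockside;
  std::vector<double> normCache(nblocks);
  std::vector<std::array<double, 5> > rows;
  for (int r0 = 0; r0 + window_px <= F.nr; r0 += stride_px) {
    for (int c0 = 0; c0 + window_px <= F.nc; c0 += stride_px) {
      std::fill(normCache.begin(), normCache.end(), -1.0);
      double score = 0.0;
      bool ok = true;
      int neval = 0;
      for (size_t s = 0; s < fs.size(); ++s) {
        const FlatStage& st = fs[s];
        double sum = 0.0;
        for (size_t i = 0; i < st.feat.size(); ++i) {
          double v = F.feature(st.feat[i], r0, c0, normCache);
          int h = (st.pol[i] > 0) ? (v >= st.thr[i] ? 1 : -1)
                                  : (v < st.thr[i] ? 1 : -1);
          sum += st.wt[i] * h;
        }
        double m = sum - st.threshold;
        ++neval;
        if (m < 0) {
          ok = false;
          if (early_exit) break;
        } else {
          score += m;
        }
      }
      rows.push_back({(double)r0, (double)c0, score, ok ? 1.0 : 0.0,
                      (double)neval});
    }
  }
  NumericMatrix out(rows.size(), 5);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = rows[i][j];
  colnames(out) = CharacterVector::create("r0", "c0", "score", "accepted",
                                          "stages_evaluated");
  return out;
}
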