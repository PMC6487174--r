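#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Unfold a H x W x C array into a (H*W) x (9*C) matrix of 3x3 neighborhoods
// (zero padding), pixel rows in column-major order so the product with a
// (9*C) x F weight matrix reshapes directly to H x W x F.
// Column order: channel outer, then kernel row, then kernel column.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  const int H = d[0], W = d[1], C = d[2];
  NumericMatrix out(H * W, 9 * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    for (int kr = -1; kr <= 1; ++kr) {
      for (int kc = -1; kc <= 1; ++kc) {
        int col = (c * 3 + (kr + 1)) * 3 + (kc + 1);
        double* po = &out(0, col);
        for (int j = 0; j < W; ++j) {
          int jj = j + kc;
          if (jj < 0 || jj >= W) continue;
          const double* src = plane + (R_xlen_t)jj * H;
          double* dst = po + (R_xlen_t)j * H;
          int i0 = std::max(0, -kr), i1 = std::min(H, H - kr);
          for (int i = i0; i < i1; ++i) dst[i] = src[i + kr];
        }
      }
    }
  }
  return out;
}

// 2x2 max-pool with stride 2 on a H x W x C array (H, W even).
// [[Rcpp::export]]
NumericVector cpp_maxpool2(NumericVector x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  const int H = d[0], W = d[1], C = d[2];
  if (H % 2 || W % 2) stop("spatial dimensions must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    double* oplane = po + (R_xlen_t)c * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = plane + (R_xlen_t)(2 * j) * H;
      const double* c1 = plane + (R_xlen_t)(2 * j + 1) * H;
      double* oc = oplane + (R_xlen_t)j * Ho;
      for (int i = 0; i < Ho; ++i) {
        double m = c0[2 * i];
        if (c0[2 * i + 1] > m) m = c0[2 * i + 1];
        if (c1[2 * i] > m) m = c1[2 * i];
        if (c1[2 * i + 1] > m) m = c1[2 * i + 1];
        oc[i] = m;
      }
    }
  }
  return out;
}

// Per-pixel sliding-window GLCM statistic map. q holds quantized levels in
// [0, levels); the window is centered on each pixel with replicate padding
// at the image border. The cooccurrence matrix is symmetric (both pair
// directions counted) and normalized within each window.
// stat: 0 = contrast, 1 = energy, 2 = homogeneity.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_map(IntegerMatrix q, int levels, int window,
                           int dr, int dc, int stat) {
  const int H = q.nrow(), W = q.ncol();
  if (window % 2 == 0 || window < 3) stop("window must be odd and >= 3");
  if (H < window || W < window) stop("window larger than image");
  if (dr == 0 && dc == 0) stop("offset must be nonzero");
  const int h = window / 2;
  NumericMatrix out(H, W);
  std::vector<double> P((size_t)levels * levels, 0.0);
  std::vector<int> touched;
  touched.reserve(2 * window * window);
  for (int cc = 0; cc < W; ++cc) {
    for (int rr = 0; rr < H; ++rr) {
      touched.clear();
      double total = 0.0;
      for (int wr = -h; wr <= h; ++wr) {
        int pr = wr + dr;
        if (pr < -h || pr > h) continue;
        for (int wc = -h; wc <= h; ++wc) {
          int pc = wc + dc;
          if (pc < -h || pc > h) continue;
          int a = q(clampi(rr + wr, 0, H - 1), clampi(cc + wc, 0, W - 1));
          int b = q(clampi(rr + pr, 0, H - 1), clampi(cc + pc, 0, W - 1));
          int i1 = a * levels + b, i2 = b * levels + a;
          if (P[i1] == 0.0) touched.push_back(i1);
          P[i1] += 1.0;
          if (P[i2] == 0.0) touched.push_back(i2);
          P[i2] += 1.0;
          total += 2.0;
        }
      }
      double s = 0.0;
      for (size_t k = 0; k < touched.size(); ++k) {
        int idx = touched[k];
        double p = P[idx] / total;
        int i = idx / levels, j = idx % levels;
        if (stat == 0) s += p * (double)(i - j) * (i - j);
        else if (stat == 1) s += p * p;
        else s += p / (1.0 + std::abs(i - j));
        P[idx] = 0.0;
      }
      out(rr, cc) = s;
    }
  }
  return out;
}

// Classic 8-neighbor radius-1 LBP code per pixel: bit set when the neighbor
// is >= the center; bits ordered clockwise from the top-left neighbor, most
// significant first; replicate padding at the border.
// [[Rcpp::export]]
IntegerMatrix cpp_lbp(IntegerMatrix g) {
  const int H = g.nrow(), W = g.ncol();
  // clockwise from top-left: NW, N, NE, E, SE, S, SW, W
  const int offr[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  const int offc[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int center = g(r, c);
      int code = 0;
      for (int k = 0; k < 8; ++k) {
        int v = g(clampi(r + offr[k], 0, H - 1), clampi(c + offc[k], 0, W - 1));
        code = (code << 1) | (v >= center ? 1 : 0);
      }
      out(r, c) = code;
    }
  }
  return out;
}
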