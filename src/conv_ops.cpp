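#include <Rcpp.h>
using namespace Rcpp;

// Unfold an (H, W, C) column-major array into the im2col matrix used by the
// convolution layers: rows index output positions (row-fastest), columns
// index (kernel row, kernel col, input channel). Zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int k,
                         int stride, int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  NumericMatrix cols(Ho * Wo, k * k * C);
  const double* px = x.begin();
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (R_xlen_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        double* out = &cols(0, col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jp = dj + stride * jo - pad;
          double* o = out + (R_xlen_t)Ho * jo;
          if (jp < 0 || jp >= W) {
            for (int io = 0; io < Ho; ++io) o[io] = 0.0;
            continue;
          }
          const double* xcj = xc + (R_xlen_t)H * jp;
          for (int io = 0; io < Ho; ++io) {
            const int ip = di + stride * io - pad;
            o[io] = (ip >= 0 && ip < H) ? xcj[ip] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add the column gradients back onto the
// (H, W, C) input gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int H, int W, int C, int k,
                         int stride, int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C);
  double* pdx = dx.begin();
  int col = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = pdx + (R_xlen_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        const double* g = &dcols(0, col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jp = dj + stride * jo - pad;
          if (jp < 0 || jp >= W) continue;
          double* xcj = xc + (R_xlen_t)H * jp;
          const double* gj = g + (R_xlen_t)Ho * jo;
          for (int io = 0; io < Ho; ++io) {
            const int ip = di + stride * io - pad;
            if (ip >= 0 && ip < H) xcj[ip] += gj[io];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// 8-connected component labeling of a logical matrix by flood fill.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int cur = 0;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!m(i0, j0) || lab(i0, j0)) continue;
      ++cur;
      lab(i0, j0) = cur;
      stack.push_back(i0 + H * j0);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int r = pi + di, c = pj + dj;
            if (r < 0 || r >= H || c < 0 || c >= W) continue;
            if (m(r, c) && !lab(r, c)) {
              lab(r, c) = cur;
              stack.push_back(r + H * c);
            }
          }
        }
      }
    }
  }
  return lab;
}
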