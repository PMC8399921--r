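#include <Rcpp.h>
using namespace Rcpp;

// im2col for same-padded 1-D convolution.
// x: (B, W, C) array; returns (B*W, K*C) matrix whose column (c*K + k)
// holds input position t + k - pad - 1 for output position t (zeros
// outside), rows ordered with the batch index fastest.
// [[Rcpp::export(name = ".ff_im2col")]]
NumericMatrix ff_im2col(NumericVector x, int b, int w, int cc, int k) {
  int pad = (k - 1) / 2;
  NumericMatrix out(b * w, k * cc);
  const double* px = x.begin();
  for (int c = 0; c < cc; ++c) {
    for (int kk = 0; kk < k; ++kk) {
      double* pcol = &out(0, c * k + kk);
      int shift = kk - pad;  // input t + shift feeds output t
      int t0 = std::max(0, -shift);
      int t1 = std::min(w, w - shift);
      for (int t = t0; t < t1; ++t) {
        const double* src = px + (size_t)(t + shift) * b + (size_t)c * b * w;
        std::copy(src, src + b, pcol + (size_t)t * b);
      }
    }
  }
  return out;
}

// adjoint of ff_im2col: scatter-add column gradients back onto (B, W, C)
// [[Rcpp::export(name = ".ff_col2im")]]
NumericVector ff_col2im(NumericMatrix dcol, int b, int w, int cc, int k) {
  int pad = (k - 1) / 2;
  NumericVector dx(Dimension(b, w, cc));
  double* pdx = dx.begin();
  for (int c = 0; c < cc; ++c) {
    for (int kk = 0; kk < k; ++kk) {
      const double* pcol = &dcol(0, c * k + kk);
      int shift = kk - pad;
      int t0 = std::max(0, -shift);
      int t1 = std::min(w, w - shift);
      for (int t = t0; t < t1; ++t) {
        double* dst = pdx + (size_t)(t + shift) * b + (size_t)c * b * w;
        const double* src = pcol + (size_t)t * b;
        for (int i = 0; i < b; ++i) dst[i] += src[i];
      }
    }
  }
  return dx;
}

// in-place fused bias add + ReLU on a freshly allocated matmul result
// [[Rcpp::export(name = ".ff_bias_relu")]]
void ff_bias_relu(NumericMatrix m, NumericVector b) {
  int nr = m.nrow(), nc = m.ncol();
  for (int j = 0; j < nc; ++j) {
    double bj = b[j];
    double* col = &m(0, j);
    for (int i = 0; i < nr; ++i) {
      double v = col[i] + bj;
      col[i] = v > 0 ? v : 0;
    }
  }
}

// max-pool (size 2) over time on a (B, W, C) activation stored as a
// (B*W, C) matrix; returns pooled (B*(W/2), C) values and the odd-wins
// mask needed for backprop
// [[Rcpp::export(name = ".ff_maxpool2")]]
List ff_maxpool2(NumericMatrix a, int b, int w, int cc) {
  int w2 = w / 2;
  NumericMatrix pooled(b * w2, cc);
  LogicalMatrix mask(b * w2, cc);
  for (int c = 0; c < cc; ++c) {
    const double* col = &a(0, c);
    double* pc = &pooled(0, c);
    int* mc = &mask(0, c);
    for (int t = 0; t < w2; ++t) {
      const double* o = col + (size_t)(2 * t) * b;
      const double* e = col + (size_t)(2 * t + 1) * b;
      double* po = pc + (size_t)t * b;
      int* pm = mc + (size_t)t * b;
      for (int i = 0; i < b; ++i) {
        bool odd = o[i] >= e[i];
        po[i] = odd ? o[i] : e[i];
        pm[i] = odd;
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["mask"] = mask);
}

// adjoint of ff_maxpool2: route gradients to the winning positions
// [[Rcpp::export(name = ".ff_unpool2")]]
NumericMatrix ff_unpool2(NumericMatrix dpool, LogicalMatrix mask,
                         int b, int w, int cc) {
  int w2 = w / 2;
  NumericMatrix da(b * w, cc);
  for (int c = 0; c < cc; ++c) {
    const double* dp = &dpool(0, c);
    const int* mc = &mask(0, c);
    double* dc = &da(0, c);
    for (int t = 0; t < w2; ++t) {
      const double* src = dp + (size_t)t * b;
      const int* m = mc + (size_t)t * b;
      double* o = dc + (size_t)(2 * t) * b;
      double* e = dc + (size_t)(2 * t + 1) * b;
      for (int i = 0; i < b; ++i) {
        if (m[i]) o[i] = src[i]; else e[i] = src[i];
      }
    }
  }
  return da;
}
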