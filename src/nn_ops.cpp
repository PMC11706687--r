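// Low-level numeric kernels for the segmentation network and augmentation.
//
// Conventions:
//  * images / feature maps are R arrays with dim (H, W, C), column-major;
//  * conv weights are R arrays with dim (k, k, Cin, Cout) so that the
//    column-major flattening (kh, kw, ci) matches the im2col column order;
//  * "same" zero padding with dilation d uses pad = d * (k - 1) / 2;
//  * all kernels are single-threaded and order-stable, so results are
//    bit-exact reproducible run to run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void dims3(const NumericVector& x, int& H, int& W, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  H = d[0]; W = d[1]; C = d[2];
}

// Build the im2col matrix: (H*W) rows, (k*k*Cin) cols.
static arma::mat im2col(const double* x, int H, int W, int Cin, int k, int dil) {
  const int half = (k - 1) / 2;
  arma::mat P(static_cast<size_t>(H) * W, static_cast<size_t>(k) * k * Cin,
              arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* plane = x + static_cast<size_t>(H) * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int q = kh + k * kw + k * k * ci;
        const int dh = dil * (kh - half), dw = dil * (kw - half);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh;
            if (sh < 0 || sh >= H) continue;
            P(h + static_cast<size_t>(H) * w, q) = plane[sh + static_cast<size_t>(H) * sw];
          }
        }
      }
    }
  }
  return P;
}

// Scatter a (H*W) x (k*k*Cin) gradient matrix back onto the input grid.
static void col2im(const arma::mat& G, double* gx, int H, int W, int Cin,
                   int k, int dil) {
  const int half = (k - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double* plane = gx + static_cast<size_t>(H) * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int q = kh + k * kw + k * k * ci;
        const int dh = dil * (kh - half), dw = dil * (kw - half);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh;
            if (sh < 0 || sh >= H) continue;
            plane[sh + static_cast<size_t>(H) * sw] += G(h + static_cast<size_t>(H) * w, q);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b, int dil) {
  int H, W, Cin;
  dims3(x, H, W, Cin);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weight must be a 4-d array");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims incompatible with input");
  arma::mat P = im2col(x.begin(), H, W, Cin, k, dil);
  arma::mat Wm(w.begin(), static_cast<size_t>(k) * k * Cin, Cout, false, true);
  arma::mat Y = P * Wm;
  Y.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int dil) {
  int H, W, Cin;
  dims3(x, H, W, Cin);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  arma::mat P = im2col(x.begin(), H, W, Cin, k, dil);
  arma::mat Wm(w.begin(), static_cast<size_t>(k) * k * Cin, Cout, false, true);
  arma::mat Gy(gy.begin(), static_cast<size_t>(H) * W, Cout, false, true);
  arma::mat Gw = P.t() * Gy;                 // (k*k*Cin) x Cout
  arma::rowvec Gb = arma::sum(Gy, 0);
  arma::mat Gp = Gy * Wm.t();                // (H*W) x (k*k*Cin)
  NumericVector gx(static_cast<size_t>(H) * W * Cin);
  col2im(Gp, gx.begin(), H, W, Cin, k, dil);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector gwv(Gw.begin(), Gw.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(Gb.begin(), Gb.end()));
}

// 2x2 max pooling, stride 2, ceil mode (odd trailing rows/cols kept).
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  int H, W, C;
  dims3(x, H, W, C);
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector y(static_cast<size_t>(Ho) * Wo * C);
  IntegerVector idx(y.size());
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        size_t besti = 0;
        for (int dw = 0; dw < 2; ++dw) {
          const int sw = 2 * wo + dw;
          if (sw >= W) continue;
          for (int dh = 0; dh < 2; ++dh) {
            const int sh = 2 * ho + dh;
            if (sh >= H) continue;
            const size_t i = sh + static_cast<size_t>(H) * sw + static_cast<size_t>(H) * W * c;
            if (px[i] > best) { best = px[i]; besti = i; }
          }
        }
        const size_t o = ho + static_cast<size_t>(Ho) * wo + static_cast<size_t>(Ho) * Wo * c;
        y[o] = best;
        idx[o] = static_cast<int>(besti);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy, int H, int W, int C) {
  NumericVector gx(static_cast<size_t>(H) * W * C);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

struct LinWeights { int lo, hi; double wlo, whi; };

static void lin_coeffs(int n_in, int n_out, std::vector<LinWeights>& cw) {
  cw.resize(n_out);
  const double scale = static_cast<double>(n_in) / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;            // align_corners = FALSE
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int lo = static_cast<int>(std::floor(s));
    int hi = std::min(lo + 1, n_in - 1);
    double f = s - lo;
    cw[i] = {lo, hi, 1.0 - f, f};
  }
}

// [[Rcpp::export(name = ".resize_bilinear_fw")]]
NumericVector resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  int H, W, C;
  dims3(x, H, W, C);
  std::vector<LinWeights> rh, rw;
  lin_coeffs(H, Ho, rh);
  lin_coeffs(W, Wo, rw);
  NumericVector y(static_cast<size_t>(Ho) * Wo * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = px + static_cast<size_t>(H) * W * c;
    double* oplane = y.begin() + static_cast<size_t>(Ho) * Wo * c;
    for (int w = 0; w < Wo; ++w) {
      const LinWeights& cw = rw[w];
      for (int h = 0; h < Ho; ++h) {
        const LinWeights& ch = rh[h];
        const double v =
          ch.wlo * (cw.wlo * plane[ch.lo + static_cast<size_t>(H) * cw.lo] +
                    cw.whi * plane[ch.lo + static_cast<size_t>(H) * cw.hi]) +
          ch.whi * (cw.wlo * plane[ch.hi + static_cast<size_t>(H) * cw.lo] +
                    cw.whi * plane[ch.hi + static_cast<size_t>(H) * cw.hi]);
        oplane[h + static_cast<size_t>(Ho) * w] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export(name = ".resize_bilinear_bw")]]
NumericVector resize_bilinear_bw(NumericVector gy, int H, int W) {
  int Ho, Wo, C;
  dims3(gy, Ho, Wo, C);
  std::vector<LinWeights> rh, rw;
  lin_coeffs(H, Ho, rh);
  lin_coeffs(W, Wo, rw);
  NumericVector gx(static_cast<size_t>(H) * W * C);
  const double* pg = gy.begin();
  for (int c = 0; c < C; ++c) {
    double* plane = gx.begin() + static_cast<size_t>(H) * W * c;
    const double* gplane = pg + static_cast<size_t>(Ho) * Wo * c;
    for (int w = 0; w < Wo; ++w) {
      const LinWeights& cw = rw[w];
      for (int h = 0; h < Ho; ++h) {
        const LinWeights& ch = rh[h];
        const double g = gplane[h + static_cast<size_t>(Ho) * w];
        plane[ch.lo + static_cast<size_t>(H) * cw.lo] += ch.wlo * cw.wlo * g;
        plane[ch.lo + static_cast<size_t>(H) * cw.hi] += ch.wlo * cw.whi * g;
        plane[ch.hi + static_cast<size_t>(H) * cw.lo] += ch.whi * cw.wlo * g;
        plane[ch.hi + static_cast<size_t>(H) * cw.hi] += ch.whi * cw.whi * g;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// Affine warp of a single plane. A is the 2x3 inverse map taking output
// (row, col) to input (row, col), 0-based pixel coordinates.
// interp: 0 = nearest (masks), 1 = bilinear (intensities); fill outside.
// [[Rcpp::export(name = ".warp_affine")]]
NumericMatrix warp_affine(NumericMatrix img, NumericMatrix A, int interp, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const double sh = A(0, 0) * h + A(0, 1) * w + A(0, 2);
      const double sw = A(1, 0) * h + A(1, 1) * w + A(1, 2);
      double v = fill;
      if (interp == 0) {
        const int rh = static_cast<int>(std::lround(sh));
        const int rw = static_cast<int>(std::lround(sw));
        if (rh >= 0 && rh < H && rw >= 0 && rw < W) v = img(rh, rw);
      } else {
        if (sh >= 0 && sh <= H - 1 && sw >= 0 && sw <= W - 1) {
          const int lh = static_cast<int>(std::floor(sh));
          const int lw = static_cast<int>(std::floor(sw));
          const int hh = std::min(lh + 1, H - 1), hw = std::min(lw + 1, W - 1);
          const double fh = sh - lh, fw = sw - lw;
          v = (1 - fh) * ((1 - fw) * img(lh, lw) + fw * img(lh, hw)) +
              fh * ((1 - fw) * img(hh, lw) + fw * img(hh, hw));
        }
      }
      out(h, w) = v;
    }
  }
  return out;
}
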