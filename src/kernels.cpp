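// Numerical kernels: direct im2col + GEMM convolutions (forward and the
// gradients needed for training), 2x2x2 max pooling, and separable image
// resampling. Layouts follow R column-major arrays:
//   2D activations (H, W, C); 2D kernels (kh, kw, Cin, Cout)
//   3D activations (X, Y, Z, C); 3D kernels (k, k, k, Cin, Cout)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col2d(const double *x, int H, int W, int Cin,
                     int kh, int kw, int stride, int pad,
                     int Ho, int Wo, arma::mat &cols) {
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int c = ki + kh * (kj + kw * ci);
        double *dst = cols.colptr(c);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kj;
          bool win = iw >= 0 && iw < W;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + ki;
            double v = 0.0;
            if (win && ih >= 0 && ih < H) v = x[ih + (size_t)H * (iw + (size_t)W * ci)];
            dst[oh + (size_t)Ho * ow] = v;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch: input has %d, kernel expects %d", Cin, (int)wd[2]);
  int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input %dx%d too small for this layer", H, W);
  arma::mat cols(Ho * Wo, kh * kw * Cin);
  im2col2d(x.begin(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, cols);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat out = cols * Wm;
  out.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  arma::mat cols(Ho * Wo, kh * kw * Cin);
  im2col2d(x.begin(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, cols);
  arma::mat G(gout.begin(), Ho * Wo, Cout, false, true);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat gW = cols.t() * G;
  arma::rowvec gB = arma::sum(G, 0);
  arma::mat gcols = G * Wm.t();
  NumericVector gx(x.size());
  double *gxp = gx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int c = ki + kh * (kj + kw * ci);
        double *src = gcols.colptr(c);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kj;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + ki;
            if (ih < 0 || ih >= H) continue;
            gxp[ih + (size_t)H * (iw + (size_t)W * ci)] += src[oh + (size_t)Ho * ow];
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = wd;
  NumericVector gb(gB.begin(), gB.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static void im2col3d(const double *x, int X, int Y, int Z, int Cin,
                     int k, int stride, int pad,
                     int Xo, int Yo, int Zo, arma::mat &cols) {
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kl = 0; kl < k; ++kl) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int c = ki + k * (kj + k * (kl + k * ci));
          double *dst = cols.colptr(c);
          for (int oz = 0; oz < Zo; ++oz) {
            int iz = oz * stride - pad + kl;
            bool zin = iz >= 0 && iz < Z;
            for (int oy = 0; oy < Yo; ++oy) {
              int iy = oy * stride - pad + kj;
              bool yin = iy >= 0 && iy < Y;
              for (int ox = 0; ox < Xo; ++ox) {
                int ix = ox * stride - pad + ki;
                double v = 0.0;
                if (zin && yin && ix >= 0 && ix < X)
                  v = x[ix + (size_t)X * (iy + (size_t)Y * (iz + (size_t)Z * ci))];
                dst[ox + (size_t)Xo * (oy + (size_t)Yo * oz)] = v;
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("channel mismatch: input has %d, kernel expects %d", Cin, (int)wd[3]);
  int Xo = out_len(X, k, stride, pad), Yo = out_len(Y, k, stride, pad), Zo = out_len(Z, k, stride, pad);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("input %dx%dx%d too small for this layer", X, Y, Z);
  arma::mat cols((size_t)Xo * Yo * Zo, (size_t)k * k * k * Cin);
  im2col3d(x.begin(), X, Y, Z, Cin, k, stride, pad, Xo, Yo, Zo, cols);
  arma::mat Wm(w.begin(), k * k * k * Cin, Cout, false, true);
  arma::mat out = cols * Wm;
  out.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector gout,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[4];
  int Xo = gd[0], Yo = gd[1], Zo = gd[2];
  arma::mat cols((size_t)Xo * Yo * Zo, (size_t)k * k * k * Cin);
  im2col3d(x.begin(), X, Y, Z, Cin, k, stride, pad, Xo, Yo, Zo, cols);
  arma::mat G(gout.begin(), (size_t)Xo * Yo * Zo, Cout, false, true);
  arma::mat Wm(w.begin(), k * k * k * Cin, Cout, false, true);
  arma::mat gW = cols.t() * G;
  arma::rowvec gB = arma::sum(G, 0);
  arma::mat gcols = G * Wm.t();
  NumericVector gx(x.size());
  double *gxp = gx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kl = 0; kl < k; ++kl) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int c = ki + k * (kj + k * (kl + k * ci));
          double *src = gcols.colptr(c);
          for (int oz = 0; oz < Zo; ++oz) {
            int iz = oz * stride - pad + kl;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < Yo; ++oy) {
              int iy = oy * stride - pad + kj;
              if (iy < 0 || iy >= Y) continue;
              for (int ox = 0; ox < Xo; ++ox) {
                int ix = ox * stride - pad + ki;
                if (ix < 0 || ix >= X) continue;
                gxp[ix + (size_t)X * (iy + (size_t)Y * (iz + (size_t)Z * ci))] +=
                  src[ox + (size_t)Xo * (oy + (size_t)Yo * oz)];
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = wd;
  NumericVector gb(gB.begin(), gB.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool3dForward")]]
List maxpool3d_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out((size_t)Xo * Yo * Zo * C);
  IntegerVector idx(out.size());
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int oz = 0; oz < Zo; ++oz) {
      for (int oy = 0; oy < Yo; ++oy) {
        for (int ox = 0; ox < Xo; ++ox) {
          double best = -1e300; size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t i = (2 * ox + dx) + (size_t)X * ((2 * oy + dy) +
                           (size_t)Y * ((2 * oz + dz) + (size_t)Z * c));
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          size_t o = ox + (size_t)Xo * (oy + (size_t)Yo * (oz + (size_t)Zo * c));
          out[o] = best;
          idx[o] = (int)besti;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3dBackward")]]
NumericVector maxpool3d_backward(NumericVector gout, IntegerVector idx, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i]] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Keys cubic convolution kernel, a = -0.5 (the classical bicubic kernel).
static inline double keys(double s) {
  const double a = -0.5;
  s = std::fabs(s);
  if (s <= 1.0) return (a + 2.0) * s * s * s - (a + 3.0) * s * s + 1.0;
  if (s < 2.0)  return a * s * s * s - 5.0 * a * s * s + 8.0 * a * s - 4.0 * a;
  return 0.0;
}

// Resample along the first axis of a (n, m) column-major block:
// output row i samples input coordinate i * ratio, edges clamped.
static void resample_axis_cubic(const double *x, int n, size_t m, int nout,
                                double ratio, double *out) {
  std::vector<int> base(nout);
  std::vector<double> wt(4 * (size_t)nout);
  for (int i = 0; i < nout; ++i) {
    double u = i * ratio;
    int f = (int)std::floor(u);
    double fr = u - f;
    base[i] = f;
    for (int t = 0; t < 4; ++t) wt[4 * (size_t)i + t] = keys(fr - (t - 1));
  }
  for (size_t j = 0; j < m; ++j) {
    const double *col = x + (size_t)n * j;
    double *oc = out + (size_t)nout * j;
    for (int i = 0; i < nout; ++i) {
      double acc = 0.0;
      for (int t = 0; t < 4; ++t) {
        int p = base[i] + t - 1;
        if (p < 0) p = 0; else if (p >= n) p = n - 1;
        acc += wt[4 * (size_t)i + t] * col[p];
      }
      oc[i] = acc;
    }
  }
}

// Separable cubic resampling of a 3D array; ratio[k] = in-spacing step per
// output voxel along axis k (output coord i maps to input coord i*ratio).
// [[Rcpp::export(name = ".resample3dCubic")]]
NumericVector resample3d_cubic(NumericVector x, IntegerVector nout, NumericVector ratio) {
  IntegerVector xd = x.attr("dim");
  int n1 = xd[0], n2 = xd[1], n3 = xd[2];
  int m1 = nout[0], m2 = nout[1], m3 = nout[2];
  // axis 1
  std::vector<double> t1((size_t)m1 * n2 * n3);
  resample_axis_cubic(x.begin(), n1, (size_t)n2 * n3, m1, ratio[0], t1.data());
  // axis 2: permute (m1, n2, n3) -> (n2, n3, m1), resample, permute back later
  std::vector<double> p1((size_t)n2 * n3 * m1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < m1; ++i)
        p1[j + (size_t)n2 * (k + (size_t)n3 * i)] = t1[i + (size_t)m1 * (j + (size_t)n2 * k)];
  std::vector<double> t2((size_t)m2 * n3 * m1);
  resample_axis_cubic(p1.data(), n2, (size_t)n3 * m1, m2, ratio[1], t2.data());
  // axis 3: permute (m2, n3, m1) -> (n3, m1, m2)
  std::vector<double> p2((size_t)n3 * m1 * m2);
  for (int i = 0; i < m1; ++i)
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < m2; ++j)
        p2[k + (size_t)n3 * (i + (size_t)m1 * j)] = t2[j + (size_t)m2 * (k + (size_t)n3 * i)];
  std::vector<double> t3((size_t)m3 * m1 * m2);
  resample_axis_cubic(p2.data(), n3, (size_t)m1 * m2, m3, ratio[2], t3.data());
  // (m3, m1, m2) -> (m1, m2, m3)
  NumericVector out((size_t)m1 * m2 * m3);
  for (int j = 0; j < m2; ++j)
    for (int i = 0; i < m1; ++i)
      for (int k = 0; k < m3; ++k)
        out[i + (size_t)m1 * (j + (size_t)m2 * k)] = t3[k + (size_t)m3 * (i + (size_t)m1 * j)];
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  return out;
}

// [[Rcpp::export(name = ".resample3dNearest")]]
NumericVector resample3d_nearest(NumericVector x, IntegerVector nout, NumericVector ratio) {
  IntegerVector xd = x.attr("dim");
  int n1 = xd[0], n2 = xd[1], n3 = xd[2];
  int m1 = nout[0], m2 = nout[1], m3 = nout[2];
  NumericVector out((size_t)m1 * m2 * m3);
  std::vector<int> i1(m1), i2(m2), i3(m3);
  for (int i = 0; i < m1; ++i) i1[i] = std::min(n1 - 1, std::max(0, (int)std::lround(i * ratio[0])));
  for (int i = 0; i < m2; ++i) i2[i] = std::min(n2 - 1, std::max(0, (int)std::lround(i * ratio[1])));
  for (int i = 0; i < m3; ++i) i3[i] = std::min(n3 - 1, std::max(0, (int)std::lround(i * ratio[2])));
  for (int k = 0; k < m3; ++k)
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i)
        out[i + (size_t)m1 * (j + (size_t)m2 * k)] =
          x[i1[i] + (size_t)n1 * (i2[j] + (size_t)n2 * i3[k])];
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  return out;
}
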