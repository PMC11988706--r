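// Dense numeric kernels for the network core and image geometry.
// Tensors are R arrays in column-major order with dim (H, W, C, N).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

static void same_pad(int in, int k, int stride, int dil, int &out, int &pad0) {
  out = (in + stride - 1) / stride;
  int eff = (k - 1) * dil + 1;
  int total = (out - 1) * stride + eff - in;
  if (total < 0) total = 0;
  pad0 = total / 2;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, int stride, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho, Wo, ph, pw;
  same_pad(H, kh, stride, dil, Ho, ph);
  same_pad(W, kw, stride, dil, Wo, pw);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *X = x.begin(), *K = w.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < C; ++ci)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            double kv = K[i + kh * (j + kw * (ci + C * co))];
            if (kv == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pw + j * dil;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = X + idx4(0, wi, ci, n, H, W, C);
              double *ycol = Y + wo * Ho + Ho * Wo * (co + Cout * n);
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - ph + i * dil;
                if (hi < 0 || hi >= H) continue;
                ycol[ho] += kv * xcol[hi];
              }
            }
          }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho, Wo, ph, pw;
  same_pad(H, kh, stride, dil, Ho, ph);
  same_pad(W, kw, stride, dil, Wo, pw);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  const double *X = x.begin(), *K = w.begin(), *G = gy.begin();
  double *DX = dx.begin(), *DW = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < C; ++ci)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            int kidx = i + kh * (j + kw * (ci + C * co));
            double kv = K[kidx], acc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pw + j * dil;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = X + idx4(0, wi, ci, n, H, W, C);
              double *dxcol = DX + idx4(0, wi, ci, n, H, W, C);
              const double *gcol = G + wo * Ho + Ho * Wo * (co + Cout * n);
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - ph + i * dil;
                if (hi < 0 || hi >= H) continue;
                double g = gcol[ho];
                acc += xcol[hi] * g;
                dxcol[hi] += kv * g;
              }
            }
            DW[kidx] += acc;
          }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Depthwise convolution: one kh x kw kernel per channel, w has dim (kh, kw, C).
// [[Rcpp::export(name = ".dwconv2d_fwd")]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w, int stride, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho, Wo, ph, pw;
  same_pad(H, kh, stride, dil, Ho, ph);
  same_pad(W, kw, stride, dil, Wo, pw);
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *X = x.begin(), *K = w.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          double kv = K[i + kh * (j + kw * c)];
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pw + j * dil;
            if (wi < 0 || wi >= W) continue;
            const double *xcol = X + idx4(0, wi, c, n, H, W, C);
            double *ycol = Y + wo * Ho + Ho * Wo * (c + C * n);
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - ph + i * dil;
              if (hi < 0 || hi >= H) continue;
              ycol[ho] += kv * xcol[hi];
            }
          }
        }
  return y;
}

// [[Rcpp::export(name = ".dwconv2d_bwd")]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho, Wo, ph, pw;
  same_pad(H, kh, stride, dil, Ho, ph);
  same_pad(W, kw, stride, dil, Wo, pw);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  const double *X = x.begin(), *K = w.begin(), *G = gy.begin();
  double *DX = dx.begin(), *DW = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          int kidx = i + kh * (j + kw * c);
          double kv = K[kidx], acc = 0.0;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pw + j * dil;
            if (wi < 0 || wi >= W) continue;
            const double *xcol = X + idx4(0, wi, c, n, H, W, C);
            double *dxcol = DX + idx4(0, wi, c, n, H, W, C);
            const double *gcol = G + wo * Ho + Ho * Wo * (c + C * n);
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - ph + i * dil;
              if (hi < 0 || hi >= H) continue;
              double g = gcol[ho];
              acc += xcol[hi] * g;
              dxcol[hi] += kv * g;
            }
          }
          DW[kidx] += acc;
        }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 stride-2 transposed convolution, w has dim (2, 2, Cin, Cout).
// [[Rcpp::export(name = ".tconv2d_fwd")]]
NumericVector tconv2d_fwd(NumericVector x, NumericVector w) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *X = x.begin(), *K = w.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < C; ++ci)
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            double kv = K[i + 2 * (j + 2 * (ci + C * co))];
            for (int wi = 0; wi < W; ++wi) {
              const double *xcol = X + idx4(0, wi, ci, n, H, W, C);
              double *ycol = Y + idx4(i, 2 * wi + j, co, n, Ho, Wo, Cout);
              for (int hi = 0; hi < H; ++hi) ycol[2 * hi] += kv * xcol[hi];
            }
          }
  return y;
}

// [[Rcpp::export(name = ".tconv2d_bwd")]]
List tconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  const double *X = x.begin(), *K = w.begin(), *G = gy.begin();
  double *DX = dx.begin(), *DW = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < C; ++ci)
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            int kidx = i + 2 * (j + 2 * (ci + C * co));
            double kv = K[kidx], acc = 0.0;
            for (int wi = 0; wi < W; ++wi) {
              const double *xcol = X + idx4(0, wi, ci, n, H, W, C);
              double *dxcol = DX + idx4(0, wi, ci, n, H, W, C);
              const double *gcol = G + idx4(i, 2 * wi + j, co, n, Ho, Wo, Cout);
              for (int hi = 0; hi < H; ++hi) {
                double g = gcol[2 * hi];
                acc += xcol[hi] * g;
                dxcol[hi] += kv * g;
              }
            }
            DW[kidx] += acc;
          }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *X = x.begin();
  double *Y = y.begin();
  int *A = arg.begin();
  int o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          int best = idx4(2 * ho, 2 * wo, c, n, H, W, C);
          double bv = X[best];
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              int id = idx4(2 * ho + i, 2 * wo + j, c, n, H, W, C);
              if (X[id] > bv) { bv = X[id]; best = id; }
            }
          Y[o] = bv; A[o] = best;
        }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector arg, NumericVector gy, IntegerVector xdim) {
  int sz = xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(sz);
  dx.attr("dim") = xdim;
  for (int o = 0; o < gy.size(); ++o) dx[arg[o]] += gy[o];
  return dx;
}

// [[Rcpp::export(name = ".avgpool2_fwd")]]
NumericVector avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *X = x.begin();
  double *Y = y.begin();
  int o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          double s = 0.0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i)
              s += X[idx4(2 * ho + i, 2 * wo + j, c, n, H, W, C)];
          Y[o] = 0.25 * s;
        }
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
NumericVector avgpool2_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx(H * W * C * N);
  dx.attr("dim") = xdim;
  double *DX = dx.begin();
  const double *G = gy.begin();
  int o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          double g = 0.25 * G[o];
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i)
              DX[idx4(2 * ho + i, 2 * wo + j, c, n, H, W, C)] += g;
        }
  return dx;
}

// [[Rcpp::export(name = ".upnear2_fwd")]]
NumericVector upnear2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *X = x.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          Y[idx4(ho, wo, c, n, Ho, Wo, C)] =
            X[idx4(ho / 2, wo / 2, c, n, H, W, C)];
  return y;
}

// [[Rcpp::export(name = ".upnear2_bwd")]]
NumericVector upnear2_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * C * N);
  dx.attr("dim") = xdim;
  double *DX = dx.begin();
  const double *G = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          DX[idx4(ho / 2, wo / 2, c, n, H, W, C)] +=
            G[idx4(ho, wo, c, n, Ho, Wo, C)];
  return dx;
}

// 2x bilinear upsampling with half-pixel centres (align_corners = FALSE).
static void up2_coef(int o, int in, int &i0, int &i1, double &t) {
  double s = (o + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < in ? i0 + 1 : i0;
  t = s - i0;
}

// [[Rcpp::export(name = ".upbilin2_fwd")]]
NumericVector upbilin2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *X = x.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo) {
        int w0, w1; double tw;
        up2_coef(wo, W, w0, w1, tw);
        for (int ho = 0; ho < Ho; ++ho) {
          int h0, h1; double th;
          up2_coef(ho, H, h0, h1, th);
          double v =
            (1 - th) * (1 - tw) * X[idx4(h0, w0, c, n, H, W, C)] +
            (1 - th) * tw       * X[idx4(h0, w1, c, n, H, W, C)] +
            th       * (1 - tw) * X[idx4(h1, w0, c, n, H, W, C)] +
            th       * tw       * X[idx4(h1, w1, c, n, H, W, C)];
          Y[idx4(ho, wo, c, n, Ho, Wo, C)] = v;
        }
      }
  return y;
}

// [[Rcpp::export(name = ".upbilin2_bwd")]]
NumericVector upbilin2_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * C * N);
  dx.attr("dim") = xdim;
  double *DX = dx.begin();
  const double *G = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo) {
        int w0, w1; double tw;
        up2_coef(wo, W, w0, w1, tw);
        for (int ho = 0; ho < Ho; ++ho) {
          int h0, h1; double th;
          up2_coef(ho, H, h0, h1, th);
          double g = G[idx4(ho, wo, c, n, Ho, Wo, C)];
          DX[idx4(h0, w0, c, n, H, W, C)] += (1 - th) * (1 - tw) * g;
          DX[idx4(h0, w1, c, n, H, W, C)] += (1 - th) * tw * g;
          DX[idx4(h1, w0, c, n, H, W, C)] += th * (1 - tw) * g;
          DX[idx4(h1, w1, c, n, H, W, C)] += th * tw * g;
        }
      }
  return dx;
}

// Bilinear resize of a single 2-D image, half-pixel centres, edge clamp.
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix x, int oh, int ow) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(oh, ow);
  for (int c = 0; c < ow; ++c) {
    double sc = (c + 0.5) * W / (double)ow - 0.5;
    if (sc < 0) sc = 0;
    if (sc > W - 1) sc = W - 1;
    int c0 = (int)std::floor(sc);
    int c1 = c0 + 1 < W ? c0 + 1 : c0;
    double tc = sc - c0;
    for (int r = 0; r < oh; ++r) {
      double sr = (r + 0.5) * H / (double)oh - 0.5;
      if (sr < 0) sr = 0;
      if (sr > H - 1) sr = H - 1;
      int r0 = (int)std::floor(sr);
      int r1 = r0 + 1 < H ? r0 + 1 : r0;
      double tr = sr - r0;
      y(r, c) = (1 - tr) * (1 - tc) * x(r0, c0) + (1 - tr) * tc * x(r0, c1) +
                tr * (1 - tc) * x(r1, c0) + tr * tc * x(r1, c1);
    }
  }
  return y;
}

// Rotation about the image centre ((H-1)/2, (W-1)/2), counter-clockwise for
// positive angles as displayed; zero fill outside the support.
// interp: 0 nearest-neighbour, 1 bilinear. sin/cos are passed in so that the
// caller can use exact values at multiples of 90 degrees.
// [[Rcpp::export(name = ".warp_rotate")]]
NumericMatrix warp_rotate(NumericMatrix x, double cs, double sn, int interp) {
  int H = x.nrow(), W = x.ncol();
  double rc = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  NumericMatrix y(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double dr = r - rc, dc = c - cc;
      double sr = rc + dr * cs + dc * sn;
      double sc = cc - dr * sn + dc * cs;
      if (interp == 0) {
        int ir = (int)std::lround(sr), ic = (int)std::lround(sc);
        y(r, c) = (ir >= 0 && ir < H && ic >= 0 && ic < W) ? x(ir, ic) : 0.0;
      } else {
        if (sr < -1 || sr > H || sc < -1 || sc > W) { y(r, c) = 0.0; continue; }
        int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        double tr = sr - r0, tc = sc - c0;
        double v = 0.0;
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            int rr = r0 + i, ccx = c0 + j;
            if (rr < 0 || rr >= H || ccx < 0 || ccx >= W) continue;
            v += (i ? tr : 1 - tr) * (j ? tc : 1 - tc) * x(rr, ccx);
          }
        y(r, c) = v;
      }
    }
  return y;
}
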