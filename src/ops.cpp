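// Dense tensor kernels for the detector: im2col convolution, modulated
// deformable convolution with full gradients (input, weights, offsets,
// modulation), bilinear resize and max-pooling. Layout conventions:
//   feature map : R array dim c(H, W, C), column-major
//   weights     : R array dim c(kh, kw, Cin, Cout)
//   offsets     : dim c(Ho, Wo, 2*K*K), channel 2n = dy, 2n+1 = dx,
//                 kernel point n = ky + K*kx (column-major over the grid)
//   modulation  : dim c(Ho, Wo, K*K)
// Samples falling outside the padded map contribute zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2col_into(const double* x, int H, int W, int C,
                        int kh, int kw, int s, int p, int Ho, int Wo,
                        arma::mat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        arma::uword col = ky + kh * kx + (arma::uword)kh * kw * c;
        for (int ox = 0; ox < Wo; ++ox) {
          int ix = ox * s - p + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            int iy = oy * s - p + ky;
            if (iy < 0 || iy >= H) continue;
            M(oy + (arma::uword)Ho * ox, col) = xc[iy + (size_t)H * ix];
          }
        }
      }
    }
  }
}

static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int s, int p, int Ho, int Wo) {
  arma::mat M(Ho * (arma::uword)Wo, kh * (arma::uword)kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        arma::uword col = ky + kh * kx + (arma::uword)kh * kw * c;
        for (int ox = 0; ox < Wo; ++ox) {
          int ix = ox * s - p + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            int iy = oy * s - p + ky;
            if (iy < 0 || iy >= H) continue;
            M(oy + (arma::uword)Ho * ox, col) = xc[iy + (size_t)H * ix];
          }
        }
      }
    }
  }
  return M;
}

static void col2im_acc(const arma::mat& M, double* gx, int H, int W, int C,
                       int kh, int kw, int s, int p, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        arma::uword col = ky + kh * kx + (arma::uword)kh * kw * c;
        for (int ox = 0; ox < Wo; ++ox) {
          int ix = ox * s - p + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            int iy = oy * s - p + ky;
            if (iy < 0 || iy >= H) continue;
            gc[iy + (size_t)H * ix] += M(oy + (arma::uword)Ho * ox, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  arma::mat M = im2col(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * Cin, Cout, false);
  arma::mat Y = M * Wm;
  if (bias.size() == (R_xlen_t)Cout) Y.each_row() += arma::rowvec(bias.begin(), Cout, false);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// forward keeping the im2col workspace for the backward pass
// [[Rcpp::export]]
List cpp_conv2d_ws(NumericVector x, NumericVector w, NumericVector bias,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  NumericMatrix Mr(Ho * Wo, kh * kw * C);
  arma::mat M(Mr.begin(), Mr.nrow(), Mr.ncol(), false);
  im2col_into(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo, M);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * Cin, Cout, false);
  NumericVector out((R_xlen_t)Ho * Wo * Cout);
  arma::mat Y(out.begin(), (arma::uword)Ho * Wo, Cout, false);
  Y = M * Wm;
  if (bias.size() == (R_xlen_t)Cout) Y.each_row() += arma::rowvec(bias.begin(), Cout, false);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return List::create(_["value"] = out, _["ws"] = Mr);
}

// group norm forward: returns y, xhat, sd per group
// [[Rcpp::export]]
List cpp_group_norm(NumericVector x, NumericVector gamma, NumericVector beta,
                    int groups, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int cg = C / groups;
  size_t np = (size_t)H * W, n_per = np * cg;
  NumericVector y(x.size()), xhat(x.size()), sds(groups);
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  for (int g = 0; g < groups; ++g) {
    const double* xg = x.begin() + n_per * g;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < n_per; ++i) { s += xg[i]; s2 += xg[i] * xg[i]; }
    double mu = s / n_per;
    double sd = std::sqrt(s2 / n_per - mu * mu + eps);
    sds[g] = sd;
    double* xh = xhat.begin() + n_per * g;
    double* yo = y.begin() + n_per * g;
    for (int cc = 0; cc < cg; ++cc) {
      int c = g * cg + cc;
      double ga = gamma[c], be = beta[c];
      for (size_t i = 0; i < np; ++i) {
        double v = (xg[cc * np + i] - mu) / sd;
        xh[cc * np + i] = v;
        yo[cc * np + i] = v * ga + be;
      }
    }
  }
  return List::create(_["value"] = y, _["xhat"] = xhat, _["sd"] = sds);
}

// [[Rcpp::export]]
List cpp_group_norm_backward(NumericVector xhat, NumericVector sds,
                             NumericVector gamma, NumericVector gout,
                             int groups) {
  IntegerVector xd = xhat.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int cg = C / groups;
  size_t np = (size_t)H * W, n_per = np * cg;
  NumericVector dx(xhat.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int g = 0; g < groups; ++g) {
    const double* xh = xhat.begin() + n_per * g;
    const double* go = gout.begin() + n_per * g;
    double s1 = 0, s2 = 0;
    for (int cc = 0; cc < cg; ++cc) {
      int c = g * cg + cc;
      double ga = gamma[c], dg = 0, db = 0;
      for (size_t i = 0; i < np; ++i) {
        double gr = go[cc * np + i];
        double v = xh[cc * np + i];
        dg += gr * v; db += gr;
        s1 += gr * ga; s2 += gr * ga * v;
      }
      dgamma[c] = dg; dbeta[c] = db;
    }
    s1 /= n_per; s2 /= n_per;
    double sd = sds[g];
    double* dxo = dx.begin() + n_per * g;
    for (int cc = 0; cc < cg; ++cc) {
      int c = g * cg + cc;
      double ga = gamma[c];
      for (size_t i = 0; i < np; ++i)
        dxo[cc * np + i] =
          (go[cc * np + i] * ga - s1 - xh[cc * np + i] * s2) / sd;
    }
  }
  return List::create(_["gx"] = dx, _["ggamma"] = dgamma, _["gbeta"] = dbeta);
}

// backward reusing the stored workspace
// [[Rcpp::export]]
List cpp_conv2d_backward_ws(NumericMatrix ws, IntegerVector xd, NumericVector w,
                            NumericVector gout, int stride, int pad,
                            bool has_bias, bool need_gx) {
  IntegerVector wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  arma::mat M(ws.begin(), ws.nrow(), ws.ncol(), false);
  arma::mat Gm(const_cast<double*>(gout.begin()), (arma::uword)Ho * Wo, Cout, false);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * Cin, Cout, false);
  arma::mat gW = M.t() * Gm;
  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = wd;
  List res = List::create(_["gw"] = gw);
  if (need_gx) {
    arma::mat gM = Gm * Wm.t();
    NumericVector gx((R_xlen_t)H * W * C);
    gx.attr("dim") = xd;
    col2im_acc(gM, gx.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
    res["gx"] = gx;
  }
  if (has_bias) {
    arma::rowvec gb = arma::sum(Gm, 0);
    res["gb"] = NumericVector(gb.begin(), gb.end());
  }
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  arma::mat M = im2col(x.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  arma::mat Gm(const_cast<double*>(gout.begin()), (arma::uword)Ho * Wo, Cout, false);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * Cin, Cout, false);
  arma::mat gW = M.t() * Gm;
  arma::mat gM = Gm * Wm.t();
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  col2im_acc(gM, gx.begin(), H, W, C, kh, kw, stride, pad, Ho, Wo);
  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = wd;
  List res = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) {
    arma::rowvec gb = arma::sum(Gm, 0);
    res["gb"] = NumericVector(gb.begin(), gb.end());
  }
  return res;
}

struct BilinSample {
  double v;            // sampled value
  double dy, dx;       // d value / d position
};

static inline BilinSample bilinear(const double* xc, int H, int W, double py, double px) {
  BilinSample s = {0.0, 0.0, 0.0};
  if (py <= -1.0 || py >= (double)H || px <= -1.0 || px >= (double)W) return s;
  int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  double ly = py - y0, lx = px - x0;
  double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
  bool y0i = y0 >= 0 && y0 < H, y1i = y0 + 1 >= 0 && y0 + 1 < H;
  bool x0i = x0 >= 0 && x0 < W, x1i = x0 + 1 >= 0 && x0 + 1 < W;
  if (y0i && x0i) v00 = xc[y0 + (size_t)H * x0];
  if (y1i && x0i) v10 = xc[y0 + 1 + (size_t)H * x0];
  if (y0i && x1i) v01 = xc[y0 + (size_t)H * (x0 + 1)];
  if (y1i && x1i) v11 = xc[y0 + 1 + (size_t)H * (x0 + 1)];
  s.v  = (1 - ly) * (1 - lx) * v00 + ly * (1 - lx) * v10 + (1 - ly) * lx * v01 + ly * lx * v11;
  s.dy = (1 - lx) * (v10 - v00) + lx * (v11 - v01);
  s.dx = (1 - ly) * (v01 - v00) + ly * (v11 - v10);
  return s;
}

static inline void bilinear_scatter(double* gc, int H, int W, double py, double px, double g) {
  if (py <= -1.0 || py >= (double)H || px <= -1.0 || px >= (double)W) return;
  int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  double ly = py - y0, lx = px - x0;
  bool y0i = y0 >= 0 && y0 < H, y1i = y0 + 1 >= 0 && y0 + 1 < H;
  bool x0i = x0 >= 0 && x0 < W, x1i = x0 + 1 >= 0 && x0 + 1 < W;
  if (y0i && x0i) gc[y0 + (size_t)H * x0] += (1 - ly) * (1 - lx) * g;
  if (y1i && x0i) gc[y0 + 1 + (size_t)H * x0] += ly * (1 - lx) * g;
  if (y0i && x1i) gc[y0 + (size_t)H * (x0 + 1)] += (1 - ly) * lx * g;
  if (y1i && x1i) gc[y0 + 1 + (size_t)H * (x0 + 1)] += ly * lx * g;
}

// corner indices and weights of one bilinear sample, with validity flags
struct BilinSetup {
  bool any;
  int i00, i10, i01, i11;     // offsets into an H*W plane (-1 = invalid)
  double w00, w10, w01, w11;
  double ly, lx;
};

static inline BilinSetup bilin_setup(int H, int W, double py, double px) {
  BilinSetup b;
  b.any = !(py <= -1.0 || py >= (double)H || px <= -1.0 || px >= (double)W);
  b.i00 = b.i10 = b.i01 = b.i11 = -1;
  if (!b.any) return b;
  int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  double ly = py - y0, lx = px - x0;
  bool y0i = y0 >= 0 && y0 < H, y1i = y0 + 1 >= 0 && y0 + 1 < H;
  bool x0i = x0 >= 0 && x0 < W, x1i = x0 + 1 >= 0 && x0 + 1 < W;
  if (y0i && x0i) b.i00 = y0 + H * x0;
  if (y1i && x0i) b.i10 = y0 + 1 + H * x0;
  if (y0i && x1i) b.i01 = y0 + H * (x0 + 1);
  if (y1i && x1i) b.i11 = y0 + 1 + H * (x0 + 1);
  b.w00 = (1 - ly) * (1 - lx); b.w10 = ly * (1 - lx);
  b.w01 = (1 - ly) * lx;       b.w11 = ly * lx;
  b.ly = ly; b.lx = lx;
  return b;
}

// Build the deformed-sample matrix (unmodulated), rows = output locations,
// cols = kernel point n + K*K*c.
static arma::mat deform_samples(const double* x, int H, int W, int C, int K,
                                int s, int p, int Ho, int Wo,
                                const double* off, const double* mod,
                                bool apply_mod) {
  int KK = K * K;
  size_t plane = (size_t)H * W;
  arma::mat D((arma::uword)Ho * Wo, (arma::uword)KK * C);
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      arma::uword row = oy + (arma::uword)Ho * ox;
      size_t loc = oy + (size_t)Ho * ox;
      for (int n = 0; n < KK; ++n) {
        int ky = n % K, kx = n / K;
        double dy = off[loc + (size_t)Ho * Wo * (2 * n)];
        double dx = off[loc + (size_t)Ho * Wo * (2 * n + 1)];
        double py = oy * s - p + ky + dy;
        double px = ox * s - p + kx + dx;
        double m = apply_mod ? mod[loc + (size_t)Ho * Wo * n] : 1.0;
        BilinSetup b = bilin_setup(H, W, py, px);
        double* drow = D.memptr() + row;  // column stride = n_rows
        arma::uword nr = D.n_rows;
        if (!b.any || m == 0.0) {
          for (int c = 0; c < C; ++c) drow[(n + (arma::uword)KK * c) * nr] = 0.0;
          continue;
        }
        for (int c = 0; c < C; ++c) {
          const double* xc = x + plane * c;
          double v = 0;
          if (b.i00 >= 0) v += b.w00 * xc[b.i00];
          if (b.i10 >= 0) v += b.w10 * xc[b.i10];
          if (b.i01 >= 0) v += b.w01 * xc[b.i01];
          if (b.i11 >= 0) v += b.w11 * xc[b.i11];
          drow[(n + (arma::uword)KK * c) * nr] = v * m;
        }
      }
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericVector cpp_deform_conv(NumericVector x, NumericVector w, NumericVector bias,
                              NumericVector offsets, NumericVector modulation,
                              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != K) stop("deform_conv: kernel must be square");
  if (Cin != C) stop("deform_conv: channel mismatch");
  int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  IntegerVector od = offsets.attr("dim");
  if (od[0] != Ho || od[1] != Wo || od[2] != 2 * K * K)
    stop("deform_conv: offsets must be %d x %d x %d", Ho, Wo, 2 * K * K);
  arma::mat D = deform_samples(x.begin(), H, W, C, K, stride, pad, Ho, Wo,
                               offsets.begin(), modulation.begin(), true);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)K * K * Cin, Cout, false);
  arma::mat Y = D * Wm;
  if (bias.size() == (R_xlen_t)Cout) Y.each_row() += arma::rowvec(bias.begin(), Cout, false);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_deform_conv_backward(NumericVector x, NumericVector w,
                              NumericVector offsets, NumericVector modulation,
                              NumericVector gout, int stride, int pad,
                              bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  int KK = K * K;
  // modulated samples for the weight gradient
  arma::mat D = deform_samples(x.begin(), H, W, C, K, stride, pad, Ho, Wo,
                               offsets.begin(), modulation.begin(), true);
  arma::mat Gm(const_cast<double*>(gout.begin()), (arma::uword)Ho * Wo, Cout, false);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)K * K * Cin, Cout, false);
  arma::mat gW = D.t() * Gm;
  arma::mat gD = Gm * Wm.t();  // gradient w.r.t. modulated samples

  NumericVector gx(x.size());          gx.attr("dim") = xd;
  NumericVector goff(offsets.size());  goff.attr("dim") = offsets.attr("dim");
  NumericVector gmod(modulation.size()); gmod.attr("dim") = modulation.attr("dim");
  const double* off = offsets.begin();
  const double* mod = modulation.begin();

  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      arma::uword row = oy + (arma::uword)Ho * ox;
      size_t loc = oy + (size_t)Ho * ox;
      for (int n = 0; n < KK; ++n) {
        int ky = n % K, kx = n / K;
        double dy = off[loc + (size_t)Ho * Wo * (2 * n)];
        double dx = off[loc + (size_t)Ho * Wo * (2 * n + 1)];
        double py = oy * stride - pad + ky + dy;
        double px = ox * stride - pad + kx + dx;
        double m = mod[loc + (size_t)Ho * Wo * n];
        double gpy = 0, gpx = 0, gm = 0;
        BilinSetup bs = bilin_setup(H, W, py, px);
        if (!bs.any) continue;
        size_t plane = (size_t)H * W;
        for (int c = 0; c < C; ++c) {
          double g = gD(row, n + (arma::uword)KK * c);  // d loss / d (v*m)
          const double* xc = x.begin() + plane * c;
          double v00 = bs.i00 >= 0 ? xc[bs.i00] : 0.0;
          double v10 = bs.i10 >= 0 ? xc[bs.i10] : 0.0;
          double v01 = bs.i01 >= 0 ? xc[bs.i01] : 0.0;
          double v11 = bs.i11 >= 0 ? xc[bs.i11] : 0.0;
          double v = bs.w00 * v00 + bs.w10 * v10 + bs.w01 * v01 + bs.w11 * v11;
          gm  += g * v;
          gpy += g * m * ((1 - bs.lx) * (v10 - v00) + bs.lx * (v11 - v01));
          gpx += g * m * ((1 - bs.ly) * (v01 - v00) + bs.ly * (v11 - v10));
          double gmv = g * m;
          double* gc = gx.begin() + plane * c;
          if (bs.i00 >= 0) gc[bs.i00] += bs.w00 * gmv;
          if (bs.i10 >= 0) gc[bs.i10] += bs.w10 * gmv;
          if (bs.i01 >= 0) gc[bs.i01] += bs.w01 * gmv;
          if (bs.i11 >= 0) gc[bs.i11] += bs.w11 * gmv;
        }
        gmod[loc + (size_t)Ho * Wo * n] += gm;
        goff[loc + (size_t)Ho * Wo * (2 * n)]     += gpy;
        goff[loc + (size_t)Ho * Wo * (2 * n + 1)] += gpx;
      }
    }
  }
  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = wd;
  List res = List::create(_["gx"] = gx, _["gw"] = gw,
                          _["goff"] = goff, _["gmod"] = gmod);
  if (has_bias) {
    arma::rowvec gb = arma::sum(Gm, 0);
    res["gb"] = NumericVector(gb.begin(), gb.end());
  }
  return res;
}

// Bilinear resize (align_corners = FALSE; half-pixel centers).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  double sy = (double)H / Ho, sx = (double)W / Wo;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)H * W * c;
    double* oc = out.begin() + (size_t)Ho * Wo * c;
    for (int ox = 0; ox < Wo; ++ox) {
      double px = std::min(std::max((ox + 0.5) * sx - 0.5, 0.0), (double)(W - 1));
      for (int oy = 0; oy < Ho; ++oy) {
        double py = std::min(std::max((oy + 0.5) * sy - 0.5, 0.0), (double)(H - 1));
        BilinSample sm = bilinear(xc, H, W, py, px);
        oc[oy + (size_t)Ho * ox] = sm.v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector gout, int H, int W) {
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2];
  double sy = (double)H / Ho, sx = (double)W / Wo;
  NumericVector gx((R_xlen_t)H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c) {
    double* gc = gx.begin() + (size_t)H * W * c;
    const double* oc = gout.begin() + (size_t)Ho * Wo * c;
    for (int ox = 0; ox < Wo; ++ox) {
      double px = std::min(std::max((ox + 0.5) * sx - 0.5, 0.0), (double)(W - 1));
      for (int oy = 0; oy < Ho; ++oy) {
        double py = std::min(std::max((oy + 0.5) * sy - 0.5, 0.0), (double)(H - 1));
        bilinear_scatter(gc, H, W, py, px, oc[oy + (size_t)Ho * ox]);
      }
    }
  }
  return gx;
}

// in-place SGD step with momentum and weight decay:
//   v <- mom*v + g + wd*value;  value <- value - lr*v
// The caller owns both buffers exclusively.
// [[Rcpp::export]]
void cpp_sgd_update(NumericVector value, NumericVector grad,
                    NumericVector velocity, double lr, double momentum,
                    double weight_decay) {
  R_xlen_t n = value.size();
  double* v = velocity.begin();
  double* w = value.begin();
  const double* g = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    v[i] = momentum * v[i] + (g[i] + weight_decay * w[i]);
    w[i] -= lr * v[i];
  }
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector out((R_xlen_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector arg((R_xlen_t)Ho * Wo * C);  // 0-based index into the H*W plane
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)H * W * c;
    double* oc = out.begin() + (size_t)Ho * Wo * c;
    int* ac = arg.begin() + (size_t)Ho * Wo * c;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        double best = R_NegInf; int bi = -1;
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            double v = xc[iy + (size_t)H * ix];
            if (v > best) { best = v; bi = iy + H * ix; }
          }
        }
        oc[oy + (size_t)Ho * ox] = (bi >= 0) ? best : 0.0;
        ac[oy + (size_t)Ho * ox] = bi;
      }
    }
  }
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gout, IntegerVector argmax,
                                   int H, int W) {
  IntegerVector gd = gout.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2];
  NumericVector gx((R_xlen_t)H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c) {
    double* gc = gx.begin() + (size_t)H * W * c;
    const double* oc = gout.begin() + (size_t)Ho * Wo * c;
    const int* ac = argmax.begin() + (size_t)Ho * Wo * c;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
      if (ac[i] >= 0) gc[ac[i]] += oc[i];
  }
  return gx;
}
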