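// Minimal convolutional primitives for the GAN: batched 2-D convolution and
// transposed convolution implemented as im2col/col2im plus GEMM.
//
// Array layout follows R's column-major convention throughout:
//   activations  (H, W, C, N)   h fastest
//   conv weights (KH*KW*Cin) x F matrix, row index kh + KH*(kw + KW*c)
//   deconv weights (KH*KW*F) x Cin matrix (F = output channels)
// Patch matrices ("cols") are (OH*OW) x (KH*KW*C) so that forward passes are
// a single cols * W product per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col_one(const double* x, int H, int W, int C,
                       int KH, int KW, int S, int PT, int PL,
                       int OH, int OW, mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        double* col = cols.colptr(kh + KH * (kw + KW * c));
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * S - PL + kw;
          if (iw < 0 || iw >= W) continue;
          const double* xcol = xc + (std::size_t)H * iw;
          double* dst = col + (std::size_t)OH * ow;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * S - PT + kh;
            if (ih >= 0 && ih < H) dst[oh] = xcol[ih];
          }
        }
      }
    }
  }
}

// scatter-add adjoint of im2col_one
static void col2im_one(const mat& cols, double* gx, int H, int W, int C,
                       int KH, int KW, int S, int PT, int PL,
                       int OH, int OW) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (std::size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const double* col = cols.colptr(kh + KH * (kw + KW * c));
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * S - PL + kw;
          if (iw < 0 || iw >= W) continue;
          double* xcol = xc + (std::size_t)H * iw;
          const double* src = col + (std::size_t)OH * ow;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * S - PT + kh;
            if (ih >= 0 && ih < H) xcol[ih] += src[oh];
          }
        }
      }
    }
  }
}

static Rcpp::IntegerVector arr_dim(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-d (H,W,C,N) array");
  return d;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
Rcpp::NumericVector conv2d_fwd_cpp(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                                   Rcpp::NumericVector b, int kh, int kw,
                                   int stride, int pt, int pb, int pl, int pr) {
  Rcpp::IntegerVector d = arr_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.ncol();
  if (w.nrow() != kh * kw * C) Rcpp::stop("weight rows != kh*kw*C");
  const int OH = (H + pt + pb - kh) / stride + 1;
  const int OW = (W + pl + pr - kw) / stride + 1;
  if (OH < 1 || OW < 1) Rcpp::stop("non-positive output size");

  mat Wm(w.begin(), w.nrow(), F, false);
  rowvec bv(b.begin(), F);
  Rcpp::NumericVector y(Rcpp::no_init((std::size_t)OH * OW * F * N));
  y.attr("dim") = Rcpp::IntegerVector::create(OH, OW, F, N);

  mat cols(OH * OW, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (std::size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, OH, OW, cols);
    mat out = cols * Wm;           // (OH*OW) x F
    out.each_row() += bv;
    std::copy(out.begin(), out.end(), y.begin() + (std::size_t)OH * OW * F * n);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd_cpp(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                          Rcpp::NumericVector dy, int kh, int kw,
                          int stride, int pt, int pb, int pl, int pr) {
  Rcpp::IntegerVector d = arr_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  Rcpp::IntegerVector dd = arr_dim(dy);
  const int OH = dd[0], OW = dd[1], F = dd[2];
  if (dd[3] != N) Rcpp::stop("batch mismatch");

  mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  mat dW(kh * kw * C, F, fill::zeros);
  rowvec db(F, fill::zeros);
  Rcpp::NumericVector dx((std::size_t)H * W * C * N);  // zero-initialised
  dx.attr("dim") = d;

  mat cols(OH * OW, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (std::size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, OH, OW, cols);
    mat dY(dy.begin() + (std::size_t)OH * OW * F * n, OH * OW, F, false);
    dW += cols.t() * dY;
    db += sum(dY, 0);
    mat dcols = dY * Wm.t();       // (OH*OW) x (kh*kw*C)
    col2im_one(dcols, dx.begin() + (std::size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, OH, OW);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = Rcpp::wrap(dW),
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}

// Transposed convolution: output v (OH,OW,F,N) from input u (h,w,Cin,N),
// where a forward convolution with the same geometry maps v -> u.
// [[Rcpp::export(name = ".deconv2d_fwd")]]
Rcpp::NumericVector deconv2d_fwd_cpp(Rcpp::NumericVector u, Rcpp::NumericMatrix w,
                                     Rcpp::NumericVector b, int kh, int kw,
                                     int stride, int pt, int pb, int pl, int pr,
                                     int OH, int OW) {
  Rcpp::IntegerVector d = arr_dim(u);
  const int h = d[0], wd = d[1], C = d[2], N = d[3];
  const int F = w.nrow() / (kh * kw);
  if (w.nrow() != kh * kw * F) Rcpp::stop("deconv weight rows != kh*kw*F");
  if (w.ncol() != C) Rcpp::stop("deconv weight cols != Cin");
  if ((OH + pt + pb - kh) / stride + 1 != h || (OW + pl + pr - kw) / stride + 1 != wd)
    Rcpp::stop("deconv geometry inconsistent");

  mat Wm(w.begin(), w.nrow(), C, false);
  Rcpp::NumericVector v((std::size_t)OH * OW * F * N);  // zero-initialised
  v.attr("dim") = Rcpp::IntegerVector::create(OH, OW, F, N);

  for (int n = 0; n < N; ++n) {
    mat U(u.begin() + (std::size_t)h * wd * C * n, h * wd, C, false);
    mat cols = U * Wm.t();         // (h*w) x (kh*kw*F)
    double* vn = v.begin() + (std::size_t)OH * OW * F * n;
    col2im_one(cols, vn, OH, OW, F, kh, kw, stride, pt, pl, h, wd);
    for (int f = 0; f < F; ++f) {
      double* vf = vn + (std::size_t)OH * OW * f;
      const double bf = b[f];
      for (int i = 0; i < OH * OW; ++i) vf[i] += bf;
    }
  }
  return v;
}

// [[Rcpp::export(name = ".deconv2d_bwd")]]
Rcpp::List deconv2d_bwd_cpp(Rcpp::NumericVector u, Rcpp::NumericMatrix w,
                            Rcpp::NumericVector dv, int kh, int kw,
                            int stride, int pt, int pb, int pl, int pr) {
  Rcpp::IntegerVector d = arr_dim(u);
  const int h = d[0], wd = d[1], C = d[2], N = d[3];
  Rcpp::IntegerVector dd = arr_dim(dv);
  const int OH = dd[0], OW = dd[1], F = dd[2];
  if (dd[3] != N) Rcpp::stop("batch mismatch");

  mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  mat dW(kh * kw * F, C, fill::zeros);
  rowvec db(F, fill::zeros);
  Rcpp::NumericVector du(Rcpp::no_init((std::size_t)h * wd * C * N));
  du.attr("dim") = d;

  mat cols(h * wd, kh * kw * F);
  for (int n = 0; n < N; ++n) {
    const double* dvn = dv.begin() + (std::size_t)OH * OW * F * n;
    im2col_one(dvn, OH, OW, F, kh, kw, stride, pt, pl, h, wd, cols);
    mat U(u.begin() + (std::size_t)h * wd * C * n, h * wd, C, false);
    dW += cols.t() * U;
    mat dU = cols * Wm;            // (h*w) x Cin
    std::copy(dU.begin(), dU.end(), du.begin() + (std::size_t)h * wd * C * n);
    for (int f = 0; f < F; ++f) {
      const double* dvf = dvn + (std::size_t)OH * OW * f;
      for (int i = 0; i < OH * OW; ++i) db[f] += dvf[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("du") = du,
                            Rcpp::Named("dw") = Rcpp::wrap(dW),
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
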