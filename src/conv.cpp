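// Convolution, batch normalization, ReLU and pooling kernels for the
// network engine.
//
// Activations are (X, Y, Z, C, N) arrays in R's column-major layout; 2D
// layers reuse the 3D code with Z = 1 and kz = 1. Convolutions are "same"
// with zero padding; weights are (kx*ky*kz*Cin) x Cout matrices whose row
// order matches the column-major flattening of an R array
// dim c(kx,ky,kz,Cin). The im2col buffers and GEMMs run in single
// precision (BLAS sgemm) for speed; parameters and gradients stay double
// on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
#include <cstring>

using namespace Rcpp;

namespace {

void toFloat(const double *src, float *dst, long n) {
  for (long i = 0; i < n; ++i) dst[i] = (float)src[i];
}

void toDouble(const float *src, double *dst, long n) {
  for (long i = 0; i < n; ++i) dst[i] = (double)src[i];
}

// Build the im2col matrix for one sample: rows = X*Y*Z voxels (column-major
// order), cols = kx*ky*kz*Cin. Zero padding outside the grid.
void im2col(const float *x, int X, int Y, int Z, int C,
            int kx, int ky, int kz, arma::fmat &col) {
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  const long nvox = (long)X * Y * Z;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const float *xc = x + (long)c * nvox;
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          const int q = dx + kx * (dy + ky * (dz + kz * c));
          float *dst = col.colptr(q);
          const int sx = dx - ox, sy = dy - oy, sz = dz - oz;
          for (int z = 0; z < Z; ++z) {
            const int zz = z + sz;
            if (zz < 0 || zz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int yy = y + sy;
              if (yy < 0 || yy >= Y) continue;
              const int x0 = std::max(0, -sx), x1 = std::min(X, X - sx);
              const float *src = xc + (long)X * (yy + (long)Y * zz) + sx;
              float *d = dst + (long)X * (y + (long)Y * z);
              for (int xi = x0; xi < x1; ++xi) d[xi] = src[xi];
            }
          }
        }
  }
}

// Scatter-add transpose of im2col (grad wrt conv input).
void col2im(const arma::fmat &col, int X, int Y, int Z, int C,
            int kx, int ky, int kz, float *x) {
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  const long nvox = (long)X * Y * Z;
  std::fill(x, x + nvox * C, 0.0f);
  for (int c = 0; c < C; ++c) {
    float *xc = x + (long)c * nvox;
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          const int q = dx + kx * (dy + ky * (dz + kz * c));
          const float *src0 = col.colptr(q);
          const int sx = dx - ox, sy = dy - oy, sz = dz - oz;
          for (int z = 0; z < Z; ++z) {
            const int zz = z + sz;
            if (zz < 0 || zz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int yy = y + sy;
              if (yy < 0 || yy >= Y) continue;
              const int x0 = std::max(0, -sx), x1 = std::min(X, X - sx);
              float *dst = xc + (long)X * (yy + (long)Y * zz) + sx;
              const float *s = src0 + (long)X * (y + (long)Y * z);
              for (int xi = x0; xi < x1; ++xi) dst[xi] += s[xi];
            }
          }
        }
  }
}

} // namespace

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, IntegerVector dims,
                       NumericMatrix W, NumericVector bias,
                       IntegerVector kdim) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int K = kx * ky * kz * C, Cout = W.ncol();
  if (W.nrow() != K) stop("weight rows do not match kernel*Cin");
  const long nvox = (long)X * Y * Z;
  NumericVector out(nvox * Cout * N);
  arma::fmat Wf(K, Cout);
  toFloat(W.begin(), Wf.memptr(), (long)K * Cout);
  arma::frowvec b(Cout);
  toFloat(bias.begin(), b.memptr(), Cout);
  arma::fmat col(nvox, K);
  arma::fvec xf(nvox * C);
  for (int n = 0; n < N; ++n) {
    toFloat(x.begin() + (long)n * nvox * C, xf.memptr(), nvox * C);
    im2col(xf.memptr(), X, Y, Z, C, kx, ky, kz, col);
    arma::fmat o = col * Wf;
    o.each_row() += b;
    toDouble(o.memptr(), out.begin() + (long)n * nvox * Cout,
             (long)nvox * Cout);
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout, N);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, IntegerVector dims, NumericMatrix W,
              IntegerVector kdim, NumericVector gout, bool needGx = true) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int K = kx * ky * kz * C, Cout = W.ncol();
  const long nvox = (long)X * Y * Z;
  NumericVector gx(needGx ? nvox * C * N : 0);
  arma::fmat Wf(K, Cout);
  toFloat(W.begin(), Wf.memptr(), (long)K * Cout);
  arma::fmat gW(K, Cout, arma::fill::zeros);
  arma::frowvec gb(Cout, arma::fill::zeros);
  arma::fmat col(nvox, K);
  arma::fvec xf(nvox * C), gof(nvox * Cout), gxf(needGx ? nvox * C : 0);
  for (int n = 0; n < N; ++n) {
    toFloat(x.begin() + (long)n * nvox * C, xf.memptr(), nvox * C);
    toFloat(gout.begin() + (long)n * nvox * Cout, gof.memptr(),
            nvox * Cout);
    arma::fmat gon(gof.memptr(), nvox, Cout, false);
    im2col(xf.memptr(), X, Y, Z, C, kx, ky, kz, col);
    gW += col.t() * gon;
    gb += arma::sum(gon, 0);
    if (needGx) {
      arma::fmat gcol = gon * Wf.t();
      col2im(gcol, X, Y, Z, C, kx, ky, kz, gxf.memptr());
      toDouble(gxf.memptr(), gx.begin() + (long)n * nvox * C, nvox * C);
    }
  }
  if (needGx) gx.attr("dim") = IntegerVector::create(X, Y, Z, C, N);
  NumericMatrix gWd(K, Cout);
  toDouble(gW.memptr(), gWd.begin(), (long)K * Cout);
  NumericVector gbd(Cout);
  toDouble(gb.memptr(), gbd.begin(), Cout);
  return List::create(_["gx"] = gx, _["gW"] = gWd, _["gb"] = gbd);
}

// Batch normalization over (X,Y,Z,N) per channel.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, IntegerVector dims, NumericVector gamma,
            NumericVector beta, NumericVector rmean, NumericVector rvar,
            bool training, double momentum, double eps) {
  const long nvox = (long)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector out(x.size());
  NumericVector mu(C), var(C), nrmean = clone(rmean), nrvar = clone(rvar);
  const long m = nvox * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    if (training) {
      for (int n = 0; n < N; ++n) {
        const double *p = x.begin() + nvox * (c + (long)C * n);
        for (long i = 0; i < nvox; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
      nrmean[c] = momentum * rmean[c] + (1 - momentum) * mu[c];
      nrvar[c] = momentum * rvar[c] + (1 - momentum) * var[c];
    } else {
      mu[c] = rmean[c];
      var[c] = rvar[c];
    }
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd;
    const double b = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + nvox * (c + (long)C * n);
      double *o = out.begin() + nvox * (c + (long)C * n);
      for (long i = 0; i < nvox; ++i) o[i] = a * p[i] + b;
    }
  }
  out.attr("dim") = dims;
  return List::create(_["out"] = out, _["mu"] = mu, _["var"] = var,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, IntegerVector dims, NumericVector gamma,
            NumericVector mu, NumericVector var, double eps,
            NumericVector gout) {
  const long nvox = (long)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  const long m = nvox * N;
  NumericVector gx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + nvox * (c + (long)C * n);
      const double *g = gout.begin() + nvox * (c + (long)C * n);
      for (long i = 0; i < nvox; ++i) {
        s1 += g[i];
        s2 += g[i] * (p[i] - mu[c]) * invstd;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double k1 = gamma[c] * invstd;
    const double k2 = s1 / m;
    const double k3 = s2 / m;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + nvox * (c + (long)C * n);
      const double *g = gout.begin() + nvox * (c + (long)C * n);
      double *o = gx.begin() + nvox * (c + (long)C * n);
      for (long i = 0; i < nvox; ++i) {
        const double xh = (p[i] - mu[c]) * invstd;
        o[i] = k1 * (g[i] - k2 - xh * k3);
      }
    }
  }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  for (long i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector out, NumericVector gout) {
  NumericVector gx(gout.size());
  for (long i = 0; i < gout.size(); ++i) gx[i] = out[i] > 0 ? gout[i] : 0.0;
  gx.attr("dim") = gout.attr("dim");
  return gx;
}

// Max pooling by an integer factor per spatial axis; records argmax for the
// backward pass. Factors must divide the corresponding dimension.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, IntegerVector dims, IntegerVector factor) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  if (X % fx || Y % fy || Z % fz) stop("pool factor must divide dims");
  const int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  const long nin = (long)X * Y * Z, nout = (long)Xo * Yo * Zo;
  NumericVector out(nout * C * N);
  NumericVector amax(nout * C * N); // linear index into full input vector
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long obase = nout * (c + (long)C * n);
      const long ibase = nin * (c + (long)C * n);
      for (int zo = 0; zo < Zo; ++zo)
        for (int yo = 0; yo < Yo; ++yo)
          for (int xo = 0; xo < Xo; ++xo) {
            double best = -std::numeric_limits<double>::infinity();
            long bidx = -1;
            for (int dz = 0; dz < fz; ++dz)
              for (int dy = 0; dy < fy; ++dy)
                for (int dx = 0; dx < fx; ++dx) {
                  const long ii = ibase + (long)(xo * fx + dx) +
                    (long)X * ((yo * fy + dy) + (long)Y * (zo * fz + dz));
                  const double v = x[ii];
                  if (v > best) { best = v; bidx = ii; }
                }
            const long oi = obase + xo + (long)Xo * (yo + (long)Yo * zo);
            out[oi] = best;
            amax[oi] = (double)bidx;
          }
    }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector gout, NumericVector amax,
                          IntegerVector indims) {
  long nin = 1;
  for (int i = 0; i < indims.size(); ++i) nin *= indims[i];
  NumericVector gx(nin);
  for (long i = 0; i < gout.size(); ++i) gx[(long)amax[i]] += gout[i];
  gx.attr("dim") = indims;
  return gx;
}

// Nearest-neighbour upsampling by factor 2 per spatial axis (decoder path).
// [[Rcpp::export(name = ".upsample_fwd")]]
NumericVector upsample_fwd(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((long)Xo * Yo * Zo * C * N);
  const long nin = (long)X * Y * Z, nout = (long)Xo * Yo * Zo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *src = x.begin() + nin * (c + (long)C * n);
      double *dst = out.begin() + nout * (c + (long)C * n);
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          const double *s = src + (long)X * ((y / 2) + (long)Y * (z / 2));
          double *d = dst + (long)Xo * (y + (long)Yo * z);
          for (int xi = 0; xi < Xo; ++xi) d[xi] = s[xi / 2];
        }
    }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, N);
  return out;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
NumericVector upsample_bwd(NumericVector gout, IntegerVector indims) {
  const int X = indims[0], Y = indims[1], Z = indims[2], C = indims[3],
    N = indims[4];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector gx((long)X * Y * Z * C * N);
  const long nin = (long)X * Y * Z, nout = (long)Xo * Yo * Zo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dst = gx.begin() + nin * (c + (long)C * n);
      const double *src = gout.begin() + nout * (c + (long)C * n);
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          double *d = dst + (long)X * ((y / 2) + (long)Y * (z / 2));
          const double *s = src + (long)Xo * (y + (long)Yo * z);
          for (int xi = 0; xi < Xo; ++xi) d[xi / 2] += s[xi];
        }
    }
  gx.attr("dim") = indims;
  return gx;
}
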