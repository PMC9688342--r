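// Cubic B-spline (order 3) and nearest-neighbour resampling under an
// affine voxel map, following the recursive-prefilter formulation of
// spline interpolation with mirror boundary conditions.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double POLE = -0.2679491924311227; // sqrt(3) - 2

double initial_causal(const double *s, int n, long stride, double z) {
  const int horizon = (int)std::ceil(std::log(1e-12) /
                                     std::log(std::fabs(z)));
  if (horizon < n) {
    double zn = z, sum = s[0];
    for (int i = 1; i < horizon; ++i) {
      sum += zn * s[(long)i * stride];
      zn *= z;
    }
    return sum;
  }
  // exact closed form under the mirror (reflect) extension
  double zn = z, z2n = std::pow(z, n - 1), iz = 1.0 / z;
  double sum = s[0] + z2n * s[(long)(n - 1) * stride];
  z2n *= z2n * iz;
  for (int i = 1; i <= n - 2; ++i) {
    sum += (zn + z2n) * s[(long)i * stride];
    zn *= z;
    z2n *= iz;
  }
  return sum / (1.0 - std::pow(z, 2 * n - 2));
}

void filter_line(double *s, int n, long stride, double z) {
  if (n < 2) return;
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) s[(long)i * stride] *= lambda;
  s[0] = initial_causal(s, n, stride, z);
  for (int i = 1; i < n; ++i)
    s[(long)i * stride] += z * s[(long)(i - 1) * stride];
  s[(long)(n - 1) * stride] =
    (z / (z * z - 1.0)) *
    (z * s[(long)(n - 2) * stride] + s[(long)(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    s[(long)i * stride] = z * (s[(long)(i + 1) * stride] - s[(long)i * stride]);
}

inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

inline void bspline_w(double f, double w[4]) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;
  w[2] = (1.0 + 3.0 * f + 3.0 * f2 - 3.0 * f3) / 6.0;
  w[3] = f3 / 6.0;
}

} // namespace

// In-place separable prefilter turning samples into B-spline coefficients.
// [[Rcpp::export(name = ".bspline_prefilter")]]
NumericVector bspline_prefilter(NumericVector data, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  NumericVector out = clone(data);
  double *p = out.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      filter_line(p + (long)X * (y + (long)Y * z), X, 1, POLE);
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x)
      filter_line(p + x + (long)X * (long)Y * z, Y, X, POLE);
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x)
      filter_line(p + x + (long)X * y, Z, (long)X * Y, POLE);
  out.attr("dim") = dims;
  return out;
}

// Sample `data` at source coordinates A %*% (i,j,k) + b for every output
// voxel (0-based indices). order = 3 expects prefiltered coefficients;
// order = 0 is nearest neighbour. Out-of-grid coordinates clamp to the edge.
// [[Rcpp::export(name = ".affine_sample")]]
NumericVector affine_sample(NumericVector data, IntegerVector dims,
                            NumericMatrix A, NumericVector b,
                            IntegerVector outdims, int order) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = outdims[0], Yo = outdims[1], Zo = outdims[2];
  NumericVector out((long)Xo * Yo * Zo);
  const double *p = data.begin();
  long o = 0;
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i, ++o) {
        const double sx = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + b[0];
        const double sy = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + b[1];
        const double sz = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + b[2];
        if (order == 0) {
          const int xi = clampi((int)std::lround(sx), X);
          const int yi = clampi((int)std::lround(sy), Y);
          const int zi = clampi((int)std::lround(sz), Z);
          out[o] = p[xi + (long)X * (yi + (long)Y * zi)];
        } else {
          const int fx = (int)std::floor(sx), fy = (int)std::floor(sy),
            fz = (int)std::floor(sz);
          double wx[4], wy[4], wz[4];
          bspline_w(sx - fx, wx);
          bspline_w(sy - fy, wy);
          bspline_w(sz - fz, wz);
          double acc = 0.0;
          for (int dz = 0; dz < 4; ++dz) {
            const int zi = clampi(fz - 1 + dz, Z);
            double accy = 0.0;
            for (int dy = 0; dy < 4; ++dy) {
              const int yi = clampi(fy - 1 + dy, Y);
              const double *row = p + (long)X * (yi + (long)Y * zi);
              double accx = 0.0;
              for (int dx = 0; dx < 4; ++dx)
                accx += wx[dx] * row[clampi(fx - 1 + dx, X)];
              accy += wy[dy] * accx;
            }
            acc += wz[dz] * accy;
          }
          out[o] = acc;
        }
      }
  out.attr("dim") = outdims;
  return out;
}
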