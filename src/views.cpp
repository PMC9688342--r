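// Batched extraction of the 3-scale x 3-view in-plane patches around query
// voxels for the 2.5D multi-view classifier. Out-of-grid samples replicate
// the nearest edge voxel.

#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// voxels: n x 3 matrix of 0-based (x,y,z) indices. Returns an array of
// dim c(inplane, inplane, 3 views, nscales, n); views are ordered
// axial (x,y), sagittal (y,z), coronal (x,z).
// [[Rcpp::export(name = ".extract_views_batch")]]
NumericVector extract_views_batch(NumericVector data, IntegerVector dims,
                                  IntegerMatrix voxels, int inplane,
                                  IntegerVector strides) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int S = strides.size(), n = voxels.nrow();
  const int half = inplane / 2;
  NumericVector out((long)inplane * inplane * 3 * S * n);
  const double *p = data.begin();
  long o = 0;
  for (int q = 0; q < n; ++q) {
    const int cx = voxels(q, 0), cy = voxels(q, 1), cz = voxels(q, 2);
    for (int s = 0; s < S; ++s) {
      const int st = strides[s];
      // axial: (x, y) at z = cz
      for (int v = 0; v < 3; ++v)
        for (int j = 0; j < inplane; ++j)
          for (int i = 0; i < inplane; ++i, ++o) {
            const int a = (i - half) * st, b = (j - half) * st;
            int xi, yi, zi;
            if (v == 0) {
              xi = clampi(cx + a, X); yi = clampi(cy + b, Y); zi = clampi(cz, Z);
            } else if (v == 1) {
              xi = clampi(cx, X); yi = clampi(cy + a, Y); zi = clampi(cz + b, Z);
            } else {
              xi = clampi(cx + a, X); yi = clampi(cy, Y); zi = clampi(cz + b, Z);
            }
            out[o] = p[xi + (long)X * (yi + (long)Y * zi)];
          }
    }
  }
  out.attr("dim") = IntegerVector::create(inplane, inplane, 3, S, n);
  return out;
}
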