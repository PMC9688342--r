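// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher lower
// envelopes, anisotropic spacing), 26-connected component labelling,
// border-connected background flood (hole detection) and majority
// relabelling of filled holes.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

namespace {

// Large finite sentinel standing in for "no source found yet"; squared
// physical distances in any realistic grid are far below it, and keeping it
// finite keeps the envelope arithmetic well defined.
const double BIG = 1e30;
const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform with sample spacing s (physical units).
void dt1d(const double *f, int n, double s, double *d,
          std::vector<double> &zbuf, std::vector<int> &vbuf) {
  int *v = vbuf.data();
  double *zz = zbuf.data();
  int k = 0;
  v[0] = 0;
  zz[0] = -INF;
  zz[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = s * q;
    while (true) {
      double sv = s * v[k];
      double ss = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * (sq - sv));
      if (k > 0 && ss <= zz[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zz[k] = ss;
        zz[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = s * q;
    while (zz[k + 1] < sq) ++k;
    double sv = s * v[k];
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

} // namespace

// Squared Euclidean distance (in physical units) from every voxel to the
// nearest true voxel of `mask`. All-false masks give +Inf everywhere.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long nvox = (long)X * Y * Z;
  NumericVector d(nvox);
  for (long i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : BIG;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> line(nmax), out(nmax), zbuf(nmax + 1);
  std::vector<int> vbuf(nmax);
  double *p = d.begin();
  // x axis
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      double *row = p + (long)X * (y + (long)Y * z);
      for (int x = 0; x < X; ++x) line[x] = row[x];
      dt1d(line.data(), X, spacing[0], out.data(), zbuf, vbuf);
      for (int x = 0; x < X; ++x) row[x] = out[x];
    }
  // y axis
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      double *col0 = p + x + (long)X * (long)Y * z;
      for (int y = 0; y < Y; ++y) line[y] = col0[(long)X * y];
      dt1d(line.data(), Y, spacing[1], out.data(), zbuf, vbuf);
      for (int y = 0; y < Y; ++y) col0[(long)X * y] = out[y];
    }
  // z axis
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      double *col0 = p + x + (long)X * y;
      for (int z = 0; z < Z; ++z) line[z] = col0[(long)X * Y * z];
      dt1d(line.data(), Z, spacing[2], out.data(), zbuf, vbuf);
      for (int z = 0; z < Z; ++z) col0[(long)X * Y * z] = out[z];
    }
  d.attr("dim") = dims;
  return d;
}

// Connected components of a binary mask; connectivity 26 or 6.
// Labels are 1..K in discovery order, 0 outside the mask.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long nvox = (long)X * Y * Z;
  IntegerVector lab(nvox);
  std::vector<long> stack;
  int next = 0;
  for (long seed = 0; seed < nvox; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const long cur = stack.back();
      stack.pop_back();
      const int x = cur % X, y = (cur / X) % Y, z = cur / ((long)X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            const int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
              continue;
            const long ni = nx + (long)X * (ny + (long)Y * nz);
            if (mask[ni] && !lab[ni]) {
              lab[ni] = next;
              stack.push_back(ni);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Interior holes of a binary mask: background voxels not 6-connected to the
// grid border through background.
// [[Rcpp::export(name = ".find_holes")]]
LogicalVector find_holes(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long nvox = (long)X * Y * Z;
  std::vector<char> vis(nvox, 0);
  std::vector<long> stack;
  for (long i = 0; i < nvox; ++i) {
    const int x = i % X, y = (i / X) % Y, z = i / ((long)X * Y);
    const bool border = x == 0 || x == X - 1 || y == 0 || y == Y - 1 ||
      z == 0 || z == Z - 1;
    if (border && !mask[i] && !vis[i]) {
      vis[i] = 1;
      stack.push_back(i);
    }
  }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    const long cur = stack.back();
    stack.pop_back();
    const int x = cur % X, y = (cur / X) % Y, z = cur / ((long)X * Y);
    for (int d = 0; d < 6; ++d) {
      const int nx = x + dxs[d], ny = y + dys[d], nz = z + dzs[d];
      if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
        continue;
      const long ni = nx + (long)X * (ny + (long)Y * nz);
      if (!mask[ni] && !vis[ni]) {
        vis[ni] = 1;
        stack.push_back(ni);
      }
    }
  }
  LogicalVector holes(nvox);
  for (long i = 0; i < nvox; ++i) holes[i] = !mask[i] && !vis[i];
  holes.attr("dim") = dims;
  return holes;
}

// Assign each voxel in `fill` the majority label (>0) of its 26
// neighbourhood, iterating in wavefronts so holes fill inward from their
// labelled rim; ties break toward the lower label.
// [[Rcpp::export(name = ".relabel_fill")]]
IntegerVector relabel_fill(IntegerVector labels, LogicalVector fill,
                           IntegerVector dims, int nclasses) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long nvox = (long)X * Y * Z;
  IntegerVector out = clone(labels);
  std::vector<long> pending;
  for (long i = 0; i < nvox; ++i)
    if (fill[i]) pending.push_back(i);
  std::vector<int> counts(nclasses + 1);
  while (!pending.empty()) {
    std::vector<long> next;
    std::vector<std::pair<long, int> > assign;
    for (size_t t = 0; t < pending.size(); ++t) {
      const long cur = pending[t];
      const int x = cur % X, y = (cur / X) % Y, z = cur / ((long)X * Y);
      std::fill(counts.begin(), counts.end(), 0);
      bool anyn = false;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
              continue;
            const int l = out[nx + (long)X * (ny + (long)Y * nz)];
            if (l > 0 && l <= nclasses) {
              ++counts[l];
              anyn = true;
            }
          }
      if (!anyn) {
        next.push_back(cur);
      } else {
        int best = 1;
        for (int l = 2; l <= nclasses; ++l)
          if (counts[l] > counts[best]) best = l;
        assign.push_back(std::make_pair(cur, best));
      }
    }
    if (assign.empty()) break; // isolated fill region with no labelled rim
    for (size_t t = 0; t < assign.size(); ++t)
      out[assign[t].first] = assign[t].second;
    pending.swap(next);
  }
  out.attr("dim") = dims;
  return out;
}
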