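// Persistent single-precision UNet engine.
//
// Mirrors the R reference implementation (unetForward/unetBackward) layer
// for layer, but keeps all activations, weights and caches in float on the
// C++ side so a training step costs one probs/gradient round-trip instead
// of a double<->float conversion per layer. The R side still owns the
// canonical (double) parameters and the Adam state; weights are pushed
// down with .eng_set_weights after every optimizer step and batch-norm
// running statistics are pulled up with .eng_get_bn at checkpoint time.
//
// Architecture (matching unetSpec/buildUNet):
//   stem: conv3 (1 -> F) + BN + ReLU
//   enc d = 1..D: residual block (conv3+BN+ReLU, conv3+BN, shortcut with
//     1x1x1 projection+BN when channels change, add, ReLU), 2x max pool
//     between levels
//   spatial (channel-wise) dropout on the bottleneck during training
//   dec d = D-1..1: NN-upsample, concat skip, 1x1x1 fuse conv+BN+ReLU,
//     conv3+BN+ReLU
//   head: 1x1x1 conv -> M channels, softmax over channels

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims {
  int X, Y, Z, C, N;
  long nvox() const { return (long)X * Y * Z; }
  long total() const { return nvox() * C * N; }
};

typedef std::vector<float> fbuf;

// write the im2col block of one sample into rows [rowOff, rowOff+nvox)
// of a (possibly taller) matrix
void im2colF(const float *x, int X, int Y, int Z, int C,
             int kx, int ky, int kz, arma::fmat &col, long rowOff = 0) {
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  const long nvox = (long)X * Y * Z;
  for (int c = 0; c < C; ++c) {
    const float *xc = x + (long)c * nvox;
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          const int q = dx + kx * (dy + ky * (dz + kz * c));
          float *dst = col.colptr(q) + rowOff;
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

void col2imF(const arma::fmat &col, int X, int Y, int Z, int C,
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

struct ConvLayer {
  int kx, ky, kz, cin, cout;
  arma::fmat W;     // (k*cin) x cout
  arma::fmat Wflip; // (k*cout) x cin, spatially flipped (for grad wrt input)
  arma::fvec b;
  arma::mat gW;
  arma::vec gb;
  arma::fmat colg;  // im2col buffer for the backward (flipped) convolution

  void buildFlip() {
    if (kx == 1 && ky == 1 && kz == 1) return;
    const int K = kx * ky * kz;
    Wflip.set_size((long)K * cout, cin);
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co)
        for (int dz = 0; dz < kz; ++dz)
          for (int dy = 0; dy < ky; ++dy)
            for (int dx = 0; dx < kx; ++dx) {
              const long q2 = dx + kx * (dy + ky * ((long)dz + kz * co));
              const long qf = (kx - 1 - dx) + kx * ((ky - 1 - dy) +
                ky * ((long)(kz - 1 - dz) + kz * ci));
              Wflip(q2, ci) = W(qf, co);
            }
  }

  void init(List p) {
    NumericMatrix Wd = p["W"];
    NumericVector bd = p["b"];
    IntegerVector k = p["k"];
    kx = k[0]; ky = k[1]; kz = k[2];
    cout = Wd.ncol();
    cin = Wd.nrow() / (kx * ky * kz);
    W.set_size(Wd.nrow(), cout);
    for (long i = 0; i < (long)Wd.nrow() * cout; ++i) W[i] = (float)Wd[i];
    b.set_size(cout);
    for (int i = 0; i < cout; ++i) b[i] = (float)bd[i];
    gW.zeros(Wd.nrow(), cout);
    gb.zeros(cout);
    buildFlip();
  }

  void setWeights(List p) {
    NumericMatrix Wd = p["W"];
    NumericVector bd = p["b"];
    for (long i = 0; i < (long)W.n_rows * W.n_cols; ++i) W[i] = (float)Wd[i];
    for (int i = 0; i < cout; ++i) b[i] = (float)bd[i];
    buildFlip();
  }

  List grads() const {
    NumericMatrix gWd(W.n_rows, W.n_cols);
    std::copy(gW.begin(), gW.end(), gWd.begin());
    NumericVector gbd(cout);
    std::copy(gb.begin(), gb.end(), gbd.begin());
    return List::create(_["W"] = gWd, _["b"] = gbd);
  }

  // out dims: same spatial, cout channels
  void fwd(const fbuf &x, Dims dx, fbuf &out, arma::fmat &colbuf) {
    const long nvox = dx.nvox();
    const int K = kx * ky * kz * cin;
    out.resize(nvox * cout * dx.N);
    if (kx == 1 && ky == 1 && kz == 1) {
      for (int n = 0; n < dx.N; ++n) {
        const arma::fmat xm(const_cast<float *>(x.data()) +
                            (long)n * nvox * cin, nvox, cin, false);
        arma::fmat om(out.data() + (long)n * nvox * cout, nvox, cout,
                      false, true);
        om = xm * W;
        om.each_row() += b.t();
      }
      return;
    }
    if ((long)colbuf.n_rows != nvox || (int)colbuf.n_cols != K)
      colbuf.set_size(nvox, K);
    for (int n = 0; n < dx.N; ++n) {
      colbuf.zeros();
      im2colF(x.data() + (long)n * nvox * cin, dx.X, dx.Y, dx.Z, cin,
              kx, ky, kz, colbuf);
      arma::fmat om(out.data() + (long)n * nvox * cout, nvox, cout,
                    false, true);
      om = colbuf * W;
      om.each_row() += b.t();
    }
  }

  void bwd(const fbuf &x, Dims dx, const fbuf &gout, fbuf &gx,
           arma::fmat &colbuf, bool needGx) {
    const long nvox = dx.nvox();
    gW.zeros();
    gb.zeros();
    if (needGx) gx.resize(nvox * cin * dx.N);
    if (kx == 1 && ky == 1 && kz == 1) {
      for (int n = 0; n < dx.N; ++n) {
        const arma::fmat xm(const_cast<float *>(x.data()) +
                            (long)n * nvox * cin, nvox, cin, false);
        const arma::fmat gm(const_cast<float *>(gout.data()) +
                            (long)n * nvox * cout, nvox, cout, false);
        gW += arma::conv_to<arma::mat>::from(xm.t() * gm);
        gb += arma::conv_to<arma::vec>::from(arma::sum(gm, 0).t());
        if (needGx) {
          arma::fmat gxm(gx.data() + (long)n * nvox * cin, nvox, cin,
                         false, true);
          gxm = gm * W.t();
        }
      }
      return;
    }
    const int K = kx * ky * kz * cin;
    const int K2 = kx * ky * kz * cout;
    if ((long)colbuf.n_rows != nvox || (int)colbuf.n_cols != K)
      colbuf.set_size(nvox, K);
    if (needGx && ((long)colg.n_rows != nvox || (int)colg.n_cols != K2))
      colg.zeros(nvox, K2);
    for (int n = 0; n < dx.N; ++n) {
      const arma::fmat gm(const_cast<float *>(gout.data()) +
                          (long)n * nvox * cout, nvox, cout, false);
      colbuf.zeros();
      im2colF(x.data() + (long)n * nvox * cin, dx.X, dx.Y, dx.Z, cin,
              kx, ky, kz, colbuf);
      gW += arma::conv_to<arma::mat>::from(colbuf.t() * gm);
      gb += arma::conv_to<arma::vec>::from(arma::sum(gm, 0).t());
      if (needGx) {
        // grad wrt input = convolution of gout with the flipped kernel;
        // colg's zero-padding cells are never written, so it is zeroed
        // once per (re)allocation only
        im2colF(gout.data() + (long)n * nvox * cout, dx.X, dx.Y, dx.Z,
                cout, kx, ky, kz, colg);
        arma::fmat gxm(gx.data() + (long)n * nvox * cin, nvox, cin,
                       false, true);
        gxm = colg * Wflip;
      }
    }
  }
};

struct BNLayer {
  int C;
  arma::fvec gamma, beta;
  arma::vec rmean, rvar, mu, var; // stats in double
  arma::vec dgamma, dbeta;
  double eps, momentum;

  void init(List p, double eps_ = 1e-3, double mom_ = 0.9) {
    NumericVector g = p["gamma"], b = p["beta"], rm = p["rmean"],
      rv = p["rvar"];
    C = g.size();
    gamma.set_size(C); beta.set_size(C);
    rmean.set_size(C); rvar.set_size(C);
    for (int i = 0; i < C; ++i) {
      gamma[i] = (float)g[i]; beta[i] = (float)b[i];
      rmean[i] = rm[i]; rvar[i] = rv[i];
    }
    mu.zeros(C); var.ones(C); dgamma.zeros(C); dbeta.zeros(C);
    eps = eps_; momentum = mom_;
  }

  void setWeights(List p) {
    NumericVector g = p["gamma"], b = p["beta"];
    for (int i = 0; i < C; ++i) {
      gamma[i] = (float)g[i];
      beta[i] = (float)b[i];
    }
  }

  List grads() const {
    return List::create(_["gamma"] = NumericVector(dgamma.begin(),
                                                   dgamma.end()),
                        _["beta"] = NumericVector(dbeta.begin(),
                                                  dbeta.end()));
  }

  List stats() const {
    return List::create(_["rmean"] = NumericVector(rmean.begin(),
                                                   rmean.end()),
                        _["rvar"] = NumericVector(rvar.begin(),
                                                  rvar.end()));
  }

  void fwd(const fbuf &x, Dims d, fbuf &out, bool training) {
    const long nvox = d.nvox();
    const long m = nvox * d.N;
    out.resize(x.size());
    for (int c = 0; c < C; ++c) {
      double muc, varc;
      if (training) {
        double s = 0, s2 = 0;
        for (int n = 0; n < d.N; ++n) {
          const float *p = x.data() + nvox * (c + (long)C * n);
          for (long i = 0; i < nvox; ++i) {
            s += p[i];
            s2 += (double)p[i] * p[i];
          }
        }
        muc = s / m;
        varc = s2 / m - muc * muc;
        if (varc < 0) varc = 0;
        rmean[c] = momentum * rmean[c] + (1 - momentum) * muc;
        rvar[c] = momentum * rvar[c] + (1 - momentum) * varc;
        mu[c] = muc;
        var[c] = varc;
      } else {
        muc = rmean[c];
        varc = rvar[c];
      }
      const float a = (float)(gamma[c] / std::sqrt(varc + eps));
      const float bb = (float)(beta[c] - a * muc);
      for (int n = 0; n < d.N; ++n) {
        const float *p = x.data() + nvox * (c + (long)C * n);
        float *o = out.data() + nvox * (c + (long)C * n);
        for (long i = 0; i < nvox; ++i) o[i] = a * p[i] + bb;
      }
    }
  }

  void bwd(const fbuf &x, Dims d, const fbuf &gout, fbuf &gx) {
    const long nvox = d.nvox();
    const long m = nvox * d.N;
    gx.resize(x.size());
    for (int c = 0; c < C; ++c) {
      const double invstd = 1.0 / std::sqrt(var[c] + eps);
      double s1 = 0, s2 = 0;
      for (int n = 0; n < d.N; ++n) {
        const float *p = x.data() + nvox * (c + (long)C * n);
        const float *g = gout.data() + nvox * (c + (long)C * n);
        for (long i = 0; i < nvox; ++i) {
          s1 += g[i];
          s2 += g[i] * ((double)p[i] - mu[c]) * invstd;
        }
      }
      dbeta[c] = s1;
      dgamma[c] = s2;
      const float k1 = (float)(gamma[c] * invstd);
      const float k2 = (float)(s1 / m);
      const float k3 = (float)(s2 / m);
      const float muf = (float)mu[c], isf = (float)invstd;
      for (int n = 0; n < d.N; ++n) {
        const float *p = x.data() + nvox * (c + (long)C * n);
        const float *g = gout.data() + nvox * (c + (long)C * n);
        float *o = gx.data() + nvox * (c + (long)C * n);
        for (long i = 0; i < nvox; ++i) {
          const float xh = (p[i] - muf) * isf;
          o[i] = k1 * (g[i] - k2 - xh * k3);
        }
      }
    }
  }
};

void reluF(const fbuf &x, fbuf &out) {
  out.resize(x.size());
  for (long i = 0; i < (long)x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : 0.0f;
}

void reluBF(const fbuf &out, const fbuf &gout, fbuf &gx) {
  gx.resize(gout.size());
  for (long i = 0; i < (long)gout.size(); ++i)
    gx[i] = out[i] > 0 ? gout[i] : 0.0f;
}

void addInto(fbuf &a, const fbuf &b) {
  for (long i = 0; i < (long)a.size(); ++i) a[i] += b[i];
}

void maxpoolF(const fbuf &x, Dims d, fbuf &out, std::vector<long> &amax) {
  const int Xo = d.X / 2, Yo = d.Y / 2, Zo = d.Z / 2;
  const long nin = d.nvox(), nout = (long)Xo * Yo * Zo;
  out.resize(nout * d.C * d.N);
  amax.resize(out.size());
  for (int n = 0; n < d.N; ++n)
    for (int c = 0; c < d.C; ++c) {
      const long ob = nout * (c + (long)d.C * n);
      const long ib = nin * (c + (long)d.C * n);
      for (int zo = 0; zo < Zo; ++zo)
        for (int yo = 0; yo < Yo; ++yo)
          for (int xo = 0; xo < Xo; ++xo) {
            float best = -1e30f;
            long bi = -1;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const long ii = ib + (long)(2 * xo + dx) +
                    (long)d.X * ((2 * yo + dy) + (long)d.Y * (2 * zo + dz));
                  if (x[ii] > best) { best = x[ii]; bi = ii; }
                }
            const long oi = ob + xo + (long)Xo * (yo + (long)Yo * zo);
            out[oi] = best;
            amax[oi] = bi;
          }
    }
}

void maxpoolBF(const fbuf &gout, const std::vector<long> &amax, long nin,
               fbuf &gx) {
  gx.assign(nin, 0.0f);
  for (long i = 0; i < (long)gout.size(); ++i) gx[amax[i]] += gout[i];
}

void upsampleF(const fbuf &x, Dims d, fbuf &out) {
  const int Xo = 2 * d.X, Yo = 2 * d.Y, Zo = 2 * d.Z;
  const long nin = d.nvox(), nout = (long)Xo * Yo * Zo;
  out.resize(nout * d.C * d.N);
  for (int n = 0; n < d.N; ++n)
    for (int c = 0; c < d.C; ++c) {
      const float *src = x.data() + nin * (c + (long)d.C * n);
      float *dst = out.data() + nout * (c + (long)d.C * n);
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          const float *s = src + (long)d.X * ((y / 2) + (long)d.Y * (z / 2));
          float *o = dst + (long)Xo * (y + (long)Yo * z);
          for (int xi = 0; xi < Xo; ++xi) o[xi] = s[xi / 2];
        }
    }
}

void upsampleBF(const fbuf &gout, Dims d, fbuf &gx) {
  // d: input (coarse) dims
  const int Xo = 2 * d.X, Yo = 2 * d.Y, Zo = 2 * d.Z;
  const long nin = d.nvox(), nout = (long)Xo * Yo * Zo;
  gx.assign(nin * d.C * d.N, 0.0f);
  for (int n = 0; n < d.N; ++n)
    for (int c = 0; c < d.C; ++c) {
      float *dst = gx.data() + nin * (c + (long)d.C * n);
      const float *src = gout.data() + nout * (c + (long)d.C * n);
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          float *o = dst + (long)d.X * ((y / 2) + (long)d.Y * (z / 2));
          const float *s = src + (long)Xo * (y + (long)Yo * z);
          for (int xi = 0; xi < Xo; ++xi) o[xi / 2] += s[xi];
        }
    }
}

// concat b after a along the channel dim
void catF(const fbuf &a, Dims da, const fbuf &b, Dims db, fbuf &out) {
  const long nvox = da.nvox();
  out.resize(nvox * (da.C + db.C) * da.N);
  for (int n = 0; n < da.N; ++n) {
    std::copy(a.data() + (long)n * nvox * da.C,
              a.data() + (long)(n + 1) * nvox * da.C,
              out.data() + (long)n * nvox * (da.C + db.C));
    std::copy(b.data() + (long)n * nvox * db.C,
              b.data() + (long)(n + 1) * nvox * db.C,
              out.data() + (long)n * nvox * (da.C + db.C) + nvox * da.C);
  }
}

void splitF(const fbuf &g, Dims da, Dims db, fbuf &ga, fbuf &gb) {
  const long nvox = da.nvox();
  ga.resize(nvox * da.C * da.N);
  gb.resize(nvox * db.C * db.N);
  for (int n = 0; n < da.N; ++n) {
    std::copy(g.data() + (long)n * nvox * (da.C + db.C),
              g.data() + (long)n * nvox * (da.C + db.C) + nvox * da.C,
              ga.data() + (long)n * nvox * da.C);
    std::copy(g.data() + (long)n * nvox * (da.C + db.C) + nvox * da.C,
              g.data() + (long)(n + 1) * nvox * (da.C + db.C),
              gb.data() + (long)n * nvox * db.C);
  }
}

struct ResBlock {
  ConvLayer conv1, conv2, proj;
  BNLayer bn1, bn2, projbn;
  bool hasProj;
  // caches
  fbuf in, z1, r1, z2, projz, sc, out;
  Dims din, dout;

  void init(List p) {
    conv1.init(p["conv1"]);
    bn1.init(p["bn1"]);
    conv2.init(p["conv2"]);
    bn2.init(p["bn2"]);
    hasProj = p.containsElementNamed("proj");
    if (hasProj) {
      proj.init(p["proj"]);
      projbn.init(p["projbn"]);
    }
  }

  void setWeights(List p) {
    conv1.setWeights(p["conv1"]);
    bn1.setWeights(p["bn1"]);
    conv2.setWeights(p["conv2"]);
    bn2.setWeights(p["bn2"]);
    if (hasProj) {
      proj.setWeights(p["proj"]);
      projbn.setWeights(p["projbn"]);
    }
  }

  List grads() const {
    List g = List::create(_["conv1"] = conv1.grads(), _["bn1"] = bn1.grads(),
                          _["conv2"] = conv2.grads(), _["bn2"] = bn2.grads());
    if (hasProj) {
      g["proj"] = proj.grads();
      g["projbn"] = projbn.grads();
    }
    return g;
  }

  List stats() const {
    List s = List::create(_["bn1"] = bn1.stats(), _["bn2"] = bn2.stats());
    if (hasProj) s["projbn"] = projbn.stats();
    return s;
  }

  void fwd(const fbuf &x, Dims d, bool training, arma::fmat &colbuf) {
    in = x;
    din = d;
    dout = d;
    dout.C = conv1.cout;
    conv1.fwd(in, din, z1, colbuf);
    fbuf tmp;
    bn1.fwd(z1, dout, tmp, training);
    reluF(tmp, r1);
    conv2.fwd(r1, dout, z2, colbuf);
    bn2.fwd(z2, dout, tmp, training);
    if (hasProj) {
      proj.fwd(in, din, projz, colbuf);
      projbn.fwd(projz, dout, sc, training);
      addInto(tmp, sc);
    } else {
      addInto(tmp, in);
    }
    reluF(tmp, out);
  }

  void bwd(const fbuf &gout, fbuf &gx, arma::fmat &colbuf) {
    fbuf gs, t1, t2;
    reluBF(out, gout, gs);
    bn2.bwd(z2, dout, gs, t1);
    conv2.bwd(r1, dout, t1, t2, colbuf, true);
    fbuf g1;
    reluBF(r1, t2, g1);
    bn1.bwd(z1, dout, g1, t1);
    conv1.bwd(in, din, t1, gx, colbuf, true);
    if (hasProj) {
      projbn.bwd(projz, dout, gs, t1);
      proj.bwd(in, din, t1, t2, colbuf, true);
      addInto(gx, t2);
    } else {
      addInto(gx, gs);
    }
  }
};

struct DecLevel {
  ConvLayer fuse, conv;
  BNLayer fusebn, bn;
  // caches
  fbuf uin, up, cat, z1, r1, z2, r2;
  Dims dUin, dUp, dSkip, dCat, dOut;

  void init(List p) {
    fuse.init(p["fuse"]);
    fusebn.init(p["fusebn"]);
    conv.init(p["conv"]);
    bn.init(p["bn"]);
  }

  void setWeights(List p) {
    fuse.setWeights(p["fuse"]);
    fusebn.setWeights(p["fusebn"]);
    conv.setWeights(p["conv"]);
    bn.setWeights(p["bn"]);
  }

  List grads() const {
    return List::create(_["fuse"] = fuse.grads(),
                        _["fusebn"] = fusebn.grads(),
                        _["conv"] = conv.grads(), _["bn"] = bn.grads());
  }

  List stats() const {
    return List::create(_["fusebn"] = fusebn.stats(), _["bn"] = bn.stats());
  }

  void fwd(const fbuf &u, Dims du, const fbuf &skip, Dims dskip,
           bool training, arma::fmat &colbuf) {
    uin = u;
    dUin = du;
    upsampleF(uin, dUin, up);
    dUp = du;
    dUp.X *= 2; dUp.Y *= 2; dUp.Z *= 2;
    dSkip = dskip;
    catF(up, dUp, skip, dSkip, cat);
    dCat = dUp;
    dCat.C = dUp.C + dSkip.C;
    dOut = dCat;
    dOut.C = fuse.cout;
    fuse.fwd(cat, dCat, z1, colbuf);
    fbuf tmp;
    fusebn.fwd(z1, dOut, tmp, training);
    reluF(tmp, r1);
    conv.fwd(r1, dOut, z2, colbuf);
    bn.fwd(z2, dOut, tmp, training);
    reluF(tmp, r2);
  }

  // returns gradient wrt deeper input u in gU and wrt skip in gSkip
  void bwd(const fbuf &gout, fbuf &gU, fbuf &gSkip, arma::fmat &colbuf) {
    fbuf t1, t2, gcat, gup;
    reluBF(r2, gout, t1);
    bn.bwd(z2, dOut, t1, t2);
    conv.bwd(r1, dOut, t2, t1, colbuf, true);
    fbuf g1;
    reluBF(r1, t1, g1);
    fusebn.bwd(z1, dOut, g1, t2);
    fuse.bwd(cat, dCat, t2, gcat, colbuf, true);
    splitF(gcat, dUp, dSkip, gup, gSkip);
    upsampleBF(gup, dUin, gU);
  }
};

struct UNetEngine {
  int depth, baseFilters, nClasses, patchSize;
  double dropout;
  ConvLayer stemConv, head;
  BNLayer stemBN;
  std::vector<ResBlock> enc;
  std::vector<DecLevel> dec; // index 0 = level 1 (shallowest)
  arma::fmat colbuf;
  // caches
  fbuf x0, stemZ, stemA, probs;
  std::vector<fbuf> poolOut;
  std::vector<std::vector<long> > poolArg;
  std::vector<Dims> poolInDims;
  fbuf dropMask; // per (channel, sample)
  Dims dIn, dProbs;
  bool trained;

  void build(List params, List spec) {
    depth = as<int>(spec["depth"]);
    baseFilters = as<int>(spec["baseFilters"]);
    nClasses = as<int>(spec["nClasses"]);
    patchSize = as<int>(spec["patchSize"]);
    dropout = as<double>(spec["dropout"]);
    stemConv.init(as<List>(params["stem"])["conv"]);
    stemBN.init(as<List>(params["stem"])["bn"]);
    enc.resize(depth);
    for (int d = 0; d < depth; ++d)
      enc[d].init(params["enc" + std::to_string(d + 1)]);
    dec.resize(depth - 1);
    for (int d = 0; d < depth - 1; ++d)
      dec[d].init(params["dec" + std::to_string(d + 1)]);
    head.init(params["head"]);
    poolOut.resize(depth);
    poolArg.resize(depth);
    poolInDims.resize(depth);
  }

  void setWeights(List params) {
    stemConv.setWeights(as<List>(params["stem"])["conv"]);
    stemBN.setWeights(as<List>(params["stem"])["bn"]);
    for (int d = 0; d < depth; ++d)
      enc[d].setWeights(params["enc" + std::to_string(d + 1)]);
    for (int d = 0; d < depth - 1; ++d)
      dec[d].setWeights(params["dec" + std::to_string(d + 1)]);
    head.setWeights(params["head"]);
  }

  List grads() const {
    List g;
    g["stem"] = List::create(_["conv"] = stemConv.grads(),
                             _["bn"] = stemBN.grads());
    for (int d = 0; d < depth; ++d)
      g["enc" + std::to_string(d + 1)] = enc[d].grads();
    for (int d = 0; d < depth - 1; ++d)
      g["dec" + std::to_string(d + 1)] = dec[d].grads();
    g["head"] = head.grads();
    return g;
  }

  List bnStats() const {
    List s;
    s["stem"] = List::create(_["bn"] = stemBN.stats());
    for (int d = 0; d < depth; ++d)
      s["enc" + std::to_string(d + 1)] = enc[d].stats();
    for (int d = 0; d < depth - 1; ++d)
      s["dec" + std::to_string(d + 1)] = dec[d].stats();
    return s;
  }

  // x: (P,P,P,1,N) doubles; returns probs (P,P,P,M,N)
  NumericVector fwd(NumericVector x, IntegerVector dims, bool training) {
    dIn.X = dims[0]; dIn.Y = dims[1]; dIn.Z = dims[2];
    dIn.C = 1; dIn.N = dims[4];
    x0.resize(dIn.total());
    for (long i = 0; i < (long)x0.size(); ++i) x0[i] = (float)x[i];
    fbuf tmp;
    stemConv.fwd(x0, dIn, stemZ, colbuf);
    Dims d = dIn;
    d.C = stemConv.cout;
    stemBN.fwd(stemZ, d, tmp, training);
    reluF(tmp, stemA);
    const fbuf *cur = &stemA;
    Dims dcur = d;
    for (int dd = 0; dd < depth; ++dd) {
      if (dd > 0) {
        poolInDims[dd] = dcur;
        maxpoolF(*cur, dcur, poolOut[dd], poolArg[dd]);
        dcur.X /= 2; dcur.Y /= 2; dcur.Z /= 2;
        cur = &poolOut[dd];
      }
      enc[dd].fwd(*cur, dcur, training, colbuf);
      dcur = enc[dd].dout;
      cur = &enc[dd].out;
    }
    // spatial dropout on the bottleneck: drop whole channels per sample
    fbuf bott = enc[depth - 1].out;
    if (training && dropout > 0) {
      dropMask.resize((long)dcur.C * dcur.N);
      GetRNGstate();
      for (long i = 0; i < (long)dropMask.size(); ++i)
        dropMask[i] = unif_rand() >= dropout ?
          (float)(1.0 / (1.0 - dropout)) : 0.0f;
      PutRNGstate();
      const long nv = dcur.nvox();
      for (int n = 0; n < dcur.N; ++n)
        for (int c = 0; c < dcur.C; ++c) {
          const float mcn = dropMask[c + (long)dcur.C * n];
          float *p = bott.data() + nv * (c + (long)dcur.C * n);
          for (long i = 0; i < nv; ++i) p[i] *= mcn;
        }
    } else {
      dropMask.clear();
    }
    const fbuf *u = &bott;
    Dims du = dcur;
    for (int dd = depth - 2; dd >= 0; --dd) {
      dec[dd].fwd(*u, du, enc[dd].out, enc[dd].dout, training, colbuf);
      u = &dec[dd].r2;
      du = dec[dd].dOut;
    }
    fbuf logits;
    head.fwd(*u, du, logits, colbuf);
    Dims dp = du;
    dp.C = head.cout;
    dProbs = dp;
    // softmax over channels
    probs.resize(logits.size());
    const long nv = dp.nvox();
    const int M = dp.C;
    for (int n = 0; n < dp.N; ++n)
      for (long i = 0; i < nv; ++i) {
        float mx = -1e30f;
        for (int c = 0; c < M; ++c)
          mx = std::max(mx, logits[i + nv * (c + (long)M * n)]);
        float s = 0;
        for (int c = 0; c < M; ++c) {
          const float e = std::exp(logits[i + nv * (c + (long)M * n)] - mx);
          probs[i + nv * (c + (long)M * n)] = e;
          s += e;
        }
        for (int c = 0; c < M; ++c)
          probs[i + nv * (c + (long)M * n)] /= s;
      }
    NumericVector out(probs.size());
    for (long i = 0; i < (long)probs.size(); ++i) out[i] = probs[i];
    out.attr("dim") = IntegerVector::create(dp.X, dp.Y, dp.Z, M, dp.N);
    return out;
  }

  List bwd(NumericVector gprobs) {
    // softmax backward: gz_c = p_c * (g_c - sum_k g_k p_k)
    const long nv = dProbs.nvox();
    const int M = dProbs.C;
    fbuf gz(probs.size());
    for (int n = 0; n < dProbs.N; ++n)
      for (long i = 0; i < nv; ++i) {
        float dot = 0;
        for (int c = 0; c < M; ++c) {
          const long ii = i + nv * (c + (long)M * n);
          dot += probs[ii] * (float)gprobs[ii];
        }
        for (int c = 0; c < M; ++c) {
          const long ii = i + nv * (c + (long)M * n);
          gz[ii] = probs[ii] * ((float)gprobs[ii] - dot);
        }
      }
    const fbuf &headin = depth > 1 ? dec[0].r2 : enc[0].out;
    Dims dh = depth > 1 ? dec[0].dOut : enc[0].dout;
    fbuf gu, tmp;
    head.bwd(headin, dh, gz, gu, colbuf, true);
    std::vector<fbuf> gskip(depth);
    for (int dd = 0; dd < depth - 1; ++dd) {
      fbuf gU;
      dec[dd].bwd(gu, gU, gskip[dd], colbuf);
      gu = gU;
    }
    // dropout backward on bottleneck gradient
    if (!dropMask.empty()) {
      Dims dcur = enc[depth - 1].dout;
      const long nvb = dcur.nvox();
      for (int n = 0; n < dcur.N; ++n)
        for (int c = 0; c < dcur.C; ++c) {
          const float mcn = dropMask[c + (long)dcur.C * n];
          float *p = gu.data() + nvb * (c + (long)dcur.C * n);
          for (long i = 0; i < nvb; ++i) p[i] *= mcn;
        }
    }
    for (int dd = depth - 1; dd >= 0; --dd) {
      if (dd < depth - 1) addInto(gu, gskip[dd]);
      fbuf gx;
      enc[dd].bwd(gu, gx, colbuf);
      if (dd > 0) {
        maxpoolBF(gx, poolArg[dd], poolInDims[dd].total(), gu);
      } else {
        gu = gx;
      }
    }
    fbuf gs, g1;
    reluBF(stemA, gu, gs);
    Dims d = dIn;
    d.C = stemConv.cout;
    stemBN.bwd(stemZ, d, gs, g1);
    fbuf unused;
    stemConv.bwd(x0, dIn, g1, unused, colbuf, false);
    return grads();
  }
};

} // namespace

// [[Rcpp::export(name = ".eng_new")]]
SEXP eng_new(List params, List spec) {
  UNetEngine *e = new UNetEngine();
  e->build(params, spec);
  XPtr<UNetEngine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export(name = ".eng_set_weights")]]
void eng_set_weights(SEXP eng, List params) {
  XPtr<UNetEngine> e(eng);
  e->setWeights(params);
}

// [[Rcpp::export(name = ".eng_fwd")]]
NumericVector eng_fwd(SEXP eng, NumericVector x, bool training) {
  XPtr<UNetEngine> e(eng);
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 5) stop("expected a (X,Y,Z,1,N) array");
  return e->fwd(x, dims, training);
}

// [[Rcpp::export(name = ".eng_bwd")]]
List eng_bwd(SEXP eng, NumericVector gprobs) {
  XPtr<UNetEngine> e(eng);
  return e->bwd(gprobs);
}

// [[Rcpp::export(name = ".eng_get_bn")]]
List eng_get_bn(SEXP eng) {
  XPtr<UNetEngine> e(eng);
  return e->bnStats();
}
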