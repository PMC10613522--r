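#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tensors are column-major R arrays laid out as (X, Y, Z, C):
// element (i,j,k,c), all 0-based, sits at i + X*(j + Y*(k + Z*c)).
// Convolutions use "same" zero padding with a 3x3x3 kernel; each output
// row is accumulated in a register block and written once.  Convolution
// arithmetic runs in single precision (the customary deep-learning
// precision; everything around the convolutions stays double).

static std::vector<float> to_float(const double *p, R_xlen_t n) {
  std::vector<float> f(n);
  for (R_xlen_t i = 0; i < n; ++i) f[i] = (float)p[i];
  return f;
}

struct TapRow { const float *row; float w0, w1, w2; };

// Collect the contributing (input-row, 3 x-tap weights) pairs for one
// output row (j,k): one entry per (ci, valid kz, valid ky).
// flip = false: forward taps; flip = true: transposed (w0/w2 swapped,
// row offsets negated) for the input-gradient pass.
static int gather_taps(TapRow *taps, const float *xp0, const float *wp,
                       int X, int Y, int Z, int Cin, int cother, int Cw,
                       int j, int k, bool flip) {
  const R_xlen_t slab = (R_xlen_t)X * Y * Z;
  int nt = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    const float *xs = xp0 + slab * ci;
    // weight block index: forward (ci_in, co)=(ci, cother); transposed
    // pass swaps the roles handled by the caller via Cw/cother packing
    const float *wblk = flip
      ? wp + 27 * ((R_xlen_t)cother + (R_xlen_t)Cw * ci)
      : wp + 27 * ((R_xlen_t)ci + (R_xlen_t)Cw * cother);
    for (int kz = 0; kz < 3; ++kz) {
      const int kk2 = flip ? k + (1 - kz) : k + (kz - 1);
      if (kk2 < 0 || kk2 >= Z) continue;
      for (int ky = 0; ky < 3; ++ky) {
        int jj = flip ? j + (1 - ky) : j + (ky - 1);
        if (jj < 0 || jj >= Y) continue;
        const float *w3 = wblk + 3 * (ky + 3 * kz);
        TapRow t;
        t.row = xs + (R_xlen_t)X * (jj + (R_xlen_t)Y * kk2);
        if (flip) { t.w0 = w3[2]; t.w1 = w3[1]; t.w2 = w3[0]; }
        else      { t.w0 = w3[0]; t.w1 = w3[1]; t.w2 = w3[2]; }
        taps[nt++] = t;
      }
    }
  }
  return nt;
}

// Accumulate all taps into one output row of length X (interior
// register-blocked by 16, edges scalar).
static void apply_taps_row(float *__restrict out, const TapRow *taps,
                           int nt, int X) {
  int i = 1;
  for (; i + 16 <= X - 1; i += 16) {
    float acc[16] = {0};
    for (int t = 0; t < nt; ++t) {
      const float *__restrict xr = taps[t].row + i;
      const float w0 = taps[t].w0, w1 = taps[t].w1, w2 = taps[t].w2;
      for (int u = 0; u < 16; ++u)
        acc[u] += w0 * xr[u - 1] + w1 * xr[u] + w2 * xr[u + 1];
    }
    for (int u = 0; u < 16; ++u) out[i + u] += acc[u];
  }
  for (; i + 8 <= X - 1; i += 8) {
    float acc[8] = {0};
    for (int t = 0; t < nt; ++t) {
      const float *__restrict xr = taps[t].row + i;
      const float w0 = taps[t].w0, w1 = taps[t].w1, w2 = taps[t].w2;
      for (int u = 0; u < 8; ++u)
        acc[u] += w0 * xr[u - 1] + w1 * xr[u] + w2 * xr[u + 1];
    }
    for (int u = 0; u < 8; ++u) out[i + u] += acc[u];
  }
  for (; i < X - 1; ++i) {
    float a = 0.0f;
    for (int t = 0; t < nt; ++t) {
      const float *xr = taps[t].row;
      a += taps[t].w0 * xr[i - 1] + taps[t].w1 * xr[i] +
           taps[t].w2 * xr[i + 1];
    }
    out[i] += a;
  }
  for (int t = 0; t < nt; ++t) {
    const float *xr = taps[t].row;
    out[0] += taps[t].w1 * xr[0] + taps[t].w2 * xr[1];
    out[X - 1] += taps[t].w0 * xr[X - 2] + taps[t].w1 * xr[X - 1];
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xd,
                         NumericVector W, IntegerVector wd,
                         NumericVector b) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K = wd[0], Co = wd[4];
  if (K != 3) stop("conv3d kernels are specialized for K = 3");
  const R_xlen_t slab = (R_xlen_t)X * Y * Z;
  NumericVector y(slab * Co);
  std::vector<float> xf = to_float(x.begin(), slab * Ci);
  std::vector<float> wf = to_float(W.begin(), W.size());
  std::vector<float> buf(X);
  std::vector<TapRow> taps(9 * Ci);

  for (int co = 0; co < Co; ++co) {
    double *ys = y.begin() + slab * co;
    const float bco = (float)b[co];
    for (int k = 0; k < Z; ++k) {
      for (int j = 0; j < Y; ++j) {
        std::fill(buf.begin(), buf.end(), bco);
        const int nt = gather_taps(taps.data(), xf.data(), wf.data(),
                                   X, Y, Z, Ci, co, Ci, j, k, false);
        apply_taps_row(buf.data(), taps.data(), nt, X);
        double *yrow = ys + (R_xlen_t)X * (j + (R_xlen_t)Y * k);
        for (int i = 0; i < X; ++i) yrow[i] = buf[i];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  return y;
}

// Gradient w.r.t. the input: correlation of gy with the flipped kernel.
// [[Rcpp::export(name = ".conv3d_bwd_x")]]
NumericVector conv3d_bwd_x(NumericVector gy, IntegerVector yd,
                           NumericVector W, IntegerVector wd) {
  const int X = yd[0], Y = yd[1], Z = yd[2], Co = yd[3];
  const int K = wd[0], Ci = wd[3];
  if (K != 3) stop("conv3d kernels are specialized for K = 3");
  const R_xlen_t slab = (R_xlen_t)X * Y * Z;
  NumericVector gx(slab * Ci);
  std::vector<float> gf = to_float(gy.begin(), slab * Co);
  std::vector<float> wf = to_float(W.begin(), W.size());
  std::vector<float> buf(X);
  std::vector<TapRow> taps(9 * Co);

  for (int ci = 0; ci < Ci; ++ci) {
    double *gs = gx.begin() + slab * ci;
    for (int k = 0; k < Z; ++k) {
      for (int j = 0; j < Y; ++j) {
        std::fill(buf.begin(), buf.end(), 0.0f);
        const int nt = gather_taps(taps.data(), gf.data(), wf.data(),
                                   X, Y, Z, Co, ci, Ci, j, k, true);
        apply_taps_row(buf.data(), taps.data(), nt, X);
        double *grow2 = gs + (R_xlen_t)X * (j + (R_xlen_t)Y * k);
        for (int i = 0; i < X; ++i) grow2[i] = buf[i];
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  return gx;
}

// Gradients w.r.t. weights and bias.
// [[Rcpp::export(name = ".conv3d_bwd_w")]]
List conv3d_bwd_w(NumericVector x, IntegerVector xd,
                  NumericVector gy, IntegerVector wd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K = wd[0], Co = wd[4];
  if (K != 3) stop("conv3d kernels are specialized for K = 3");
  const R_xlen_t slab = (R_xlen_t)X * Y * Z;
  NumericVector gW((R_xlen_t)27 * Ci * Co);
  NumericVector gb(Co);
  std::vector<float> xf = to_float(x.begin(), slab * Ci);
  std::vector<float> gf = to_float(gy.begin(), slab * Co);
  double *gwp = gW.begin();

  for (int co = 0; co < Co; ++co) {
    const float *gys = gf.data() + slab * co;
    double s = 0.0;
    for (R_xlen_t v = 0; v < slab; ++v) s += gys[v];
    gb[co] = s;
    for (int ci = 0; ci < Ci; ++ci) {
      const float *xs = xf.data() + slab * ci;
      for (int kz = 0; kz < 3; ++kz) {
        const int dk = kz - 1;
        for (int ky = 0; ky < 3; ++ky) {
          const int dj = ky - 1;
          const int j0 = dj < 0 ? -dj : 0, j1 = dj > 0 ? Y - dj : Y;
          const int k0 = dk < 0 ? -dk : 0, k1 = dk > 0 ? Z - dk : Z;
          float a0v[16] = {0}, a1v[16] = {0}, a2v[16] = {0};
          double e0 = 0.0, e1 = 0.0, e2 = 0.0;
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              const float *__restrict grow =
                gys + (R_xlen_t)X * (j + (R_xlen_t)Y * k);
              const float *__restrict xrow =
                xs + (R_xlen_t)X * ((j + dj) + (R_xlen_t)Y * (k + dk));
              int i = 1;
              for (; i + 16 <= X - 1; i += 16) {
                const float *__restrict g8 = grow + i;
                const float *__restrict x8 = xrow + i;
                for (int u = 0; u < 16; ++u) {
                  const float g = g8[u];
                  a0v[u] += g * x8[u - 1];
                  a1v[u] += g * x8[u];
                  a2v[u] += g * x8[u + 1];
                }
              }
              for (; i < X - 1; ++i) {
                const double g = grow[i];
                e0 += g * xrow[i - 1];
                e1 += g * xrow[i];
                e2 += g * xrow[i + 1];
              }
              e1 += (double)grow[0] * xrow[0];
              e2 += (double)grow[0] * xrow[1];
              e0 += (double)grow[X - 1] * xrow[X - 2];
              e1 += (double)grow[X - 1] * xrow[X - 1];
            }
          }
          for (int u = 0; u < 16; ++u) {
            e0 += a0v[u]; e1 += a1v[u]; e2 += a2v[u];
          }
          double *gk = gwp + 3 * (ky + 3 * ((R_xlen_t)kz +
                       3 * (ci + (R_xlen_t)Ci * co)));
          gk[0] = e0; gk[1] = e1; gk[2] = e2;
        }
      }
    }
  }
  gW.attr("dim") = IntegerVector::create(3, 3, 3, Ci, Co);
  return List::create(Named("W") = gW, Named("b") = gb);
}

static inline R_xlen_t idx4(int i, int j, int k, int c, int X, int Y, int Z) {
  return (R_xlen_t)i + (R_xlen_t)X * (j + (R_xlen_t)Y * (k + (R_xlen_t)Z * c));
}

// 2x2x2 max pooling with stride 2; returns pooled values and 0-based argmax
// linear indices into the input (per channel).
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const R_xlen_t slab_o = (R_xlen_t)Xo * Yo * Zo;
  NumericVector y(slab_o * C);
  IntegerVector arg(slab_o * C);
  const double *xp = x.begin();

  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < Zo; ++k) {
      for (int j = 0; j < Yo; ++j) {
        for (int i = 0; i < Xo; ++i) {
          double best = -HUGE_VAL;
          R_xlen_t bidx = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const R_xlen_t ii =
                  idx4(2 * i + di, 2 * j + dj, 2 * k + dk, c, X, Y, Z);
                if (xp[ii] > best) { best = xp[ii]; bidx = ii; }
              }
          const R_xlen_t oo = idx4(i, j, k, c, Xo, Yo, Zo);
          y[oo] = best;
          arg[oo] = (int)bidx;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(Named("y") = y, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector gy, IntegerVector argmax,
                          IntegerVector xd) {
  const R_xlen_t n = (R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3];
  NumericVector gx(n);
  for (R_xlen_t v = 0; v < gy.size(); ++v) gx[argmax[v]] += gy[v];
  gx.attr("dim") = xd;
  return gx;
}

// Affine resampling of a 3D volume.  A is a 3x4 matrix (column-major, 12
// values) mapping 0-based OUTPUT voxel coordinates to 0-based INPUT
// coordinates.  nearest = true uses nearest-neighbour (for label maps),
// otherwise trilinear.  Out-of-bounds samples take `fill`.
// [[Rcpp::export(name = ".affine_resample")]]
NumericVector affine_resample(NumericVector vol, IntegerVector vd,
                              NumericVector A, IntegerVector od,
                              bool nearest, double fill) {
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int Xo = od[0], Yo = od[1], Zo = od[2];
  NumericVector out((R_xlen_t)Xo * Yo * Zo);
  const double *v = vol.begin();
  const double a11 = A[0], a21 = A[1], a31 = A[2];
  const double a12 = A[3], a22 = A[4], a32 = A[5];
  const double a13 = A[6], a23 = A[7], a33 = A[8];
  const double t1 = A[9], t2 = A[10], t3 = A[11];
  R_xlen_t o = 0;
  for (int k = 0; k < Zo; ++k) {
    for (int j = 0; j < Yo; ++j) {
      for (int i = 0; i < Xo; ++i, ++o) {
        const double xi = a11 * i + a12 * j + a13 * k + t1;
        const double yi = a21 * i + a22 * j + a23 * k + t2;
        const double zi = a31 * i + a32 * j + a33 * k + t3;
        if (nearest) {
          const int ri = (int)std::lround(xi);
          const int rj = (int)std::lround(yi);
          const int rk = (int)std::lround(zi);
          if (ri < 0 || ri >= X || rj < 0 || rj >= Y || rk < 0 || rk >= Z) {
            out[o] = fill;
          } else {
            out[o] = v[(R_xlen_t)ri + (R_xlen_t)X * (rj + (R_xlen_t)Y * rk)];
          }
        } else {
          const int fi = (int)std::floor(xi), fj = (int)std::floor(yi),
                    fk = (int)std::floor(zi);
          if (fi < 0 || fi + 1 >= X || fj < 0 || fj + 1 >= Y ||
              fk < 0 || fk + 1 >= Z) {
            // nearest at the one-voxel border, fill outside
            if (xi < -0.5 || xi > X - 0.5 || yi < -0.5 || yi > Y - 0.5 ||
                zi < -0.5 || zi > Z - 0.5) {
              out[o] = fill;
            } else {
              const int ri = std::min(X - 1, std::max(0, (int)std::lround(xi)));
              const int rj = std::min(Y - 1, std::max(0, (int)std::lround(yi)));
              const int rk = std::min(Z - 1, std::max(0, (int)std::lround(zi)));
              out[o] = v[(R_xlen_t)ri + (R_xlen_t)X * (rj + (R_xlen_t)Y * rk)];
            }
          } else {
            const double dx = xi - fi, dy = yi - fj, dz = zi - fk;
            double acc = 0.0;
            for (int dk = 0; dk < 2; ++dk)
              for (int dj2 = 0; dj2 < 2; ++dj2)
                for (int di = 0; di < 2; ++di) {
                  const double w = (di ? dx : 1 - dx) * (dj2 ? dy : 1 - dy) *
                                   (dk ? dz : 1 - dz);
                  acc += w * v[(R_xlen_t)(fi + di) +
                               (R_xlen_t)X * ((fj + dj2) +
                               (R_xlen_t)Y * (fk + dk))];
                }
            out[o] = acc;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  return out;
}

// Instance-style batch normalization over the spatial dimensions of a
// (V x C) activation matrix: per-channel mean/sd of the current volume.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd_cpp(NumericVector r, int V, int C, NumericVector gamma,
                NumericVector beta, double eps) {
  NumericVector y((R_xlen_t)V * C), xhat((R_xlen_t)V * C), s(C);
  for (int c = 0; c < C; ++c) {
    const double *rc = r.begin() + (R_xlen_t)V * c;
    double m = 0.0, q = 0.0;
    for (int v = 0; v < V; ++v) m += rc[v];
    m /= V;
    for (int v = 0; v < V; ++v) { const double d = rc[v] - m; q += d * d; }
    const double sd = std::sqrt(q / V + eps);
    s[c] = sd;
    const double g = gamma[c], b = beta[c], inv = 1.0 / sd;
    double *xc = xhat.begin() + (R_xlen_t)V * c;
    double *yc = y.begin() + (R_xlen_t)V * c;
    for (int v = 0; v < V; ++v) {
      const double xh = (rc[v] - m) * inv;
      xc[v] = xh;
      yc[v] = g * xh + b;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat, Named("s") = s);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd_cpp(NumericVector gy, NumericVector xhat, NumericVector s,
                NumericVector gamma, int V, int C) {
  NumericVector gx((R_xlen_t)V * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *gc = gy.begin() + (R_xlen_t)V * c;
    const double *xc = xhat.begin() + (R_xlen_t)V * c;
    double dg = 0.0, db = 0.0;
    for (int v = 0; v < V; ++v) { dg += gc[v] * xc[v]; db += gc[v]; }
    dgamma[c] = dg; dbeta[c] = db;
    const double mg = db / V, mgx = dg / V, f = gamma[c] / s[c];
    double *oc = gx.begin() + (R_xlen_t)V * c;
    for (int v = 0; v < V; ++v)
      oc[v] = f * (gc[v] - mg - xc[v] * mgx);
  }
  return List::create(Named("gx") = gx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
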