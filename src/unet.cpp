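// 3D U-Net for single-leg Dixon muscle segmentation, implemented directly on
// float32 buffers. Convolutions are 3x3x3 with zero padding 1 everywhere,
// down-sampling is a stride-2 3x3x3 convolution and up-sampling is
// nearest-neighbour x2 followed by a 3x3x3 convolution, so the output grid
// always equals the input grid. im2col + GEMM (R's BLAS) does the heavy
// lifting; activations use the (n_voxels x channels) layout, which matches an
// R array of dim (X, Y, Z, C) with no repacking.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct D3 {
  int x, y, z;
  arma::uword n() const { return (arma::uword)x * y * z; }
};

static inline D3 half_dims(const D3& d) {
  return D3{(d.x - 1) / 2 + 1, (d.y - 1) / 2 + 1, (d.z - 1) / 2 + 1};
}

// col(:, k + 27*c) holds channel c sampled at kernel offset k, zero padded.
// `col` is reused across calls (set_size only reallocates on shape change).
static void im2col(const fmat& X, const D3& d, int stride, fmat& col, D3& od) {
  const int C = X.n_cols;
  od = (stride == 1) ? d : half_dims(d);
  const uword No = od.n();
  col.set_size(No, 27 * (uword)C);
  const uword slab = (uword)od.x * od.y;
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    for (int k = 0; k < 27; ++k) {
      const int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
      float* dst = col.colptr(k + 27 * (uword)c);
      for (int oz = 0; oz < od.z; ++oz) {
        const int iz = oz * stride + dz;
        if (iz < 0 || iz >= d.z) {
          std::memset(dst + slab * oz, 0, slab * sizeof(float));
          continue;
        }
        for (int oy = 0; oy < od.y; ++oy) {
          const uword obase = (uword)od.x * oy + slab * oz;
          const int iy = oy * stride + dy;
          if (iy < 0 || iy >= d.y) {
            std::memset(dst + obase, 0, (size_t)od.x * sizeof(float));
            continue;
          }
          const uword ibase = (uword)d.x * (iy + (uword)d.y * iz);
          if (stride == 1) {
            const int x0 = std::max(0, -dx), x1 = std::min(d.x, d.x - dx);
            if (x0 > 0) std::memset(dst + obase, 0, (size_t)x0 * sizeof(float));
            if (x1 > x0)
              std::memcpy(dst + obase + x0, src + ibase + x0 + dx,
                          (size_t)(x1 - x0) * sizeof(float));
            if (x1 < od.x)
              std::memset(dst + obase + x1, 0, (size_t)(od.x - x1) * sizeof(float));
          } else {
            for (int ox = 0; ox < od.x; ++ox) {
              const int ix = ox * stride + dx;
              dst[obase + ox] = (ix >= 0 && ix < d.x) ? src[ibase + ix] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col; d = input dims, dcol is (No x 27C)
static void col2im(const fmat& dcol, const D3& d, int stride, int C, fmat& dX) {
  const D3 od = (stride == 1) ? d : half_dims(d);
  dX.zeros(d.n(), C);
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    for (int k = 0; k < 27; ++k) {
      const int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
      const float* src = dcol.colptr(k + 27 * (uword)c);
      for (int oz = 0; oz < od.z; ++oz) {
        const int iz = oz * stride + dz;
        if (iz < 0 || iz >= d.z) continue;
        for (int oy = 0; oy < od.y; ++oy) {
          const int iy = oy * stride + dy;
          if (iy < 0 || iy >= d.y) continue;
          const uword obase = (uword)od.x * (oy + (uword)od.y * oz);
          const uword ibase = (uword)d.x * (iy + (uword)d.y * iz);
          if (stride == 1) {
            const int x0 = std::max(0, -dx), x1 = std::min(d.x, d.x - dx);
            float* dd = dst + ibase + dx;
            const float* ss = src + obase;
            for (int x = x0; x < x1; ++x) dd[x] += ss[x];
          } else {
            for (int ox = 0; ox < od.x; ++ox) {
              const int ix = ox * stride + dx;
              if (ix >= 0 && ix < d.x) dst[ibase + ix] += src[obase + ox];
            }
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Direct stride-1 3x3x3 convolution.
//
// Output voxel (x,y,z) reads input (x+dx, y+dy, z+dz) with weight row
// k + 27*ci, k = (dx+1) + 3*(dy+1) + 9*(dz+1) — the same convention as
// im2col. The hot kernel is register-tiled: x is processed in tiles of TX
// voxels whose COUT running sums live in registers across the whole
// (dz,dy,ci,dx) reduction, with the weight matrix pre-transposed to
// (cout, 27*cin) so each step reads one contiguous weight panel. COUT is a
// compile-time constant for the channel widths the network actually uses;
// other widths fall back to a generic variant of the same loop.
// ---------------------------------------------------------------------------
template <int COUT, int TX>
static void conv3d_tile(const fmat& X, const D3& d, const fmat& Wt, fmat& Y) {
  const int cin = X.n_cols;
  const int Xd = d.x, Yd = d.y, Zd = d.z;
  for (int z = 0; z < Zd; ++z)
    for (int y = 0; y < Yd; ++y) {
      const uword orow = (uword)Xd * (y + (uword)Yd * z);
      for (int x0 = 0; x0 < Xd; x0 += TX) {
        const int tl = std::min(TX, Xd - x0);
        float acc[COUT * TX] = {0};
        const bool interior = (x0 >= 1) && (x0 + TX + 1 <= Xd);
        for (int dz = -1; dz <= 1; ++dz) {
          const int iz = z + dz;
          if (iz < 0 || iz >= Zd) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int iy = y + dy;
            if (iy < 0 || iy >= Yd) continue;
            const uword irow = (uword)Xd * (iy + (uword)Yd * iz);
            const int kyz = 3 * ((dy + 1) + 3 * (dz + 1));
            for (int ci = 0; ci < cin; ++ci) {
              const float* __restrict__ srow = X.colptr(ci) + irow;
              // weight panels for dx = -1, 0, +1 are consecutive Wt columns
              const float* __restrict__ wp = Wt.colptr(kyz + 27 * (uword)ci);
              const float* __restrict__ s;
              float tmp[TX + 2];
              if (interior) {
                s = srow + x0 - 1;
              } else {
                for (int j = -1; j <= TX; ++j) {
                  const int xx = x0 + j;
                  tmp[j + 1] = (xx >= 0 && xx < Xd) ? srow[xx] : 0.0f;
                }
                s = tmp;
              }
              for (int co = 0; co < COUT; ++co) {
                const float w0 = wp[co], w1 = wp[COUT + co], w2 = wp[2 * COUT + co];
                float* __restrict__ a = acc + co * TX;
                for (int j = 0; j < TX; ++j)
                  a[j] += s[j] * w0 + s[j + 1] * w1 + s[j + 2] * w2;
              }
            }
          }
        }
        for (int co = 0; co < COUT; ++co) {
          float* __restrict__ yr = Y.colptr(co) + orow + x0;
          for (int j = 0; j < tl; ++j) yr[j] += acc[co * TX + j];
        }
      }
    }
}

static void conv3d_tile_gen(const fmat& X, const D3& d, const fmat& Wt, fmat& Y) {
  const int TX = 16;
  const int cin = X.n_cols, cout = Y.n_cols;
  const int Xd = d.x, Yd = d.y, Zd = d.z;
  std::vector<float> accv((size_t)cout * TX);
  float* __restrict__ acc = accv.data();
  for (int z = 0; z < Zd; ++z)
    for (int y = 0; y < Yd; ++y) {
      const uword orow = (uword)Xd * (y + (uword)Yd * z);
      for (int x0 = 0; x0 < Xd; x0 += TX) {
        const int tl = std::min(TX, Xd - x0);
        std::memset(acc, 0, (size_t)cout * TX * sizeof(float));
        const bool interior = (x0 >= 1) && (x0 + TX + 1 <= Xd);
        for (int dz = -1; dz <= 1; ++dz) {
          const int iz = z + dz;
          if (iz < 0 || iz >= Zd) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int iy = y + dy;
            if (iy < 0 || iy >= Yd) continue;
            const uword irow = (uword)Xd * (iy + (uword)Yd * iz);
            const int kyz = 3 * ((dy + 1) + 3 * (dz + 1));
            for (int ci = 0; ci < cin; ++ci) {
              const float* __restrict__ srow = X.colptr(ci) + irow;
              const float* __restrict__ wp = Wt.colptr(kyz + 27 * (uword)ci);
              const float* __restrict__ s;
              float tmp[TX + 2];
              if (interior) {
                s = srow + x0 - 1;
              } else {
                for (int j = -1; j <= TX; ++j) {
                  const int xx = x0 + j;
                  tmp[j + 1] = (xx >= 0 && xx < Xd) ? srow[xx] : 0.0f;
                }
                s = tmp;
              }
              for (int co = 0; co < cout; ++co) {
                const float w0 = wp[co], w1 = wp[cout + co], w2 = wp[2 * cout + co];
                float* __restrict__ a = acc + (size_t)co * TX;
                for (int j = 0; j < TX; ++j)
                  a[j] += s[j] * w0 + s[j + 1] * w1 + s[j + 2] * w2;
              }
            }
          }
        }
        for (int co = 0; co < cout; ++co) {
          float* __restrict__ yr = Y.colptr(co) + orow + x0;
          for (int j = 0; j < tl; ++j) yr[j] += acc[(size_t)co * TX + j];
        }
      }
    }
}

static void conv3d_direct(const fmat& X, const D3& d, const fmat& W, fmat& Y) {
  const fmat Wt = W.t();  // (cout, 27*cin): contiguous weight panels
  switch ((int)Y.n_cols) {
    case 8:  conv3d_tile<8, 24>(X, d, Wt, Y); break;
    case 16: conv3d_tile<16, 24>(X, d, Wt, Y); break;
    case 32: conv3d_tile<32, 8>(X, d, Wt, Y); break;
    case 64: conv3d_tile<64, 8>(X, d, Wt, Y); break;
    default: conv3d_tile_gen(X, d, Wt, Y); break;
  }
}

// weight gradient for the direct path: dW[k + 27*ci, co] += X(j+d, ci) * dY(j, co).
// Per input channel the row is copied once into a zero-padded buffer; the
// three x-offsets then come out of one pass of shifted lane-parallel dot
// products against each dY row.
static const int DW_LANES = 16;

static void conv3d_dw(const fmat& X, const fmat& dY, const D3& d, mat& dWacc) {
  const int cin = X.n_cols, cout = dY.n_cols;
  const int Xd = d.x, Yd = d.y, Zd = d.z;
  const int nx = (Xd + DW_LANES - 1) / DW_LANES * DW_LANES;
  std::vector<float> padv(nx + 2 * DW_LANES, 0.0f);
  float* const pad = padv.data() + DW_LANES;  // pad[-1] and pad[Xd] valid zeros
  std::vector<float> ddpv((size_t)cout * nx, 0.0f);
  // lane accumulators, reduced only once at the end; index ((k + 27*ci)*cout + co)
  std::vector<float> laccv((size_t)27 * cin * cout * DW_LANES, 0.0f);
  float* const lacc = laccv.data();
  const size_t cstride = (size_t)cout * DW_LANES;
  for (int z = 0; z < Zd; ++z)
    for (int y = 0; y < Yd; ++y) {
      const uword orow = (uword)Xd * (y + (uword)Yd * z);
      for (int co = 0; co < cout; ++co)
        std::memcpy(ddpv.data() + (size_t)co * nx, dY.colptr(co) + orow,
                    (size_t)Xd * sizeof(float));
      for (int dz = -1; dz <= 1; ++dz) {
        const int iz = z + dz;
        if (iz < 0 || iz >= Zd) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int iy = y + dy;
          if (iy < 0 || iy >= Yd) continue;
          const uword irow = (uword)Xd * (iy + (uword)Yd * iz);
          const int kyz = 3 * ((dy + 1) + 3 * (dz + 1));
          for (int ci = 0; ci < cin; ++ci) {
            std::memcpy(pad, X.colptr(ci) + irow, (size_t)Xd * sizeof(float));
            if (Xd < nx) std::memset(pad + Xd, 0, (size_t)(nx - Xd) * sizeof(float));
            float* const lbase = lacc + ((size_t)kyz + 27 * (size_t)ci) * cstride;
            const float* __restrict__ pp = pad;
            for (int co = 0; co < cout; ++co) {
              const float* __restrict__ ddp = ddpv.data() + (size_t)co * nx;
              float r0[DW_LANES] = {0}, r1[DW_LANES] = {0}, r2[DW_LANES] = {0};
              for (int x = 0; x < nx; x += DW_LANES)
                for (int j = 0; j < DW_LANES; ++j) {
                  const float v = ddp[x + j];
                  r0[j] += pp[x + j - 1] * v;
                  r1[j] += pp[x + j] * v;
                  r2[j] += pp[x + j + 1] * v;
                }
              float* __restrict__ a0 = lbase + (size_t)co * DW_LANES;
              float* __restrict__ a1 = a0 + cstride;
              float* __restrict__ a2 = a1 + cstride;
              for (int j = 0; j < DW_LANES; ++j) {
                a0[j] += r0[j];
                a1[j] += r1[j];
                a2[j] += r2[j];
              }
            }
          }
        }
      }
    }
  for (int ci = 0; ci < cin; ++ci)
    for (int k = 0; k < 27; ++k) {
      const float* l = lacc + ((size_t)k + 27 * (size_t)ci) * cstride;
      for (int co = 0; co < cout; ++co) {
        double a = 0;
        for (int j = 0; j < DW_LANES; ++j) a += l[(size_t)co * DW_LANES + j];
        dWacc(k + 27 * (uword)ci, co) += a;
      }
    }
}

// the data gradient of a stride-1 conv is a stride-1 conv of dY with the
// kernel flipped in all three offsets and in/out channels swapped
static fmat flip_weights(const fmat& W, int cin, int cout) {
  fmat Wt(27 * (uword)cout, cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int k = 0; k < 27; ++k)
      for (int co = 0; co < cout; ++co)
        Wt((26 - k) + 27 * (uword)co, ci) = W(k + 27 * (uword)ci, co);
  return Wt;
}

static const float IN_EPS = 1e-5f;
static const float ADAM_B1 = 0.9f, ADAM_B2 = 0.999f, ADAM_EPS = 1e-8f;

struct AdamState {
  fmat m, v;
  void init(uword r, uword c) { m.zeros(r, c); v.zeros(r, c); }
  void step(fmat& w, const fmat& g, float lr, long t) {
    m = ADAM_B1 * m + (1.0f - ADAM_B1) * g;
    v = ADAM_B2 * v + (1.0f - ADAM_B2) * square(g);
    const float bc1 = 1.0f - std::pow(ADAM_B1, (float)t);
    const float bc2 = 1.0f - std::pow(ADAM_B2, (float)t);
    w -= (lr / bc1) * (m / (sqrt(v / bc2) + ADAM_EPS));
  }
};

// conv -> (optional) instance norm -> (optional) ReLU
struct Conv {
  int cin = 0, cout = 0, stride = 1;
  bool norm = true, relu = true, bias = false;
  fmat W;                 // (27*cin, cout)
  fvec b, g, bt;          // bias / norm scale / norm shift
  AdamState aW, ab, ag, abt;
  // saved during a training forward pass
  fmat xhat;
  fvec invstd;
  // gradient-check mode: raw gradients stored here instead of updating
  bool collect = false;
  fmat gW; fvec gb, gg_, gbt;
  D3 din{0, 0, 0}, dout{0, 0, 0};

  void setup(int ci, int co, int s, bool nrm, bool rl, bool bi) {
    cin = ci; cout = co; stride = s; norm = nrm; relu = rl; bias = bi;
    W.zeros(27 * (uword)ci, co);
    aW.init(W.n_rows, W.n_cols);
    if (bias) { b.zeros(co); ab.init(co, 1); }
    if (norm) {
      g.ones(co); bt.zeros(co);
      ag.init(co, 1); abt.init(co, 1);
    }
  }

  fmat col, dcol;  // persistent im2col buffers (stride-2 path only)
  fmat xin;        // saved input (stride-1 path)

  fmat fwd(const fmat& x, const D3& d, bool save) {
    D3 od;
    fmat z;
    if (stride == 1) {
      od = d;
      z.zeros(d.n(), cout);
      conv3d_direct(x, d, W, z);
      if (save) xin = x;
    } else {
      im2col(x, d, stride, col, od);
      z = col * W;
    }
    if (bias) z.each_row() += b.t();
    if (norm) {
      // lane-parallel moments pass, then a branchless normalize+affine+ReLU pass
      const uword N = z.n_rows;
      if (save) { xhat.set_size(N, cout); invstd.set_size(cout); }
      for (int c = 0; c < cout; ++c) {
        float* __restrict__ zc = z.colptr(c);
        float l1[16] = {0}, l2[16] = {0};
        uword i = 0;
        for (; i + 16 <= N; i += 16)
          for (int j = 0; j < 16; ++j) {
            const float v = zc[i + j];
            l1[j] += v;
            l2[j] += v * v;
          }
        double s1 = 0.0, s2 = 0.0;
        for (; i < N; ++i) { s1 += zc[i]; s2 += (double)zc[i] * zc[i]; }
        for (int j = 0; j < 16; ++j) { s1 += l1[j]; s2 += l2[j]; }
        const double mu = s1 / N;
        const double va = std::max(0.0, s2 / N - mu * mu);
        const float is = (float)(1.0 / std::sqrt(va + IN_EPS));
        const float gg = g(c), bb = bt(c), fmu = (float)mu;
        if (save) {
          float* __restrict__ xh = xhat.colptr(c);
          if (relu) {
            for (uword q = 0; q < N; ++q) {
              const float v = (zc[q] - fmu) * is;
              xh[q] = v;
              const float o = gg * v + bb;
              zc[q] = o > 0 ? o : 0.0f;
            }
          } else {
            for (uword q = 0; q < N; ++q) {
              const float v = (zc[q] - fmu) * is;
              xh[q] = v;
              zc[q] = gg * v + bb;
            }
          }
          invstd(c) = is;
        } else if (relu) {
          for (uword q = 0; q < N; ++q) {
            const float o = gg * (zc[q] - fmu) * is + bb;
            zc[q] = o > 0 ? o : 0.0f;
          }
        } else {
          for (uword q = 0; q < N; ++q) zc[q] = gg * (zc[q] - fmu) * is + bb;
        }
      }
    } else if (relu) {
      float* __restrict__ zp = z.memptr();
      for (uword i = 0; i < z.n_elem; ++i) zp[i] = zp[i] > 0 ? zp[i] : 0.0f;
    }
    if (save) { din = d; dout = od; }
    return z;
  }

  // dy = grad wrt output (modified in place); updates parameters via Adam;
  // returns grad wrt input when need_dx
  fmat bwd(fmat dy, bool need_dx, float lr, long t) {
    const uword N = dy.n_rows;
    if (relu && !norm) Rcpp::stop("internal error: ReLU without norm has no saved mask");
    if (norm) {
      // ReLU gate recomputed from xhat (output was g*xhat + bt, clamped at 0)
      fvec dg(cout), dbt(cout);
      for (int c = 0; c < cout; ++c) {
        const float* __restrict__ xh = xhat.colptr(c);
        float* __restrict__ dd = dy.colptr(c);
        const float gg = g(c), bb = bt(c);
        if (relu)
          for (uword i = 0; i < N; ++i)
            dd[i] = (gg * xh[i] + bb > 0) ? dd[i] : 0.0f;
        float lg[16] = {0}, lb[16] = {0};
        uword i = 0;
        for (; i + 16 <= N; i += 16)
          for (int j = 0; j < 16; ++j) {
            const float v = dd[i + j];
            lg[j] += v * xh[i + j];
            lb[j] += v;
          }
        double sg = 0.0, sb = 0.0;
        for (; i < N; ++i) { sg += (double)dd[i] * xh[i]; sb += dd[i]; }
        for (int j = 0; j < 16; ++j) { sg += lg[j]; sb += lb[j]; }
        dg(c) = (float)sg;
        dbt(c) = (float)sb;
        const float a = gg * invstd(c);
        const float mg = (float)(sg / N), mb = (float)(sb / N);
        for (uword q = 0; q < N; ++q)
          dd[q] = a * (dd[q] - mb - xh[q] * mg);
      }
      if (collect) { gg_ = dg; gbt = dbt; }
      else {
        ag.step(g, dg, lr, t);
        abt.step(bt, dbt, lr, t);
      }
    }
    fmat dW;
    fmat dX;
    if (stride == 1) {
      mat dWacc(27 * (uword)cin, cout, fill::zeros);
      conv3d_dw(xin, dy, din, dWacc);
      dW = conv_to<fmat>::from(dWacc);
      if (need_dx) {
        fmat Wf = flip_weights(W, cin, cout);
        dX.zeros(din.n(), cin);
        conv3d_direct(dy, din, Wf, dX);
      }
      xin.reset();
    } else {
      dW = col.t() * dy;
      if (need_dx) {
        dcol = dy * W.t();
        col2im(dcol, din, stride, cin, dX);
      }
    }
    if (bias) {
      fvec db = sum(dy, 0).t();
      if (collect) gb = db; else ab.step(b, db, lr, t);
    }
    if (collect) gW = dW; else aW.step(W, dW, lr, t);
    xhat.reset();
    return dX;
  }

  uword n_params() const {
    return W.n_elem + b.n_elem + g.n_elem + bt.n_elem;
  }
};

static fmat upsample2(const fmat& X, const D3& d, D3& od) {
  od = D3{2 * d.x, 2 * d.y, 2 * d.z};
  fmat Y(od.n(), X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    for (int z = 0; z < od.z; ++z)
      for (int y = 0; y < od.y; ++y) {
        const uword ibase = (uword)d.x * ((y / 2) + (uword)d.y * (z / 2));
        const uword obase = (uword)od.x * (y + (uword)od.y * z);
        for (int x = 0; x < od.x; ++x) dst[obase + x] = src[ibase + x / 2];
      }
  }
  return Y;
}

static fmat upsample2_bwd(const fmat& dY, const D3& d /* small dims */) {
  const D3 od{2 * d.x, 2 * d.y, 2 * d.z};
  fmat dX(d.n(), dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const float* src = dY.colptr(c);
    float* dst = dX.colptr(c);
    for (int z = 0; z < od.z; ++z)
      for (int y = 0; y < od.y; ++y) {
        const uword ibase = (uword)d.x * ((y / 2) + (uword)d.y * (z / 2));
        const uword obase = (uword)od.x * (y + (uword)od.y * z);
        for (int x = 0; x < od.x; ++x) dst[ibase + x / 2] += src[obase + x];
      }
  }
  return dX;
}

class UNet {
 public:
  int depth, base, growth, in_ch, K;
  std::vector<int> chans;
  std::vector<Conv> enc;   // 2 per encoder level
  std::vector<Conv> down;  // depth-1
  std::vector<Conv> deep;  // 4 convs at the deepest level
  std::vector<Conv> up;    // depth-1, indexed by target level
  std::vector<Conv> dec;   // 2 per decoder level
  Conv fin;
  long t_adam = 0;
  // forward-pass state for backward
  std::vector<fmat> skips;
  std::vector<D3> sdims;

  UNet(int depth_, int base_, int growth_, int in_ch_, int K_)
      : depth(depth_), base(base_), growth(growth_), in_ch(in_ch_), K(K_) {
    if (depth < 2) Rcpp::stop("model depth must be >= 2");
    chans.resize(depth);
    chans[0] = base;
    for (int l = 1; l < depth; ++l) chans[l] = chans[l - 1] * growth;
    enc.resize(2 * (depth - 1));
    down.resize(depth - 1);
    deep.resize(4);
    up.resize(depth - 1);
    dec.resize(2 * (depth - 1));
    for (int l = 0; l < depth - 1; ++l) {
      enc[2 * l].setup(l == 0 ? in_ch : chans[l - 1], chans[l], 1, true, true, false);
      enc[2 * l + 1].setup(chans[l], chans[l], 1, true, true, false);
      down[l].setup(chans[l], chans[l], 2, true, true, false);
      up[l].setup(chans[l + 1], chans[l], 1, true, true, false);
      dec[2 * l].setup(2 * chans[l], chans[l], 1, true, true, false);
      dec[2 * l + 1].setup(chans[l], chans[l], 1, true, true, false);
    }
    deep[0].setup(chans[depth - 2], chans[depth - 1], 1, true, true, false);
    for (int j = 1; j < 4; ++j)
      deep[j].setup(chans[depth - 1], chans[depth - 1], 1, true, true, false);
    fin.setup(chans[0], K, 1, false, false, true);
  }

  void check_dims(const D3& d) const {
    const int m = 1 << (depth - 1);
    if (d.x % m || d.y % m || d.z % m)
      Rcpp::stop("input shape (%d, %d, %d) must be divisible by %d (= 2^(depth-1)) along every axis",
                 d.x, d.y, d.z, m);
  }

  fmat forward(const fmat& x0, const D3& d, bool save) {
    check_dims(d);
    fmat cur = x0;
    D3 dc = d;
    skips.assign(depth - 1, fmat());
    sdims.assign(depth - 1, D3{0, 0, 0});
    for (int l = 0; l < depth - 1; ++l) {
      cur = enc[2 * l].fwd(cur, dc, save);
      cur = enc[2 * l + 1].fwd(cur, dc, save);
      skips[l] = cur;
      sdims[l] = dc;
      cur = down[l].fwd(cur, dc, save);
      dc = half_dims(dc);
    }
    for (int j = 0; j < 4; ++j) cur = deep[j].fwd(cur, dc, save);
    for (int l = depth - 2; l >= 0; --l) {
      // 3x3x3 up-convolution applied on the coarse grid, then NN x2 upsampling
      // (computes at the same resolution a stride-2 transposed conv would)
      cur = up[l].fwd(cur, dc, save);
      D3 od;
      cur = upsample2(cur, dc, od);
      dc = od;
      cur = join_rows(skips[l], cur);
      cur = dec[2 * l].fwd(cur, dc, save);
      cur = dec[2 * l + 1].fwd(cur, dc, save);
    }
    return fin.fwd(cur, dc, save);
  }

  void backward(fmat dlogits, float lr) {
    ++t_adam;
    fmat dcur = fin.bwd(std::move(dlogits), true, lr, t_adam);
    std::vector<fmat> dskips(depth - 1);
    for (int l = 0; l < depth - 1; ++l) {
      dcur = dec[2 * l + 1].bwd(std::move(dcur), true, lr, t_adam);
      dcur = dec[2 * l].bwd(std::move(dcur), true, lr, t_adam);
      const int c = chans[l];
      dskips[l] = dcur.cols(0, c - 1);
      fmat dup = dcur.cols(c, 2 * c - 1);
      dup = upsample2_bwd(dup, half_dims(sdims[l]));
      dcur = up[l].bwd(std::move(dup), true, lr, t_adam);
    }
    for (int j = 3; j >= 0; --j) dcur = deep[j].bwd(std::move(dcur), true, lr, t_adam);
    for (int l = depth - 2; l >= 0; --l) {
      dcur = down[l].bwd(std::move(dcur), true, lr, t_adam);
      dcur += dskips[l];
      dcur = enc[2 * l + 1].bwd(std::move(dcur), true, lr, t_adam);
      dcur = enc[2 * l].bwd(std::move(dcur), l > 0, lr, t_adam);
    }
    skips.clear();
    sdims.clear();
  }

  std::vector<Conv*> all_layers() {
    std::vector<Conv*> v;
    for (int l = 0; l < depth - 1; ++l) {
      v.push_back(&enc[2 * l]);
      v.push_back(&enc[2 * l + 1]);
      v.push_back(&down[l]);
    }
    for (int j = 0; j < 4; ++j) v.push_back(&deep[j]);
    for (int l = depth - 2; l >= 0; --l) {
      v.push_back(&up[l]);
      v.push_back(&dec[2 * l]);
      v.push_back(&dec[2 * l + 1]);
    }
    v.push_back(&fin);
    return v;
  }
};

static fmat softmax_rows(const fmat& logits) {
  fvec mx = max(logits, 1);
  fmat P = logits;
  P.each_col() -= mx;
  P = exp(P);
  fvec s = sum(P, 1);
  P.each_col() /= s;
  return P;
}

static fmat as_fmat(const Rcpp::NumericVector& x, uword nrow, uword ncol) {
  if ((uword)x.size() != nrow * ncol)
    Rcpp::stop("input length %d does not match expected %d x %d", x.size(), nrow, ncol);
  fmat M(nrow, ncol);
  const double* p = x.begin();
  float* q = M.memptr();
  for (uword i = 0; i < nrow * ncol; ++i) q[i] = (float)p[i];
  return M;
}

static D3 as_d3(const Rcpp::IntegerVector& dims) {
  if (dims.size() != 3) Rcpp::stop("dims must have length 3");
  return D3{dims[0], dims[1], dims[2]};
}

// raw 3x3x3 convolution (no norm/ReLU/bias), selectable code path; exposed
// so the direct kernel can be cross-checked against the im2col+GEMM route
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv3d(Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                               Rcpp::NumericVector w, int cin, int cout,
                               int stride, bool direct) {
  const D3 d = as_d3(dims);
  fmat X = as_fmat(x, d.n(), cin);
  fmat W = as_fmat(w, 27 * (uword)cin, cout);
  fmat Y;
  if (direct) {
    if (stride != 1) Rcpp::stop("direct path is stride-1 only");
    Y.zeros(d.n(), cout);
    conv3d_direct(X, d, W, Y);
  } else {
    fmat col; D3 od;
    im2col(X, d, stride, col, od);
    Y = col * W;
  }
  Rcpp::NumericMatrix out(Y.n_rows, Y.n_cols);
  std::copy(Y.begin(), Y.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
SEXP unet_create(int depth, int base_filters, int growth, int in_channels, int n_classes) {
  Rcpp::XPtr<UNet> p(new UNet(depth, base_filters, growth, in_channels, n_classes), true);
  return p;
}

// [[Rcpp::export]]
Rcpp::List unet_param_info(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  auto ls = net->all_layers();
  Rcpp::CharacterVector name;
  Rcpp::IntegerVector size, fanin;
  Rcpp::CharacterVector kind;
  for (size_t i = 0; i < ls.size(); ++i) {
    const std::string id = "layer" + std::to_string(i);
    name.push_back(id + ".W"); size.push_back(ls[i]->W.n_elem);
    fanin.push_back(27 * ls[i]->cin); kind.push_back("weight");
    if (ls[i]->bias) {
      name.push_back(id + ".b"); size.push_back(ls[i]->b.n_elem);
      fanin.push_back(0); kind.push_back("bias");
    }
    if (ls[i]->norm) {
      name.push_back(id + ".g"); size.push_back(ls[i]->g.n_elem);
      fanin.push_back(0); kind.push_back("scale");
      name.push_back(id + ".bt"); size.push_back(ls[i]->bt.n_elem);
      fanin.push_back(0); kind.push_back("shift");
    }
  }
  return Rcpp::List::create(Rcpp::Named("name") = name, Rcpp::Named("size") = size,
                            Rcpp::Named("fan_in") = fanin, Rcpp::Named("kind") = kind);
}

// [[Rcpp::export]]
Rcpp::List unet_get_params(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  auto ls = net->all_layers();
  Rcpp::List out;
  for (size_t i = 0; i < ls.size(); ++i) {
    const std::string id = "layer" + std::to_string(i);
    out[id + ".W"] = Rcpp::NumericVector(ls[i]->W.begin(), ls[i]->W.end());
    if (ls[i]->bias) out[id + ".b"] = Rcpp::NumericVector(ls[i]->b.begin(), ls[i]->b.end());
    if (ls[i]->norm) {
      out[id + ".g"] = Rcpp::NumericVector(ls[i]->g.begin(), ls[i]->g.end());
      out[id + ".bt"] = Rcpp::NumericVector(ls[i]->bt.begin(), ls[i]->bt.end());
    }
  }
  return out;
}

static void fill_from(const Rcpp::List& params, const std::string& key, fmat& M) {
  Rcpp::NumericVector v = params[key];
  if ((uword)v.size() != M.n_elem) Rcpp::stop("parameter %s has wrong length", key.c_str());
  for (uword i = 0; i < M.n_elem; ++i) M.memptr()[i] = (float)v[i];
}
static void fill_from(const Rcpp::List& params, const std::string& key, fvec& V) {
  Rcpp::NumericVector v = params[key];
  if ((uword)v.size() != V.n_elem) Rcpp::stop("parameter %s has wrong length", key.c_str());
  for (uword i = 0; i < V.n_elem; ++i) V(i) = (float)v[i];
}

// [[Rcpp::export]]
void unet_set_params(SEXP ptr, Rcpp::List params) {
  Rcpp::XPtr<UNet> net(ptr);
  auto ls = net->all_layers();
  for (size_t i = 0; i < ls.size(); ++i) {
    const std::string id = "layer" + std::to_string(i);
    fill_from(params, id + ".W", ls[i]->W);
    if (ls[i]->bias) fill_from(params, id + ".b", ls[i]->b);
    if (ls[i]->norm) {
      fill_from(params, id + ".g", ls[i]->g);
      fill_from(params, id + ".bt", ls[i]->bt);
    }
  }
}

// [[Rcpp::export]]
void unet_reset_adam(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  net->t_adam = 0;
  for (Conv* c : net->all_layers()) {
    c->aW.init(c->W.n_rows, c->W.n_cols);
    if (c->bias) c->ab.init(c->b.n_elem, 1);
    if (c->norm) { c->ag.init(c->g.n_elem, 1); c->abt.init(c->bt.n_elem, 1); }
  }
}

// [[Rcpp::export]]
double unet_n_params(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  double n = 0;
  for (Conv* c : net->all_layers()) n += c->n_params();
  return n;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix unet_predict(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  Rcpp::XPtr<UNet> net(ptr);
  const D3 d = as_d3(dims);
  fmat X = as_fmat(x, d.n(), net->in_ch);
  fmat P = softmax_rows(net->forward(X, d, false));
  Rcpp::NumericMatrix out(P.n_rows, P.n_cols);
  std::copy(P.begin(), P.end(), out.begin());
  return out;
}

static double ce_loss(const fmat& P, const Rcpp::IntegerVector& labels) {
  double loss = 0.0;
  for (uword i = 0; i < P.n_rows; ++i) {
    const int k = labels[i];
    loss -= std::log(std::max(P(i, k), 1e-12f));
  }
  return loss / P.n_rows;
}

static void check_labels(const Rcpp::IntegerVector& labels, uword n, int K) {
  if ((uword)labels.size() != n) Rcpp::stop("label volume does not match input grid");
  for (uword i = 0; i < n; ++i)
    if (labels[i] < 0 || labels[i] >= K) Rcpp::stop("label id %d outside [0, %d]", labels[i], K - 1);
}

// [[Rcpp::export]]
double unet_eval_loss(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                      Rcpp::IntegerVector labels) {
  Rcpp::XPtr<UNet> net(ptr);
  const D3 d = as_d3(dims);
  check_labels(labels, d.n(), net->K);
  fmat X = as_fmat(x, d.n(), net->in_ch);
  fmat P = softmax_rows(net->forward(X, d, false));
  return ce_loss(P, labels);
}

// gradients of the mean voxel cross-entropy wrt every parameter, leaving the
// parameters and optimizer state untouched (for finite-difference checks)
// [[Rcpp::export]]
Rcpp::List unet_gradients(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                          Rcpp::IntegerVector labels) {
  Rcpp::XPtr<UNet> net(ptr);
  const D3 d = as_d3(dims);
  check_labels(labels, d.n(), net->K);
  fmat X = as_fmat(x, d.n(), net->in_ch);
  for (Conv* c : net->all_layers()) c->collect = true;
  fmat P = softmax_rows(net->forward(X, d, true));
  const float invn = 1.0f / P.n_rows;
  for (uword i = 0; i < P.n_rows; ++i) P(i, labels[i]) -= 1.0f;
  P *= invn;
  net->backward(std::move(P), 0.0f);
  --net->t_adam;  // collection does not consume an optimizer step
  Rcpp::List out;
  auto ls = net->all_layers();
  for (size_t i = 0; i < ls.size(); ++i) {
    const std::string id = "layer" + std::to_string(i);
    out[id + ".W"] = Rcpp::NumericVector(ls[i]->gW.begin(), ls[i]->gW.end());
    if (ls[i]->bias) out[id + ".b"] = Rcpp::NumericVector(ls[i]->gb.begin(), ls[i]->gb.end());
    if (ls[i]->norm) {
      out[id + ".g"] = Rcpp::NumericVector(ls[i]->gg_.begin(), ls[i]->gg_.end());
      out[id + ".bt"] = Rcpp::NumericVector(ls[i]->gbt.begin(), ls[i]->gbt.end());
    }
    ls[i]->collect = false;
    ls[i]->gW.reset(); ls[i]->gb.reset(); ls[i]->gg_.reset(); ls[i]->gbt.reset();
  }
  return out;
}

// [[Rcpp::export]]
double unet_train_step(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                       Rcpp::IntegerVector labels, double lr) {
  Rcpp::XPtr<UNet> net(ptr);
  const D3 d = as_d3(dims);
  check_labels(labels, d.n(), net->K);
  fmat X = as_fmat(x, d.n(), net->in_ch);
  fmat P = softmax_rows(net->forward(X, d, true));
  const double loss = ce_loss(P, labels);
  const float invn = 1.0f / P.n_rows;
  for (uword i = 0; i < P.n_rows; ++i) P(i, labels[i]) -= 1.0f;
  P *= invn;
  net->backward(std::move(P), (float)lr);
  return loss;
}
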