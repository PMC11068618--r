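// Hot inner loops of the 3D network layers: im2col patch gathering for
// the GEMM-based convolutions and trilinear deformable sampling with
// its backward pass.  Everything else (GEMMs, normalisation, autodiff
// bookkeeping) stays in R.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Same-padded 3D convolution, forward.  x: nvox x Cin; idx: nvox*K
// neighbour map (1-based, 0 = outside); W: (K*Cin) x Cout with rows
// tap-fastest within channel blocks; b: length Cout.  Accumulates one
// dgemm per kernel tap over a reused gather buffer, so no K*Cin patch
// matrix is ever materialised.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& x, const IntegerVector& idx,
                           int K, const NumericMatrix& W,
                           const NumericVector& b) {
  const int nvox = x.nrow(), Cin = x.ncol(), Cout = W.ncol();
  NumericMatrix out(nvox, Cout);
  for (int o = 0; o < Cout; ++o) {
    double* oc = out.begin() + (size_t)nvox * o;
    const double bo = b[o];
    for (int v = 0; v < nvox; ++v) oc[v] = bo;
  }
  std::vector<double> xbuf((size_t)nvox * Cin);
  std::vector<double> wt((size_t)Cin * Cout);
  const double one = 1.0;
  const char* N = "N";
  for (int t = 0; t < K; ++t) {
    const int* it = idx.begin() + (size_t)nvox * t;
    for (int c = 0; c < Cin; ++c) {
      const double* xc = x.begin() + (size_t)nvox * c;
      double* bc = xbuf.data() + (size_t)nvox * c;
      for (int v = 0; v < nvox; ++v) {
        const int j = it[v];
        bc[v] = j > 0 ? xc[j - 1] : 0.0;
      }
      for (int o = 0; o < Cout; ++o)
        wt[c + (size_t)Cin * o] = W[(t + (size_t)K * c) + (size_t)(K * Cin) * o];
    }
    F77_CALL(dgemm)(N, N, &nvox, &Cout, &Cin, &one, xbuf.data(), &nvox,
                    wt.data(), &Cin, &one, out.begin(), &nvox
                    FCONE FCONE);
  }
  return out;
}

// Backward of cpp_conv_fwd: returns dx (nvox x Cin), dW, db.
// [[Rcpp::export]]
List cpp_conv_bwd(const NumericMatrix& x, const IntegerVector& idx, int K,
                  const NumericMatrix& W, const NumericMatrix& g) {
  const int nvox = x.nrow(), Cin = x.ncol(), Cout = W.ncol();
  NumericMatrix dx(nvox, Cin), dW(K * Cin, Cout);
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) {
    const double* gc = g.begin() + (size_t)nvox * o;
    double s = 0.0;
    for (int v = 0; v < nvox; ++v) s += gc[v];
    db[o] = s;
  }
  std::vector<double> xbuf((size_t)nvox * Cin);
  std::vector<double> dwt((size_t)Cin * Cout);
  std::vector<double> dxbuf((size_t)nvox * Cin);
  const double one = 1.0, zero = 0.0;
  const char* N = "N";
  const char* T = "T";
  for (int t = 0; t < K; ++t) {
    const int* it = idx.begin() + (size_t)nvox * t;
    std::vector<double> wt((size_t)Cin * Cout);
    for (int c = 0; c < Cin; ++c) {
      const double* xc = x.begin() + (size_t)nvox * c;
      double* bc = xbuf.data() + (size_t)nvox * c;
      for (int v = 0; v < nvox; ++v) {
        const int j = it[v];
        bc[v] = j > 0 ? xc[j - 1] : 0.0;
      }
      for (int o = 0; o < Cout; ++o)
        wt[c + (size_t)Cin * o] = W[(t + (size_t)K * c) + (size_t)(K * Cin) * o];
    }
    // dW_t = xbuf^T g
    F77_CALL(dgemm)(T, N, &Cin, &Cout, &nvox, &one, xbuf.data(), &nvox,
                    g.begin(), &nvox, &zero, dwt.data(), &Cin FCONE FCONE);
    for (int c = 0; c < Cin; ++c)
      for (int o = 0; o < Cout; ++o)
        dW[(t + (size_t)K * c) + (size_t)(K * Cin) * o] = dwt[c + (size_t)Cin * o];
    // dxbuf = g W_t^T, scattered back through the neighbour map
    F77_CALL(dgemm)(N, T, &nvox, &Cin, &Cout, &one, g.begin(), &nvox,
                    wt.data(), &Cin, &zero, dxbuf.data(), &nvox FCONE FCONE);
    for (int c = 0; c < Cin; ++c) {
      double* dxc = dx.begin() + (size_t)nvox * c;
      const double* bc = dxbuf.data() + (size_t)nvox * c;
      for (int v = 0; v < nvox; ++v) {
        const int j = it[v];
        if (j > 0) dxc[j - 1] += bc[v];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline void corner_setup(double p, int n, int& i0, int& i1,
                                double& f, bool& ok0, bool& ok1) {
  const double fl = std::floor(p);
  f = p - fl;
  const int a0 = (int)fl;
  i0 = a0 < 1 ? 1 : (a0 > n ? n : a0);
  const int a1 = a0 + 1;
  i1 = a1 < 1 ? 1 : (a1 > n ? n : a1);
  ok0 = a0 >= 1 && a0 <= n;
  ok1 = a1 >= 1 && a1 <= n;
}

// Trilinear sampling of x (nvox x C) at positions (PX,PY,PZ) (each
// nvox x K, fractional 1-based voxel coordinates); zero outside.
// Output nvox x (K*C), tap-fastest as in cpp_im2col.
// [[Rcpp::export]]
NumericMatrix cpp_defsample_fwd(const NumericMatrix& x,
                                const NumericMatrix& PX,
                                const NumericMatrix& PY,
                                const NumericMatrix& PZ,
                                const IntegerVector& dims) {
  const int nvox = x.nrow(), C = x.ncol(), K = PX.ncol();
  const int W = dims[0], H = dims[1], D = dims[2];
  NumericMatrix out(nvox, K * C);
  const double* xp = x.begin();
  for (int t = 0; t < K; ++t) {
    const double* px = PX.begin() + (size_t)nvox * t;
    const double* py = PY.begin() + (size_t)nvox * t;
    const double* pz = PZ.begin() + (size_t)nvox * t;
    for (int v = 0; v < nvox; ++v) {
      int x0, x1, y0, y1, z0, z1;
      double fx, fy, fz;
      bool okx0, okx1, oky0, oky1, okz0, okz1;
      corner_setup(px[v], W, x0, x1, fx, okx0, okx1);
      corner_setup(py[v], H, y0, y1, fy, oky0, oky1);
      corner_setup(pz[v], D, z0, z1, fz, okz0, okz1);
      // 8 corner linear indices (0-based) and weights
      long idx[8];
      double w[8];
      const long sxy = (long)W * H;
      idx[0] = (x0 - 1) + (long)(y0 - 1) * W + (long)(z0 - 1) * sxy;
      idx[1] = (x1 - 1) + (long)(y0 - 1) * W + (long)(z0 - 1) * sxy;
      idx[2] = (x0 - 1) + (long)(y1 - 1) * W + (long)(z0 - 1) * sxy;
      idx[3] = (x1 - 1) + (long)(y1 - 1) * W + (long)(z0 - 1) * sxy;
      idx[4] = (x0 - 1) + (long)(y0 - 1) * W + (long)(z1 - 1) * sxy;
      idx[5] = (x1 - 1) + (long)(y0 - 1) * W + (long)(z1 - 1) * sxy;
      idx[6] = (x0 - 1) + (long)(y1 - 1) * W + (long)(z1 - 1) * sxy;
      idx[7] = (x1 - 1) + (long)(y1 - 1) * W + (long)(z1 - 1) * sxy;
      w[0] = (okx0 && oky0 && okz0) ? (1 - fx) * (1 - fy) * (1 - fz) : 0.0;
      w[1] = (okx1 && oky0 && okz0) ? fx * (1 - fy) * (1 - fz) : 0.0;
      w[2] = (okx0 && oky1 && okz0) ? (1 - fx) * fy * (1 - fz) : 0.0;
      w[3] = (okx1 && oky1 && okz0) ? fx * fy * (1 - fz) : 0.0;
      w[4] = (okx0 && oky0 && okz1) ? (1 - fx) * (1 - fy) * fz : 0.0;
      w[5] = (okx1 && oky0 && okz1) ? fx * (1 - fy) * fz : 0.0;
      w[6] = (okx0 && oky1 && okz1) ? (1 - fx) * fy * fz : 0.0;
      w[7] = (okx1 && oky1 && okz1) ? fx * fy * fz : 0.0;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)nvox * c;
        double acc = 0.0;
        for (int q = 0; q < 8; ++q) acc += w[q] * xc[idx[q]];
        out[v + (size_t)nvox * (t + (size_t)K * c)] = acc;
      }
    }
  }
  return out;
}

// Backward of cpp_defsample_fwd.  g: nvox x (K*C) gradient of the
// patch tensor.  Returns dx (nvox x C) and dP{X,Y,Z} (nvox x K), the
// gradients w.r.t. the sampling positions.
// [[Rcpp::export]]
List cpp_defsample_bwd(const NumericMatrix& x, const NumericMatrix& PX,
                       const NumericMatrix& PY, const NumericMatrix& PZ,
                       const NumericMatrix& g, const IntegerVector& dims) {
  const int nvox = x.nrow(), C = x.ncol(), K = PX.ncol();
  const int W = dims[0], H = dims[1], D = dims[2];
  NumericMatrix dx(nvox, C), dPX(nvox, K), dPY(nvox, K), dPZ(nvox, K);
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dxp = dx.begin();
  for (int t = 0; t < K; ++t) {
    const double* px = PX.begin() + (size_t)nvox * t;
    const double* py = PY.begin() + (size_t)nvox * t;
    const double* pz = PZ.begin() + (size_t)nvox * t;
    double* dpx = dPX.begin() + (size_t)nvox * t;
    double* dpy = dPY.begin() + (size_t)nvox * t;
    double* dpz = dPZ.begin() + (size_t)nvox * t;
    for (int v = 0; v < nvox; ++v) {
      int x0, x1, y0, y1, z0, z1;
      double fx, fy, fz;
      bool okx0, okx1, oky0, oky1, okz0, okz1;
      corner_setup(px[v], W, x0, x1, fx, okx0, okx1);
      corner_setup(py[v], H, y0, y1, fy, oky0, oky1);
      corner_setup(pz[v], D, z0, z1, fz, okz0, okz1);
      const long sxy = (long)W * H;
      long idx[8];
      double wq[8], dwx[8], dwy[8], dwz[8];
      bool okq[8];
      const double wx0 = 1 - fx, wx1 = fx, wy0 = 1 - fy, wy1 = fy,
        wz0 = 1 - fz, wz1 = fz;
      idx[0] = (x0 - 1) + (long)(y0 - 1) * W + (long)(z0 - 1) * sxy;
      idx[1] = (x1 - 1) + (long)(y0 - 1) * W + (long)(z0 - 1) * sxy;
      idx[2] = (x0 - 1) + (long)(y1 - 1) * W + (long)(z0 - 1) * sxy;
      idx[3] = (x1 - 1) + (long)(y1 - 1) * W + (long)(z0 - 1) * sxy;
      idx[4] = (x0 - 1) + (long)(y0 - 1) * W + (long)(z1 - 1) * sxy;
      idx[5] = (x1 - 1) + (long)(y0 - 1) * W + (long)(z1 - 1) * sxy;
      idx[6] = (x0 - 1) + (long)(y1 - 1) * W + (long)(z1 - 1) * sxy;
      idx[7] = (x1 - 1) + (long)(y1 - 1) * W + (long)(z1 - 1) * sxy;
      okq[0] = okx0 && oky0 && okz0;  okq[1] = okx1 && oky0 && okz0;
      okq[2] = okx0 && oky1 && okz0;  okq[3] = okx1 && oky1 && okz0;
      okq[4] = okx0 && oky0 && okz1;  okq[5] = okx1 && oky0 && okz1;
      okq[6] = okx0 && oky1 && okz1;  okq[7] = okx1 && oky1 && okz1;
      wq[0] = wx0 * wy0 * wz0;  dwx[0] = -wy0 * wz0;  dwy[0] = -wx0 * wz0;  dwz[0] = -wx0 * wy0;
      wq[1] = wx1 * wy0 * wz0;  dwx[1] =  wy0 * wz0;  dwy[1] = -wx1 * wz0;  dwz[1] = -wx1 * wy0;
      wq[2] = wx0 * wy1 * wz0;  dwx[2] = -wy1 * wz0;  dwy[2] =  wx0 * wz0;  dwz[2] = -wx0 * wy1;
      wq[3] = wx1 * wy1 * wz0;  dwx[3] =  wy1 * wz0;  dwy[3] =  wx1 * wz0;  dwz[3] = -wx1 * wy1;
      wq[4] = wx0 * wy0 * wz1;  dwx[4] = -wy0 * wz1;  dwy[4] = -wx0 * wz1;  dwz[4] =  wx0 * wy0;
      wq[5] = wx1 * wy0 * wz1;  dwx[5] =  wy0 * wz1;  dwy[5] = -wx1 * wz1;  dwz[5] =  wx1 * wy0;
      wq[6] = wx0 * wy1 * wz1;  dwx[6] = -wy1 * wz1;  dwy[6] =  wx0 * wz1;  dwz[6] =  wx0 * wy1;
      wq[7] = wx1 * wy1 * wz1;  dwx[7] =  wy1 * wz1;  dwy[7] =  wx1 * wz1;  dwz[7] =  wx1 * wy1;
      double ax = 0.0, ay = 0.0, az = 0.0;
      for (int c = 0; c < C; ++c) {
        const double gv = gp[v + (size_t)nvox * (t + (size_t)K * c)];
        if (gv == 0.0) continue;
        const double* xc = xp + (size_t)nvox * c;
        double* dxc = dxp + (size_t)nvox * c;
        for (int q = 0; q < 8; ++q) {
          if (!okq[q]) continue;
          dxc[idx[q]] += wq[q] * gv;
          const double xv = xc[idx[q]];
          ax += dwx[q] * xv * gv;
          ay += dwy[q] * xv * gv;
          az += dwz[q] * xv * gv;
        }
      }
      dpx[v] = ax;
      dpy[v] = ay;
      dpz[v] = az;
    }
  }
  return List::create(_["dx"] = dx, _["dPX"] = dPX, _["dPY"] = dPY,
                      _["dPZ"] = dPZ);
}
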