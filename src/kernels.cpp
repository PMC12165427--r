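#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Feature maps are N x C matrices (voxels x channels); row n is the
// column-major linear index of a d1 x d2 x d3 grid, so each channel is a
// contiguous column matching R array layout.

static inline int out_dim(int d, int k, int stride, int dil, int pad) {
  int eff = dil * (k - 1) + 1;
  return (d + 2 * pad - eff) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, IntegerVector dims,
                         int k, int stride, int dilation, int pad) {
  const int C = x.ncol();
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dim(d1, k, stride, dilation, pad);
  const int o2 = out_dim(d2, k, stride, dilation, pad);
  const int o3 = out_dim(d3, k, stride, dilation, pad);
  const size_t Nout = (size_t)o1 * o2 * o3;
  const int K3 = k * k * k;
  NumericMatrix col((int)Nout, C * K3);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * d1 * d2 * d3;
    for (int kk = 0; kk < k; ++kk) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          double* dst = cp + ((size_t)c * K3 + ki + k * (kj + k * kk)) * Nout;
          for (int ok = 0; ok < o3; ++ok) {
            const int ii3 = ok * stride - pad + kk * dilation;
            if (ii3 < 0 || ii3 >= d3) continue;  // stays zero
            for (int oj = 0; oj < o2; ++oj) {
              const int ii2 = oj * stride - pad + kj * dilation;
              if (ii2 < 0 || ii2 >= d2) continue;
              double* line = dst + ((size_t)ok * o2 + oj) * o1;
              const double* srcline = xc + ((size_t)ii3 * d2 + ii2) * d1;
              if (stride == 1) {
                // valid oi range: 0 <= oi - pad + ki*dilation < d1
                int lo = pad - ki * dilation;
                if (lo < 0) lo = 0;
                int hi = d1 + pad - ki * dilation;
                if (hi > o1) hi = o1;
                if (hi > lo)
                  std::memcpy(line + lo, srcline + lo - pad + ki * dilation,
                              (size_t)(hi - lo) * sizeof(double));
              } else {
                for (int oi = 0; oi < o1; ++oi) {
                  const int ii1 = oi * stride - pad + ki * dilation;
                  if (ii1 >= 0 && ii1 < d1) line[oi] = srcline[ii1];
                }
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col: scatter-add an Nout x (C*k^3) matrix back to N x C.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& col, IntegerVector dims, int C,
                         int k, int stride, int dilation, int pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dim(d1, k, stride, dilation, pad);
  const int o2 = out_dim(d2, k, stride, dilation, pad);
  const int o3 = out_dim(d3, k, stride, dilation, pad);
  const size_t Nout = (size_t)o1 * o2 * o3;
  const int K3 = k * k * k;
  NumericMatrix x(d1 * d2 * d3, C);
  const double* cp = col.begin();
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * d1 * d2 * d3;
    for (int kk = 0; kk < k; ++kk) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double* src =
            cp + ((size_t)c * K3 + ki + k * (kj + k * kk)) * Nout;
          for (int ok = 0; ok < o3; ++ok) {
            const int ii3 = ok * stride - pad + kk * dilation;
            if (ii3 < 0 || ii3 >= d3) continue;
            for (int oj = 0; oj < o2; ++oj) {
              const int ii2 = oj * stride - pad + kj * dilation;
              if (ii2 < 0 || ii2 >= d2) continue;
              const double* line = src + ((size_t)ok * o2 + oj) * o1;
              double* dstline = xc + ((size_t)ii3 * d2 + ii2) * d1;
              for (int oi = 0; oi < o1; ++oi) {
                const int ii1 = oi * stride - pad + ki * dilation;
                if (ii1 >= 0 && ii1 < d1) dstline[ii1] += line[oi];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

struct LinW { int lo; int hi; double w; };  // src lo/hi indices + hi weight

static void lin_weights(int nin, int nout, std::vector<LinW>& w) {
  w.resize(nout);
  const double scale = (double)nin / nout;
  for (int o = 0; o < nout; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > nin - 1) s = nin - 1;
    int lo = (int)std::floor(s);
    int hi = lo + 1 < nin ? lo + 1 : lo;
    w[o] = {lo, hi, s - lo};
  }
}

// Trilinear resize of an N x C feature matrix to a new grid.
// [[Rcpp::export]]
NumericMatrix cpp_resize3(const NumericMatrix& x, IntegerVector dims,
                          IntegerVector odims) {
  const int C = x.ncol();
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = odims[0], o2 = odims[1], o3 = odims[2];
  std::vector<LinW> w1, w2, w3;
  lin_weights(d1, o1, w1); lin_weights(d2, o2, w2); lin_weights(d3, o3, w3);
  NumericMatrix y(o1 * o2 * o3, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * d1 * d2 * d3;
    double* yc = yp + (size_t)c * o1 * o2 * o3;
    for (int ok = 0; ok < o3; ++ok) {
      const LinW& a3 = w3[ok];
      for (int oj = 0; oj < o2; ++oj) {
        const LinW& a2 = w2[oj];
        const double* p00 = xc + ((size_t)a3.lo * d2 + a2.lo) * d1;
        const double* p10 = xc + ((size_t)a3.lo * d2 + a2.hi) * d1;
        const double* p01 = xc + ((size_t)a3.hi * d2 + a2.lo) * d1;
        const double* p11 = xc + ((size_t)a3.hi * d2 + a2.hi) * d1;
        const double w00 = (1 - a2.w) * (1 - a3.w), w10 = a2.w * (1 - a3.w),
                     w01 = (1 - a2.w) * a3.w, w11 = a2.w * a3.w;
        double* line = yc + ((size_t)ok * o2 + oj) * o1;
        for (int oi = 0; oi < o1; ++oi) {
          const LinW& a1 = w1[oi];
          const double f0 = 1 - a1.w, f1 = a1.w;
          line[oi] =
            w00 * (f0 * p00[a1.lo] + f1 * p00[a1.hi]) +
            w10 * (f0 * p10[a1.lo] + f1 * p10[a1.hi]) +
            w01 * (f0 * p01[a1.lo] + f1 * p01[a1.hi]) +
            w11 * (f0 * p11[a1.lo] + f1 * p11[a1.hi]);
        }
      }
    }
  }
  return y;
}

// Adjoint of cpp_resize3: scatter gradients from the output grid back.
// [[Rcpp::export]]
NumericMatrix cpp_resize3_adj(const NumericMatrix& g, IntegerVector dims,
                              IntegerVector odims) {
  const int C = g.ncol();
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = odims[0], o2 = odims[1], o3 = odims[2];
  std::vector<LinW> w1, w2, w3;
  lin_weights(d1, o1, w1); lin_weights(d2, o2, w2); lin_weights(d3, o3, w3);
  NumericMatrix x(d1 * d2 * d3, C);
  const double* gp = g.begin();
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * d1 * d2 * d3;
    const double* gc = gp + (size_t)c * o1 * o2 * o3;
    for (int ok = 0; ok < o3; ++ok) {
      const LinW& a3 = w3[ok];
      for (int oj = 0; oj < o2; ++oj) {
        const LinW& a2 = w2[oj];
        double* p00 = xc + ((size_t)a3.lo * d2 + a2.lo) * d1;
        double* p10 = xc + ((size_t)a3.lo * d2 + a2.hi) * d1;
        double* p01 = xc + ((size_t)a3.hi * d2 + a2.lo) * d1;
        double* p11 = xc + ((size_t)a3.hi * d2 + a2.hi) * d1;
        const double w00 = (1 - a2.w) * (1 - a3.w), w10 = a2.w * (1 - a3.w),
                     w01 = (1 - a2.w) * a3.w, w11 = a2.w * a3.w;
        const double* line = gc + ((size_t)ok * o2 + oj) * o1;
        for (int oi = 0; oi < o1; ++oi) {
          const LinW& a1 = w1[oi];
          const double f0 = 1 - a1.w, f1 = a1.w;
          const double gv = line[oi];
          p00[a1.lo] += w00 * f0 * gv; p00[a1.hi] += w00 * f1 * gv;
          p10[a1.lo] += w10 * f0 * gv; p10[a1.hi] += w10 * f1 * gv;
          p01[a1.lo] += w01 * f0 * gv; p01[a1.hi] += w01 * f1 * gv;
          p11[a1.lo] += w11 * f0 * gv; p11[a1.hi] += w11 * f1 * gv;
        }
      }
    }
  }
  return x;
}

// Sample a scalar volume at arbitrary (0-based) voxel coordinates, trilinear,
// border-clamped. coords is n x 3.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(const NumericVector& vol, IntegerVector dims,
                                   const NumericMatrix& coords) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  const double* vp = vol.begin();
  for (int i = 0; i < n; ++i) {
    double c1 = coords(i, 0), c2 = coords(i, 1), c3 = coords(i, 2);
    if (c1 < 0) c1 = 0; if (c1 > d1 - 1) c1 = d1 - 1;
    if (c2 < 0) c2 = 0; if (c2 > d2 - 1) c2 = d2 - 1;
    if (c3 < 0) c3 = 0; if (c3 > d3 - 1) c3 = d3 - 1;
    const int l1 = (int)std::floor(c1), l2 = (int)std::floor(c2),
              l3 = (int)std::floor(c3);
    const int h1 = l1 + 1 < d1 ? l1 + 1 : l1;
    const int h2 = l2 + 1 < d2 ? l2 + 1 : l2;
    const int h3 = l3 + 1 < d3 ? l3 + 1 : l3;
    const double f1 = c1 - l1, f2 = c2 - l2, f3 = c3 - l3;
    double acc = 0;
    for (int b3 = 0; b3 < 2; ++b3) {
      const int i3 = b3 ? h3 : l3;
      const double w3 = b3 ? f3 : 1 - f3;
      if (w3 == 0) continue;
      for (int b2 = 0; b2 < 2; ++b2) {
        const int i2 = b2 ? h2 : l2;
        const double w23 = (b2 ? f2 : 1 - f2) * w3;
        if (w23 == 0) continue;
        for (int b1 = 0; b1 < 2; ++b1) {
          const int i1 = b1 ? h1 : l1;
          const double w = (b1 ? f1 : 1 - f1) * w23;
          if (w == 0) continue;
          acc += w * vp[i1 + (size_t)d1 * (i2 + (size_t)d2 * i3)];
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// Separable convolution of a scalar volume with a symmetric 1D kernel along
// all three axes (border replicated). Used for Gaussian smoothing.
// [[Rcpp::export]]
NumericVector cpp_sep_smooth3(const NumericVector& vol, IntegerVector dims,
                              const NumericVector& kernel) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int kn = kernel.size();
  const int r = kn / 2;
  const size_t N = (size_t)d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(N);
  for (int ax = 0; ax < 3; ++ax) {
    const int len = d[ax];
    size_t stride = 1;
    for (int t = 0; t < ax; ++t) stride *= d[t];
    const size_t nlines = N / len;
    for (size_t line = 0; line < nlines; ++line) {
      // base index of this line
      const size_t outer = line / stride, inner = line % stride;
      const size_t base = inner + outer * stride * len;
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int j = i + t;
          if (j < 0) j = 0;
          if (j >= len) j = len - 1;
          acc += kernel[t + r] * a[base + (size_t)j * stride];
        }
        b[base + (size_t)i * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// For each row of a (n x 3, physical coordinates), the distance to the
// nearest row of b. Brute force; used for HD95 surface distances.
// [[Rcpp::export]]
NumericVector cpp_min_dists(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Euler-Maruyama integration of the bistable system
//   dx/dt = x - x^3 + A sin(omega t) + sqrt(2 D) xi(t)
// for each sample independently, A[i] constant per sample, x0[i] initial
// state. Uses R's RNG (honors set.seed) when D > 0; draws are sample-major
// within each step. Returns terminal states.
// [[Rcpp::export]]
NumericVector cpp_sr_integrate(const NumericVector& A, const NumericVector& x0,
                               double D, double omega, double dt, int nsteps) {
  const int n = A.size();
  std::vector<double> x(x0.begin(), x0.end());
  const double sq = std::sqrt(2.0 * D * dt);
  if (D > 0) {
    GetRNGstate();
    for (int s = 0; s < nsteps; ++s) {
      const double f = std::sin(omega * s * dt);
      for (int i = 0; i < n; ++i) {
        const double xi = x[i];
        x[i] = xi + dt * (xi - xi * xi * xi + A[i] * f) + sq * norm_rand();
      }
    }
    PutRNGstate();
  } else {
    for (int s = 0; s < nsteps; ++s) {
      const double f = std::sin(omega * s * dt);
      for (int i = 0; i < n; ++i) {
        const double xi = x[i];
        x[i] = xi + dt * (xi - xi * xi * xi + A[i] * f);
      }
    }
  }
  return NumericVector(x.begin(), x.end());
}
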