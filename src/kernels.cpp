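#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 3D scalar-volume kernels shared by the resampler, the MI metric and the
// synthetic generator. Volumes are column-major arrays (R layout), voxel
// (i,j,k) zero-based at linear index i + nx*(j + ny*k). Continuous voxel
// coordinates are zero-based; positions outside [0, n-1] sample as NaN and
// callers decide whether that means "0" (resampling) or "skip" (MI overlap).

static const int INTERP_NN = 0, INTERP_LINEAR = 1, INTERP_BSPLINE = 2;

static inline double sample_nn(const double* v, int nx, int ny, int nz,
                               double cx, double cy, double cz) {
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5)
    return NA_REAL;
  int i = (int)std::lround(cx), j = (int)std::lround(cy), k = (int)std::lround(cz);
  if (i < 0) i = 0; if (i >= nx) i = nx - 1;
  if (j < 0) j = 0; if (j >= ny) j = ny - 1;
  if (k < 0) k = 0; if (k >= nz) k = nz - 1;
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

static inline double sample_linear(const double* v, int nx, int ny, int nz,
                                   double cx, double cy, double cz) {
  if (cx < 0 || cy < 0 || cz < 0 || cx > nx - 1 || cy > ny - 1 || cz > nz - 1)
    return NA_REAL;
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  if (i0 >= nx - 1) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 >= ny - 1) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 >= nz - 1) k0 = nz - 2; if (k0 < 0) k0 = 0;
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  size_t base = i0 + (size_t)nx * (j0 + (size_t)ny * k0);
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c000 = v[base],            c100 = v[base + sx];
  double c010 = v[base + sy],       c110 = v[base + sx + sy];
  double c001 = v[base + sz],       c101 = v[base + sx + sz];
  double c011 = v[base + sy + sz],  c111 = v[base + sx + sy + sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline int mirror_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Cubic B-spline evaluation; `v` must hold prefiltered spline coefficients.
static inline double sample_bspline(const double* v, int nx, int ny, int nz,
                                    double cx, double cy, double cz) {
  if (cx < 0 || cy < 0 || cz < 0 || cx > nx - 1 || cy > ny - 1 || cz > nz - 1)
    return NA_REAL;
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  double tx = cx - i0, ty = cy - j0, tz = cz - k0;
  double wx[4], wy[4], wz[4];
  auto weights = [](double t, double* w) {
    double t2 = t * t, t3 = t2 * t;
    w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
    w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
    w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
    w[3] = t3 / 6.0;
  };
  weights(tx, wx); weights(ty, wy); weights(tz, wz);
  double acc = 0.0;
  for (int dk = 0; dk < 4; ++dk) {
    int k = mirror_index(k0 - 1 + dk, nz);
    for (int dj = 0; dj < 4; ++dj) {
      int j = mirror_index(j0 - 1 + dj, ny);
      double wjk = wy[dj] * wz[dk];
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int di = 0; di < 4; ++di) {
        int i = mirror_index(i0 - 1 + di, nx);
        acc += wx[di] * wjk * v[base + i];
      }
    }
  }
  return acc;
}

static inline double sample_any(const double* v, int nx, int ny, int nz,
                                double cx, double cy, double cz, int interp) {
  switch (interp) {
    case INTERP_NN:     return sample_nn(v, nx, ny, nz, cx, cy, cz);
    case INTERP_LINEAR: return sample_linear(v, nx, ny, nz, cx, cy, cz);
    default:            return sample_bspline(v, nx, ny, nz, cx, cy, cz);
  }
}

// In-place recursive prefilter along one line (Unser's cubic-spline pole).
static void prefilter_line(double* c, int n, int stride) {
  const double z = std::sqrt(3.0) - 2.0;          // -0.267949...
  const double lambda = 6.0;                      // (1 - z)(1 - 1/z)
  if (n == 1) { return; }
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double sum = c[0], zn = z;
  for (int i = 1; i < horizon; ++i) { sum += zn * c[i * stride]; zn *= z; }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z * c[(i - 1) * stride];
  c[(n - 1) * stride] = (z / (z * z - 1.0)) *
    (c[(n - 1) * stride] + z * c[(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double* p = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      prefilter_line(p + (size_t)nx * (j + (size_t)ny * k), nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      prefilter_line(p + i + (size_t)nx * (size_t)ny * k, ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      prefilter_line(p + i + (size_t)nx * j, nz, nx * ny);
  return out;
}

// Resample a volume onto its own grid through the affine map y = M x + v
// (pull convention: output voxel at physical x takes the input value at y).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix M, NumericVector v, int interp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* src = REAL(vol);
  double* dst = REAL(out);
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + i * spacing[0];
        double tx = m00 * x + m01 * y + m02 * z + v[0];
        double ty = m10 * x + m11 * y + m12 * z + v[1];
        double tz = m20 * x + m21 * y + m22 * z + v[2];
        double s = sample_any(src, nx, ny, nz,
                              (tx - origin[0]) / spacing[0],
                              (ty - origin[1]) / spacing[1],
                              (tz - origin[2]) / spacing[2], interp);
        dst[idx] = ISNAN(s) ? 0.0 : s;
      }
    }
  }
  return out;
}

// Sample a volume at arbitrary physical points; out-of-domain gives 0.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, int interp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* src = REAL(vol);
  for (int r = 0; r < n; ++r) {
    double s = sample_any(src, nx, ny, nz,
                          (pts(r, 0) - origin[0]) / spacing[0],
                          (pts(r, 1) - origin[1]) / spacing[1],
                          (pts(r, 2) - origin[2]) / spacing[2], interp);
    out[r] = ISNAN(s) ? 0.0 : s;
  }
  return out;
}

// Mutual information (nats) between fixed intensities at sample points and
// the moving image sampled at y = M x + v, with linear (partial-volume
// style) binning on both histogram axes. Samples falling outside the moving
// domain are excluded from the joint histogram when outsideZero == 0
// (returning NA when fewer than 50 samples overlap), or treated as
// background intensity 0 when outsideZero != 0 — appropriate for magnitude
// images that are genuinely zero outside their support, and immune to the
// shrinking-overlap artefact of exclusion-style MI.
// [[Rcpp::export]]
double cpp_mi_affine(NumericVector fixedVals, NumericMatrix pts,
                     NumericVector mov, IntegerVector mdim,
                     NumericVector mspacing, NumericVector morigin,
                     NumericMatrix M, NumericVector v, int interp, int bins,
                     double fmin, double fmax, double mmin, double mmax,
                     int outsideZero) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int n = pts.nrow();
  const double* src = REAL(mov);
  const double* px = REAL(pts);
  const double* py = px + n;
  const double* pz = py + n;
  const double* fv = REAL(fixedVals);
  std::vector<double> H((size_t)bins * bins, 0.0);
  double fscale = (fmax > fmin) ? (bins - 1) / (fmax - fmin) : 0.0;
  double mscale = (mmax > mmin) ? (bins - 1) / (mmax - mmin) : 0.0;
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  double total = 0.0;
  long nvalid = 0;
  for (int r = 0; r < n; ++r) {
    double x = px[r], y = py[r], z = pz[r];
    double tx = m00 * x + m01 * y + m02 * z + v[0];
    double ty = m10 * x + m11 * y + m12 * z + v[1];
    double tz = m20 * x + m21 * y + m22 * z + v[2];
    double mv = sample_any(src, nx, ny, nz,
                           (tx - morigin[0]) / mspacing[0],
                           (ty - morigin[1]) / mspacing[1],
                           (tz - morigin[2]) / mspacing[2], interp);
    if (ISNAN(mv)) {
      if (!outsideZero) continue;
      mv = 0.0;
    }
    double bf = (fv[r] - fmin) * fscale;
    double bm = (mv - mmin) * mscale;
    if (bf < 0) bf = 0; if (bf > bins - 1) bf = bins - 1;
    if (bm < 0) bm = 0; if (bm > bins - 1) bm = bins - 1;
    int i0 = (int)std::floor(bf); if (i0 > bins - 2) i0 = bins - 2;
    int j0 = (int)std::floor(bm); if (j0 > bins - 2) j0 = bins - 2;
    double wi = bf - i0, wj = bm - j0;
    H[i0     + (size_t)bins * j0]       += (1 - wi) * (1 - wj);
    H[i0 + 1 + (size_t)bins * j0]       += wi * (1 - wj);
    H[i0     + (size_t)bins * (j0 + 1)] += (1 - wi) * wj;
    H[i0 + 1 + (size_t)bins * (j0 + 1)] += wi * wj;
    total += 1.0;
    ++nvalid;
  }
  if (nvalid < 50) return NA_REAL;
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      double p = H[i + (size_t)bins * j] / total;
      pf[i] += p; pm[j] += p;
    }
  double mi = 0.0;
  for (int j = 0; j < bins; ++j) {
    if (pm[j] <= 0) continue;
    for (int i = 0; i < bins; ++i) {
      double p = H[i + (size_t)bins * j] / total;
      if (p > 0 && pf[i] > 0) mi += p * std::log(p / (pf[i] * pm[j]));
    }
  }
  return mi;
}

// Separable Gaussian smoothing (sigma in voxels, reflected boundaries).
// [[Rcpp::export]]
NumericVector cpp_smooth_gauss(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double ksum = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += kern[t + radius];
  }
  for (double& w : kern) w /= ksum;
  NumericVector a = clone(vol), b((size_t)nx * ny * nz);
  double *pa = REAL(a), *pb = REAL(b);
  int dims[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    int n = dims[axis];
    size_t stride = strides[axis];
    int d1 = (axis == 0) ? ny : nx;
    int d2 = (axis == 2) ? ny : nz;
    size_t s1 = (axis == 0) ? strides[1] : strides[0];
    size_t s2 = (axis == 2) ? strides[1] : strides[2];
    for (int q = 0; q < d2; ++q)
      for (int p = 0; p < d1; ++p) {
        double* lineIn = pa + p * s1 + q * s2;
        double* lineOut = pb + p * s1 + q * s2;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int t = -radius; t <= radius; ++t)
            acc += kern[t + radius] * lineIn[(size_t)mirror_index(i + t, n) * stride];
          lineOut[(size_t)i * stride] = acc;
        }
      }
    std::swap(pa, pb);
  }
  // after 3 passes the result sits in the buffer pa points to
  if (pa == REAL(a)) return a;
  return b;
}

// Thin-plate-spline displacement field: disp_c(x) = a0 + a1 x + a2 y + a3 z
// + sum_k W[k,c] * |x - ctrl_k| (3D biharmonic kernel U(r) = r).
// [[Rcpp::export]]
NumericMatrix cpp_tps_disp(NumericMatrix ctrl, NumericMatrix W,
                           NumericMatrix A, NumericMatrix pts) {
  int K = ctrl.nrow(), n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    double x = pts(r, 0), y = pts(r, 1), z = pts(r, 2);
    double d0 = A(0,0) + A(1,0) * x + A(2,0) * y + A(3,0) * z;
    double d1 = A(0,1) + A(1,1) * x + A(2,1) * y + A(3,1) * z;
    double d2 = A(0,2) + A(1,2) * x + A(2,2) * y + A(3,2) * z;
    for (int k = 0; k < K; ++k) {
      double dx = x - ctrl(k,0), dy = y - ctrl(k,1), dz = z - ctrl(k,2);
      double r3 = std::sqrt(dx * dx + dy * dy + dz * dz);
      d0 += W(k,0) * r3; d1 += W(k,1) * r3; d2 += W(k,2) * r3;
    }
    out(r,0) = d0; out(r,1) = d1; out(r,2) = d2;
  }
  return out;
}
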