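#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic B-spline free-form deformation and image warping kernels.
//
// Control point grids live in world (mm) coordinates: node (a,b,c) sits at
// cpg_origin + (a,b,c)*cpg_spacing, displacements in mm. Evaluation at world
// point x uses local coordinate g = (x - cpg_origin)/cpg_spacing, the cell
// index i = floor(g) and the four uniform cubic B-spline basis functions on
// nodes i-1..i+2; full support (g in [1, nc-2]) is required.

static inline void bs_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline void bs_dweights(double t, double w[4]) {
  double t2 = t * t;
  w[0] = (-1.0 + 2.0 * t - t2) / 2.0;
  w[1] = (-4.0 * t + 3.0 * t2) / 2.0;
  w[2] = (1.0 + 2.0 * t - 3.0 * t2) / 2.0;
  w[3] = t2 / 2.0;
}

struct AxisTab { std::vector<int> i0; std::vector<double> w; bool ok; };

// per-axis table of base node index and 4 weights for every output sample
static AxisTab axis_table(int n, double o, double s, int nc, double co, double cs) {
  AxisTab t; t.i0.resize(n); t.w.resize(4 * (size_t)n); t.ok = true;
  for (int i = 0; i < n; ++i) {
    double g = (o + i * s - co) / cs;
    int b = (int)std::floor(g);
    if (b < 1 || b + 2 > nc - 1) { t.ok = false; b = std::min(std::max(b, 1), nc - 3); }
    bs_weights(g - b, &t.w[4 * (size_t)i]);
    t.i0[i] = b - 1;
  }
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_ffd_to_dvf(NumericVector cpg, IntegerVector cdim,
                             NumericVector corigin, NumericVector cspacing,
                             IntegerVector dim, NumericVector spacing,
                             NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  AxisTab tx = axis_table(nx, origin[0], spacing[0], cx, corigin[0], cspacing[0]);
  AxisTab ty = axis_table(ny, origin[1], spacing[1], cy, corigin[1], cspacing[1]);
  AxisTab tz = axis_table(nz, origin[2], spacing[2], cz, corigin[2], cspacing[2]);
  if (!tx.ok || !ty.ok || !tz.ok)
    stop("control point grid does not cover the target grid with full B-spline support");
  const size_t nvox = (size_t)nx * ny * nz, ncp = (size_t)cx * cy * cz;
  NumericVector out(3 * nvox);
  const double *C = cpg.begin();
  double *O = out.begin();
  for (int comp = 0; comp < 3; ++comp) {
    const double *Cc = C + comp * ncp;
    double *Oc = O + comp * nvox;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double *wz = &tz.w[4 * (size_t)k]; int kz = tz.i0[k];
      for (int j = 0; j < ny; ++j) {
        const double *wy = &ty.w[4 * (size_t)j]; int jy = ty.i0[j];
        for (int i = 0; i < nx; ++i, ++idx) {
          const double *wx = &tx.w[4 * (size_t)i]; int ix = tx.i0[i];
          double acc = 0.0;
          for (int c3 = 0; c3 < 4; ++c3) {
            double wzz = wz[c3];
            size_t base3 = (size_t)(kz + c3) * cy;
            for (int c2 = 0; c2 < 4; ++c2) {
              double wyz = wy[c2] * wzz;
              size_t base2 = ((base3 + jy + c2) * cx) + ix;
              acc += wyz * (wx[0] * Cc[base2] + wx[1] * Cc[base2 + 1] +
                            wx[2] * Cc[base2 + 2] + wx[3] * Cc[base2 + 3]);
            }
          }
          Oc[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Exact transpose of cpp_ffd_to_dvf: scatter a voxel-wise 3-vector field into
// control-point space with the same weights.
// [[Rcpp::export]]
NumericVector cpp_ffd_adjoint(NumericVector field, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              IntegerVector cdim, NumericVector corigin,
                              NumericVector cspacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  AxisTab tx = axis_table(nx, origin[0], spacing[0], cx, corigin[0], cspacing[0]);
  AxisTab ty = axis_table(ny, origin[1], spacing[1], cy, corigin[1], cspacing[1]);
  AxisTab tz = axis_table(nz, origin[2], spacing[2], cz, corigin[2], cspacing[2]);
  if (!tx.ok || !ty.ok || !tz.ok)
    stop("control point grid does not cover the target grid with full B-spline support");
  const size_t nvox = (size_t)nx * ny * nz, ncp = (size_t)cx * cy * cz;
  NumericVector out(3 * ncp);
  const double *F = field.begin();
  double *O = out.begin();
  for (int comp = 0; comp < 3; ++comp) {
    const double *Fc = F + comp * nvox;
    double *Oc = O + comp * ncp;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double *wz = &tz.w[4 * (size_t)k]; int kz = tz.i0[k];
      for (int j = 0; j < ny; ++j) {
        const double *wy = &ty.w[4 * (size_t)j]; int jy = ty.i0[j];
        for (int i = 0; i < nx; ++i, ++idx) {
          double f = Fc[idx];
          if (f == 0.0) continue;
          const double *wx = &tx.w[4 * (size_t)i]; int ix = tx.i0[i];
          for (int c3 = 0; c3 < 4; ++c3) {
            double wzz = wz[c3] * f;
            size_t base3 = (size_t)(kz + c3) * cy;
            for (int c2 = 0; c2 < 4; ++c2) {
              double wyz = wy[c2] * wzz;
              size_t base2 = ((base3 + jy + c2) * cx) + ix;
              Oc[base2] += wx[0] * wyz;
              Oc[base2 + 1] += wx[1] * wyz;
              Oc[base2 + 2] += wx[2] * wyz;
              Oc[base2 + 3] += wx[3] * wyz;
            }
          }
        }
      }
    }
  }
  return out;
}

// ---- cubic B-spline interpolation coefficients (prefilter) -----------------
// Standard recursive filter with pole sqrt(3)-2, mirror boundaries.

static void prefilter_line(double *c, int n, int stride) {
  const double z = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  if (n == 1) { c[0] *= 1.0; return; }
  for (int i = 0; i < n; ++i) c[(size_t)i * stride] *= lambda;
  // causal init (mirror): truncated sum
  int horizon = std::min(n, (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z))));
  double sum = c[0];
  double zn = z;
  for (int i = 1; i < horizon; ++i) { sum += zn * c[(size_t)i * stride]; zn *= z; }
  c[0] = sum;
  for (int i = 1; i < n; ++i)
    c[(size_t)i * stride] += z * c[(size_t)(i - 1) * stride];
  // anticausal init
  c[(size_t)(n - 1) * stride] =
    (z / (z * z - 1.0)) * (z * c[(size_t)(n - 2) * stride] + c[(size_t)(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[(size_t)i * stride] = z * (c[(size_t)(i + 1) * stride] - c[(size_t)i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double *V = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      prefilter_line(V + (size_t)nx * (j + (size_t)ny * k), nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      prefilter_line(V + i + (size_t)nx * ny * k, ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      prefilter_line(V + i + (size_t)nx * j, nz, (int)((size_t)nx * ny));
  return out;
}

static inline double tri_sample(const double *V, int nx, int ny, int nz,
                                double cx, double cy, double cz,
                                double fill, bool clamp) {
  if (clamp) {
    cx = std::min(std::max(cx, 0.0), (double)(nx - 1));
    cy = std::min(std::max(cy, 0.0), (double)(ny - 1));
    cz = std::min(std::max(cz, 0.0), (double)(nz - 1));
  } else if (cx < 0 || cy < 0 || cz < 0 ||
             cx > nx - 1 || cy > ny - 1 || cz > nz - 1) {
    return fill;
  }
  int i0 = (int)cx; if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)cy; if (j0 > ny - 2) j0 = ny - 2;
  int k0 = (int)cz; if (k0 > nz - 2) k0 = nz - 2;
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    double wz = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      double wy = dj ? fy : 1.0 - fy;
      double v0 = V[(i0) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
      double v1 = V[(i0 + 1) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
      acc += wz * wy * ((1.0 - fx) * v0 + fx * v1);
    }
  }
  return acc;
}

// Warp a scalar volume by a dense displacement field (mm, pull-back:
// out(x) = img(x + D(x))). mode 0: trilinear on raw values; mode 1: cubic
// B-spline on prefiltered coefficients. If with_grad, also returns the
// spatial intensity gradient (per mm) at the warped sample positions: cubic
// mode uses the analytic spline derivative; linear mode a +/- half-voxel
// secant of the trilinear interpolant (exactly central differences when the
// sample falls on a grid node).
// [[Rcpp::export]]
List cpp_warp(NumericVector img, IntegerVector dim, NumericVector spacing,
              NumericVector origin, NumericVector dvf, int mode,
              double fill, bool clamp, bool with_grad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double *V = img.begin();
  const double *Dx = dvf.begin(), *Dy = Dx + nvox, *Dz = Dy + nvox;
  NumericVector out(nvox);
  NumericVector gx, gy, gz;
  double *Gx = nullptr, *Gy = nullptr, *Gz = nullptr;
  if (with_grad) {
    gx = NumericVector(nvox); gy = NumericVector(nvox); gz = NumericVector(nvox);
    Gx = gx.begin(); Gy = gy.begin(); Gz = gz.begin();
  }
  double *O = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double cx = i + Dx[idx] / spacing[0];
        double cy = j + Dy[idx] / spacing[1];
        double cz = k + Dz[idx] / spacing[2];
        if (mode == 0) {
          O[idx] = tri_sample(V, nx, ny, nz, cx, cy, cz, fill, clamp);
          if (with_grad) {
            Gx[idx] = (tri_sample(V, nx, ny, nz, cx + 0.5, cy, cz, 0.0, true) -
                       tri_sample(V, nx, ny, nz, cx - 0.5, cy, cz, 0.0, true)) / spacing[0];
            Gy[idx] = (tri_sample(V, nx, ny, nz, cx, cy + 0.5, cz, 0.0, true) -
                       tri_sample(V, nx, ny, nz, cx, cy - 0.5, cz, 0.0, true)) / spacing[1];
            Gz[idx] = (tri_sample(V, nx, ny, nz, cx, cy, cz + 0.5, 0.0, true) -
                       tri_sample(V, nx, ny, nz, cx, cy, cz - 0.5, 0.0, true)) / spacing[2];
          }
        } else {
          // outside the volume: fill; inside, evaluate the spline with
          // mirror-extended coefficients (the prefilter's boundary
          // convention), so interpolation is exact at every voxel and the
          // value and its derivative are continuous in the displacement
          if (cx < 0 || cy < 0 || cz < 0 ||
              cx > nx - 1 || cy > ny - 1 || cz > nz - 1) {
            O[idx] = fill;
            if (with_grad) { Gx[idx] = 0.0; Gy[idx] = 0.0; Gz[idx] = 0.0; }
            continue;
          }
          int bi = (int)std::floor(cx), bj = (int)std::floor(cy), bk = (int)std::floor(cz);
          if (bi > nx - 2) bi = nx - 2;
          if (bj > ny - 2) bj = ny - 2;
          if (bk > nz - 2) bk = nz - 2;
          double wxv[4], wyv[4], wzv[4], wxd[4], wyd[4], wzd[4];
          bs_weights(cx - bi, wxv); bs_weights(cy - bj, wyv); bs_weights(cz - bk, wzv);
          if (with_grad) {
            bs_dweights(cx - bi, wxd); bs_dweights(cy - bj, wyd); bs_dweights(cz - bk, wzd);
          }
          auto mir = [](int i, int n) {
            if (i < 0) return -i;
            if (i >= n) return 2 * (n - 1) - i;
            return i;
          };
          double v = 0.0, dx = 0.0, dy = 0.0, dz = 0.0;
          for (int c3 = 0; c3 < 4; ++c3) {
            int kk = mir(bk - 1 + c3, nz);
            for (int c2 = 0; c2 < 4; ++c2) {
              int jj = mir(bj - 1 + c2, ny);
              size_t base = (size_t)nx * (jj + (size_t)ny * kk);
              double s0 = 0.0, s1 = 0.0;
              for (int c1 = 0; c1 < 4; ++c1) {
                int ii = mir(bi - 1 + c1, nx);
                double cval = V[base + ii];
                s0 += wxv[c1] * cval;
                if (with_grad) s1 += wxd[c1] * cval;
              }
              double wy_ = wyv[c2], wz_ = wzv[c3];
              v += wy_ * wz_ * s0;
              if (with_grad) {
                dx += wy_ * wz_ * s1;
                dy += wyd[c2] * wz_ * s0;
                dz += wy_ * wzd[c3] * s0;
              }
            }
          }
          O[idx] = v;
          if (with_grad) {
            Gx[idx] = dx / spacing[0];
            Gy[idx] = dy / spacing[1];
            Gz[idx] = dz / spacing[2];
          }
        }
      }
    }
  }
  if (with_grad)
    return List::create(_["value"] = out, _["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
  return List::create(_["value"] = out);
}

// Sample a 3-component displacement field at positions x + offset(x)
// (trilinear, edge-clamped) — one fixed-point sweep of DVF inversion.
// [[Rcpp::export]]
NumericVector cpp_compose_dvf(NumericVector dvf, IntegerVector dim,
                              NumericVector spacing, NumericVector offset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double *Ox = offset.begin(), *Oy = Ox + nvox, *Oz = Oy + nvox;
  NumericVector out(3 * nvox);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double cx = i + Ox[idx] / spacing[0];
        double cy = j + Oy[idx] / spacing[1];
        double cz = k + Oz[idx] / spacing[2];
        for (int comp = 0; comp < 3; ++comp)
          out[idx + comp * nvox] = tri_sample(dvf.begin() + comp * nvox,
                                              nx, ny, nz, cx, cy, cz, 0.0, true);
      }
  return out;
}

// Dyadic cubic B-spline coefficient refinement along one axis (halved node
// spacing, same origin): even nodes (c[i-1] + 6 c[i] + c[i+1])/8, odd nodes
// (c[i] + c[i+1])/2, zero extension outside.
// [[Rcpp::export]]
NumericVector cpp_refine_axis(NumericVector arr, IntegerVector dim, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int nn[3] = {nx, ny, nz};
  int n = nn[axis];
  int nout = 2 * n - 1;
  int odim[3] = {nx, ny, nz};
  odim[axis] = nout;
  NumericVector out((size_t)odim[0] * odim[1] * odim[2] * (arr.size() / ((size_t)nx * ny * nz)));
  int ncomp = (int)(arr.size() / ((size_t)nx * ny * nz));
  const double *A = arr.begin();
  double *O = out.begin();
  size_t involsz = (size_t)nx * ny * nz;
  size_t outvolsz = (size_t)odim[0] * odim[1] * odim[2];
  for (int comp = 0; comp < ncomp; ++comp) {
    for (int k = 0; k < odim[2]; ++k)
      for (int j = 0; j < odim[1]; ++j)
        for (int i = 0; i < odim[0]; ++i) {
          int oi[3] = {i, j, k};
          int t = oi[axis];
          int src[3] = {i, j, k};
          double val;
          auto get = [&](int s) -> double {
            if (s < 0 || s >= n) return 0.0;
            int c[3] = {src[0], src[1], src[2]};
            c[axis] = s;
            return A[comp * involsz + c[0] + (size_t)nx * (c[1] + (size_t)ny * c[2])];
          };
          if (t % 2 == 0) {
            int s = t / 2;
            val = (get(s - 1) + 6.0 * get(s) + get(s + 1)) / 8.0;
          } else {
            int s = (t - 1) / 2;
            val = 0.5 * (get(s) + get(s + 1));
          }
          O[comp * outvolsz + i + (size_t)odim[0] * (j + (size_t)odim[1] * k)] = val;
        }
  }
  return out;
}

// Separable (zero-padded) Gaussian convolution of a 3D volume; used by the
// volumetric SSIM. Kernel truncated at 3.5 sigma.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int rad = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (auto &v : ker) v /= s;
  NumericVector a = clone(vol), b(vol.size());
  int nn[3] = {nx, ny, nz};
  double *src = a.begin(), *dst = b.begin();
  for (int axis = 0; axis < 3; ++axis) {
    int n = nn[axis];
    size_t stride = 1;
    for (int t = 0; t < axis; ++t) stride *= nn[t];
    size_t nline = (size_t)nx * ny * nz / n;
    // iterate over all lines along `axis`
    for (size_t line = 0; line < nline; ++line) {
      // compute base index of this line
      size_t rem = line, base = 0, mult = 1;
      for (int t = 0; t < 3; ++t) {
        if (t == axis) { mult *= nn[t]; continue; }
        size_t coord = rem % nn[t];
        rem /= nn[t];
        base += coord * mult;
        mult *= nn[t];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        int lo = std::max(0, i - rad), hi = std::min(n - 1, i + rad);
        for (int m = lo; m <= hi; ++m)
          acc += ker[m - i + rad] * src[base + (size_t)m * stride];
        dst[base + (size_t)i * stride] = acc;
      }
    }
    std::swap(src, dst);
  }
  if (src == a.begin()) return a; else return b;
}
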