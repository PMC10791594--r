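#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circular-trajectory cone-beam geometry.
// World frame: isocenter at origin, gantry rotates in the x-y (axial) plane,
// z is the rotation axis. At gantry angle theta (radians) the source sits at
//   S = ( sid*cos(theta), sid*sin(theta), 0 )
// and the detector is a flat panel perpendicular to the source-isocenter line
// at distance sdd from the source, centered on that line, with in-plane axes
//   e_u = (-sin(theta), cos(theta), 0),  e_v = (0, 0, 1).
// Detector pixel (iu, iv) (0-based) has panel coordinates
//   u = (iu - (nu-1)/2)*du,  v = (iv - (nv-1)/2)*dv.
//
// Volumes are column-major (i + nx*(j + ny*k)); voxel (i,j,k) center is at
// origin + i*spacing (per axis). Trilinear sampling is valid for continuous
// voxel coordinates in [0, n-1]; outside, the volume contributes zero.
// Non-finite (null) voxel values contribute zero.

static inline void slab_clip(double p, double d, double lo, double hi,
                             double &t0, double &t1) {
  if (std::fabs(d) < 1e-12) {
    if (p < lo || p > hi) { t0 = 1.0; t1 = 0.0; } // miss
  } else {
    double a = (lo - p) / d, b = (hi - p) / d;
    if (a > b) std::swap(a, b);
    if (a > t0) t0 = a;
    if (b < t1) t1 = b;
  }
}

struct Ray {
  double sx, sy, sz;  // source
  double dx, dy, dz;  // unit direction
  double t0, t1;      // param interval inside sampling box (t1<t0: miss)
};

static Ray make_ray(double sid, double sdd, int nu, int nv, double du, double dv,
                    double ct, double st, int iu, int iv,
                    const double *orig, const double *sp, const int *n) {
  Ray r;
  r.sx = sid * ct; r.sy = sid * st; r.sz = 0.0;
  double u = (iu - 0.5 * (nu - 1)) * du;
  double v = (iv - 0.5 * (nv - 1)) * dv;
  // pixel world position
  double px = (sid - sdd) * ct - u * st;
  double py = (sid - sdd) * st + u * ct;
  double pz = v;
  double dx = px - r.sx, dy = py - r.sy, dz = pz - r.sz;
  double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
  r.dx = dx / nrm; r.dy = dy / nrm; r.dz = dz / nrm;
  r.t0 = 0.0; r.t1 = nrm; // never beyond the detector
  slab_clip(r.sx, r.dx, orig[0], orig[0] + (n[0] - 1) * sp[0], r.t0, r.t1);
  slab_clip(r.sy, r.dy, orig[1], orig[1] + (n[1] - 1) * sp[1], r.t0, r.t1);
  slab_clip(r.sz, r.dz, orig[2], orig[2] + (n[2] - 1) * sp[2], r.t0, r.t1);
  return r;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  double sid, double sdd,
                                  int nu, int nv, double du, double dv,
                                  double angle, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n[3] = {nx, ny, nz};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  const double ct = std::cos(angle), st = std::sin(angle);
  const double *V = vol.begin();
  NumericMatrix out(nu, nv);
  for (int iv = 0; iv < nv; ++iv) {
    for (int iu = 0; iu < nu; ++iu) {
      Ray r = make_ray(sid, sdd, nu, nv, du, dv, ct, st, iu, iv, orig, sp, n);
      if (r.t1 <= r.t0) { out(iu, iv) = 0.0; continue; }
      int K = (int)std::floor((r.t1 - r.t0) / step);
      double acc = 0.0;
      for (int m = 0; m < K; ++m) {
        double t = r.t0 + (m + 0.5) * step;
        double cx = (r.sx + t * r.dx - orig[0]) / sp[0];
        double cy = (r.sy + t * r.dy - orig[1]) / sp[1];
        double cz = (r.sz + t * r.dz - orig[2]) / sp[2];
        if (cx < 0 || cy < 0 || cz < 0 ||
            cx > nx - 1 || cy > ny - 1 || cz > nz - 1) continue;
        int i0 = (int)cx; if (i0 > nx - 2) i0 = nx - 2;
        int j0 = (int)cy; if (j0 > ny - 2) j0 = ny - 2;
        int k0 = (int)cz; if (k0 > nz - 2) k0 = nz - 2;
        double fx = cx - i0, fy = cy - j0, fz = cz - k0;
        for (int dk = 0; dk < 2; ++dk) {
          double wz = dk ? fz : 1.0 - fz;
          for (int dj = 0; dj < 2; ++dj) {
            double wy = dj ? fy : 1.0 - fy;
            for (int di = 0; di < 2; ++di) {
              double wx = di ? fx : 1.0 - fx;
              double val = V[(i0 + di) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
              if (R_finite(val)) acc += wx * wy * wz * val;
            }
          }
        }
      }
      out(iu, iv) = acc * step;
    }
  }
  return out;
}

// Exact transpose of cpp_forward_project: identical ray walk, scattering
// proj(iu,iv) * step * (trilinear weight) into the volume.
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericMatrix proj, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               double sid, double sdd,
                               int nu, int nv, double du, double dv,
                               double angle, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n[3] = {nx, ny, nz};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  const double ct = std::cos(angle), st = std::sin(angle);
  NumericVector vol((size_t)nx * ny * nz);
  double *V = vol.begin();
  for (int iv = 0; iv < nv; ++iv) {
    for (int iu = 0; iu < nu; ++iu) {
      double pval = proj(iu, iv);
      if (pval == 0.0) continue;
      Ray r = make_ray(sid, sdd, nu, nv, du, dv, ct, st, iu, iv, orig, sp, n);
      if (r.t1 <= r.t0) continue;
      int K = (int)std::floor((r.t1 - r.t0) / step);
      double w0 = pval * step;
      for (int m = 0; m < K; ++m) {
        double t = r.t0 + (m + 0.5) * step;
        double cx = (r.sx + t * r.dx - orig[0]) / sp[0];
        double cy = (r.sy + t * r.dy - orig[1]) / sp[1];
        double cz = (r.sz + t * r.dz - orig[2]) / sp[2];
        if (cx < 0 || cy < 0 || cz < 0 ||
            cx > nx - 1 || cy > ny - 1 || cz > nz - 1) continue;
        int i0 = (int)cx; if (i0 > nx - 2) i0 = nx - 2;
        int j0 = (int)cy; if (j0 > ny - 2) j0 = ny - 2;
        int k0 = (int)cz; if (k0 > nz - 2) k0 = nz - 2;
        double fx = cx - i0, fy = cy - j0, fz = cz - k0;
        for (int dk = 0; dk < 2; ++dk) {
          double wz = dk ? fz : 1.0 - fz;
          for (int dj = 0; dj < 2; ++dj) {
            double wy = dj ? fy : 1.0 - fy;
            for (int di = 0; di < 2; ++di) {
              double wx = di ? fx : 1.0 - fx;
              V[(i0 + di) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))] +=
                w0 * wx * wy * wz;
            }
          }
        }
      }
    }
  }
  return vol;
}

// Detector validity mask: a pixel is valid when the ray segment inside the
// volume sampling box stays within the (infinite in z) FOV cylinder of
// radius fov_radius (+ a one-voxel margin) about the rotation axis. The
// squared radial distance along a ray is a convex quadratic in the ray
// parameter, so checking the segment endpoints is exact. Rays that miss the
// box entirely carry a zero line integral and are treated as valid.
// [[Rcpp::export]]
LogicalMatrix cpp_detector_validity(IntegerVector dim, NumericVector spacing,
                                    NumericVector origin,
                                    double sid, double sdd,
                                    int nu, int nv, double du, double dv,
                                    double angle, double fov_radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n[3] = {nx, ny, nz};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  const double ct = std::cos(angle), st = std::sin(angle);
  const double margin = std::max(sp[0], std::max(sp[1], sp[2]));
  const double r2max = (fov_radius + margin) * (fov_radius + margin);
  LogicalMatrix out(nu, nv);
  for (int iv = 0; iv < nv; ++iv) {
    for (int iu = 0; iu < nu; ++iu) {
      Ray r = make_ray(sid, sdd, nu, nv, du, dv, ct, st, iu, iv, orig, sp, n);
      if (r.t1 <= r.t0) { out(iu, iv) = true; continue; }
      bool ok = true;
      for (double t : {r.t0, r.t1}) {
        double x = r.sx + t * r.dx, y = r.sy + t * r.dy;
        if (x * x + y * y > r2max) ok = false;
      }
      out(iu, iv) = ok;
    }
  }
  return out;
}

// Voxel-driven distance-weighted backprojection of one filtered projection
// (FDK accumulation step). `q` is the cosine-weighted, ramp-filtered
// projection; sampling is bilinear in isocenter-scaled detector coordinates.
// The per-voxel weight sid^2/depth^2 is applied here; the angular weight
// (2*pi/N_t) is applied by the caller.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject_frame(NumericMatrix q, IntegerVector dim,
                                        NumericVector spacing, NumericVector origin,
                                        double sid, double sdd,
                                        int nu, int nv, double du, double dv,
                                        double angle) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ct = std::cos(angle), st = std::sin(angle);
  const double dus = du * sid / sdd, dvs = dv * sid / sdd; // isocenter scale
  NumericVector vol((size_t)nx * ny * nz);
  double *V = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + i * spacing[0];
        double depth = sid - (x * ct + y * st);
        if (depth < 1e-3) continue;
        double s = sid * (-x * st + y * ct) / depth;
        double vv = sid * z / depth;
        double cu = s / dus + 0.5 * (nu - 1);
        double cv = vv / dvs + 0.5 * (nv - 1);
        if (cu < 0 || cv < 0 || cu > nu - 1 || cv > nv - 1) continue;
        int u0 = (int)cu; if (u0 > nu - 2) u0 = nu - 2;
        int v0 = (int)cv; if (v0 > nv - 2) v0 = nv - 2;
        double fu = cu - u0, fv = cv - v0;
        double val =
          (1 - fu) * (1 - fv) * q(u0, v0) + fu * (1 - fv) * q(u0 + 1, v0) +
          (1 - fu) * fv * q(u0, v0 + 1) + fu * fv * q(u0 + 1, v0 + 1);
        double w = sid / depth;
        V[idx] = w * w * val;
      }
    }
  }
  return vol;
}
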