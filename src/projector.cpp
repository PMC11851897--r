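#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Radiological path integration through an axis-aligned voxel grid.
// The grid occupies [origin, origin + dims*spacing] in the CT frame;
// voxel (i,j,k) spans [origin + (i,j,k)*spacing, origin + (i+1,j+1,k+1)*spacing].
// mu is the R column-major array value at linear index i + nx*(j + ny*k).

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Parametric entry/exit of segment p1 + a*(p2-p1), a in [0,1], with the box.
static bool box_clip(const double *p1, const double *d, const double *lo,
                     const double *hi, double &amin, double &amax) {
  amin = 0.0;
  amax = 1.0;
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(d[ax]) < 1e-14) {
      if (p1[ax] < lo[ax] || p1[ax] > hi[ax]) return false;
    } else {
      double a0 = (lo[ax] - p1[ax]) / d[ax];
      double a1 = (hi[ax] - p1[ax]) / d[ax];
      if (a0 > a1) std::swap(a0, a1);
      if (a0 > amin) amin = a0;
      if (a1 < amax) amax = a1;
    }
  }
  return amax > amin;
}

// Exact line integral of the piecewise-constant field along one segment
// (Siddon's parametric plane-crossing traversal, incremental form).
static double siddon_ray(const double *mu, const int *n, const double *org,
                         const double *sp, const double *p1, const double *p2) {
  double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double lo[3], hi[3];
  for (int ax = 0; ax < 3; ++ax) {
    lo[ax] = org[ax];
    hi[ax] = org[ax] + n[ax] * sp[ax];
  }
  double amin, amax;
  if (!box_clip(p1, d, lo, hi, amin, amax)) return 0.0;

  const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L == 0.0) return 0.0;

  // Voxel containing the entry point (nudged inward off the boundary).
  int idx[3];
  double anext[3], da[3];
  const double nudge = 1e-12;
  for (int ax = 0; ax < 3; ++ax) {
    double pos = p1[ax] + (amin + nudge) * d[ax];
    int i = (int)std::floor((pos - org[ax]) / sp[ax]);
    if (i < 0) i = 0;
    if (i >= n[ax]) i = n[ax] - 1;
    idx[ax] = i;
    if (d[ax] > 1e-14) {
      anext[ax] = (org[ax] + (i + 1) * sp[ax] - p1[ax]) / d[ax];
      da[ax] = sp[ax] / d[ax];
    } else if (d[ax] < -1e-14) {
      anext[ax] = (org[ax] + i * sp[ax] - p1[ax]) / d[ax];
      da[ax] = -sp[ax] / d[ax];
    } else {
      anext[ax] = std::numeric_limits<double>::infinity();
      da[ax] = std::numeric_limits<double>::infinity();
    }
  }

  const int nx = n[0], ny = n[1];
  double a = amin, total = 0.0;
  while (a < amax - 1e-14) {
    double astep = std::min(std::min(anext[0], anext[1]),
                            std::min(anext[2], amax));
    double seg = (astep - a) * L;
    if (seg > 0)
      total += seg * mu[idx[0] + nx * (idx[1] + (size_t)ny * idx[2])];
    // advance every axis whose plane we just crossed
    bool left_grid = false;
    for (int ax = 0; ax < 3; ++ax) {
      if (anext[ax] <= astep + 1e-14 && astep < amax) {
        idx[ax] += (d[ax] > 0) ? 1 : -1;
        anext[ax] += da[ax];
        if (idx[ax] < 0 || idx[ax] >= n[ax]) left_grid = true;
      }
    }
    a = astep;
    if (left_grid) break;
  }
  return total;
}

// Trilinear interpolation with voxel-center convention; outside the grid
// of voxel centers the nearest value is used (clamped coordinates).
static double trilin(const double *mu, const int *n, const double *org,
                     const double *sp, const double *p) {
  double u[3];
  for (int ax = 0; ax < 3; ++ax) {
    u[ax] = (p[ax] - org[ax]) / sp[ax] - 0.5;
    u[ax] = clampd(u[ax], 0.0, (double)(n[ax] - 1));
  }
  int i0 = (int)std::floor(u[0]), j0 = (int)std::floor(u[1]),
      k0 = (int)std::floor(u[2]);
  if (i0 >= n[0] - 1) i0 = n[0] - 2 >= 0 ? n[0] - 2 : 0;
  if (j0 >= n[1] - 1) j0 = n[1] - 2 >= 0 ? n[1] - 2 : 0;
  if (k0 >= n[2] - 1) k0 = n[2] - 2 >= 0 ? n[2] - 2 : 0;
  double fx = clampd(u[0] - i0, 0.0, 1.0);
  double fy = clampd(u[1] - j0, 0.0, 1.0);
  double fz = clampd(u[2] - k0, 0.0, 1.0);
  const int nx = n[0], ny = n[1];
  int i1 = i0 + 1 < n[0] ? i0 + 1 : i0;
  int j1 = j0 + 1 < n[1] ? j0 + 1 : j0;
  int k1 = k0 + 1 < n[2] ? k0 + 1 : k0;
#define MU(i, j, k) mu[(i) + nx * ((j) + (size_t)ny * (k))]
  double c00 = MU(i0, j0, k0) * (1 - fx) + MU(i1, j0, k0) * fx;
  double c10 = MU(i0, j1, k0) * (1 - fx) + MU(i1, j1, k0) * fx;
  double c01 = MU(i0, j0, k1) * (1 - fx) + MU(i1, j0, k1) * fx;
  double c11 = MU(i0, j1, k1) * (1 - fx) + MU(i1, j1, k1) * fx;
#undef MU
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".cpp_project_siddon")]]
NumericVector cpp_project_siddon(NumericVector mu, IntegerVector dims,
                                 NumericVector origin, NumericVector spacing,
                                 NumericVector src, NumericMatrix pix) {
  int n[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double p1[3] = {src[0], src[1], src[2]};
  const int m = pix.nrow();
  NumericVector out(m);
  const double *muv = REAL(mu);
  for (int r = 0; r < m; ++r) {
    double p2[3] = {pix(r, 0), pix(r, 1), pix(r, 2)};
    out[r] = siddon_ray(muv, n, org, sp, p1, p2);
  }
  return out;
}

// Trapezoidal integration of the trilinearly interpolated field along each
// ray, clipped to the voxel box; an independent slow reference for the
// Siddon projector.
// [[Rcpp::export(name = ".cpp_project_dense")]]
NumericVector cpp_project_dense(NumericVector mu, IntegerVector dims,
                                NumericVector origin, NumericVector spacing,
                                NumericVector src, NumericMatrix pix,
                                double step) {
  int n[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double p1[3] = {src[0], src[1], src[2]};
  const int m = pix.nrow();
  NumericVector out(m);
  const double *muv = REAL(mu);
  double lo[3], hi[3];
  for (int ax = 0; ax < 3; ++ax) {
    lo[ax] = org[ax];
    hi[ax] = org[ax] + n[ax] * sp[ax];
  }
  for (int r = 0; r < m; ++r) {
    double p2[3] = {pix(r, 0), pix(r, 1), pix(r, 2)};
    double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double amin, amax;
    if (!box_clip(p1, d, lo, hi, amin, amax)) { out[r] = 0.0; continue; }
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double seg = (amax - amin) * L;
    int nstep = (int)std::ceil(seg / step);
    if (nstep < 2) nstep = 2;
    double dt = (amax - amin) / nstep;
    double total = 0.0, prev = 0.0;
    for (int s = 0; s <= nstep; ++s) {
      double a = amin + s * dt;
      double p[3] = {p1[0] + a * d[0], p1[1] + a * d[1], p1[2] + a * d[2]};
      double f = trilin(muv, n, org, sp, p);
      if (s > 0) total += 0.5 * (prev + f) * dt * L;
      prev = f;
    }
    out[r] = total;
  }
  return out;
}
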