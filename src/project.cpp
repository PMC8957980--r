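#include <Rcpp.h>
#include <cmath>
#include <vector>

// Slice-parallel 2D parallel-beam projector with exact voxel-ray
// intersection lengths (Amanatides-Woo traversal). The same traversal
// routine produces the (voxel, length) pairs for the forward projection,
// the back projection and the attenuation line integrals, so X^T is the
// exact adjoint of X.

namespace {

struct Seg {
  int idx;
  double len;
};

// Trace the LOR with radial offset s (mm) and angle theta through an
// nx x ny pixel grid centered on the origin. Appends (pixel, length-mm).
void trace_ray(double s, double theta, int nx, int ny, double vx, double vy,
               std::vector<Seg>& segs) {
  segs.clear();
  const double ct = std::cos(theta), st = std::sin(theta);
  const double dx = -st, dy = ct;        // ray direction
  const double px = s * ct, py = s * st; // a point on the ray
  const double x0 = -0.5 * nx * vx, y0 = -0.5 * ny * vy;
  double tmin = -1e30, tmax = 1e30;
  if (std::fabs(dx) > 1e-12) {
    double t1 = (x0 - px) / dx, t2 = (x0 + nx * vx - px) / dx;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
  } else if (px <= x0 || px >= x0 + nx * vx) {
    return;
  }
  if (std::fabs(dy) > 1e-12) {
    double t1 = (y0 - py) / dy, t2 = (y0 + ny * vy - py) / dy;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
  } else if (py <= y0 || py >= y0 + ny * vy) {
    return;
  }
  if (tmin >= tmax) return;

  const double eps = 1e-9 * (vx + vy);
  double t = tmin;
  double xs = px + dx * (t + eps), ys = py + dy * (t + eps);
  int ix = (int)std::floor((xs - x0) / vx);
  int iy = (int)std::floor((ys - y0) / vy);
  if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
  int stepx = (dx > 0) - (dx < 0);
  int stepy = (dy > 0) - (dy < 0);
  double tMaxX, tMaxY, tDeltaX, tDeltaY;
  if (stepx != 0) {
    double bx = x0 + (ix + (stepx > 0 ? 1 : 0)) * vx;
    tMaxX = (bx - px) / dx;
    tDeltaX = vx / std::fabs(dx);
  } else {
    tMaxX = 1e30; tDeltaX = 1e30;
  }
  if (stepy != 0) {
    double by = y0 + (iy + (stepy > 0 ? 1 : 0)) * vy;
    tMaxY = (by - py) / dy;
    tDeltaY = vy / std::fabs(dy);
  } else {
    tMaxY = 1e30; tDeltaY = 1e30;
  }
  while (t < tmax - eps) {
    double tnext = std::min(std::min(tMaxX, tMaxY), tmax);
    double len = tnext - t;
    if (len > 0) segs.push_back({ix + nx * iy, len});
    t = tnext;
    if (t >= tmax - eps) break;
    if (tMaxX <= tMaxY) {
      ix += stepx;
      tMaxX += tDeltaX;
      if (ix < 0 || ix >= nx) break;
    } else {
      iy += stepy;
      tMaxY += tDeltaY;
      if (iy < 0 || iy >= ny) break;
    }
  }
}

}  // namespace

// Forward projection: sinogram[radial, angle, slice] = sum_j x_ij f_j.
// thetas are the angles (radians) of the (possibly subset) projection.
// [[Rcpp::export(name = ".cpp_forward_project")]]
Rcpp::NumericVector cpp_forward_project(Rcpp::NumericVector img,
                                        int nx, int ny, int nz,
                                        double vx, double vy,
                                        int n_radial, double bin,
                                        Rcpp::NumericVector thetas) {
  int na = thetas.size();
  Rcpp::NumericVector out((R_xlen_t)n_radial * na * nz);
  std::vector<Seg> segs;
  const double s0 = -0.5 * (n_radial - 1) * bin;
  for (int a = 0; a < na; ++a) {
    for (int r = 0; r < n_radial; ++r) {
      trace_ray(s0 + r * bin, thetas[a], nx, ny, vx, vy, segs);
      if (segs.empty()) continue;
      for (int z = 0; z < nz; ++z) {
        const double* slab = &img[(R_xlen_t)nx * ny * z];
        double acc = 0.0;
        for (const Seg& sg : segs) acc += sg.len * slab[sg.idx];
        out[r + (R_xlen_t)n_radial * (a + (R_xlen_t)na * z)] = acc;
      }
    }
  }
  return out;
}

// Back projection (exact adjoint): img_j = sum_i x_ij g_i.
// [[Rcpp::export(name = ".cpp_back_project")]]
Rcpp::NumericVector cpp_back_project(Rcpp::NumericVector sino,
                                     int nx, int ny, int nz,
                                     double vx, double vy,
                                     int n_radial, double bin,
                                     Rcpp::NumericVector thetas) {
  int na = thetas.size();
  Rcpp::NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<Seg> segs;
  const double s0 = -0.5 * (n_radial - 1) * bin;
  for (int a = 0; a < na; ++a) {
    for (int r = 0; r < n_radial; ++r) {
      trace_ray(s0 + r * bin, thetas[a], nx, ny, vx, vy, segs);
      if (segs.empty()) continue;
      for (int z = 0; z < nz; ++z) {
        double g = sino[r + (R_xlen_t)n_radial * (a + (R_xlen_t)na * z)];
        if (g == 0.0) continue;
        double* slab = &out[(R_xlen_t)nx * ny * z];
        for (const Seg& sg : segs) slab[sg.idx] += sg.len * g;
      }
    }
  }
  return out;
}

// Per-LOR attenuation factors w_i = exp(-sum_j x_ij mu_j / 10); mu in
// cm^-1, intersection lengths in mm.
// [[Rcpp::export(name = ".cpp_attenuation_factors")]]
Rcpp::NumericVector cpp_attenuation_factors(Rcpp::NumericVector mu,
                                            int nx, int ny, int nz,
                                            double vx, double vy,
                                            int n_radial, double bin,
                                            Rcpp::NumericVector thetas) {
  int na = thetas.size();
  Rcpp::NumericVector out((R_xlen_t)n_radial * na * nz);
  std::vector<Seg> segs;
  const double s0 = -0.5 * (n_radial - 1) * bin;
  for (int a = 0; a < na; ++a) {
    for (int r = 0; r < n_radial; ++r) {
      trace_ray(s0 + r * bin, thetas[a], nx, ny, vx, vy, segs);
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        const double* slab = &mu[(R_xlen_t)nx * ny * z];
        for (const Seg& sg : segs) acc += sg.len * slab[sg.idx];
        out[r + (R_xlen_t)n_radial * (a + (R_xlen_t)na * z)] =
            std::exp(-acc / 10.0);
      }
    }
  }
  return out;
}
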