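#include <Rcpp.h>
#include <cmath>
#include <random>

// Condensed-history positron transport.
//
// Per step the positron loses a fixed fraction of its kinetic energy via the
// collision stopping power of the local medium (Berger-Seltzer closed form
// for water, scaled by electron density relative to water), advances by
// dE / (dE/dx), and is deflected by a Highland multiple-scattering angle
// drawn from a Rayleigh distribution of the plane-projected RMS. Below the
// energy cutoff it annihilates in place. Annihilation-in-flight,
// bremsstrahlung transport and positronium formation are ignored.

namespace {

const double ME = 0.510998950;   // electron rest energy, MeV
const double I_WATER = 75.0e-6;  // mean excitation energy of water, MeV
const double ZA_WATER = 0.55509; // Z/A of water

// Collision stopping power of water for positrons, MeV cm^2/g.
// Berger-Seltzer formula with the positron form of the F term; density
// effect omitted (small below 3 MeV). Valid over the tabulated window
// 10 keV - 3 MeV; clamped outside.
double sp_mass_water(double T) {
  if (T < 0.010) T = 0.010;
  if (T > 3.0) T = 3.0;
  double tau = T / ME;
  double gamma = tau + 1.0;
  double beta2 = 1.0 - 1.0 / (gamma * gamma);
  double d = tau + 2.0;
  double fpos = 2.0 * std::log(2.0) -
                (beta2 / 12.0) *
                    (23.0 + 14.0 / d + 10.0 / (d * d) + 4.0 / (d * d * d));
  double im = I_WATER / ME;
  double lnterm = std::log(tau * tau * d / (2.0 * im * im));
  return 0.153536 / beta2 * ZA_WATER * (lnterm + fpos);
}

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t s) : g(s * 2654435761ULL + 0x9E3779B97F4A7C15ULL) {}
  // uniform in [0, 1)
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1]
  double unif_pos() { return 1.0 - unif(); }
};

struct Vec3 {
  double x, y, z;
};

Vec3 iso_dir(Rng& rng) {
  double c = 2.0 * rng.unif() - 1.0;
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = 2.0 * M_PI * rng.unif();
  Vec3 d;
  d.x = s * std::cos(phi);
  d.y = s * std::sin(phi);
  d.z = c;
  return d;
}

// Rotate unit vector d away from itself by polar angle theta, uniform
// azimuth phi, using an orthonormal basis perpendicular to d.
Vec3 deflect(const Vec3& d, double theta, double phi) {
  Vec3 a;  // any vector not parallel to d
  if (std::fabs(d.z) < 0.9) {
    a.x = 0; a.y = 0; a.z = 1;
  } else {
    a.x = 1; a.y = 0; a.z = 0;
  }
  // e1 = normalize(a x d), e2 = d x e1
  Vec3 e1;
  e1.x = a.y * d.z - a.z * d.y;
  e1.y = a.z * d.x - a.x * d.z;
  e1.z = a.x * d.y - a.y * d.x;
  double n = std::sqrt(e1.x * e1.x + e1.y * e1.y + e1.z * e1.z);
  e1.x /= n; e1.y /= n; e1.z /= n;
  Vec3 e2;
  e2.x = d.y * e1.z - d.z * e1.y;
  e2.y = d.z * e1.x - d.x * e1.z;
  e2.z = d.x * e1.y - d.y * e1.x;
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  Vec3 out;
  out.x = ct * d.x + st * (cp * e1.x + sp * e2.x);
  out.y = ct * d.y + st * (cp * e1.y + sp * e2.y);
  out.z = ct * d.z + st * (cp * e1.z + sp * e2.z);
  return out;
}

// Highland plane-projected RMS scattering angle for a step of x g/cm^2 in a
// medium of radiation length X0 g/cm^2, at kinetic energy T (MeV).
double highland_theta0(double T, double x_gcm2, double X0_gcm2) {
  if (x_gcm2 <= 0.0) return 0.0;
  double E = T + ME;
  double p = std::sqrt(E * E - ME * ME);
  double beta = p / E;
  double t = x_gcm2 / X0_gcm2;
  double corr = 1.0 + 0.038 * std::log(t);
  if (corr < 0.1) corr = 0.1;
  // 13.6 MeV with p in MeV gives theta in radians
  return 13.6 / (beta * p) * std::sqrt(t) * corr;
}

}  // namespace

// Transport a batch of positrons in a homogeneous medium. Emission at the
// origin, isotropic initial direction. Returns the n x 3 matrix of
// annihilation coordinates in mm.
// [[Rcpp::export(name = ".cpp_transport_uniform")]]
Rcpp::NumericMatrix cpp_transport_uniform(Rcpp::NumericVector T0,
                                          double rho_e_rel,
                                          double rho_mass,
                                          double X0_gcm2,
                                          double cutoff_MeV,
                                          double fstep,
                                          double seed) {
  int n = T0.size();
  Rcpp::NumericMatrix out(n, 3);
  Rng rng(static_cast<uint64_t>(seed));
  for (int i = 0; i < n; ++i) {
    double T = T0[i];
    Vec3 pos = {0, 0, 0};
    if (T > cutoff_MeV) {
      Vec3 dir = iso_dir(rng);
      while (T > cutoff_MeV) {
        double S = sp_mass_water(T) * rho_e_rel / 10.0;  // MeV/mm
        double dE = fstep * T;
        double step = dE / S;  // mm
        pos.x += dir.x * step;
        pos.y += dir.y * step;
        pos.z += dir.z * step;
        T -= dE;
        if (T <= cutoff_MeV) break;
        double x_gcm2 = step / 10.0 * rho_mass;
        double th0 = highland_theta0(T, x_gcm2, X0_gcm2);
        double theta = th0 * std::sqrt(-2.0 * std::log(rng.unif_pos()));
        double phi = 2.0 * M_PI * rng.unif();
        dir = deflect(dir, theta, phi);
      }
    }
    out(i, 0) = pos.x;
    out(i, 1) = pos.y;
    out(i, 2) = pos.z;
  }
  return out;
}

// Transport in a voxelized material map. labels: 0-based material index per
// voxel (column-major x fastest); per-material electron density, mass
// density and radiation length vectors. Emission at source_mm (grid-centered
// mm coordinates). Steps are capped at half the smallest voxel pitch so the
// local material is re-evaluated at least twice per voxel crossed.
// Positions outside the map use the nearest in-map voxel's material.
// [[Rcpp::export(name = ".cpp_transport_map")]]
Rcpp::NumericMatrix cpp_transport_map(Rcpp::NumericVector T0,
                                      Rcpp::IntegerVector labels,
                                      int nx, int ny, int nz,
                                      Rcpp::NumericVector voxel,
                                      Rcpp::NumericVector source_mm,
                                      Rcpp::NumericVector rho_e_rel,
                                      Rcpp::NumericVector rho_mass,
                                      Rcpp::NumericVector X0_gcm2,
                                      double cutoff_MeV,
                                      double fstep,
                                      double seed) {
  int n = T0.size();
  Rcpp::NumericMatrix out(n, 3);
  Rng rng(static_cast<uint64_t>(seed));
  double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  double hx = 0.5 * nx * vx, hy = 0.5 * ny * vy, hz = 0.5 * nz * vz;
  double max_step = 0.5 * std::min(vx, std::min(vy, vz));
  auto mat_at = [&](const Vec3& p) -> int {
    int ix = (int)std::floor((p.x + hx) / vx);
    int iy = (int)std::floor((p.y + hy) / vy);
    int iz = (int)std::floor((p.z + hz) / vz);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
    return labels[ix + nx * (iy + (R_xlen_t)ny * iz)];
  };
  for (int i = 0; i < n; ++i) {
    double T = T0[i];
    Vec3 pos = {source_mm[0], source_mm[1], source_mm[2]};
    if (T > cutoff_MeV) {
      Vec3 dir = iso_dir(rng);
      while (T > cutoff_MeV) {
        int m = mat_at(pos);
        double S = sp_mass_water(T) * rho_e_rel[m] / 10.0;  // MeV/mm
        double dE = fstep * T;
        double step = dE / S;
        if (step > max_step) {
          step = max_step;
          dE = step * S;
        }
        pos.x += dir.x * step;
        pos.y += dir.y * step;
        pos.z += dir.z * step;
        T -= dE;
        if (T <= cutoff_MeV) break;
        double x_gcm2 = step / 10.0 * rho_mass[m];
        double th0 = highland_theta0(T, x_gcm2, X0_gcm2[m]);
        double theta = th0 * std::sqrt(-2.0 * std::log(rng.unif_pos()));
        double phi = 2.0 * M_PI * rng.unif();
        dir = deflect(dir, theta, phi);
      }
    }
    out(i, 0) = pos.x;
    out(i, 1) = pos.y;
    out(i, 2) = pos.z;
  }
  return out;
}

// Collision stopping power of water for positrons (MeV cm^2/g), vectorized;
// exposed so the tabulation backing the transport can be inspected/tested.
// [[Rcpp::export(name = ".cpp_sp_mass_water")]]
Rcpp::NumericVector cpp_sp_mass_water(Rcpp::NumericVector T) {
  int n = T.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sp_mass_water(T[i]);
  return out;
}
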