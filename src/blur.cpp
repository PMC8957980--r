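#include <Rcpp.h>
#include <cmath>
#include <vector>

// Positron-range resolution operator H and its exact transpose.
//
// H is applied as per-voxel scatter: every source voxel j distributes its
// value over the kernel attached to j; kernel mass falling outside the
// image is dropped (no renormalization at the image border, which keeps
// H^T an exact transpose). The kernel attached to j is, per provider mode:
//   0 (uniform):            one fixed kernel for every voxel;
//   1 (tissue-dependent):   the uniform kernel of the material at j;
//   2 (spatially variant):  composed per offset u from the uniform kernel
//                           of the material at the destination voxel j+u
//                           (clamped to the image for the material lookup),
//                           then renormalized to sum 1.

namespace {

struct Off {
  int du, dv, dw;
  double val;
};

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Compose the spatially variant kernel at voxel (jx,jy,jz); writes s^3
// values (normalized) into k.
void compose_at(const double* kern, int s, int half, int nmat,
                const int* labels, int nx, int ny, int nz,
                int jx, int jy, int jz, std::vector<double>& k) {
  (void)nmat;
  const int s2 = s * s;
  // homogeneous neighborhood: copy the material's kernel verbatim (it is
  // already normalized), keeping the composition bitwise-identical to the
  // uniform kernel away from borders
  {
    int lab0 = labels[clampi(jx - half, 0, nx - 1) +
                      nx * (clampi(jy - half, 0, ny - 1) +
                            (R_xlen_t)ny * clampi(jz - half, 0, nz - 1))];
    bool homog = true;
    for (int w = -half; w <= half && homog; ++w) {
      int z = clampi(jz + w, 0, nz - 1);
      for (int v = -half; v <= half && homog; ++v) {
        int y = clampi(jy + v, 0, ny - 1);
        for (int u = -half; u <= half; ++u) {
          int x = clampi(jx + u, 0, nx - 1);
          if (labels[x + nx * (y + (R_xlen_t)ny * z)] != lab0) {
            homog = false;
            break;
          }
        }
      }
    }
    if (homog) {
      for (int o = 0; o < s2 * s; ++o) k[o] = kern[o + (R_xlen_t)s2 * s * lab0];
      return;
    }
  }
  double tot = 0.0;
  for (int w = 0; w < s; ++w) {
    int z = clampi(jz + w - half, 0, nz - 1);
    for (int v = 0; v < s; ++v) {
      int y = clampi(jy + v - half, 0, ny - 1);
      for (int u = 0; u < s; ++u) {
        int x = clampi(jx + u - half, 0, nx - 1);
        int lab = labels[x + nx * (y + (R_xlen_t)ny * z)];
        int o = u + s * v + s2 * w;
        double val = kern[o + (R_xlen_t)s2 * s * lab];
        k[o] = val;
        tot += val;
      }
    }
  }
  if (tot > 0.0) {
    for (int o = 0; o < s2 * s; ++o) k[o] /= tot;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_compose_kernel")]]
Rcpp::NumericVector cpp_compose_kernel(Rcpp::NumericMatrix kernels, int half,
                                       Rcpp::IntegerVector labels,
                                       int nx, int ny, int nz,
                                       int jx, int jy, int jz) {
  int s = 2 * half + 1;
  std::vector<double> k((size_t)s * s * s);
  compose_at(&kernels[0], s, half, kernels.ncol(), &labels[0], nx, ny, nz,
             jx, jy, jz, k);
  return Rcpp::NumericVector(k.begin(), k.end());
}

// Apply H (adjoint = false) or H^T (adjoint = true).
// kernels: s^3 x nmat matrix of normalized kernels (material-major
// columns); mode 0 uses column 0 only; labels required for modes 1 and 2.
// [[Rcpp::export(name = ".cpp_pr_blur")]]
Rcpp::NumericVector cpp_pr_blur(Rcpp::NumericVector img,
                                int nx, int ny, int nz,
                                int mode,
                                Rcpp::NumericMatrix kernels, int half,
                                Rcpp::IntegerVector labels,
                                bool adjoint) {
  const int s = 2 * half + 1, s2 = s * s;
  Rcpp::NumericVector out((R_xlen_t)nx * ny * nz);

  if (mode == 0 || mode == 1) {
    // precompute nonzero offsets per material column
    int nmat = (mode == 0) ? 1 : kernels.ncol();
    std::vector<std::vector<Off>> offs(nmat);
    for (int m = 0; m < nmat; ++m) {
      for (int w = 0; w < s; ++w)
        for (int v = 0; v < s; ++v)
          for (int u = 0; u < s; ++u) {
            double val = kernels(u + s * v + s2 * w, m);
            if (val != 0.0) offs[m].push_back({u - half, v - half, w - half, val});
          }
    }
    for (int jz = 0; jz < nz; ++jz)
      for (int jy = 0; jy < ny; ++jy)
        for (int jx = 0; jx < nx; ++jx) {
          R_xlen_t j = jx + nx * (jy + (R_xlen_t)ny * jz);
          int m = (mode == 0) ? 0 : labels[j];
          double fj = img[j];
          if (!adjoint && fj == 0.0) continue;
          double acc = 0.0;
          for (const Off& o : offs[m]) {
            int x = jx + o.du, y = jy + o.dv, z = jz + o.dw;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            R_xlen_t jp = x + nx * (y + (R_xlen_t)ny * z);
            if (adjoint)
              acc += o.val * img[jp];
            else
              out[jp] += o.val * fj;
          }
          if (adjoint) out[j] = acc;
        }
    return out;
  }

  // mode 2: spatially variant, kernel composed on the fly per voxel
  std::vector<double> k((size_t)s2 * s);
  for (int jz = 0; jz < nz; ++jz)
    for (int jy = 0; jy < ny; ++jy)
      for (int jx = 0; jx < nx; ++jx) {
        R_xlen_t j = jx + nx * (jy + (R_xlen_t)ny * jz);
        double fj = img[j];
        if (!adjoint && fj == 0.0) continue;
        compose_at(&kernels[0], s, half, kernels.ncol(), &labels[0],
                   nx, ny, nz, jx, jy, jz, k);
        double acc = 0.0;
        for (int w = 0; w < s; ++w) {
          int z = jz + w - half;
          if (z < 0 || z >= nz) continue;
          for (int v = 0; v < s; ++v) {
            int y = jy + v - half;
            if (y < 0 || y >= ny) continue;
            for (int u = 0; u < s; ++u) {
              int x = jx + u - half;
              if (x < 0 || x >= nx) continue;
              double val = k[u + s * v + s2 * w];
              if (val == 0.0) continue;
              R_xlen_t jp = x + nx * (y + (R_xlen_t)ny * z);
              if (adjoint)
                acc += val * img[jp];
              else
                out[jp] += val * fj;
            }
          }
        }
        if (adjoint) out[j] = acc;
      }
  return out;
}
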