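#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All volumes are cubic n x n x n arrays in R column-major order
// (index = ix + n*(iy + n*iz)), voxel coordinates 0-based, object/FFT
// center at c = floor(n/2).  Images are n x n matrices indexed [u, v],
// filament axis along v at zero tilt/psi.

static inline bool trilinear(const double* v, int n, double x, double y,
                             double z, double& out) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > n - 1.0 || y > n - 1.0 || z > n - 1.0) return false;
  int x0 = (int)std::floor(x); if (x0 > n - 2) x0 = n - 2;
  int y0 = (int)std::floor(y); if (y0 > n - 2) y0 = n - 2;
  int z0 = (int)std::floor(z); if (z0 > n - 2) z0 = n - 2;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double* p = v + x0 + n * (y0 + (size_t)n * z0);
  size_t sy = n, sz = (size_t)n * n;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + 1] * fx;
  out = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
        (c01 * (1 - fy) + c11 * fy) * fz;
  return true;
}

static inline bool bilinear(const double* im, int n, double x, double y,
                            double& out) {
  if (x < 0.0 || y < 0.0 || x > n - 1.0 || y > n - 1.0) return false;
  int x0 = (int)std::floor(x); if (x0 > n - 2) x0 = n - 2;
  int y0 = (int)std::floor(y); if (y0 > n - 2) y0 = n - 2;
  double fx = x - x0, fy = y - y0;
  const double* p = im + x0 + (size_t)n * y0;
  out = (p[0] * (1 - fx) + p[1] * fx) * (1 - fy) +
        (p[n] * (1 - fx) + p[n + 1] * fx) * fy;
  return true;
}

// Line-integral projection of a cubic volume along direction d, image
// basis (u, v); image value at (i, j) integrates the volume at
// cen + (i - cen - sx)*u + (j - cen - sy)*v + t*d over t (voxel steps).
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, int n,
                          NumericVector u, NumericVector v,
                          NumericVector d, double sx, double sy) {
  NumericMatrix out(n, n);
  const double* vp = vol.begin();
  double cen = std::floor(n / 2.0);
  for (int j = 0; j < n; ++j) {
    double bj = j - cen - sy;
    for (int i = 0; i < n; ++i) {
      double bi = i - cen - sx;
      double px = cen + bi * u[0] + bj * v[0];
      double py = cen + bi * u[1] + bj * v[1];
      double pz = cen + bi * u[2] + bj * v[2];
      double acc = 0.0, s;
      for (int t = 0; t < n; ++t) {
        double tt = t - cen;
        if (trilinear(vp, n, px + tt * d[0], py + tt * d[1],
                      pz + tt * d[2], s)) acc += s;
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Voxel-driven back-projection of one image: each voxel p accumulates the
// bilinearly interpolated image value at (dot(p - cen, u) + cen,
// dot(p - cen, v) + cen).  Accumulates into acc in place.
// [[Rcpp::export]]
void cpp_backproject(NumericVector acc, NumericMatrix img, int n,
                     NumericVector u, NumericVector v) {
  double* ap = acc.begin();
  const double* ip = img.begin();
  double cen = std::floor(n / 2.0);
  size_t idx = 0;
  for (int iz = 0; iz < n; ++iz) {
    double qz = iz - cen;
    for (int iy = 0; iy < n; ++iy) {
      double qy = iy - cen;
      for (int ix = 0; ix < n; ++ix, ++idx) {
        double qx = ix - cen;
        double xi = qx * u[0] + qy * u[1] + qz * u[2] + cen;
        double yi = qx * v[0] + qy * v[1] + qz * v[2] + cen;
        double s;
        if (bilinear(ip, n, xi, yi, s)) ap[idx] += s;
      }
    }
  }
}

// Average a volume over the helical symmetry operators k*twist/k*rise
// (k = -kmax..kmax) combined with Cn rotations; source points restricted
// to the axial band [zlo, zhi] (voxels); voxels at cylinder radius
// > mask_r are zeroed.  twist in radians, rise in voxels.
// [[Rcpp::export]]
NumericVector cpp_symmetrize(NumericVector vol, int n, double twist,
                             double rise, int kmax, int cn,
                             double mask_r, double zlo, double zhi) {
  NumericVector out((size_t)n * n * n);
  const double* vp = vol.begin();
  double* op = out.begin();
  double cen = std::floor(n / 2.0);
  int nops = (2 * kmax + 1) * cn;
  std::vector<double> ca(nops), sa(nops), dz(nops);
  int q = 0;
  for (int k = -kmax; k <= kmax; ++k) {
    for (int j = 0; j < cn; ++j, ++q) {
      double ang = -(k * twist + j * 2.0 * M_PI / cn);
      ca[q] = std::cos(ang); sa[q] = std::sin(ang);
      dz[q] = k * rise;
    }
  }
  size_t idx = 0;
  for (int iz = 0; iz < n; ++iz) {
    double z = iz - cen;
    for (int iy = 0; iy < n; ++iy) {
      double y = iy - cen;
      for (int ix = 0; ix < n; ++ix, ++idx) {
        double x = ix - cen;
        if (x * x + y * y > mask_r * mask_r) continue;
        double acc = 0.0; int cnt = 0; double s;
        for (int t = 0; t < nops; ++t) {
          double zz = iz - dz[t];
          if (zz < zlo || zz > zhi) continue;
          double xx = ca[t] * x - sa[t] * y + cen;
          double yy = sa[t] * x + ca[t] * y + cen;
          if (trilinear(vp, n, xx, yy, zz, s)) { acc += s; ++cnt; }
        }
        op[idx] = cnt > 0 ? acc / cnt : 0.0;
      }
    }
  }
  return out;
}

// Masked mean-squared self-mismatch of a volume under one forward helical
// operator (twist radians, rise voxels), evaluated symmetrically: the
// half-operator images g^(+1/2) and g^(-1/2) of each voxel are compared,
// so both sides carry the same interpolation smoothing and the minimum is
// unbiased.  Compared voxels: cylinder radius <= mask_r, z in [zlo, zhi],
// both preimages inside the box.  Returns c(mse, n_compared).
// [[Rcpp::export]]
NumericVector cpp_helical_residual(NumericVector vol, int n, double twist,
                                   double rise, double mask_r,
                                   double zlo, double zhi) {
  const double* vp = vol.begin();
  double cen = std::floor(n / 2.0);
  double hca = std::cos(twist / 2.0), hsa = std::sin(twist / 2.0);
  double hr = rise / 2.0;
  double acc = 0.0; double cnt = 0.0;
  int iz0 = std::max(0, (int)std::ceil(zlo));
  int iz1 = std::min(n - 1, (int)std::floor(zhi));
  for (int iz = iz0; iz <= iz1; ++iz) {
    for (int iy = 0; iy < n; ++iy) {
      double y = iy - cen;
      for (int ix = 0; ix < n; ++ix) {
        double x = ix - cen;
        if (x * x + y * y > mask_r * mask_r) continue;
        // g^(-1/2) p = R(-t/2) p - (r/2) z ; g^(+1/2) p = R(+t/2) p + (r/2) z
        double xp = hca * x + hsa * y + cen;    // rotate by -twist/2
        double yp = -hsa * x + hca * y + cen;
        double xm = hca * x - hsa * y + cen;    // rotate by +twist/2
        double ym = hsa * x + hca * y + cen;
        double a, b;
        if (!trilinear(vp, n, xp, yp, iz - hr, a)) continue;
        if (!trilinear(vp, n, xm, ym, iz + hr, b)) continue;
        double dfr = a - b;
        acc += dfr * dfr; cnt += 1.0;
      }
    }
  }
  return NumericVector::create(cnt > 0 ? acc / cnt : NA_REAL, cnt);
}

// In-plane rotation of a square image by ang (radians, counter-clockwise
// for the [u, v] indexing), bilinear, zeros outside.
// [[Rcpp::export]]
NumericMatrix cpp_rotate2d(NumericMatrix img, double ang) {
  int n = img.nrow();
  NumericMatrix out(n, n);
  const double* ip = img.begin();
  double cen = std::floor(n / 2.0);
  double ca = std::cos(ang), sa = std::sin(ang);
  for (int j = 0; j < n; ++j) {
    double y = j - cen;
    for (int i = 0; i < n; ++i) {
      double x = i - cen;
      // sample source at inverse rotation
      double xs = ca * x + sa * y + cen;
      double ys = -sa * x + ca * y + cen;
      double s;
      out(i, j) = bilinear(ip, n, xs, ys, s) ? s : 0.0;
    }
  }
  return out;
}

// Sample the central plane spanned by (u, v) through the center of a
// cubic (fftshifted) 3-D array; used for central sections of 3-D power
// spectra.
// [[Rcpp::export]]
NumericMatrix cpp_central_plane(NumericVector vol, int n,
                                NumericVector u, NumericVector v) {
  NumericMatrix out(n, n);
  const double* vp = vol.begin();
  double cen = std::floor(n / 2.0);
  for (int j = 0; j < n; ++j) {
    double bj = j - cen;
    for (int i = 0; i < n; ++i) {
      double bi = i - cen;
      double s;
      bool ok = trilinear(vp, n,
                          cen + bi * u[0] + bj * v[0],
                          cen + bi * u[1] + bj * v[1],
                          cen + bi * u[2] + bj * v[2], s);
      out(i, j) = ok ? s : 0.0;
    }
  }
  return out;
}

// Rasterize weighted Gaussian blobs onto a cubic grid.  centers are in
// Angstroms relative to the box center; each blob is normalized so its
// discrete integral equals its weight.  Truncated at 6 sigma.
// [[Rcpp::export]]
NumericVector cpp_rasterize_gauss(int n, double apix, NumericMatrix centers,
                                  NumericVector weights, double sigma) {
  NumericVector out((size_t)n * n * n);
  double* op = out.begin();
  double cen = std::floor(n / 2.0);
  double sv = sigma / apix;                 // sigma in voxels
  int w = (int)std::ceil(6.0 * sv);
  double norm = 1.0 / std::pow(std::sqrt(2.0 * M_PI) * sv, 3.0);
  double inv2s2 = 1.0 / (2.0 * sv * sv);
  for (int a = 0; a < centers.nrow(); ++a) {
    double cx = centers(a, 0) / apix + cen;
    double cy = centers(a, 1) / apix + cen;
    double cz = centers(a, 2) / apix + cen;
    double wt = weights[a] * norm;
    int x0 = std::max(0, (int)std::floor(cx) - w);
    int x1 = std::min(n - 1, (int)std::ceil(cx) + w);
    int y0 = std::max(0, (int)std::floor(cy) - w);
    int y1 = std::min(n - 1, (int)std::ceil(cy) + w);
    int z0 = std::max(0, (int)std::floor(cz) - w);
    int z1 = std::min(n - 1, (int)std::ceil(cz) + w);
    for (int iz = z0; iz <= z1; ++iz) {
      double dz = iz - cz;
      for (int iy = y0; iy <= y1; ++iy) {
        double dy = iy - cy;
        double r2yz = dy * dy + dz * dz;
        double* row = op + n * (iy + (size_t)n * iz);
        for (int ix = x0; ix <= x1; ++ix) {
          double dx = ix - cx;
          row[ix] += wt * std::exp(-(dx * dx + r2yz) * inv2s2);
        }
      }
    }
  }
  return out;
}

// Rigid transform about the helix axis: rotate by ang (radians) and
// translate dz voxels along z, trilinear, zeros outside.
// [[Rcpp::export]]
NumericVector cpp_zrot_shift(NumericVector vol, int n, double ang,
                             double dz) {
  NumericVector out((size_t)n * n * n);
  const double* vp = vol.begin();
  double* op = out.begin();
  double cen = std::floor(n / 2.0);
  double ca = std::cos(-ang), sa = std::sin(-ang);
  size_t idx = 0;
  for (int iz = 0; iz < n; ++iz) {
    double zz = iz - dz;
    for (int iy = 0; iy < n; ++iy) {
      double y = iy - cen;
      for (int ix = 0; ix < n; ++ix, ++idx) {
        double x = ix - cen;
        double xx = ca * x - sa * y + cen;
        double yy = sa * x + ca * y + cen;
        double s;
        op[idx] = trilinear(vp, n, xx, yy, zz, s) ? s : 0.0;
      }
    }
  }
  return out;
}
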