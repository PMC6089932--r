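#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Parallel-beam projector, voxel-driven with a footprint kernel: every
// voxel of a z-slice deposits voxel_mm * value spread uniformly over its
// projected footprint of width w = |cos(theta)| + |sin(theta)| detector
// pixels (the exact support of a square voxel's shadow), split across
// bins by overlap length.  This conserves the slice integral exactly at
// every angle (up to rays falling off the detector, which the caller
// guards against) and suppresses the angular moire that plain two-bin
// linear splatting produces at diagonal angles.
//
// Conventions: volume dims (nx, ny, nz), x fastest; voxel i (0-based) has
// centre i + 0.5 in voxel units; rotation axis is the z line through the
// volume centre (nx/2, ny/2).  Angle theta = 0 projects along +y so the
// detector coordinate is x; theta increases counterclockwise.  The axis
// maps to the detector *boundary* coordinate ndet/2 + axis_offset (pixels),
// so integer offsets keep opposed projections pixel-aligned.
//
// Along a row the footprint centre t(i) = base + i*cos(theta) is affine,
// so the i-range whose deposits fall fully on the detector is precomputed
// and the inner loop runs without bounds checks; the few boundary voxels
// are handled explicitly.

// i-range [iA, iB) with u(i) = base + i*step inside [lo, hi]
static inline void affine_range(double base, double step, int n,
                                double lo, double hi, int &iA, int &iB) {
  if (std::fabs(step) < 1e-12) {
    const bool in = base >= lo && base <= hi;
    iA = 0; iB = in ? n : 0;
    return;
  }
  double a = (lo - base) / step, b = (hi - base) / step;
  if (a > b) std::swap(a, b);
  a = std::max(a, -1.0);
  b = std::min(b, n + 1.0);
  iA = std::min(n, std::max(0, static_cast<int>(std::ceil(a))));
  iB = std::min(n, std::max(iA, static_cast<int>(std::floor(b)) + 1));
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, int nx, int ny, int nz,
                                  int ndet, NumericVector angles,
                                  double axis_offset, double voxel_mm) {
  const int na = angles.size();
  NumericVector sino(static_cast<R_xlen_t>(ndet) * na * nz);
  sino.attr("dim") = IntegerVector::create(ndet, na, nz);
  const double t0 = ndet / 2.0 + axis_offset;
  const double *v = REAL(vol);
  double *out = REAL(sino);

  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    const double w = std::fabs(c) + std::fabs(s);  // footprint width, px
    const double hw = w / 2.0, inv_w = 1.0 / w;
    for (int z = 0; z < nz; ++z) {
      const double *slice = v + static_cast<size_t>(z) * nx * ny;
      double *row = out + (static_cast<size_t>(z) * na + a) * ndet;
      for (int j = 0; j < ny; ++j) {
        // footprint centre in detector boundary coordinates
        const double base =
          (0.5 - nx / 2.0) * c + (j + 0.5 - ny / 2.0) * s + t0;
        const double *src = slice + static_cast<size_t>(j) * nx;
        int iA, iB;
        affine_range(base, c, nx, hw, ndet - hw - 1e-9, iA, iB);
        for (int pass = 0; pass < 2; ++pass) {
          // boundary voxels: clip the footprint at the detector edges
          const int lo = pass == 0 ? 0 : iB, hi = pass == 0 ? iA : nx;
          for (int i = lo; i < hi; ++i) {
            const double val = src[i];
            if (val == 0.0) continue;
            const double t = base + i * c;
            const double dep = val * voxel_mm * inv_w;
            int j0 = static_cast<int>(std::floor(t - hw));
            const int j1 = static_cast<int>(std::floor(t + hw));
            for (; j0 <= j1; ++j0) {
              if (j0 < 0 || j0 >= ndet) continue;
              const double ov = std::min(t + hw, j0 + 1.0) -
                                std::max(t - hw, static_cast<double>(j0));
              if (ov > 0) row[j0] += dep * ov;
            }
          }
        }
        double t = base + iA * c;
        for (int i = iA; i < iB; ++i, t += c) {
          const double val = src[i];
          if (val != 0.0) {
            const double dep = val * voxel_mm * inv_w;
            const double lo = t - hw, hi2 = t + hw;
            int j0 = static_cast<int>(lo);
            const int j1 = static_cast<int>(hi2);
            for (; j0 <= j1; ++j0) {
              const double ov = std::min(hi2, j0 + 1.0) -
                                std::max(lo, static_cast<double>(j0));
              if (ov > 0) row[j0] += dep * ov;
            }
          }
        }
      }
    }
  }
  return sino;
}

// Back-projection with linear detector interpolation; the ramp-filtered
// sinogram comes in as (ndet, na, nz).  Output grid shares the projector's
// conventions; the pi/na FBP normalisation is applied by the caller.

// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector sino, int ndet, int na, int nz,
                               NumericVector angles, double axis_offset,
                               int nx, int ny) {
  NumericVector vol(static_cast<R_xlen_t>(nx) * ny * nz);
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double t0 = ndet / 2.0 + axis_offset;
  const double *sp = REAL(sino);
  double *v = REAL(vol);

  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int z = 0; z < nz; ++z) {
      const double *row = sp + (static_cast<size_t>(z) * na + a) * ndet;
      double *slice = v + static_cast<size_t>(z) * nx * ny;
      for (int j = 0; j < ny; ++j) {
        const double base =
          (0.5 - nx / 2.0) * c + (j + 0.5 - ny / 2.0) * s + t0 - 0.5;
        double *dst = slice + static_cast<size_t>(j) * nx;
        int iA, iB;
        affine_range(base, c, nx, 0.0, ndet - 2.0 + 1e-9, iA, iB);
        for (int pass = 0; pass < 2; ++pass) {
          const int lo = pass == 0 ? 0 : iB, hi = pass == 0 ? iA : nx;
          for (int i = lo; i < hi; ++i) {
            const double u = base + i * c;
            const int i0 = static_cast<int>(std::floor(u));
            const double f = u - i0;
            double val = 0.0;
            if (i0 >= 0 && i0 < ndet) val += row[i0] * (1.0 - f);
            if (i0 + 1 >= 0 && i0 + 1 < ndet) val += row[i0 + 1] * f;
            dst[i] += val;
          }
        }
        double u = base + iA * c;
        for (int i = iA; i < iB; ++i, u += c) {
          const int i0 = static_cast<int>(u);
          const double f = u - i0;
          dst[i] += row[i0] * (1.0 - f) + row[i0 + 1] * f;
        }
      }
    }
  }
  return vol;
}
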