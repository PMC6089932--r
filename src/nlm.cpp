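#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Slice-wise non-local means with Gaussian patch weighting, organised
// offset-by-offset: for each search offset d the squared difference image
// (I(x) - I(x+d))^2 is smoothed with a separable Gaussian patch kernel,
// giving the patch distance for every pixel at once.  The distance is
// symmetric in d, so each offset pair (d, -d) is processed once and
// contributes to both endpoints.  Weights use the noise-compensated form
// w = exp(-max(d2 - 2*sigma^2, 0) / h^2) so that statistically identical
// patches (expected distance 2*sigma^2 under iid noise) get full weight.
// Cost is O(npix * search_window / 2) per slice.

static void gaussian_kernel(int radius, std::vector<double> &k) {
  const double sigma = std::max(radius / 2.0, 0.5);
  k.resize(2 * radius + 1);
  double sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    sum += k[i + radius];
  }
  for (double &v : k) v /= sum;
}

// separable Gaussian smoothing with clamped borders; fast interior path
static void smooth2d(const std::vector<double> &in, std::vector<double> &tmp,
                     std::vector<double> &out, int nx, int ny,
                     const std::vector<double> &k, int r) {
  const int nk = 2 * r + 1;
  for (int y = 0; y < ny; ++y) {
    const double *row = in.data() + static_cast<size_t>(nx) * y;
    double *trow = tmp.data() + static_cast<size_t>(nx) * y;
    for (int x = 0; x < std::min(r, nx); ++x) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
        s += k[i + r] * row[xx];
      }
      trow[x] = s;
    }
    for (int x = r; x < nx - r; ++x) {
      double s = 0.0;
      const double *p = row + x - r;
      for (int i = 0; i < nk; ++i) s += k[i] * p[i];
      trow[x] = s;
    }
    for (int x = std::max(nx - r, r); x < nx; ++x) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
        s += k[i + r] * row[xx];
      }
      trow[x] = s;
    }
  }
  for (int y = 0; y < ny; ++y) {
    double *orow = out.data() + static_cast<size_t>(nx) * y;
    const bool interior = y >= r && y < ny - r;
    for (int x = 0; x < nx; ++x) orow[x] = 0.0;
    for (int i = -r; i <= r; ++i) {
      int yy = y + i;
      if (!interior) {
        if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
      }
      const double w = k[i + r];
      const double *trow = tmp.data() + static_cast<size_t>(nx) * yy;
      for (int x = 0; x < nx; ++x) orow[x] += w * trow[x];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_nlm_stack(NumericVector vol, int nx, int ny, int nz,
                            int patch_radius, int search_radius,
                            double h, double sigma_noise) {
  NumericVector res(static_cast<R_xlen_t>(nx) * ny * nz);
  res.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double *v = REAL(vol);
  double *o = REAL(res);
  std::vector<double> kern;
  gaussian_kernel(patch_radius, kern);
  const double h2 = h * h;
  const double bias = 2.0 * sigma_noise * sigma_noise;
  const size_t npix = static_cast<size_t>(nx) * ny;
  std::vector<double> diff(npix), tmp(npix), d2(npix), wsum(npix), acc(npix);

  for (int z = 0; z < nz; ++z) {
    const double *I = v + npix * z;
    // centre offset: weight 1
    for (size_t p = 0; p < npix; ++p) {
      wsum[p] = 1.0;
      acc[p] = I[p];
    }
    for (int oy = 0; oy <= search_radius; ++oy) {
      const int ox_start = (oy == 0) ? 1 : -search_radius;
      for (int ox = ox_start; ox <= search_radius; ++ox) {
        // valid region for x: I(x) and I(x+d) both in range
        const int x0 = std::max(0, -ox), x1 = nx - std::max(0, ox);
        const int y0 = 0, y1 = ny - oy;
        if (x1 <= x0 || y1 <= y0) continue;
        std::fill(diff.begin(), diff.end(), 0.0);
        const long od = ox + static_cast<long>(nx) * oy;
        for (int y = y0; y < y1; ++y) {
          const double *a = I + static_cast<size_t>(nx) * y;
          const double *b = a + od;
          double *drow = diff.data() + static_cast<size_t>(nx) * y;
          for (int x = x0; x < x1; ++x) {
            const double dd = a[x] - b[x];
            drow[x] = dd * dd;
          }
        }
        smooth2d(diff, tmp, d2, nx, ny, kern, patch_radius);
        for (int y = y0; y < y1; ++y) {
          const size_t row = static_cast<size_t>(nx) * y;
          const double *a = I + row;
          const double *b = a + od;
          const double *drow = d2.data() + row;
          double *wr = wsum.data() + row, *ar = acc.data() + row;
          double *wr2 = wr + od, *ar2 = ar + od;
          for (int x = x0; x < x1; ++x) {
            const double e = drow[x] - bias;
            const double w = e <= 0.0 ? 1.0 : std::exp(-e / h2);
            wr[x] += w;
            ar[x] += w * b[x];
            wr2[x] += w;   // symmetric contribution at x + d
            ar2[x] += w * a[x];
          }
        }
      }
    }
    double *O = o + npix * z;
    for (size_t p = 0; p < npix; ++p) O[p] = acc[p] / wsum[p];
  }
  return res;
}
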