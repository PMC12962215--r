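#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zeroth-order modified Bessel function of the first kind (series).
static double bessel_i0(double x) {
  double ax = std::fabs(x), sum = 1.0, term = 1.0;
  double y = ax * ax / 4.0;
  for (int k = 1; k < 64; ++k) {
    term *= y / (k * (double)k);
    sum += term;
    if (term < 1e-16 * sum) break;
  }
  return sum;
}

static inline double kb_kernel(double u, double halfw, double beta) {
  // Kaiser-Bessel interpolation kernel, support |u| <= halfw (grid cells).
  double t = u / halfw;
  double s = 1.0 - t * t;
  if (s <= 0.0) return 0.0;
  return bessel_i0(beta * std::sqrt(s));
}

// [[Rcpp::export]]
NumericVector kb_kernel_eval(NumericVector u, double width, double beta) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kb_kernel(u[i], width / 2.0, beta);
  return out;
}

// Adjoint gridding: spread weighted complex samples onto an oversampled
// G^3 grid (frequency-centered layout: grid index g corresponds to
// frequency g - G/2). coords are in grid units (k * G_fov), centered at 0.
// Kernel taps wrap periodically.
// [[Rcpp::export]]
ComplexVector grid_spread3(NumericMatrix coords, ComplexVector values,
                           int G, double width, double beta) {
  const int n = coords.nrow();
  const double halfw = width / 2.0;
  const int half = (int)std::ceil(halfw);
  ComplexVector grid(G * G * G);
  std::vector<double> wx(2 * half + 1), wy(2 * half + 1), wz(2 * half + 1);
  std::vector<int> ix(2 * half + 1), iy(2 * half + 1), iz(2 * half + 1);
  for (int j = 0; j < n; ++j) {
    double ux = coords(j, 0) + G / 2.0;
    double uy = coords(j, 1) + G / 2.0;
    double uz = coords(j, 2) + G / 2.0;
    int cx = (int)std::floor(ux), cy = (int)std::floor(uy), cz = (int)std::floor(uz);
    int nx = 0, ny = 0, nz = 0;
    for (int t = -half; t <= half; ++t) {
      double dx = cx + t - ux;
      double w = kb_kernel(dx, halfw, beta);
      if (w > 0) { wx[nx] = w; ix[nx] = ((cx + t) % G + G) % G; ++nx; }
      double dy = cy + t - uy;
      w = kb_kernel(dy, halfw, beta);
      if (w > 0) { wy[ny] = w; iy[ny] = ((cy + t) % G + G) % G; ++ny; }
      double dz = cz + t - uz;
      w = kb_kernel(dz, halfw, beta);
      if (w > 0) { wz[nz] = w; iz[nz] = ((cz + t) % G + G) % G; ++nz; }
    }
    Rcomplex v = values[j];
    for (int a = 0; a < nz; ++a) {
      double wza = wz[a];
      int offz = iz[a] * G * G;
      for (int b = 0; b < ny; ++b) {
        double wyz = wy[b] * wza;
        int offyz = offz + iy[b] * G;
        for (int c = 0; c < nx; ++c) {
          double w = wx[c] * wyz;
          Rcomplex &g = grid[offyz + ix[c]];
          g.r += v.r * w;
          g.i += v.i * w;
        }
      }
    }
  }
  grid.attr("dim") = IntegerVector::create(G, G, G);
  return grid;
}

// Forward interpolation: sample a frequency-centered G^3 grid at
// non-integer coordinates (grid units, centered at 0) with the same
// kernel. Transpose of grid_spread3.
// [[Rcpp::export]]
ComplexVector grid_interp3(ComplexVector grid, NumericMatrix coords,
                           int G, double width, double beta) {
  const int n = coords.nrow();
  const double halfw = width / 2.0;
  const int half = (int)std::ceil(halfw);
  ComplexVector out(n);
  std::vector<double> wx(2 * half + 1), wy(2 * half + 1), wz(2 * half + 1);
  std::vector<int> ix(2 * half + 1), iy(2 * half + 1), iz(2 * half + 1);
  for (int j = 0; j < n; ++j) {
    double ux = coords(j, 0) + G / 2.0;
    double uy = coords(j, 1) + G / 2.0;
    double uz = coords(j, 2) + G / 2.0;
    int cx = (int)std::floor(ux), cy = (int)std::floor(uy), cz = (int)std::floor(uz);
    int nx = 0, ny = 0, nz = 0;
    for (int t = -half; t <= half; ++t) {
      double w = kb_kernel(cx + t - ux, halfw, beta);
      if (w > 0) { wx[nx] = w; ix[nx] = ((cx + t) % G + G) % G; ++nx; }
      w = kb_kernel(cy + t - uy, halfw, beta);
      if (w > 0) { wy[ny] = w; iy[ny] = ((cy + t) % G + G) % G; ++ny; }
      w = kb_kernel(cz + t - uz, halfw, beta);
      if (w > 0) { wz[nz] = w; iz[nz] = ((cz + t) % G + G) % G; ++nz; }
    }
    double accr = 0.0, acci = 0.0;
    for (int a = 0; a < nz; ++a) {
      double wza = wz[a];
      int offz = iz[a] * G * G;
      for (int b = 0; b < ny; ++b) {
        double wyz = wy[b] * wza;
        int offyz = offz + iy[b] * G;
        for (int c = 0; c < nx; ++c) {
          double w = wx[c] * wyz;
          const Rcomplex &g = grid[offyz + ix[c]];
          accr += g.r * w;
          acci += g.i * w;
        }
      }
    }
    out[j].r = accr;
    out[j].i = acci;
  }
  return out;
}
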