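// Median-term anisotropic diffusion and separable smoothing kernels.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int iclamp(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Explicit Perona-Malik diffusion in flux (divergence) form with Neumann
// boundaries, plus an additive median-attachment term gamma * (med(u) - u).
// Flux form keeps the volume mean exactly conserved when gamma = 0.
// [[Rcpp::export]]
NumericVector cpp_median_diffuse(NumericVector vol, IntegerVector dims,
                                 int iterations, double dt, double kappa,
                                 double gamma, int window) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> u(vol.begin(), vol.end());
  std::vector<double> nu(n), med(n);
  int hw = window / 2;
  double k2 = kappa * kappa;
  auto IDX = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  std::vector<double> buf;
  buf.reserve((size_t)window * window * window);
  for (int it = 0; it < iterations; ++it) {
    if (gamma > 0) {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            buf.clear();
            for (int dk = -hw; dk <= hw; ++dk)
              for (int dj = -hw; dj <= hw; ++dj)
                for (int di = -hw; di <= hw; ++di)
                  buf.push_back(u[IDX(iclamp(i + di, nx), iclamp(j + dj, ny),
                                      iclamp(k + dk, nz))]);
            size_t m = buf.size() / 2;
            std::nth_element(buf.begin(), buf.begin() + m, buf.end());
            med[IDX(i, j, k)] = buf[m];
          }
    }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = IDX(i, j, k);
          double uc = u[c];
          double div = 0.0;
          // one face flux per axis direction; boundary faces carry zero flux
          if (i + 1 < nx) { double d = u[IDX(i + 1, j, k)] - uc; div += d / (1 + d * d / k2); }
          if (i > 0)      { double d = u[IDX(i - 1, j, k)] - uc; div += d / (1 + d * d / k2); }
          if (j + 1 < ny) { double d = u[IDX(i, j + 1, k)] - uc; div += d / (1 + d * d / k2); }
          if (j > 0)      { double d = u[IDX(i, j - 1, k)] - uc; div += d / (1 + d * d / k2); }
          if (k + 1 < nz) { double d = u[IDX(i, j, k + 1)] - uc; div += d / (1 + d * d / k2); }
          if (k > 0)      { double d = u[IDX(i, j, k - 1)] - uc; div += d / (1 + d * d / k2); }
          double rhs = div;
          if (gamma > 0) rhs += gamma * (med[c] - uc);
          nu[c] = uc + dt * rhs;
        }
    u.swap(nu);
  }
  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dims;
  return out;
}

static void smooth_axis(std::vector<double>& u, int nx, int ny, int nz,
                        int axis, const std::vector<double>& kern) {
  int r = (int)kern.size() / 2;
  std::vector<double> out(u.size());
  int dims[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx3[3] = {i, j, k};
        size_t base = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = iclamp(idx3[axis] + t, dims[axis]);
          acc += kern[t + r] * u[base + ((size_t)p - idx3[axis]) * stride[axis]];
        }
        out[base] = acc;
      }
  u.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> u(vol.begin(), vol.end());
  if (sigma > 0) {
    int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> kern(2 * r + 1);
    double s = 0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
      s += kern[t + r];
    }
    for (double& w : kern) w /= s;
    if (nx > 1) smooth_axis(u, nx, ny, nz, 0, kern);
    if (ny > 1) smooth_axis(u, nx, ny, nz, 1, kern);
    if (nz > 1) smooth_axis(u, nx, ny, nz, 2, kern);
  }
  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_box_smooth(NumericVector vol, IntegerVector dims, int w) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> u(vol.begin(), vol.end());
  std::vector<double> kern(w, 1.0 / w);
  if (nx > 1) smooth_axis(u, nx, ny, nz, 0, kern);
  if (ny > 1) smooth_axis(u, nx, ny, nz, 1, kern);
  if (nz > 1) smooth_axis(u, nx, ny, nz, 2, kern);
  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dims;
  return out;
}

// Central-difference gradient magnitude (grid units).
// [[Rcpp::export]]
NumericVector cpp_gradient_magnitude(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = vol.begin();
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  auto IDX = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = 0.5 * (v[IDX(iclamp(i + 1, nx), j, k)] -
                           v[IDX(iclamp(i - 1, nx), j, k)]);
        double gy = 0.5 * (v[IDX(i, iclamp(j + 1, ny), k)] -
                           v[IDX(i, iclamp(j - 1, ny), k)]);
        double gz = 0.5 * (v[IDX(i, j, iclamp(k + 1, nz))] -
                           v[IDX(i, j, iclamp(k - 1, nz))]);
        out[IDX(i, j, k)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}
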