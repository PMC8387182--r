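// Resampling kernels shared by the acquisition simulator and the
// polar-to-Cartesian scan converter.  All coordinates are 0-based voxel
// indices; physical spacing is applied on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z, bool clamp) {
  if (clamp) {
    x = std::min(std::max(x, 0.0), (double)nx - 1);
    y = std::min(std::max(y, 0.0), (double)ny - 1);
    z = std::min(std::max(z, 0.0), (double)nz - 1);
  } else {
    // out-of-volume reads are 0 (unscanned space is echo-free)
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      return 0.0;
  }
  int x0 = std::min(std::max((int)std::floor(x), 0), std::max(nx - 2, 0));
  int y0 = std::min(std::max((int)std::floor(y), 0), std::max(ny - 2, 0));
  int z0 = std::min(std::max((int)std::floor(z), 0), std::max(nz - 2, 0));
  double fx = nx == 1 ? 0 : x - x0;
  double fy = ny == 1 ? 0 : y - y0;
  double fz = nz == 1 ? 0 : z - z0;
  int x1 = nx == 1 ? 0 : x0 + 1, y1 = ny == 1 ? 0 : y0 + 1,
      z1 = nz == 1 ? 0 : z0 + 1;
#define V(i, j, k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dims,
                                NumericMatrix pts, bool clamp) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), clamp);
  return out;
}

// Extract one full-diameter planar slice at rotation angle theta (degrees)
// about the central depth axis.  Column w spans the diameter, row d the depth.
// [[Rcpp::export]]
NumericMatrix cpp_extract_slice(NumericVector vol, IntegerVector dims,
                                double theta_deg, int W, int D,
                                double jx, double jy, double jz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = vol.begin();
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double half = (W - 1) / 2.0;
  NumericMatrix out(W, D);
  for (int d = 0; d < D; ++d) {
    for (int w = 0; w < W; ++w) {
      double off = w - half;
      out(w, d) = trilinear(v, nx, ny, nz, cx + off * ct + jx,
                            cy + off * st + jy, d + jz, false);
    }
  }
  return out;
}

// Polar-to-Cartesian scan conversion of a rotational slice stack.
// slices: W x D x S array, slice s acquired at angle s*step degrees.
// Output: W x W x D, bilinear in (angle, signed radius), depth row-exact.
// [[Rcpp::export]]
NumericVector cpp_scan_convert(NumericVector slices, IntegerVector sdims,
                               double step_deg) {
  int W = sdims[0], D = sdims[1], S = sdims[2];
  const double* sl = slices.begin();
  double half = (W - 1) / 2.0;
  NumericVector out((size_t)W * W * D);
  out.attr("dim") = IntegerVector::create(W, W, D);
  double* o = out.begin();
#define SL(w, d, s) sl[(w) + (size_t)W * ((d) + (size_t)D * (s))]
  // linear interpolation along the signed-radius (column) axis of one slice
  auto radial = [&](int s, double col, int d) -> double {
    if (col < 0 || col > W - 1) return 0.0;
    int c0 = (int)std::floor(col);
    if (c0 > W - 2) c0 = W - 2;
    double f = col - c0;
    return SL(c0, d, s) * (1 - f) + SL(c0 + 1, d, s) * f;
  };
  for (int k = 0; k < D; ++k) {
    for (int j = 0; j < W; ++j) {
      double dy = j - half;
      for (int i = 0; i < W; ++i) {
        double dx = i - half;
        double R = std::sqrt(dx * dx + dy * dy);
        size_t idx = (size_t)i + (size_t)W * ((size_t)j + (size_t)W * k);
        if (R > half + 1e-12) { o[idx] = 0.0; continue; }
        double alpha = std::atan2(dy, dx) * 180.0 / M_PI;
        if (alpha < 0) alpha += 360.0;
        double Rs = R;
        if (alpha >= 180.0) { alpha -= 180.0; Rs = -R; }
        double s = alpha / step_deg;
        int s0 = (int)std::floor(s);
        double f = s - s0;
        if (s0 >= S) { s0 = S - 1; f = 1.0; }
        int s1 = s0 + 1;
        double R1 = Rs;
        if (s1 >= S) { s1 = 0; R1 = -Rs; }  // wrap at 180 deg mirrors radius
        double a = radial(s0, half + Rs, k);
        double b = radial(s1, half + R1, k);
        o[idx] = a * (1 - f) + b * f;
      }
    }
  }
#undef SL
  return out;
}

// In-plane azimuth coverage mask for one full-volume wedge [a0, a1] degrees.
// Boundary angles are shared: a voxel is covered when its azimuth lies within
// half a pixel's arc of the interval, so seam voxels belong to both wedges.
// [[Rcpp::export]]
LogicalVector cpp_azimuth_mask(IntegerVector dims, double a0, double a1) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  LogicalVector out((size_t)nx * ny * nz);
  out.attr("dim") = dims;
  std::vector<char> plane((size_t)nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double dx = i - cx, dy = j - cy;
      double R = std::sqrt(dx * dx + dy * dy);
      bool cov;
      if (R < 0.5) {
        cov = true;  // on-axis voxels are seen by every wedge
      } else {
        double alpha = std::atan2(dy, dx) * 180.0 / M_PI;
        if (alpha < 0) alpha += 360.0;
        double tol = std::atan2(0.5, R) * 180.0 / M_PI;
        cov = (alpha >= a0 - tol) && (alpha <= a1 + tol);
      }
      plane[(size_t)i + (size_t)nx * j] = cov ? 1 : 0;
    }
  }
  for (int k = 0; k < nz; ++k)
    for (size_t p = 0; p < (size_t)nx * ny; ++p)
      out[p + (size_t)nx * ny * k] = plane[p] != 0;
  return out;
}

// Resample a volume onto a grid of given shape with coordinate scale factors
// (used for pyramid down/upsampling); clamped boundary reads.
// [[Rcpp::export]]
NumericVector cpp_rescale(NumericVector vol, IntegerVector dims,
                          IntegerVector odims, NumericVector scale) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = odims[0], oy = odims[1], oz = odims[2];
  const double* v = vol.begin();
  NumericVector out((size_t)ox * oy * oz);
  out.attr("dim") = odims;
  double* o = out.begin();
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i)
        o[(size_t)i + (size_t)ox * ((size_t)j + (size_t)oy * k)] =
            trilinear(v, nx, ny, nz, i * scale[0], j * scale[1], k * scale[2],
                      true);
  return out;
}
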