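#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear lookup in a 3D array stored column-major with dims d0,d1,d2.
// Coordinates are 0-based voxel indices; outside the grid the value is 0.
static double trilinear(const double *v, int d0, int d1, int d2,
                        double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > d0 - 1 || y > d1 - 1 || z > d2 - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < d0 ? x0 + 1 : x0;
  int y1 = y0 + 1 < d1 ? y0 + 1 : y0;
  int z1 = z0 + 1 < d2 ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  #define V(i, j, k) v[(i) + (size_t)d0 * ((j) + (size_t)d1 * (k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// out(x) = in(A (x - c) + c + b), all in 0-based voxel coordinates,
// c = (dim - 1)/2 the geometric centre of the grid.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dim,
                                NumericMatrix A, NumericVector b) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  double c0 = (d0 - 1) / 2.0, c1 = (d1 - 1) / 2.0, c2 = (d2 - 1) / 2.0;
  NumericVector out((size_t)d0 * d1 * d2);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < d2; ++k) {
    double zc = k - c2;
    for (int j = 0; j < d1; ++j) {
      double yc = j - c1;
      for (int i = 0; i < d0; ++i) {
        double xc = i - c0;
        double xs = A(0, 0) * xc + A(0, 1) * yc + A(0, 2) * zc + c0 + b[0];
        double ys = A(1, 0) * xc + A(1, 1) * yc + A(1, 2) * zc + c1 + b[1];
        double zs = A(2, 0) * xc + A(2, 1) * yc + A(2, 2) * zc + c2 + b[2];
        o[i + (size_t)d0 * (j + (size_t)d1 * k)] =
            trilinear(v, d0, d1, d2, xs, ys, zs);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Sum of isotropic Gaussians rendered on a voxel grid. Coordinates are
// 0-based voxel units; each blob is truncated at 4 sigma.
// [[Rcpp::export]]
NumericVector cpp_render_gaussians(NumericMatrix centres, NumericVector amp,
                                   NumericVector sigma, IntegerVector dim) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector out((size_t)d0 * d1 * d2);
  double *o = out.begin();
  for (int n = 0; n < centres.nrow(); ++n) {
    double cx = centres(n, 0), cy = centres(n, 1), cz = centres(n, 2);
    double s = sigma[n % sigma.size()], a = amp[n % amp.size()];
    double inv2s2 = 1.0 / (2.0 * s * s), r = 4.0 * s;
    int i0 = std::max(0, (int)std::ceil(cx - r));
    int i1 = std::min(d0 - 1, (int)std::floor(cx + r));
    int j0 = std::max(0, (int)std::ceil(cy - r));
    int j1 = std::min(d1 - 1, (int)std::floor(cy + r));
    int k0 = std::max(0, (int)std::ceil(cz - r));
    int k1 = std::min(d2 - 1, (int)std::floor(cz + r));
    for (int k = k0; k <= k1; ++k) {
      double dz = k - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = j - cy;
        double ryz = dy * dy + dz * dz;
        for (int i = i0; i <= i1; ++i) {
          double dx = i - cx;
          o[i + (size_t)d0 * (j + (size_t)d1 * k)] +=
              a * std::exp(-(dx * dx + ryz) * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Interpolate a volume at arbitrary 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_trilinear_at(NumericVector vol, IntegerVector dim,
                               NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(vol.begin(), dim[0], dim[1], dim[2],
                       pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}
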