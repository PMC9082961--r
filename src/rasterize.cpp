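#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Silhouette membership in the leaf frame: u along the axis (mm from the
// leaf base), v across. Inside iff u in [x0, x1] and |v| <= w(u)/2 with
// w(u) = W * (4 (u/L)(1 - u/L))^a (a == 0 -> rectangle of width W).
static inline bool inside_silhouette(double u, double v,
                                     double x0, double x1,
                                     double L, double W, double a) {
  if (u < x0 || u > x1) return false;
  double av = std::fabs(v);
  if (av > 0.5 * W) return false;  // cheap reject before the power
  if (a == 0.0) return true;
  double g = 4.0 * (u / L) * (1.0 - u / L);
  if (g <= 0.0) return false;
  // (2|v|/W)^2 <= g^(2a) avoids pow() for the common a = 0.5 profile
  double lhs = 2.0 * av / W;
  if (a == 0.5) return lhs * lhs <= g;
  return lhs <= std::pow(g, a);
}

// Count scanner pixels whose centre falls inside the placed silhouette.
// Pixel centres are at ((i + 0.5) * pitch, (j + 0.5) * pitch) for
// i = 0..nx-1, j = 0..ny-1 (mm). The placement maps leaf-frame (u, v) to
// scanner p = o + R(theta) (u - x0, v); the inverse is applied per pixel.
// [[Rcpp::export(name = ".silhouette_count")]]
double silhouette_count(int nx, int ny, double pitch,
                        double ox, double oy, double ctheta, double stheta,
                        double x0, double x1, double L, double W, double a) {
  double count = 0.0;
  for (int j = 0; j < ny; ++j) {
    double sy = (j + 0.5) * pitch - oy;
    for (int i = 0; i < nx; ++i) {
      double sx = (i + 0.5) * pitch - ox;
      double u = x0 + ctheta * sx + stheta * sy;
      double v = -stheta * sx + ctheta * sy;
      if (inside_silhouette(u, v, x0, x1, L, W, a)) count += 1.0;
    }
  }
  return count;
}

// Full coverage raster: fraction of ss x ss subsamples of each pixel inside
// the silhouette. ss = 1 reproduces the binary centre test. Rows index y.
// [[Rcpp::export(name = ".silhouette_coverage")]]
NumericMatrix silhouette_coverage(int nx, int ny, double pitch,
                                  double ox, double oy,
                                  double ctheta, double stheta,
                                  double x0, double x1,
                                  double L, double W, double a, int ss) {
  NumericMatrix out(ny, nx);
  double sub = pitch / ss;
  double norm = 1.0 / (ss * ss);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int hits = 0;
      for (int sj = 0; sj < ss; ++sj) {
        double sy = j * pitch + (sj + 0.5) * sub - oy;
        for (int si = 0; si < ss; ++si) {
          double sx = i * pitch + (si + 0.5) * sub - ox;
          double u = x0 + ctheta * sx + stheta * sy;
          double v = -stheta * sx + ctheta * sy;
          if (inside_silhouette(u, v, x0, x1, L, W, a)) ++hits;
        }
      }
      out(j, i) = hits * norm;
    }
  }
  return out;
}
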