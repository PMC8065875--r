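// 3D resampling under an arbitrary affine voxel map.
//
// The matrix M (3x4) maps 0-based output voxel indices to continuous
// 0-based source voxel coordinates. Samples falling outside the source grid
// contribute the fill value, so objects moved off-grid fade to background.
//
// Interpolators: 0 nearest, 1 trilinear, 2 cubic (Catmull-Rom
// approximation), 3 windowed sinc (Hann window, radius 4), applied
// separably per axis.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  if (std::fabs(x) < 1e-12) return 1.0;
  double px = M_PI * x;
  return std::sin(px) / px;
}

// Per-axis interpolation weights around continuous coordinate x.
// Fills taps[] with 0-based integer sample positions and w[] with weights.
// Returns the number of taps.
static int axisWeights(double x, int interp, int *taps, double *w) {
  if (interp == 0) { // nearest
    taps[0] = (int)std::floor(x + 0.5);
    w[0] = 1.0;
    return 1;
  }
  int i0 = (int)std::floor(x);
  double f = x - i0;
  if (interp == 1) { // linear
    taps[0] = i0; taps[1] = i0 + 1;
    w[0] = 1.0 - f; w[1] = f;
    return 2;
  }
  if (interp == 2) { // Catmull-Rom cubic
    double f2 = f * f, f3 = f2 * f;
    taps[0] = i0 - 1; taps[1] = i0; taps[2] = i0 + 1; taps[3] = i0 + 2;
    w[0] = 0.5 * (-f3 + 2 * f2 - f);
    w[1] = 0.5 * (3 * f3 - 5 * f2 + 2);
    w[2] = 0.5 * (-3 * f3 + 4 * f2 + f);
    w[3] = 0.5 * (f3 - f2);
    return 4;
  }
  // windowed sinc, radius 4
  const int R = 4;
  int n = 0;
  double sum = 0.0;
  for (int k = i0 - R + 1; k <= i0 + R; ++k) {
    double d = x - k;
    double win = 0.5 * (1.0 + std::cos(M_PI * d / R)); // Hann over [-R, R]
    double wk = sinc(d) * win;
    taps[n] = k; w[n] = wk; sum += wk; ++n;
  }
  for (int k = 0; k < n; ++k) w[k] /= sum; // unit DC gain
  return n;
}

// [[Rcpp::export(name = ".resampleAffineC")]]
NumericVector resampleAffineC(NumericVector src, IntegerVector srcDim,
                              IntegerVector outDim, NumericMatrix M,
                              int interp, double fill) {
  const int sx = srcDim[0], sy = srcDim[1], sz = srcDim[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *s = src.begin();
  double *o = out.begin();

  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);

  int tx[8], ty[8], tz[8];
  double wx[8], wy[8], wz[8];

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      // start of the row in source coordinates
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = m00 * i + bx;
        double y = m10 * i + by;
        double z = m20 * i + bz;
        if (x < -4 || x > sx + 3 || y < -4 || y > sy + 3 ||
            z < -4 || z > sz + 3) { o[idx] = fill; continue; }
        int nx = axisWeights(x, interp, tx, wx);
        int ny = axisWeights(y, interp, ty, wy);
        int nz = axisWeights(z, interp, tz, wz);
        double acc = 0.0;
        for (int c = 0; c < nz; ++c) {
          int zz = tz[c];
          bool zin = (zz >= 0 && zz < sz);
          double accz = 0.0;
          for (int b = 0; b < ny; ++b) {
            int yy = ty[b];
            bool yin = zin && (yy >= 0 && yy < sy);
            double accy = 0.0;
            if (yin) {
              const double *row = s + ((R_xlen_t)zz * sy + yy) * sx;
              for (int a = 0; a < nx; ++a) {
                int xx = tx[a];
                double v = (xx >= 0 && xx < sx) ? row[xx] : fill;
                accy += wx[a] * v;
              }
            } else {
              for (int a = 0; a < nx; ++a) accy += wx[a] * fill;
            }
            accz += wy[b] * accy;
          }
          acc += wz[c] * accz;
        }
        o[idx] = acc;
      }
    }
  }
  out.attr("dim") = outDim;
  return out;
}
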