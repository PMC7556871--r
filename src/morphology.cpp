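#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat ball structuring element of
// the given pixel radius (height b(u) = sqrt(r^2 - |u|^2)), with border
// replication. Opening (erode then dilate) yields the classic
// rolling-ball background estimate. Implemented offset-major over a
// padded copy for contiguous memory access.

static std::vector<double> pad_replicate(const NumericMatrix &img, int r,
                                         int &pny, int &pnx) {
  int ny = img.nrow(), nx = img.ncol();
  pny = ny + 2 * r;
  pnx = nx + 2 * r;
  std::vector<double> pad((size_t)pny * pnx);
  for (int j = 0; j < pnx; ++j) {
    int js = std::min(std::max(j - r, 0), nx - 1);
    for (int i = 0; i < pny; ++i) {
      int is = std::min(std::max(i - r, 0), ny - 1);
      pad[(size_t)j * pny + i] = img(is, js);
    }
  }
  return pad;
}

// [[Rcpp::export(name = ".ball_morph")]]
NumericMatrix ball_morph(NumericMatrix img, double radius, bool erode) {
  int ny = img.nrow(), nx = img.ncol();
  int r = (int)std::floor(radius);
  int pny, pnx;
  std::vector<double> pad = pad_replicate(img, r, pny, pnx);
  NumericMatrix out(ny, nx);
  std::fill(out.begin(), out.end(), erode ? R_PosInf : R_NegInf);
  double *o = REAL(out);
  for (int dx = -r; dx <= r; ++dx) {
    for (int dy = -r; dy <= r; ++dy) {
      double d2 = (double)dx * dx + (double)dy * dy;
      if (d2 > radius * radius) continue;
      double h = std::sqrt(radius * radius - d2);
      for (int j = 0; j < nx; ++j) {
        const double *src = &pad[(size_t)(j + r + dx) * pny + (r + dy)];
        double *dst = o + (size_t)j * ny;
        if (erode) {
          for (int i = 0; i < ny; ++i) {
            double v = src[i] - h;
            if (v < dst[i]) dst[i] = v;
          }
        } else {
          for (int i = 0; i < ny; ++i) {
            double v = src[i] + h;
            if (v > dst[i]) dst[i] = v;
          }
        }
      }
    }
  }
  return out;
}

// Median filter over a disc neighbourhood of the given radius, border
// replication.
// [[Rcpp::export(name = ".disc_median")]]
NumericMatrix disc_median(NumericMatrix img, double radius) {
  int ny = img.nrow(), nx = img.ncol();
  int r = (int)std::floor(radius);
  int pny, pnx;
  std::vector<double> pad = pad_replicate(img, r, pny, pnx);
  std::vector<int> dy, dx;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)a * a + (double)b * b <= radius * radius) {
        dy.push_back(a);
        dx.push_back(b);
      }
  size_t m = dy.size();
  NumericMatrix out(ny, nx);
  std::vector<double> buf(m);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      for (size_t k = 0; k < m; ++k) {
        buf[k] = pad[(size_t)(j + r + dx[k]) * pny + (i + r + dy[k])];
      }
      size_t mid = m / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}
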