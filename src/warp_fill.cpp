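#include <Rcpp.h>
using namespace Rcpp;

// Backward piecewise-affine fill: for each triangle (rows of `tri`, 1-based
// indices into the control-point sets S/D), rasterise the destination
// triangle and pull pixels from the source image by bilinear interpolation.
// Pixels outside every destination triangle keep their input value (the
// output starts as a copy of the input). Returns the number of triangles
// whose orientation flips between source and destination; a zero-area
// destination triangle raises an error.

static inline double bilin(const NumericMatrix& img, double x, double y) {
  int w = img.ncol(), h = img.nrow();
  if (x < 0) x = 0; if (x > w - 1) x = w - 1;
  if (y < 0) y = 0; if (y > h - 1) y = h - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < w ? x0 + 1 : w - 1;
  int y1 = y0 + 1 < h ? y0 + 1 : h - 1;
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// [[Rcpp::export]]
List warp_fill_cpp(NumericMatrix img, NumericMatrix S, NumericMatrix D,
                   IntegerMatrix tri) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out = clone(img);
  int flips = 0;

  for (int r = 0; r < tri.nrow(); ++r) {
    int i1 = tri(r, 0) - 1, i2 = tri(r, 1) - 1, i3 = tri(r, 2) - 1;
    double d1x = D(i1, 0), d1y = D(i1, 1);
    double d2x = D(i2, 0), d2y = D(i2, 1);
    double d3x = D(i3, 0), d3y = D(i3, 1);
    double det = (d2x - d1x) * (d3y - d1y) - (d3x - d1x) * (d2y - d1y);
    if (std::fabs(det) < 2e-9)
      stop("degenerate destination triangle (points %d, %d, %d) has zero area",
           i1 + 1, i2 + 1, i3 + 1);
    double dets = (S(i2, 0) - S(i1, 0)) * (S(i3, 1) - S(i1, 1)) -
                  (S(i3, 0) - S(i1, 0)) * (S(i2, 1) - S(i1, 1));
    if ((det > 0) != (dets > 0)) ++flips;

    int x0 = std::max(0, (int)std::floor(std::min({d1x, d2x, d3x})));
    int x1 = std::min(w - 1, (int)std::ceil(std::max({d1x, d2x, d3x})));
    int y0 = std::max(0, (int)std::floor(std::min({d1y, d2y, d3y})));
    int y1 = std::min(h - 1, (int)std::ceil(std::max({d1y, d2y, d3y})));

    for (int py = y0; py <= y1; ++py) {
      for (int px = x0; px <= x1; ++px) {
        double l2 = ((px - d1x) * (d3y - d1y) - (py - d1y) * (d3x - d1x)) / det;
        double l3 = ((py - d1y) * (d2x - d1x) - (px - d1x) * (d2y - d1y)) / det;
        double l1 = 1.0 - l2 - l3;
        const double eps = -1e-9;
        if (l1 < eps || l2 < eps || l3 < eps) continue;
        double sx = l1 * S(i1, 0) + l2 * S(i2, 0) + l3 * S(i3, 0);
        double sy = l1 * S(i1, 1) + l2 * S(i2, 1) + l3 * S(i3, 1);
        out(py, px) = bilin(img, sx, sy);
      }
    }
  }
  return List::create(_["out"] = out, _["flips"] = flips);
}
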