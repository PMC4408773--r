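#include <Rcpp.h>
using namespace Rcpp;

// circular difference a-b mapped into (-180, 180]; matches R's wrap_angle()
// bit for bit (floor-based modulo, like R's %%)
static inline double wrap180(double x) {
  double z = x + 180.0;
  double y = z - std::floor(z / 360.0) * 360.0 - 180.0;
  if (y == -180.0) y = 180.0;
  return y;
}

static inline double circdist(double a, double b) {
  return std::fabs(wrap180(a - b));
}

// Sum of weights w over samples x within a circular window of halfwidth hw
// (inclusive) around each grid point. Used for occupancy/time and event
// counts in bearing-resolved profiles.
// [[Rcpp::export(name = ".circ_window_sum")]]
NumericVector circ_window_sum_cpp(NumericVector grid, NumericVector x,
                                  NumericVector w, double hw) {
  int g = grid.size(), n = x.size();
  NumericVector out(g);
  for (int i = 0; i < g; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j)
      if (circdist(x[j], grid[i]) <= hw) acc += w[j];
    out[i] = acc;
  }
  return out;
}

// 2D sliding box filter: dimension 1 circular (bearing) or linear,
// dimension 2 linear (distance or time). Returns sum of w within the box.
// [[Rcpp::export(name = ".box_window_sum")]]
NumericMatrix box_window_sum_cpp(NumericVector grid1, NumericVector grid2,
                                 NumericVector x1, NumericVector x2,
                                 NumericVector w, double hw1, double hw2,
                                 bool circular1) {
  int g1 = grid1.size(), g2 = grid2.size(), n = x1.size();
  NumericMatrix out(g1, g2);
  for (int i = 0; i < g1; ++i) {
    for (int j = 0; j < n; ++j) {
      double d1 = circular1 ? circdist(x1[j], grid1[i])
                            : std::fabs(x1[j] - grid1[i]);
      if (d1 > hw1) continue;
      for (int k = 0; k < g2; ++k)
        if (std::fabs(x2[j] - grid2[k]) <= hw2) out(i, k) += w[j];
    }
  }
  return out;
}
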