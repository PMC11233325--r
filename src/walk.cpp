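#include <Rcpp.h>
using namespace Rcpp;

// Isotropic random walk inside a rectangular arena [0,W] x [0,H].
// Each step has a prescribed length; the heading is uniform among
// directions that keep the next position inside the arena (rejection
// sampling), so step lengths -- and hence per-frame speeds -- are
// preserved exactly at the walls. Callers must guarantee
// max(step) <= min(W, H) / 2: then from any point a 45-degree heading
// into the far-corner quadrant is admissible, so rejection terminates.
// [[Rcpp::export]]
NumericMatrix bounded_walk_cpp(double x0, double y0, NumericVector step,
                               double width, double height) {
  const int n = step.size();
  NumericMatrix out(n + 1, 2);
  double x = x0, y = y0;
  out(0, 0) = x;
  out(0, 1) = y;
  for (int i = 0; i < n; ++i) {
    const double L = step[i];
    double nx, ny;
    int tries = 0;
    for (;;) {
      const double th = 2.0 * M_PI * unif_rand();
      nx = x + L * std::cos(th);
      ny = y + L * std::sin(th);
      if (nx >= 0.0 && nx <= width && ny >= 0.0 && ny <= height) break;
      if (++tries > 100000) {
        Rcpp::stop("bounded_walk_cpp: no admissible heading (step too large for arena)");
      }
    }
    x = nx;
    y = ny;
    out(i + 1, 0) = x;
    out(i + 1, 1) = y;
  }
  return out;
}
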