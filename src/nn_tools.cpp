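#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Nearest neighbour of every row of X (points in rows), excluding candidates
// closer in time than the Theiler window. Returns 1-based indices and
// Euclidean distances; index 0 if no admissible candidate exists.
// [[Rcpp::export(name = ".nn_theiler_cpp")]]
List nn_theiler_cpp(NumericMatrix X, int theiler) {
  const int M = X.nrow(), d = X.ncol();
  IntegerVector idx(M);
  NumericVector dist(M);
  for (int i = 0; i < M; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int best_j = 0;
    for (int j = 0; j < M; ++j) {
      int sep = i - j; if (sep < 0) sep = -sep;
      if (sep <= theiler) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - X(j, k);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; best_j = j + 1; }
    }
    idx[i] = best_j;
    dist[i] = best_j > 0 ? std::sqrt(best) : NA_REAL;
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Mean log divergence of neighbour pairs tracked k = 0..ksteps ahead.
// Pairs with zero initial distance, or with no admissible neighbour, are
// excluded throughout. A pair contributes at step k only while both
// trajectories remain inside the embedded series.
// [[Rcpp::export(name = ".divergence_curve_cpp")]]
List divergence_curve_cpp(NumericMatrix X, IntegerVector nn, int ksteps) {
  const int M = X.nrow(), d = X.ncol();
  NumericVector mean_log(ksteps + 1, NA_REAL);
  IntegerVector n_pairs(ksteps + 1);
  std::vector<double> acc(ksteps + 1, 0.0);
  for (int i = 0; i < M; ++i) {
    int j = nn[i] - 1;
    if (j < 0) continue;
    // initial separation
    double s0 = 0.0;
    for (int k = 0; k < d; ++k) {
      double diff = X(i, k) - X(j, k);
      s0 += diff * diff;
    }
    if (s0 <= 0.0) continue;
    int kmax = std::min(ksteps, M - 1 - std::max(i, j));
    for (int step = 0; step <= kmax; ++step) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i + step, k) - X(j + step, k);
        s += diff * diff;
      }
      if (s <= 0.0) continue;  // exact coincidence later on: skip this step
      acc[step] += 0.5 * std::log(s);
      n_pairs[step] += 1;
    }
  }
  for (int step = 0; step <= ksteps; ++step)
    if (n_pairs[step] > 0) mean_log[step] = acc[step] / n_pairs[step];
  return List::create(_["mean_log"] = mean_log, _["n_pairs"] = n_pairs);
}

// Kennel-style global false nearest neighbour fractions for d = 1..max_dim.
// A neighbour pair at dimension d is false when the extra (d+1)-th
// coordinate either inflates the distance by more than r_tol, or pushes it
// beyond a_tol times the series scale. Zero-distance neighbours (exactly
// repeating states) are judged by the second criterion alone.
// [[Rcpp::export(name = ".fnn_fractions_cpp")]]
NumericVector fnn_fractions_cpp(NumericVector x, int delayT, int max_dim,
                                double r_tol, double a_tol, double scale,
                                int theiler) {
  const int N = x.size();
  NumericVector frac(max_dim, NA_REAL);
  for (int d = 1; d <= max_dim; ++d) {
    // use only points whose (d+1)-dim image exists
    const int M = N - d * delayT;
    if (M < 2) break;
    int n_false = 0, n_tested = 0;
    for (int i = 0; i < M; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int best_j = -1;
      for (int j = 0; j < M; ++j) {
        int sep = i - j; if (sep < 0) sep = -sep;
        if (sep <= theiler) continue;
        double s = 0.0;
        for (int m = 0; m < d; ++m) {
          double diff = x[i + m * delayT] - x[j + m * delayT];
          s += diff * diff;
          if (s >= best) break;
        }
        if (s < best) { best = s; best_j = j; }
      }
      if (best_j < 0) continue;
      double rd = std::sqrt(best);
      double extra = std::fabs(x[i + d * delayT] - x[best_j + d * delayT]);
      double rd1 = std::sqrt(best + extra * extra);
      // distances at rounding-noise level (exactly repeating states) would
      // make the inflation ratio meaningless; judge those by size alone
      bool is_false;
      if (rd > 1e-8 * scale)
        is_false = (extra / rd > r_tol) || (rd1 > a_tol * scale);
      else
        is_false = (rd1 > a_tol * scale);
      ++n_tested;
      if (is_false) ++n_false;
    }
    frac[d - 1] = n_tested > 0 ? (double)n_false / n_tested : NA_REAL;
  }
  return frac;
}
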