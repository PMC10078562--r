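#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void lorenz_rhs(double sigma, double rho, double beta,
                              const double s[3], double ds[3]) {
  ds[0] = sigma * (s[1] - s[0]);
  ds[1] = s[0] * (rho - s[2]) - s[1];
  ds[2] = s[0] * s[1] - beta * s[2];
}

// Fixed-step RK4 integration of the Lorenz system; returns an n x 3 matrix
// of states (initial state is the first row's predecessor, i.e. row 1 is the
// state after one step).
// [[Rcpp::export(name = ".lorenz_rk4_cpp")]]
NumericMatrix lorenz_rk4_cpp(double sigma, double rho, double beta, double dt,
                             int n, double x0, double y0, double z0) {
  NumericMatrix out(n, 3);
  double s[3] = {x0, y0, z0};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  for (int i = 0; i < n; ++i) {
    lorenz_rhs(sigma, rho, beta, s, k1);
    for (int j = 0; j < 3; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    lorenz_rhs(sigma, rho, beta, tmp, k2);
    for (int j = 0; j < 3; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    lorenz_rhs(sigma, rho, beta, tmp, k3);
    for (int j = 0; j < 3; ++j) tmp[j] = s[j] + dt * k3[j];
    lorenz_rhs(sigma, rho, beta, tmp, k4);
    for (int j = 0; j < 3; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!std::isfinite(s[0]) || !std::isfinite(s[1]) || !std::isfinite(s[2]))
      stop("Lorenz integration diverged (non-finite state) at step %d", i + 1);
    out(i, 0) = s[0]; out(i, 1) = s[1]; out(i, 2) = s[2];
  }
  return out;
}
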