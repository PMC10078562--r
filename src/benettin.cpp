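// Tangent-space (Benettin) estimator of the largest Lyapunov exponent of the
// Lorenz system. Deliberately self-contained: it shares no code with the
// divergence-curve estimator it is used to validate.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct State { double x, y, z, dx, dy, dz; };

// combined flow: Lorenz equations plus their variational (tangent) equations
inline State flow(double sg, double rh, double bt, const State& s) {
  State d;
  d.x = sg * (s.y - s.x);
  d.y = s.x * (rh - s.z) - s.y;
  d.z = s.x * s.y - bt * s.z;
  d.dx = sg * (s.dy - s.dx);
  d.dy = (rh - s.z) * s.dx - s.dy - s.x * s.dz;
  d.dz = s.y * s.dx + s.x * s.dy - bt * s.dz;
  return d;
}

inline State axpy(const State& s, double h, const State& d) {
  State r;
  r.x = s.x + h * d.x;   r.y = s.y + h * d.y;   r.z = s.z + h * d.z;
  r.dx = s.dx + h * d.dx; r.dy = s.dy + h * d.dy; r.dz = s.dz + h * d.dz;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".benettin_lorenz_cpp")]]
double benettin_lorenz_cpp(double sigma, double rho, double beta, double dt,
                           int n_steps, int n_transient,
                           double x0, double y0, double z0) {
  State s = {x0, y0, z0, 1.0, 0.0, 0.0};
  double log_sum = 0.0;
  for (int i = 0; i < n_transient + n_steps; ++i) {
    State k1 = flow(sigma, rho, beta, s);
    State k2 = flow(sigma, rho, beta, axpy(s, 0.5 * dt, k1));
    State k3 = flow(sigma, rho, beta, axpy(s, 0.5 * dt, k2));
    State k4 = flow(sigma, rho, beta, axpy(s, dt, k3));
    s.x += dt / 6.0 * (k1.x + 2 * k2.x + 2 * k3.x + k4.x);
    s.y += dt / 6.0 * (k1.y + 2 * k2.y + 2 * k3.y + k4.y);
    s.z += dt / 6.0 * (k1.z + 2 * k2.z + 2 * k3.z + k4.z);
    s.dx += dt / 6.0 * (k1.dx + 2 * k2.dx + 2 * k3.dx + k4.dx);
    s.dy += dt / 6.0 * (k1.dy + 2 * k2.dy + 2 * k3.dy + k4.dy);
    s.dz += dt / 6.0 * (k1.dz + 2 * k2.dz + 2 * k3.dz + k4.dz);
    double nrm = std::sqrt(s.dx * s.dx + s.dy * s.dy + s.dz * s.dz);
    if (!std::isfinite(nrm) || nrm <= 0.0)
      stop("tangent vector degenerate at step %d", i + 1);
    s.dx /= nrm; s.dy /= nrm; s.dz /= nrm;
    if (i >= n_transient) log_sum += std::log(nrm);
  }
  return log_sum / (n_steps * dt);
}
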