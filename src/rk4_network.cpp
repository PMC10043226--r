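#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for a network of Epileptor oscillators coupled
// through the permittivity variable z.  State layout per node:
// (x1, y1, z, x2, y2, g).  The coupling vector is recomputed at every RK4
// substage.  Optional additive Gaussian noise on x2 is applied
// Euler-Maruyama style after the deterministic step, drawn from R's RNG so
// set.seed() governs it.

namespace {

struct ModelConsts {
  double I1, I2, tau0, tau2, gamma;
  int coupling_sign;   // +1: dz has -coupling (as printed); -1: dz has +coupling
  bool g_from_x2;      // filter input: x1 (false) or x2 (true)
  bool f2_on_x2;       // f2 branch condition variable: x1 (false) or x2 (true)
};

inline double f1_val(double x1, double x2, double z) {
  if (x1 < 0.0) return x1 * x1 * x1 - 3.0 * x1 * x1;
  return (x2 - 0.6 * (z - 4.0) * (z - 4.0)) * x1;
}

inline double f2_val(double branch_var, double x2) {
  if (branch_var < -0.25) return 0.0;
  return 6.0 * (x2 + 0.25);
}

// y: length 6n state (node-major), dy: output, coup: scratch length n
void deriv(const std::vector<double>& y, std::vector<double>& dy,
           const std::vector<double>& Sflat, const std::vector<double>& x0,
           int n, const ModelConsts& mc, std::vector<double>& x1v,
           std::vector<double>& coup) {
  for (int i = 0; i < n; ++i) x1v[i] = y[6 * i];
  // coupling_i = sum_j S_ij (x1_i - x1_j), summed in difference form so
  // that synchronized states give exactly zero term by term
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const double xi = x1v[i];
    const double* Srow = &Sflat[(size_t)i * n];
    for (int j = 0; j < n; ++j) acc += Srow[j] * (xi - x1v[j]);
    coup[i] = acc;
  }
  for (int i = 0; i < n; ++i) {
    const double x1 = y[6 * i], y1 = y[6 * i + 1], z = y[6 * i + 2];
    const double x2 = y[6 * i + 3], y2 = y[6 * i + 4], g = y[6 * i + 5];
    dy[6 * i]     = y1 - f1_val(x1, x2, z) - z + mc.I1;
    dy[6 * i + 1] = 1.0 - 5.0 * x1 * x1 - y1;
    dy[6 * i + 2] = (4.0 * (x1 - x0[i]) - z - mc.coupling_sign * coup[i]) / mc.tau0;
    dy[6 * i + 3] = -y2 + x2 - x2 * x2 * x2 + mc.I2 + 0.002 * g - 0.3 * (z - 3.5);
    dy[6 * i + 4] = (-y2 + f2_val(mc.f2_on_x2 ? x2 : x1, x2)) / mc.tau2;
    dy[6 * i + 5] = (mc.g_from_x2 ? x2 : x1) - mc.gamma * g;
  }
}

} // namespace

// [[Rcpp::export]]
List rk4_network_cpp(NumericMatrix S, NumericVector x0, NumericMatrix init,
                     double dt, int n_steps, int save_every,
                     double I1, double I2, double tau0, double tau2,
                     double gamma, int coupling_sign, bool g_from_x2,
                     bool f2_on_x2, double noise_sigma, double guard) {
  const int n = S.nrow();
  if (S.ncol() != n) stop("connectivity matrix must be square");
  if (init.nrow() != n || init.ncol() != 6)
    stop("init must be an n x 6 matrix");
  if (x0.size() != n) stop("x0 must have one value per node");
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (save_every < 1) stop("save_every must be >= 1");

  ModelConsts mc{I1, I2, tau0, tau2, gamma, coupling_sign, g_from_x2, f2_on_x2};

  std::vector<double> Sflat((size_t)n * n), x0v(n);
  for (int i = 0; i < n; ++i) {
    x0v[i] = x0[i];
    for (int j = 0; j < n; ++j) Sflat[(size_t)i * n + j] = S(i, j);
  }

  const int n_save = n_steps / save_every + 1;  // includes the initial state
  NumericMatrix out_x1(n_save, n), out_y1(n_save, n), out_z(n_save, n),
      out_x2(n_save, n), out_y2(n_save, n), out_g(n_save, n);
  NumericVector times(n_save);

  std::vector<double> y((size_t)6 * n), k1(6 * n), k2(6 * n), k3(6 * n),
      k4(6 * n), tmp(6 * n), x1v(n), coup(n);
  for (int i = 0; i < n; ++i)
    for (int v = 0; v < 6; ++v) y[6 * i + v] = init(i, v);

  int row = 0;
  auto record = [&](int step) {
    times[row] = step * dt;
    for (int i = 0; i < n; ++i) {
      out_x1(row, i) = y[6 * i];
      out_y1(row, i) = y[6 * i + 1];
      out_z(row, i)  = y[6 * i + 2];
      out_x2(row, i) = y[6 * i + 3];
      out_y2(row, i) = y[6 * i + 4];
      out_g(row, i)  = y[6 * i + 5];
    }
    ++row;
  };
  record(0);

  const bool noisy = noise_sigma > 0.0;
  const double sq_dt = std::sqrt(dt);
  RNGScope rng_scope;  // harmless when noise is off

  for (int step = 1; step <= n_steps; ++step) {
    deriv(y, k1, Sflat, x0v, n, mc, x1v, coup);
    for (int m = 0; m < 6 * n; ++m) tmp[m] = y[m] + 0.5 * dt * k1[m];
    deriv(tmp, k2, Sflat, x0v, n, mc, x1v, coup);
    for (int m = 0; m < 6 * n; ++m) tmp[m] = y[m] + 0.5 * dt * k2[m];
    deriv(tmp, k3, Sflat, x0v, n, mc, x1v, coup);
    for (int m = 0; m < 6 * n; ++m) tmp[m] = y[m] + dt * k3[m];
    deriv(tmp, k4, Sflat, x0v, n, mc, x1v, coup);
    for (int m = 0; m < 6 * n; ++m)
      y[m] += dt / 6.0 * (k1[m] + 2.0 * k2[m] + 2.0 * k3[m] + k4[m]);
    if (noisy)
      for (int i = 0; i < n; ++i)
        y[6 * i + 3] += noise_sigma * sq_dt * norm_rand();

    for (int m = 0; m < 6 * n; ++m) {
      if (!std::isfinite(y[m]) || std::fabs(y[m]) > guard) {
        stop("integration blow-up at step %d (t = %g), node %d, component %d",
             step, step * dt, m / 6 + 1, m % 6 + 1);
      }
    }
    if (step % save_every == 0) record(step);
  }

  return List::create(_["times"] = times, _["x1"] = out_x1, _["y1"] = out_y1,
                      _["z"] = out_z, _["x2"] = out_x2, _["y2"] = out_y2,
                      _["g"] = out_g);
}
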