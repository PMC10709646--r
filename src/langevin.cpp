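// Underdamped Langevin dynamics (BAOAB splitting with exact
// Ornstein-Uhlenbeck thermostat step) for the two proton coordinates on an
// analytic model surface. The surface terms mirror R/surface.R exactly:
// Gaussian terms + quadratic confinement + cubic-hinge compression walls +
// separation coupling scaled by s. Random numbers come from R's RNG so
// trajectories are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Surface {
  const double* gx; const double* gy; const double* ga; const double* gw;
  int ng;
  const double* sx; const double* sy; const double* sa; const double* sw;
  int ns;
  double c0, xc, yc, offset;
  double wall_amp, wall_x_on, wall_y_on, wall_lo_amp, wall_lo_on;

  double energy(double r1, double r2, double s) const {
    double dx1 = r1 - xc, dy1 = r2 - yc;
    double e = offset + c0 * (dx1 * dx1 + dy1 * dy1);
    double wx = r1 - wall_x_on, wy = r2 - wall_y_on;
    if (wx > 0) e += wall_amp * wx * wx * wx;
    if (wy > 0) e += wall_amp * wy * wy * wy;
    double lx = wall_lo_on - r1, ly = wall_lo_on - r2;
    if (lx > 0) e += wall_lo_amp * lx * lx * lx;
    if (ly > 0) e += wall_lo_amp * ly * ly * ly;
    for (int i = 0; i < ng; ++i) {
      double dx = r1 - gx[i], dy = r2 - gy[i], w2 = gw[i] * gw[i];
      e += ga[i] * std::exp(-(dx * dx + dy * dy) / (2.0 * w2));
    }
    if (s != 0.0) for (int i = 0; i < ns; ++i) {
      double dx = r1 - sx[i], dy = r2 - sy[i], w2 = sw[i] * sw[i];
      e += s * sa[i] * std::exp(-(dx * dx + dy * dy) / (2.0 * w2));
    }
    return e;
  }

  void grad(double r1, double r2, double s, double& g1, double& g2) const {
    g1 = 2.0 * c0 * (r1 - xc);
    g2 = 2.0 * c0 * (r2 - yc);
    double wx = r1 - wall_x_on, wy = r2 - wall_y_on;
    if (wx > 0) g1 += 3.0 * wall_amp * wx * wx;
    if (wy > 0) g2 += 3.0 * wall_amp * wy * wy;
    double lx = wall_lo_on - r1, ly = wall_lo_on - r2;
    if (lx > 0) g1 -= 3.0 * wall_lo_amp * lx * lx;
    if (ly > 0) g2 -= 3.0 * wall_lo_amp * ly * ly;
    for (int i = 0; i < ng; ++i) {
      double dx = r1 - gx[i], dy = r2 - gy[i], w2 = gw[i] * gw[i];
      double e = ga[i] * std::exp(-(dx * dx + dy * dy) / (2.0 * w2));
      g1 -= e * dx / w2;
      g2 -= e * dy / w2;
    }
    if (s != 0.0) for (int i = 0; i < ns; ++i) {
      double dx = r1 - sx[i], dy = r2 - sy[i], w2 = sw[i] * sw[i];
      double e = s * sa[i] * std::exp(-(dx * dx + dy * dy) / (2.0 * w2));
      g1 -= e * dx / w2;
      g2 -= e * dy / w2;
    }
  }
};

inline void reflect(double& r, double& v, double lo, double hi, int& n) {
  if (r < lo) { r = 2.0 * lo - r; v = -v; ++n; }
  else if (r > hi) { r = 2.0 * hi - r; v = -v; ++n; }
}

} // namespace

// [[Rcpp::export]]
List langevin_core(NumericMatrix gauss, NumericMatrix sep,
                   NumericVector conf, double offset, NumericVector wall,
                   NumericVector r0, int n_steps, double dt,
                   double gamma_fs, double mass, double kT,
                   NumericVector bias_center, double bias_k,
                   double s0, double s_rate, double s_max,
                   NumericVector domain,
                   int store_stride, int burn_in,
                   NumericVector lambda_coef, double stop_lambda,
                   bool stop_enabled) {
  Surface S;
  S.ng = gauss.nrow();
  S.gx = S.ng ? &gauss(0, 0) : nullptr;
  S.gy = S.ng ? &gauss(0, 1) : nullptr;
  S.ga = S.ng ? &gauss(0, 2) : nullptr;
  S.gw = S.ng ? &gauss(0, 3) : nullptr;
  S.ns = sep.nrow();
  S.sx = S.ns ? &sep(0, 0) : nullptr;
  S.sy = S.ns ? &sep(0, 1) : nullptr;
  S.sa = S.ns ? &sep(0, 2) : nullptr;
  S.sw = S.ns ? &sep(0, 3) : nullptr;
  S.c0 = conf[0]; S.xc = conf[1]; S.yc = conf[2];
  S.offset = offset;
  S.wall_amp = wall[0]; S.wall_x_on = wall[1]; S.wall_y_on = wall[2];
  S.wall_lo_amp = wall[3]; S.wall_lo_on = wall[4];

  const bool has_bias = bias_center.size() == 2;
  const double ba = has_bias ? bias_center[0] : 0.0;
  const double bb = has_bias ? bias_center[1] : 0.0;
  const double lo = domain[0], hi = domain[1];
  const double la1 = lambda_coef[0], la2 = lambda_coef[1], lb = lambda_coef[2];

  const double c1 = std::exp(-gamma_fs * dt);
  const double c2 = (kT > 0.0) ? std::sqrt(kT / mass * (1.0 - c1 * c1)) : 0.0;

  double r1 = r0[0], r2 = r0[1], v1 = 0.0, v2 = 0.0;
  int n_reflect = 0;
  int first_passage = -1;

  const int n_store = (n_steps - burn_in + store_stride - 1) / store_stride;
  std::vector<double> t_out, r1_out, r2_out, e_out, s_out;
  t_out.reserve(n_store); r1_out.reserve(n_store); r2_out.reserve(n_store);
  e_out.reserve(n_store); s_out.reserve(n_store);

  RNGScope scope;
  double g1, g2;
  double s_now = (s_rate != 0.0) ? std::min(s0, s_max) : s0;
  S.grad(r1, r2, s_now, g1, g2);
  double f1 = -g1, f2 = -g2;
  if (has_bias) { f1 -= 2.0 * bias_k * (r1 - ba); f2 -= 2.0 * bias_k * (r2 - bb); }

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    v1 += 0.5 * dt * f1 / mass;
    v2 += 0.5 * dt * f2 / mass;
    // A: half drift
    r1 += 0.5 * dt * v1;
    r2 += 0.5 * dt * v2;
    // O: exact OU
    if (kT > 0.0) {
      v1 = c1 * v1 + c2 * norm_rand();
      v2 = c1 * v2 + c2 * norm_rand();
    } else {
      v1 *= c1; v2 *= c1;
    }
    // A: half drift
    r1 += 0.5 * dt * v1;
    r2 += 0.5 * dt * v2;
    reflect(r1, v1, lo, hi, n_reflect);
    reflect(r2, v2, lo, hi, n_reflect);
    // B: half kick with new force
    s_now = (s_rate != 0.0) ? std::min(s0 + s_rate * step * dt, s_max) : s0;
    S.grad(r1, r2, s_now, g1, g2);
    f1 = -g1; f2 = -g2;
    if (has_bias) { f1 -= 2.0 * bias_k * (r1 - ba); f2 -= 2.0 * bias_k * (r2 - bb); }
    v1 += 0.5 * dt * f1 / mass;
    v2 += 0.5 * dt * f2 / mass;

    if (stop_enabled && first_passage < 0) {
      double lam = la1 * r1 + la2 * r2 + lb;
      if (lam < stop_lambda) first_passage = step;
    }
    if (step > burn_in && ((step - burn_in - 1) % store_stride == 0)) {
      t_out.push_back(step * dt);
      r1_out.push_back(r1);
      r2_out.push_back(r2);
      e_out.push_back(S.energy(r1, r2, s_now));
      s_out.push_back(s_now);
    }
    if (stop_enabled && first_passage > 0) break;
  }

  return List::create(
    _["t_fs"] = t_out, _["r1"] = r1_out, _["r2"] = r2_out,
    _["E_eV"] = e_out, _["s"] = s_out,
    _["n_reflect"] = n_reflect,
    _["first_passage_step"] = first_passage);
}
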