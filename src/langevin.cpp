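// Underdamped Langevin dynamics (BAOAB splitting) for the built-in 1D
// systems.  All randomness is drawn from R's RNG stream so that runs are
// reproducible from a single engine seed.
//
// Potentials: 0 = quartic double well V(x) = a*(x^2-1)^2
//             1 = harmonic           V(x) = 0.5*a*x^2

#include <Rcpp.h>
using namespace Rcpp;

static inline double force(int pot, double a, double x) {
  if (pot == 0) return -4.0 * a * x * (x * x - 1.0);
  return -a * x;
}

struct Baoab {
  int pot; double a, gamma, kT, dt, mass, c1, c2;
  Baoab(int pot_, double a_, double gamma_, double kT_, double dt_, double mass_)
    : pot(pot_), a(a_), gamma(gamma_), kT(kT_), dt(dt_), mass(mass_) {
    c1 = std::exp(-gamma * dt);
    c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  }
  void step(double &x, double &v) const {
    v += 0.5 * dt * force(pot, a, x) / mass;   // B
    x += 0.5 * dt * v;                          // A
    v = c1 * v + c2 * R::norm_rand();           // O
    x += 0.5 * dt * v;                          // A
    v += 0.5 * dt * force(pot, a, x) / mass;   // B
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_baoab_run(double x0, double v0, int n_steps, int pot,
                            double a, double gamma, double kT, double dt,
                            double mass, int thin = 1) {
  Baoab in(pot, a, gamma, kT, dt, mass);
  int n_out = n_steps / thin + 1;
  NumericMatrix out(n_out, 2);
  double x = x0, v = v0;
  out(0, 0) = x; out(0, 1) = v;
  int k = 1;
  for (int i = 1; i <= n_steps; ++i) {
    in.step(x, v);
    if (i % thin == 0 && k < n_out) { out(k, 0) = x; out(k, 1) = v; ++k; }
  }
  return out;
}

// Integrate from (x0, v0) until x < lo or x >= hi (the terminating slice is
// included), or until max_steps.  status: 0 hit lo, 1 hit hi, 2 max_steps.
// [[Rcpp::export]]
List cpp_integrate_until(double x0, double v0, int pot, double a,
                         double gamma, double kT, double dt, double mass,
                         double lo, double hi, int max_steps) {
  Baoab in(pot, a, gamma, kT, dt, mass);
  std::vector<double> xs, vs;
  xs.reserve(256); vs.reserve(256);
  double x = x0, v = v0;
  xs.push_back(x); vs.push_back(v);
  int status = 2;
  for (int i = 0; i < max_steps; ++i) {
    in.step(x, v);
    xs.push_back(x); vs.push_back(v);
    if (x < lo) { status = 0; break; }
    if (x >= hi) { status = 1; break; }
  }
  return List::create(_["x"] = wrap(xs), _["v"] = wrap(vs),
                      _["status"] = status);
}

// First-passage times from x0 (velocity redrawn from Maxwell-Boltzmann at
// each restart) to x >= target.  Returns passage times in time units.
// [[Rcpp::export]]
NumericVector cpp_first_passage(int n, double x0, double target, int pot,
                                double a, double gamma, double kT, double dt,
                                double mass, int max_steps) {
  Baoab in(pot, a, gamma, kT, dt, mass);
  NumericVector out(n);
  double sd = std::sqrt(kT / mass);
  for (int r = 0; r < n; ++r) {
    double x = x0, v = sd * R::norm_rand();
    int i = 0;
    for (; i < max_steps; ++i) {
      in.step(x, v);
      if (x >= target) break;
    }
    out[r] = (i + 1) * dt;
    if (i == max_steps) out[r] = NA_REAL;
  }
  return out;
}

// History-based rate measurement on one long trajectory: the system is in
// state A from the moment x < lam0 until it first reaches x >= lamM, and in
// B from then until it returns below lam0.  Counts A->B transitions and
// A-residence time per trajectory block.
// [[Rcpp::export]]
List cpp_transition_rate(double x0, double v0, double n_steps_d, int pot,
                         double a, double gamma, double kT, double dt,
                         double mass, double lam0, double lamM,
                         int n_blocks) {
  Baoab in(pot, a, gamma, kT, dt, mass);
  long long n_steps = (long long)n_steps_d;
  NumericVector nAB(n_blocks), tA(n_blocks);
  double x = x0, v = v0;
  bool inA = (x < lamM);
  long long per_block = n_steps / n_blocks;
  for (int b = 0; b < n_blocks; ++b) {
    double cnt = 0.0, ta = 0.0;
    for (long long i = 0; i < per_block; ++i) {
      in.step(x, v);
      if (inA) {
        ta += dt;
        if (x >= lamM) { cnt += 1.0; inA = false; }
      } else {
        if (x < lam0) inA = true;
      }
    }
    nAB[b] = cnt; tA[b] = ta;
  }
  return List::create(_["nAB"] = nAB, _["tA"] = tA);
}
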