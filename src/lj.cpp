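#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Small self-contained RNG (xoshiro256++) so the integrator's inner loop does
// not go through R's RNG API; seeded from R's RNG stream by the caller, so
// set.seed() in R fully determines the trajectory.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of a single seed word
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() { // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

inline double wrap(double x, double lo, double len) {
  double y = x - lo;
  y -= len * std::floor(y / len);
  if (y >= len) y -= len; // guard against floating round-up
  return y + lo;
}

} // namespace

// 2D Langevin dynamics (BAOAB splitting) under truncated, unshifted
// Lennard-Jones pair potentials with per-type-pair well depths, periodic
// boundaries, cell-list neighbor search. Returns final positions, a kinetic
// temperature trace, and the mean kinetic temperature over the last quarter
// of the run.
// [[Rcpp::export]]
List lj_simulate_cpp(NumericMatrix xy0, IntegerVector type, NumericMatrix eps,
                     double sigma, double rc, double box_lo, double box_hi,
                     double temperature, double mass, double dt, double damping,
                     int n_steps, double seed, int limit_steps, double vmax) {
  const int n = xy0.nrow();
  const double L = box_hi - box_lo;
  const double rc2 = rc * rc;
  const int ncell = std::max(1, (int)std::floor(L / rc));
  const double cellw = L / ncell;

  std::vector<double> x(n), y(n), vx(n), vy(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap(xy0(i, 0), box_lo, L);
    y[i] = wrap(xy0(i, 1), box_lo, L);
  }

  Xoshiro rng((uint64_t)(seed * 2147483647.0) + 0x9e3779b9ULL);

  // Maxwell-Boltzmann initial velocities at the target temperature,
  // zero total momentum.
  const double vsd = std::sqrt(temperature / mass);
  double px = 0, py = 0;
  for (int i = 0; i < n; ++i) {
    vx[i] = vsd * rng.norm(); vy[i] = vsd * rng.norm();
    px += vx[i]; py += vy[i];
  }
  for (int i = 0; i < n; ++i) { vx[i] -= px / n; vy[i] -= py / n; }

  std::vector<int> head(ncell * ncell), nxt(n);
  const int ntype = eps.nrow();
  std::vector<double> eps_flat(ntype * ntype);
  for (int a = 0; a < ntype; ++a)
    for (int b = 0; b < ntype; ++b) eps_flat[a * ntype + b] = eps(a, b);

  // forward half-stencil per cell (self handled separately): each pair of
  // neighboring cells is visited exactly once
  const int fdx[4] = {1, 1, 0, -1};
  const int fdy[4] = {0, 1, 1, 1};
  std::vector<int> fwd(ncell * ncell * 4);
  for (int cy = 0; cy < ncell; ++cy)
    for (int cx = 0; cx < ncell; ++cx)
      for (int k = 0; k < 4; ++k) {
        int ncx = (cx + fdx[k] + ncell) % ncell;
        int ncy = (cy + fdy[k] + ncell) % ncell;
        fwd[(cy * ncell + cx) * 4 + k] = ncy * ncell + ncx;
      }

  const double s2 = sigma * sigma;
  auto pair_force = [&](int i, int j) {
    double rx = x[i] - x[j], ry = y[i] - y[j];
    rx -= L * std::round(rx / L);
    ry -= L * std::round(ry / L);
    double r2 = rx * rx + ry * ry;
    if (r2 >= rc2 || r2 <= 1e-12) return;
    double inv2 = s2 / r2;
    double inv6 = inv2 * inv2 * inv2;
    double e = eps_flat[type[i] * ntype + type[j]];
    // F(r)/r = 24 eps (2 (s/r)^12 - (s/r)^6) / r^2
    double fr = 24.0 * e * inv6 * (2.0 * inv6 - 1.0) / r2;
    fx[i] += fr * rx; fy[i] += fr * ry;
    fx[j] -= fr * rx; fy[j] -= fr * ry;
  };

  auto compute_forces = [&]() {
    if (ncell < 3) { // stencil degenerates: plain O(n^2) pairs
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair_force(i, j);
      return;
    }
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int cxi = (int)((x[i] - box_lo) / cellw); if (cxi >= ncell) cxi = ncell - 1;
      int cyi = (int)((y[i] - box_lo) / cellw); if (cyi >= ncell) cyi = ncell - 1;
      int c = cyi * ncell + cxi;
      nxt[i] = head[c]; head[c] = i;
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int c = 0; c < ncell * ncell; ++c) {
      for (int i = head[c]; i >= 0; i = nxt[i]) {
        for (int j = nxt[i]; j >= 0; j = nxt[j]) pair_force(i, j);
        for (int k = 0; k < 4; ++k)
          for (int j = head[fwd[c * 4 + k]]; j >= 0; j = nxt[j])
            pair_force(i, j);
      }
    }
  };

  compute_forces();

  const double c1 = std::exp(-dt / damping);
  const double c2 = std::sqrt((1.0 - c1 * c1) * temperature / mass);
  const int trace_every = std::max(1, n_steps / 200);
  std::vector<double> t_trace;
  t_trace.reserve(n_steps / trace_every + 2);
  double t_accum = 0.0; int t_count = 0;
  const int tail_start = n_steps - n_steps / 4;

  for (int step = 1; step <= n_steps; ++step) {
    const bool limited = step <= limit_steps;
    for (int i = 0; i < n; ++i) { // B + A
      vx[i] += 0.5 * dt * fx[i] / mass;
      vy[i] += 0.5 * dt * fy[i] / mass;
      if (limited) {
        double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
        if (sp > vmax) { vx[i] *= vmax / sp; vy[i] *= vmax / sp; }
      }
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
    }
    for (int i = 0; i < n; ++i) { // O + A
      vx[i] = c1 * vx[i] + c2 * rng.norm();
      vy[i] = c1 * vy[i] + c2 * rng.norm();
      x[i] = wrap(x[i] + 0.5 * dt * vx[i], box_lo, L);
      y[i] = wrap(y[i] + 0.5 * dt * vy[i], box_lo, L);
    }
    compute_forces();
    for (int i = 0; i < n; ++i) { // B
      vx[i] += 0.5 * dt * fx[i] / mass;
      vy[i] += 0.5 * dt * fy[i] / mass;
    }
    if (step % trace_every == 0 || step == n_steps) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) ke += vx[i] * vx[i] + vy[i] * vy[i];
      double tk = mass * ke / (2.0 * n); // 2 dof per particle
      t_trace.push_back(tk);
      if (step > tail_start) { t_accum += tk; ++t_count; }
    }
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return List::create(
    _["coords"] = out,
    _["temperature_trace"] = NumericVector(t_trace.begin(), t_trace.end()),
    _["final_temperature"] = t_count > 0 ? t_accum / t_count : NA_REAL);
}

// Lennard-Jones pair potential, vectorized over distances; used for
// closed-form checks and documentation examples.
// [[Rcpp::export]]
NumericVector lj_potential_cpp(NumericVector r, double eps, double sigma) {
  int n = r.size();
  NumericVector v(n);
  for (int i = 0; i < n; ++i) {
    double s = sigma / r[i];
    double s6 = s * s * s; s6 *= s6;
    v[i] = 4.0 * eps * (s6 * s6 - s6);
  }
  return v;
}
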