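#include <Rcpp.h>
using namespace Rcpp;

// Packed analytic potential: sum of Gaussian terms (amplitude < 0 is a well,
// > 0 a barrier), harmonic terms, a constant baseline, and quartic confining
// walls that switch on `wall_m` Angstrom inside the rectangular domain.
// Everything is C^2, so gradients are exact analytic derivatives.
struct PackedPotential {
  NumericMatrix gc, gw;   // Gaussian centers / widths, n_g x d
  NumericVector ga;       // Gaussian amplitudes, kcal/mol
  NumericMatrix hc, hk;   // harmonic centers / force constants, n_h x d
  double baseline;
  NumericVector lo, hi;   // domain
  double wall_h, wall_m;
  int d;
};

static PackedPotential unpack(const List& pot) {
  PackedPotential p;
  p.gc = as<NumericMatrix>(pot["gc"]);
  p.gw = as<NumericMatrix>(pot["gw"]);
  p.ga = as<NumericVector>(pot["ga"]);
  p.hc = as<NumericMatrix>(pot["hc"]);
  p.hk = as<NumericMatrix>(pot["hk"]);
  p.baseline = as<double>(pot["baseline"]);
  p.lo = as<NumericVector>(pot["lo"]);
  p.hi = as<NumericVector>(pot["hi"]);
  p.wall_h = as<double>(pot["wall_h"]);
  p.wall_m = as<double>(pot["wall_m"]);
  p.d = p.lo.size();
  return p;
}

// energy and gradient at x (length d); grad overwritten
static double eval_point(const PackedPotential& p, const double* x, double* grad) {
  const int d = p.d;
  double e = p.baseline;
  for (int j = 0; j < d; ++j) grad[j] = 0.0;
  for (int i = 0; i < p.ga.size(); ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double u = (x[j] - p.gc(i, j)) / p.gw(i, j);
      s += u * u;
    }
    double g = p.ga[i] * std::exp(-0.5 * s);
    e += g;
    for (int j = 0; j < d; ++j)
      grad[j] += g * (-(x[j] - p.gc(i, j)) / (p.gw(i, j) * p.gw(i, j)));
  }
  for (int i = 0; i < p.hc.nrow(); ++i) {
    for (int j = 0; j < d; ++j) {
      double dx = x[j] - p.hc(i, j);
      e += 0.5 * p.hk(i, j) * dx * dx;
      grad[j] += p.hk(i, j) * dx;
    }
  }
  if (p.wall_h > 0.0) {
    for (int j = 0; j < d; ++j) {
      double m = p.wall_m;
      double over = x[j] - (p.hi[j] - m);
      if (over > 0.0) {
        double u = over / m;
        e += p.wall_h * u * u * u * u;
        grad[j] += 4.0 * p.wall_h * u * u * u / m;
      }
      double under = (p.lo[j] + m) - x[j];
      if (under > 0.0) {
        double u = under / m;
        e += p.wall_h * u * u * u * u;
        grad[j] -= 4.0 * p.wall_h * u * u * u / m;
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_potential_eval(List pot, NumericMatrix pts) {
  PackedPotential p = unpack(pot);
  const int n = pts.nrow(), d = p.d;
  if (pts.ncol() != d) stop("points have %d columns, potential is %d-dimensional", pts.ncol(), d);
  NumericVector energy(n);
  NumericMatrix grad(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = pts(i, j);
    energy[i] = eval_point(p, x.data(), g.data());
    for (int j = 0; j < d; ++j) grad(i, j) = g[j];
  }
  return List::create(_["energy"] = energy, _["gradient"] = grad);
}

// Overdamped Euler-Maruyama: dx = -beta*D*grad(U+bias)*dt + sqrt(2*D*dt)*xi.
// Uses R's RNG so set.seed() governs reproducibility. Records every `stride`-th
// step (step 0 always included); returns (n_recorded x d) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_propagate(List pot, NumericVector start, int n_steps,
                            double beta, double D, double dt,
                            Nullable<NumericVector> bias_center,
                            Nullable<NumericVector> bias_k, int stride) {
  PackedPotential p = unpack(pot);
  const int d = p.d;
  if (start.size() != d) stop("start has length %d, potential is %d-dimensional", start.size(), d);
  bool biased = bias_center.isNotNull();
  NumericVector bc, bk;
  if (biased) { bc = bias_center.get(); bk = bias_k.get(); }
  int n_rec = n_steps / stride + 1;
  NumericMatrix out(n_rec, d);
  std::vector<double> x(d), g(d);
  for (int j = 0; j < d; ++j) { x[j] = start[j]; out(0, j) = x[j]; }
  double noise = std::sqrt(2.0 * D * dt);
  RNGScope scope;
  int row = 1;
  for (int s = 1; s <= n_steps; ++s) {
    eval_point(p, x.data(), g.data());
    if (biased)
      for (int j = 0; j < d; ++j) g[j] += bk[j] * (x[j] - bc[j]);
    for (int j = 0; j < d; ++j) {
      x[j] += -beta * D * g[j] * dt + noise * norm_rand();
      if (!std::isfinite(x[j]))
        stop("Langevin step %d produced a non-finite coordinate; the timestep is too large for this landscape", s);
    }
    if (s % stride == 0) {
      for (int j = 0; j < d; ++j) out(row, j) = x[j];
      ++row;
    }
  }
  return out;
}

// RMSD-steered dynamics: harmonic, one-sided restraint on the CV-space RMSD to
// `target` with a reference value ramping down at `speed` per step from the
// initial RMSD. Flat-bottomed: no force while RMSD <= ramp. Terminates once
// RMSD <= stop_rmsd. Returns recorded trajectory plus termination info.
// [[Rcpp::export]]
List cpp_steer(List pot, NumericVector start, NumericVector target,
               double speed, double stop_rmsd, double k_steer,
               double beta, double D, double dt, int max_steps, int stride) {
  PackedPotential p = unpack(pot);
  const int d = p.d;
  std::vector<double> x(d), g(d);
  for (int j = 0; j < d; ++j) x[j] = start[j];
  auto rmsd_to_target = [&](const std::vector<double>& y) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double u = y[j] - target[j]; s += u * u; }
    return std::sqrt(s / d);
  };
  double r0 = rmsd_to_target(x);
  std::vector<double> rec;
  rec.reserve((max_steps / stride + 2) * d);
  for (int j = 0; j < d; ++j) rec.push_back(x[j]);
  double noise = std::sqrt(2.0 * D * dt);
  RNGScope scope;
  int steps_done = 0;
  bool converged = r0 <= stop_rmsd;
  double rmsd = r0;
  for (int s = 1; s <= max_steps && !converged; ++s) {
    double ramp = r0 - speed * s;
    if (ramp < 0.0) ramp = 0.0;
    eval_point(p, x.data(), g.data());
    rmsd = rmsd_to_target(x);
    if (rmsd > ramp && rmsd > 1e-12) {
      // dRMSD/dx_j = (x_j - t_j) / (d * RMSD)
      double f = k_steer * (rmsd - ramp);
      for (int j = 0; j < d; ++j)
        g[j] += f * (x[j] - target[j]) / (d * rmsd);
    }
    for (int j = 0; j < d; ++j) {
      x[j] += -beta * D * g[j] * dt + noise * norm_rand();
      if (!std::isfinite(x[j]))
        stop("steering step %d produced a non-finite coordinate", s);
    }
    steps_done = s;
    if (s % stride == 0)
      for (int j = 0; j < d; ++j) rec.push_back(x[j]);
    rmsd = rmsd_to_target(x);
    if (rmsd <= stop_rmsd) converged = true;
  }
  if (converged && (steps_done % stride != 0 || steps_done == 0)) {
    if (steps_done > 0)
      for (int j = 0; j < d; ++j) rec.push_back(x[j]);
  }
  int n_rec = rec.size() / d;
  NumericMatrix traj(n_rec, d);
  for (int i = 0; i < n_rec; ++i)
    for (int j = 0; j < d; ++j) traj(i, j) = rec[i * d + j];
  return List::create(_["trajectory"] = traj, _["steps"] = steps_done,
                      _["final_rmsd"] = rmsd, _["converged"] = converged);
}
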