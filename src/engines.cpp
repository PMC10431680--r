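// Simulation engines for the sigma-B circuit chemical reaction network.
//
// Two engines operate on a generic compiled network representation
// (stoichiometry matrix + per-reaction kinetic codes):
//   * a fixed-step drift-implicit / diffusion-explicit Euler-Maruyama
//     integrator for the chemical Langevin equation (noise amplitudes 0
//     give the deterministic reaction-rate ODE path), and
//   * Gillespie's direct-method SSA on integer molecule counts.
// Both use R's RNG so set.seed() on the R side fixes the path exactly.
// The stoichiometry is stored column-sparse (at most four species change
// per reaction), which keeps the per-step cost of propensity, drift,
// Jacobian and noise assembly linear in the number of reactions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// kinetic type codes
static const int RX_PRODUCTION = 0;  // rate * f([sigB])
static const int RX_MASS1 = 1;       // rate * x[i1]
static const int RX_MASS2 = 2;       // rate * x[i1] * x[i2]
static const int RX_DIMER = 3;       // rate * x[i1]^2/2 (counts: x*(x-1)/2)

struct NetSpec {
  arma::mat S;              // nspec x m (dense copy, used to seed sparsity)
  arma::ivec type, i1, i2;  // per reaction
  arma::vec rate, nscale;
  double v0, F, K;
  int form;                 // 0 offset: v0*(1+F*s/(K+s)); 1 ratio: v0*(1+F*s)/(K+s)
  int isigb;
  // sparse stoichiometry: entries (row, value) per reaction
  std::vector<std::vector<std::pair<int, double> > > scol;
};

static NetSpec as_spec(const List& spec) {
  NetSpec ns;
  ns.S = as<arma::mat>(spec["S"]);
  ns.type = as<arma::ivec>(spec["type"]);
  ns.i1 = as<arma::ivec>(spec["i1"]);
  ns.i2 = as<arma::ivec>(spec["i2"]);
  ns.rate = as<arma::vec>(spec["rate"]);
  ns.nscale = as<arma::vec>(spec["nscale"]);
  ns.v0 = as<double>(spec["v0"]);
  ns.F = as<double>(spec["F"]);
  ns.K = as<double>(spec["K"]);
  ns.form = as<int>(spec["form"]);
  ns.isigb = as<int>(spec["isigb"]);
  ns.scol.resize(ns.S.n_cols);
  for (arma::uword j = 0; j < ns.S.n_cols; ++j)
    for (arma::uword i = 0; i < ns.S.n_rows; ++i)
      if (ns.S(i, j) != 0.0)
        ns.scol[j].push_back(std::make_pair((int)i, ns.S(i, j)));
  return ns;
}

static inline double hillf(const NetSpec& ns, double s) {
  if (ns.form == 0) return ns.v0 * (1.0 + ns.F * s / (ns.K + s));
  return ns.v0 * (1.0 + ns.F * s) / (ns.K + s);
}

static inline double hillf_d(const NetSpec& ns, double s) {
  double d = ns.K + s;
  if (ns.form == 0) return ns.v0 * ns.F * ns.K / (d * d);
  return ns.v0 * (ns.F * ns.K - 1.0) / (d * d);
}

static inline double propensity1(const NetSpec& ns, const double* x, int j,
                                 bool discrete, double f) {
  switch (ns.type[j]) {
  case RX_PRODUCTION: return ns.rate[j] * f;
  case RX_MASS1: return ns.rate[j] * x[ns.i1[j]];
  case RX_MASS2: return ns.rate[j] * x[ns.i1[j]] * x[ns.i2[j]];
  case RX_DIMER: {
    double w = x[ns.i1[j]];
    return discrete ? ns.rate[j] * w * (w - 1.0) / 2.0
                    : ns.rate[j] * w * w / 2.0;
  }
  }
  return 0.0;
}

static void propensities(const NetSpec& ns, const arma::vec& x, bool discrete,
                         arma::vec& a) {
  const double f = hillf(ns, x[ns.isigb]);
  for (arma::uword j = 0; j < ns.type.n_elem; ++j)
    a[j] = propensity1(ns, x.memptr(), (int)j, discrete, f);
}

// drift = S a(x), accumulated sparsely
static void drift_vec(const NetSpec& ns, const arma::vec& x, arma::vec& out) {
  const double f = hillf(ns, x[ns.isigb]);
  out.zeros();
  for (arma::uword j = 0; j < ns.type.n_elem; ++j) {
    double a = propensity1(ns, x.memptr(), (int)j, false, f);
    if (a == 0.0) continue;
    const std::vector<std::pair<int, double> >& sc = ns.scol[j];
    for (size_t q = 0; q < sc.size(); ++q) out[sc[q].first] += sc[q].second * a;
  }
}

// drift Jacobian J(i,l) = sum_j S(i,j) da_j/dx_l, accumulated sparsely
static void drift_jacobian(const NetSpec& ns, const arma::vec& x, arma::mat& J) {
  J.zeros();
  const double fp = hillf_d(ns, x[ns.isigb]);
  int dvar[2];
  double dval[2];
  for (arma::uword j = 0; j < ns.type.n_elem; ++j) {
    int nd = 0;
    switch (ns.type[j]) {
    case RX_PRODUCTION:
      dvar[0] = ns.isigb; dval[0] = ns.rate[j] * fp; nd = 1; break;
    case RX_MASS1:
      dvar[0] = ns.i1[j]; dval[0] = ns.rate[j]; nd = 1; break;
    case RX_MASS2:
      dvar[0] = ns.i1[j]; dval[0] = ns.rate[j] * x[ns.i2[j]];
      dvar[1] = ns.i2[j]; dval[1] = ns.rate[j] * x[ns.i1[j]]; nd = 2; break;
    case RX_DIMER:
      dvar[0] = ns.i1[j]; dval[0] = ns.rate[j] * x[ns.i1[j]]; nd = 1; break;
    }
    const std::vector<std::pair<int, double> >& sc = ns.scol[j];
    for (int q2 = 0; q2 < nd; ++q2)
      for (size_t q = 0; q < sc.size(); ++q)
        J(sc[q].first, dvar[q2]) += sc[q].second * dval[q2];
  }
}

// [[Rcpp::export]]
arma::vec drift_cpp(List spec, arma::vec x) {
  NetSpec ns = as_spec(spec);
  arma::vec out(x.n_elem);
  drift_vec(ns, x, out);
  return out;
}

// [[Rcpp::export]]
arma::vec propensities_cpp(List spec, arma::vec x, bool discrete) {
  NetSpec ns = as_spec(spec);
  arma::vec a(ns.type.n_elem);
  propensities(ns, x, discrete, a);
  return a;
}

// in-place LU with partial pivoting for the small (n <= 16) Newton systems;
// avoids LAPACK call overhead in the per-step hot loop
static const int NMAX = 16;

static bool lu_factor(double* A, int* piv, int n) {
  for (int k = 0; k < n; ++k) {
    int p = k;
    double amax = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i * n + k]);
      if (v > amax) { amax = v; p = i; }
    }
    if (amax == 0.0 || !std::isfinite(amax)) return false;
    piv[k] = p;
    if (p != k)
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[p * n + j]);
    double pivv = A[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      double l = A[i * n + k] / pivv;
      A[i * n + k] = l;
      for (int j = k + 1; j < n; ++j) A[i * n + j] -= l * A[k * n + j];
    }
  }
  return true;
}

static void lu_solve(const double* A, const int* piv, int n, double* b) {
  for (int k = 0; k < n; ++k) {
    if (piv[k] != k) std::swap(b[k], b[piv[k]]);
    for (int i = k + 1; i < n; ++i) b[i] -= A[i * n + k] * b[k];
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) b[i] -= A[i * n + j] * b[j];
    b[i] /= A[i * n + i];
  }
}

// One drift-implicit step: solve y = x + dt * S a(y) + d by damped modified
// Newton (the Jacobian is factorised once and refreshed only if the
// iteration stalls).
static bool implicit_step(const NetSpec& ns, const arma::vec& x, double dt,
                          const arma::vec& d, double tol, int maxit,
                          arma::vec& y, int& iters) {
  const int n = (int)x.n_elem;
  arma::vec G(n), delta(n), fy(n), ytry(n), Gtry(n);
  arma::mat J(n, n);
  double A[NMAX * NMAX];
  int piv[NMAX];
  // start from the current state shifted by the noise increment; an explicit
  // drift predictor overshoots badly at the stiff stress onset
  y = x + d;
  bool have_lu = false;
  double gprev = R_PosInf;
  for (int it = 0; it < maxit; ++it) {
    ++iters;
    drift_vec(ns, y, fy);
    G = y - x - dt * fy - d;
    double g0 = arma::abs(G).max();
    if (!std::isfinite(g0)) return false;
    if (g0 < tol) return true;
    // refresh the factorisation at the first iteration and whenever the
    // residual is not contracting fast enough
    if (!have_lu || g0 > 0.25 * gprev) {
      drift_jacobian(ns, y, J);
      for (int i = 0; i < n; ++i)
        for (int j2 = 0; j2 < n; ++j2)
          A[i * n + j2] = (i == j2 ? 1.0 : 0.0) - dt * J(i, j2);
      if (!lu_factor(A, piv, n)) return false;
      have_lu = true;
    }
    gprev = g0;
    for (int i = 0; i < n; ++i) delta[i] = -G[i];
    lu_solve(A, piv, n, delta.memptr());
    // damped update: backtrack until the residual norm decreases
    double step = 1.0;
    for (int h = 0; h < 8; ++h) {
      ytry = y + step * delta;
      drift_vec(ns, ytry, fy);
      Gtry = ytry - x - dt * fy - d;
      double g1 = arma::abs(Gtry).max();
      if (std::isfinite(g1) && (g1 < g0 || g1 < tol)) break;
      step *= 0.5;
    }
    y = ytry;
  }
  drift_vec(ns, y, fy);
  G = y - x - dt * fy - d;
  return arma::abs(G).max() < tol;
}

// On Newton failure, retake the step as two half steps with the noise
// increment split in half, recursing a few levels (rare stiff-onset
// fallback; the diffusion term stays the one drawn for the full step).
static bool recursive_step(const NetSpec& ns, const arma::vec& x, double dt,
                           const arma::vec& d, double tol, int maxit,
                           arma::vec& y, int& iters, int& halvings, int depth) {
  if (implicit_step(ns, x, dt, d, tol, maxit, y, iters)) return true;
  if (depth >= 10) return false;
  ++halvings;
  arma::vec xh;
  return recursive_step(ns, x, dt / 2, d / 2, tol, maxit, xh, iters, halvings, depth + 1) &&
         recursive_step(ns, xh, dt / 2, d / 2, tol, maxit, y, iters, halvings, depth + 1);
}

// Fixed-step CLE / ODE path. Noise term is diffusion-explicit:
// d_i = sum_j nscale_j * S_ij * sqrt(|a_j(x_n)|) * dW_j, dW_j ~ N(0, dt),
// absolute value inside the square root per the CLE non-negativity
// convention; species may transiently dip negative.
// [[Rcpp::export]]
List cle_simulate_cpp(List spec, arma::vec x0, double t0, double tstress,
                      double tend, double dt, int out_every,
                      arma::vec stress_add, bool stochastic,
                      double newton_tol, int newton_max) {
  NetSpec ns = as_spec(spec);
  const arma::uword n = x0.n_elem, m = ns.type.n_elem;
  const int nsteps = (int)std::lround((tend - t0) / dt);
  const int kstress = (int)std::lround((tstress - t0) / dt);
  const int nout = nsteps / out_every + 1;
  arma::mat out(nout, n);
  RNGScope rngScope;

  arma::vec x = x0, a(m), d(n), y(n);
  const double sqdt = std::sqrt(dt);
  out.row(0) = x.t();
  int iters = 0, halvings = 0, oi = 1;
  for (int k = 1; k <= nsteps; ++k) {
    if (k - 1 == kstress) x += stress_add;  // stress applied at t_stress
    d.zeros();
    if (stochastic) {
      propensities(ns, x, false, a);
      for (arma::uword j = 0; j < m; ++j) {
        double dW = norm_rand() * sqdt;  // fixed reaction order
        double b = ns.nscale[j] * std::sqrt(std::fabs(a[j])) * dW;
        if (b == 0.0) continue;
        const std::vector<std::pair<int, double> >& sc = ns.scol[j];
        for (size_t q = 0; q < sc.size(); ++q) d[sc[q].first] += sc[q].second * b;
      }
    }
    if (!recursive_step(ns, x, dt, d, newton_tol, newton_max, y, iters,
                        halvings, 0))
      stop("implicit Euler-Maruyama failed to converge at step %d (t = %g)",
           k, t0 + k * dt);
    x = y;
    if (!x.is_finite() || arma::abs(x).max() > 1e6)
      stop("non-finite or diverged state at step %d (t = %g)", k, t0 + k * dt);
    if (k % out_every == 0) out.row(oi++) = x.t();
  }
  // the sample at t_stress must reflect the post-stress state
  if (kstress % out_every == 0) {
    int si = kstress / out_every;
    for (arma::uword i = 0; i < n; ++i) out(si, i) += stress_add[i];
  }
  return List::create(_["x"] = out, _["newton_iters"] = iters,
                      _["halvings"] = halvings);
}

// Gillespie direct method on molecule counts, sampled onto a fixed output
// grid (piecewise-constant). Stress adds stress_add counts at t_stress.
// [[Rcpp::export]]
arma::mat ssa_simulate_cpp(List spec, arma::vec x0, double t0, double tstress,
                           double tend, arma::vec out_times,
                           arma::vec stress_add) {
  NetSpec ns = as_spec(spec);
  const arma::uword m = ns.type.n_elem;
  arma::mat out(out_times.n_elem, x0.n_elem);
  RNGScope rngScope;
  arma::vec x = x0, a(m);
  double t = t0;
  arma::uword oi = 0;
  bool stressed = false;
  while (oi < out_times.n_elem) {
    propensities(ns, x, true, a);
    double atot = 0.0;
    for (arma::uword j = 0; j < m; ++j) atot += a[j];
    double tnext = (atot > 0.0) ? t + exp_rand() / atot : R_PosInf;
    double tbound = stressed ? R_PosInf : tstress;
    double tev = std::min(tnext, tbound);
    // emit all grid points strictly before the next state change
    while (oi < out_times.n_elem && out_times[oi] < tev) out.row(oi++) = x.t();
    if (oi >= out_times.n_elem) break;
    if (!stressed && tev == tbound) {
      x += stress_add;
      stressed = true;
      t = tstress;
      continue;
    }
    if (!std::isfinite(tnext)) {  // nothing can fire: hold state to the end
      while (oi < out_times.n_elem) out.row(oi++) = x.t();
      break;
    }
    double u = unif_rand() * atot, c = 0.0;
    arma::uword jsel = m - 1;
    for (arma::uword j = 0; j < m; ++j) {
      c += a[j];
      if (u <= c) { jsel = j; break; }
    }
    const std::vector<std::pair<int, double> >& sc = ns.scol[jsel];
    for (size_t q = 0; q < sc.size(); ++q) x[sc[q].first] += sc[q].second;
    t = tnext;
  }
  return out;
}
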