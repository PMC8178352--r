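#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// The lumped chain for a sample of size 2 in a symmetric n-island component
// has states (S: same deme, D: different demes, C: coalesced).  The C row is
// absorbing, so all propagation happens on the 2x2 transient block
//   [ -(1/s + M)   M        ]
//   [  M/(n-1)    -M/(n-1)  ]
// whose eigenvalues are real and distinct (off-diagonal product > 0), giving
// a closed-form matrix exponential.

struct Block {
  double a, b, c, d; // row-major transient block
};

static inline Block make_block(int n, double M, double s) {
  Block q;
  q.a = -(1.0 / s + M);
  q.b = M;
  q.c = M / (n - 1.0);
  q.d = -M / (n - 1.0);
  return q;
}

// E = exp(dt * Q2), row-major 2x2 into e[4].  Uses the spectral projectors
// E = e^mu1 (A - mu2 I)/delta - e^mu2 (A - mu1 I)/delta with rationalized
// differences: for b, c > 0 we have delta > |a - d|, so hp = (a-d) + delta
// and hm = (a-d) - delta have fixed signs and the stable one of each pair
// is obtained from hp * hm = -4bc.  All diagonal contributions then carry
// the same sign and no cancellation occurs even when one mode dominates.
static inline void expm2(const Block& q, double dt, double* e) {
  const double a = q.a * dt, b = q.b * dt, c = q.c * dt, d = q.d * dt;
  const double tr = a + d;
  const double h = a - d;
  const double bc4 = 4.0 * b * c;
  const double delta = std::sqrt(h * h + bc4);
  if (delta > 1e-12 * (std::fabs(tr) + 1.0)) {
    const double hp = (h >= 0.0) ? h + delta : bc4 / (delta - h); // > 0
    const double hm = (h <= 0.0) ? h - delta : -bc4 / (delta + h); // < 0
    // tr < 0 for generator blocks: tr - delta is cancellation-free and the
    // small root comes from the determinant (mu1 mu2 = det)
    const double mu2 = 0.5 * (tr - delta);
    const double det = a * d - b * c;
    const double mu1 = (mu2 != 0.0) ? det / mu2 : 0.5 * (tr + delta);
    const double e1 = std::exp(mu1), e2 = std::exp(mu2);
    e[0] = (e1 * hp - e2 * hm) / (2.0 * delta);
    e[1] = b * (e1 - e2) / delta;
    e[2] = c * (e1 - e2) / delta;
    e[3] = (e2 * hp - e1 * hm) / (2.0 * delta);
  } else {
    // near-defective: exp(A) ~ e^mu (I + (A - mu I)) with mu = tr/2
    const double mu = 0.5 * tr, em = std::exp(mu);
    e[0] = em * (1.0 + (a - mu));
    e[1] = em * b;
    e[2] = em * c;
    e[3] = em * (1.0 + (d - mu));
  }
}

// p <- p * E (row vector times matrix)
static inline void apply2(double* p, const double* e) {
  const double s0 = p[0] * e[0] + p[1] * e[2];
  const double s1 = p[0] * e[1] + p[1] * e[3];
  p[0] = s0;
  p[1] = s1;
}

// State probabilities (pS, pD), survival, density and IICR of the
// piecewise-stationary model at each requested time (2N-generation units).
// times must be nondecreasing and nonnegative; t_ev strictly increasing.
// [[Rcpp::export(name = ".cpp_iicr_curve")]]
List cpp_iicr_curve(int n, NumericVector t_ev, NumericVector M,
                    NumericVector s, NumericVector times) {
  const int gamma = t_ev.size();
  const int nt = times.size();
  // state at the left edge of each component
  std::vector<double> bS(gamma + 1), bD(gamma + 1);
  bS[0] = 1.0;
  bD[0] = 0.0;
  double e[4];
  for (int i = 0; i < gamma; ++i) {
    const double t_lo = (i == 0) ? 0.0 : t_ev[i - 1];
    Block q = make_block(n, M[i], s[i]);
    expm2(q, t_ev[i] - t_lo, e);
    double p[2] = {bS[i], bD[i]};
    apply2(p, e);
    bS[i + 1] = p[0];
    bD[i + 1] = p[1];
  }
  NumericVector pS(nt), pD(nt), surv(nt), dens(nt), iicr(nt);
  for (int j = 0; j < nt; ++j) {
    const double t = times[j];
    int comp = 0;
    while (comp < gamma && t >= t_ev[comp]) ++comp;
    const double t_lo = (comp == 0) ? 0.0 : t_ev[comp - 1];
    Block q = make_block(n, M[comp], s[comp]);
    expm2(q, t - t_lo, e);
    double p[2] = {bS[comp], bD[comp]};
    apply2(p, e);
    pS[j] = p[0];
    pD[j] = p[1];
    surv[j] = p[0] + p[1];
    dens[j] = p[0] / s[comp];
    iicr[j] = surv[j] / dens[j];
  }
  return List::create(_["p_same"] = pS, _["p_diff"] = pD,
                      _["survival"] = surv, _["density"] = dens,
                      _["iicr"] = iicr);
}

// ---------------------------------------------------------------------------
// Objective: decode an optimizer vector and measure the weighted distance
// between the target step curve and the candidate model's exact IICR.
//
// Encoding (length 2*gamma + 2, +1 when scaled):
//   x[0]                 n, continuous, rounded and clamped on decode
//   x[1 .. gamma]        log10 of event times, sorted on decode
//                        (2N-generation units unscaled, generations scaled)
//   x[gamma+1 .. 2g+1]   migration rates, linear
//   x[2g+2]              log10 of the reference size N (scaled fit only)
// Deme sizes are fixed to 1 in the optimizer.
//
// tau has length I+1 (tau_0 = 0 included); y length I; wdt length I holds
// the precomputed per-interval factor (weight * interval width for the
// omega distance, a 0/1 mask for the visual distance, zeros for intervals
// dropped by a time-range restriction).

struct ObjCtx {
  int c;
  int n_lo, n_hi;
  bool scaled;
  const double* tau; // right endpoints tau_1..tau_I
  const double* y;
  const double* wdt;
  int I;
};

static const double PENALTY = 1e12;

static double eval_objective(const double* x, const ObjCtx& ctx) {
  const int gamma = ctx.c - 1;
  int n = (int)std::lround(x[0]);
  if (n < ctx.n_lo) n = ctx.n_lo;
  if (n > ctx.n_hi) n = ctx.n_hi;
  double N = 1.0;
  if (ctx.scaled) N = std::pow(10.0, x[2 * gamma + 2]);
  std::vector<double> tev(gamma), Mv(gamma + 1), sv(gamma + 1, 1.0);
  for (int i = 0; i < gamma; ++i) {
    tev[i] = std::pow(10.0, x[1 + i]);
    if (ctx.scaled) tev[i] /= 2.0 * N; // generations -> 2N units
  }
  std::sort(tev.begin(), tev.end());
  for (int i = 0; i <= gamma; ++i) Mv[i] = x[1 + gamma + i];

  // propagate boundary states
  std::vector<double> bS(gamma + 1), bD(gamma + 1);
  bS[0] = 1.0;
  bD[0] = 0.0;
  double e[4];
  for (int i = 0; i < gamma; ++i) {
    const double t_lo = (i == 0) ? 0.0 : tev[i - 1];
    Block q = make_block(n, Mv[i], sv[i]);
    expm2(q, tev[i] - t_lo, e);
    double p[2] = {bS[i], bD[i]};
    apply2(p, e);
    bS[i + 1] = p[0];
    bD[i + 1] = p[1];
  }
  double dist = 0.0;
  for (int j = 0; j < ctx.I; ++j) {
    if (ctx.wdt[j] == 0.0) continue;
    double t = ctx.tau[j];
    if (ctx.scaled) t /= 2.0 * N; // generations -> 2N units
    int comp = 0;
    while (comp < gamma && t >= tev[comp]) ++comp;
    const double t_lo = (comp == 0) ? 0.0 : tev[comp - 1];
    Block q = make_block(n, Mv[comp], sv[comp]);
    expm2(q, t - t_lo, e);
    double p[2] = {bS[comp], bD[comp]};
    apply2(p, e);
    double v = (p[0] + p[1]) * sv[comp] / p[0];
    if (ctx.scaled) v *= N;
    if (!std::isfinite(v)) return PENALTY;
    dist += std::fabs(ctx.y[j] - v) * ctx.wdt[j];
  }
  return std::isfinite(dist) ? dist : PENALTY;
}

// [[Rcpp::export(name = ".cpp_objective")]]
double cpp_objective(NumericVector x, int c, int n_lo, int n_hi, bool scaled,
                     NumericVector tau, NumericVector y, NumericVector wdt) {
  ObjCtx ctx{c, n_lo, n_hi, scaled, REAL(tau), REAL(y), REAL(wdt),
             (int)y.size()};
  return eval_objective(REAL(x), ctx);
}

// One differential-evolution convergence cycle: latin-hypercube
// initialization, binomial crossover with dithered F, immediate update,
// bounds handled by clamping.  strategy 0 = rand/1 (explorative),
// 1 = best/1 (exploitative, the scipy default).  Uses R's RNG so runs are
// reproducible under set.seed().  Stops when the population energies have
// collapsed (sd <= tol * |mean| + atol) or after maxiter generations.
// Returns the top `nkeep` distinct members for downstream polishing.
// [[Rcpp::export(name = ".cpp_de_round")]]
List cpp_de_round(NumericVector lower, NumericVector upper, int np,
                  double cr, double f_lo, double f_hi, int maxiter,
                  double tol, double atol, NumericVector init,
                  int strategy, int nkeep,
                  int c, int n_lo, int n_hi, bool scaled,
                  NumericVector tau, NumericVector y, NumericVector wdt) {
  const int dim = lower.size();
  ObjCtx ctx{c, n_lo, n_hi, scaled, REAL(tau), REAL(y), REAL(wdt),
             (int)y.size()};
  std::vector<double> pop((size_t)np * dim), fit(np);
  // latin hypercube: one sample per row-stratum per dimension
  {
    std::vector<int> perm(np);
    for (int d = 0; d < dim; ++d) {
      for (int i = 0; i < np; ++i) perm[i] = i;
      for (int i = np - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      for (int i = 0; i < np; ++i)
        pop[(size_t)i * dim + d] =
            lower[d] + (perm[i] + unif_rand()) / np * (upper[d] - lower[d]);
    }
  }
  if (init.size() == dim)
    for (int d = 0; d < dim; ++d)
      pop[d] = std::min(std::max((double)init[d], (double)lower[d]),
                        (double)upper[d]);
  int ib = 0;
  for (int i = 0; i < np; ++i) {
    fit[i] = eval_objective(&pop[(size_t)i * dim], ctx);
    if (fit[i] < fit[ib]) ib = i;
  }

  std::vector<double> trial(dim);
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= maxiter; ++iter) {
    const double F = f_lo + unif_rand() * (f_hi - f_lo);
    for (int i = 0; i < np; ++i) {
      int r1, r2, r3;
      if (strategy == 1) {
        r1 = ib;
      } else {
        do { r1 = (int)(unif_rand() * np); } while (r1 == i || r1 == np);
      }
      do { r2 = (int)(unif_rand() * np); } while (r2 == i || r2 == r1 || r2 == np);
      do { r3 = (int)(unif_rand() * np); } while (r3 == i || r3 == r1 || r3 == r2 || r3 == np);
      int jrand = (int)(unif_rand() * dim);
      if (jrand == dim) jrand = dim - 1;
      for (int d = 0; d < dim; ++d) {
        if (d == jrand || unif_rand() < cr) {
          double v = pop[(size_t)r1 * dim + d] +
                     F * (pop[(size_t)r2 * dim + d] - pop[(size_t)r3 * dim + d]);
          trial[d] = std::min(std::max(v, (double)lower[d]), (double)upper[d]);
        } else {
          trial[d] = pop[(size_t)i * dim + d];
        }
      }
      const double ft = eval_objective(trial.data(), ctx);
      if (ft <= fit[i]) {
        fit[i] = ft;
        std::copy(trial.begin(), trial.end(), pop.begin() + (size_t)i * dim);
        if (ft < fit[ib]) ib = i;
      }
    }
    double mean = 0.0;
    for (int i = 0; i < np; ++i) mean += fit[i];
    mean /= np;
    double var = 0.0;
    for (int i = 0; i < np; ++i) var += (fit[i] - mean) * (fit[i] - mean);
    const double sd = std::sqrt(var / np);
    if (sd <= tol * std::fabs(mean) + atol) {
      converged = true;
      break;
    }
  }
  // top nkeep members by fitness
  std::vector<int> ord(np);
  for (int i = 0; i < np; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return fit[a] < fit[b]; });
  if (nkeep < 1) nkeep = 1;
  if (nkeep > np) nkeep = np;
  NumericMatrix top(nkeep, dim);
  NumericVector topval(nkeep);
  for (int k = 0; k < nkeep; ++k) {
    for (int d = 0; d < dim; ++d) top(k, d) = pop[(size_t)ord[k] * dim + d];
    topval[k] = fit[ord[k]];
  }
  NumericVector best(dim);
  for (int d = 0; d < dim; ++d) best[d] = pop[(size_t)ord[0] * dim + d];
  return List::create(_["par"] = best, _["value"] = fit[ord[0]],
                      _["top"] = top, _["top_values"] = topval,
                      _["iterations"] = std::min(iter, maxiter),
                      _["converged"] = converged);
}

// Gillespie draws of the absorption (coalescence) time of the lumped chain
// started in state S, honouring component boundaries exactly: by the
// memoryless property a holding time crossing a boundary is discarded and
// redrawn under the next component's rates.
// [[Rcpp::export(name = ".cpp_simulate_t2")]]
NumericVector cpp_simulate_t2(int n, NumericVector t_ev, NumericVector M,
                              NumericVector s, int n_draws) {
  const int gamma = t_ev.size();
  NumericVector out(n_draws);
  for (int k = 0; k < n_draws; ++k) {
    double t = 0.0;
    int comp = 0;
    bool same = true; // state S
    for (;;) {
      const double coal = same ? 1.0 / s[comp] : 0.0;
      const double mig = same ? M[comp] : M[comp] / (n - 1.0);
      const double total = coal + mig;
      const double hold = exp_rand() / total;
      if (comp < gamma && t + hold >= t_ev[comp]) {
        t = t_ev[comp];
        ++comp;
        continue;
      }
      t += hold;
      if (same && unif_rand() < coal / total) break; // coalesced
      same = !same;
    }
    out[k] = t;
  }
  return out;
}
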