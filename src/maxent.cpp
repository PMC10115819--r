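#include <Rcpp.h>
using namespace Rcpp;

// Conditional draw for one component given its local field f.
// Binary components follow a Bernoulli with logit f; continuous components
// follow the density proportional to exp(f * x) on [0, 1], whose inverse CDF
// is available in closed form (truncated exponential).
static double draw_component(double f, bool binary) {
  if (binary) {
    double p = 1.0 / (1.0 + std::exp(-f));
    return (R::unif_rand() < p) ? 1.0 : 0.0;
  }
  if (f > 500.0) f = 500.0;
  if (f < -500.0) f = -500.0;
  double u = R::unif_rand();
  if (std::fabs(f) < 1e-8) return u;
  return std::log1p(u * std::expm1(f)) / f;
}

// One full-systematic-scan Gibbs sweep over every free component of every chain.
static void sweep_chains(NumericMatrix chains,
                         const NumericVector &h, const NumericMatrix &J,
                         const NumericVector &ga, const NumericVector &gs,
                         double ea, double es,
                         const LogicalVector &binary,
                         const LogicalVector &clamped) {
  const int M = chains.nrow(), N = chains.ncol();
  for (int i = 0; i < N; ++i) {
    if (clamped[i]) continue;
    const double bias = h[i] + ga[i] * ea + gs[i] * es;
    for (int m = 0; m < M; ++m) {
      double f = bias;
      for (int j = 0; j < N; ++j) {
        if (j != i) f += J(i, j) * chains(m, j);
      }
      chains(m, i) = draw_component(f, binary[i]);
    }
  }
}

// [[Rcpp::export(name = ".cs_gibbs")]]
NumericMatrix cs_gibbs(NumericVector h, NumericMatrix J,
                       NumericVector ga, NumericVector gs,
                       double ea, double es,
                       NumericMatrix init,
                       LogicalVector binary, LogicalVector clamped,
                       int n_record, int burn_in, int thin) {
  NumericMatrix chains = clone(init);
  const int M = chains.nrow(), N = chains.ncol();
  NumericMatrix out(n_record * M, N);
  RNGScope scope;
  for (int s = 0; s < burn_in; ++s)
    sweep_chains(chains, h, J, ga, gs, ea, es, binary, clamped);
  for (int r = 0; r < n_record; ++r) {
    for (int t = 0; t < thin; ++t)
      sweep_chains(chains, h, J, ga, gs, ea, es, binary, clamped);
    for (int m = 0; m < M; ++m)
      for (int j = 0; j < N; ++j) out(r * M + m, j) = chains(m, j);
  }
  return out;
}

// Robbins-Monro stochastic approximation for the extended pairwise
// maximum-entropy model.  Persistent Gibbs chains are kept per distinct
// environment; each iteration advances every chain and nudges the parameters
// by a_t * (observed - simulated) sufficient statistics.  The returned
// parameters are tail averages (Polyak averaging over the final fraction of
// iterations) to damp Monte Carlo jitter.
// [[Rcpp::export(name = ".cs_sa_fit")]]
List cs_sa_fit(NumericVector obs_h, NumericMatrix obs_J,
               NumericVector obs_ga, NumericVector obs_gs,
               NumericVector env_ea, NumericVector env_es, NumericVector env_w,
               LogicalVector binary,
               NumericVector h0, NumericMatrix J0,
               NumericVector ga0, NumericVector gs0,
               int n_iter, double a0, double tau,
               int n_chains, int sweeps_per_iter,
               double h_max, double avg_frac,
               bool estimate_ga, bool estimate_gs) {
  const int N = obs_h.size(), E = env_ea.size();
  NumericVector h = clone(h0), ga = clone(ga0), gs = clone(gs0);
  NumericMatrix J = clone(J0);
  RNGScope scope;

  // persistent chains, one block per environment
  std::vector<NumericMatrix> chains(E);
  for (int e = 0; e < E; ++e) {
    NumericMatrix ch(n_chains, N);
    for (int m = 0; m < n_chains; ++m)
      for (int j = 0; j < N; ++j)
        ch(m, j) = binary[j] ? (R::unif_rand() < 0.5 ? 1.0 : 0.0)
                             : R::unif_rand();
    chains[e] = ch;
  }

  NumericVector trace(n_iter);
  NumericVector sim_h(N), sim_ga(N), sim_gs(N);
  NumericMatrix sim_J(N, N);
  NumericVector h_acc(N), ga_acc(N), gs_acc(N);
  NumericMatrix J_acc(N, N);
  int n_avg_target = std::max(1, (int)std::floor(avg_frac * n_iter));
  int avg_start = n_iter - n_avg_target, n_avg = 0;
  LogicalVector no_clamp(N, false);

  for (int t = 0; t < n_iter; ++t) {
    std::fill(sim_h.begin(), sim_h.end(), 0.0);
    std::fill(sim_ga.begin(), sim_ga.end(), 0.0);
    std::fill(sim_gs.begin(), sim_gs.end(), 0.0);
    std::fill(sim_J.begin(), sim_J.end(), 0.0);

    for (int e = 0; e < E; ++e) {
      for (int s = 0; s < sweeps_per_iter; ++s)
        sweep_chains(chains[e], h, J, ga, gs, env_ea[e], env_es[e],
                     binary, no_clamp);
      const double w = env_w[e] / n_chains;
      NumericMatrix &ch = chains[e];
      for (int m = 0; m < n_chains; ++m) {
        for (int i = 0; i < N; ++i) {
          const double xi = ch(m, i);
          sim_h[i] += w * xi;
          sim_ga[i] += w * env_ea[e] * xi;
          sim_gs[i] += w * env_es[e] * xi;
          for (int j = i + 1; j < N; ++j)
            sim_J(i, j) += w * xi * ch(m, j);
        }
      }
    }

    const double a = a0 / (1.0 + t / tau);
    double mism = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = obs_h[i] - sim_h[i];
      mism = std::max(mism, std::fabs(d));
      h[i] += a * d;
      if (h[i] > h_max) h[i] = h_max;
      if (h[i] < -h_max) h[i] = -h_max;
      if (estimate_ga) {
        double dg = obs_ga[i] - sim_ga[i];
        mism = std::max(mism, std::fabs(dg));
        ga[i] += a * dg;
      }
      if (estimate_gs) {
        double dg = obs_gs[i] - sim_gs[i];
        mism = std::max(mism, std::fabs(dg));
        gs[i] += a * dg;
      }
      for (int j = i + 1; j < N; ++j) {
        double dJ = obs_J(i, j) - sim_J(i, j);
        mism = std::max(mism, std::fabs(dJ));
        J(i, j) += a * dJ;
        J(j, i) = J(i, j);
      }
    }
    trace[t] = mism;

    if (t >= avg_start) {
      ++n_avg;
      for (int i = 0; i < N; ++i) {
        h_acc[i] += h[i];
        ga_acc[i] += ga[i];
        gs_acc[i] += gs[i];
        for (int j = i + 1; j < N; ++j) J_acc(i, j) += J(i, j);
      }
    }
  }

  NumericVector h_out(N), ga_out(N), gs_out(N);
  NumericMatrix J_out(N, N);
  for (int i = 0; i < N; ++i) {
    h_out[i] = h_acc[i] / n_avg;
    ga_out[i] = ga_acc[i] / n_avg;
    gs_out[i] = gs_acc[i] / n_avg;
    for (int j = i + 1; j < N; ++j) {
      J_out(i, j) = J_acc(i, j) / n_avg;
      J_out(j, i) = J_out(i, j);
    }
  }

  return List::create(_["h"] = h_out, _["J"] = J_out,
                      _["g_a"] = ga_out, _["g_s"] = gs_out,
                      _["trace"] = trace,
                      _["sim_h"] = sim_h, _["sim_J"] = sim_J,
                      _["sim_ga"] = sim_ga, _["sim_gs"] = sim_gs);
}
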