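#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Gillespie direct-method SSA over a mass-action-monomial network.
// Propensity of reaction j: k[j] * prod_i state[f_species[j][i]] ^ f_exp[j][i].
// Uses R's RNG (caller seeds with set.seed) so trajectories are reproducible.
//
// Returns final state at t_end (last-event state carried forward) and, when
// record = true, the full event history (times, states after each event,
// including the initial state at t = 0).
// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(IntegerMatrix stoich,
             NumericVector k,
             List f_species,
             List f_exp,
             NumericVector state0,
             double t_end,
             bool record,
             double max_events) {
  const int n_species = stoich.nrow();
  const int n_rxn = stoich.ncol();

  std::vector<std::vector<int> > fs(n_rxn), fe(n_rxn);
  for (int j = 0; j < n_rxn; ++j) {
    IntegerVector s = f_species[j], e = f_exp[j];
    fs[j].assign(s.begin(), s.end());
    fe[j].assign(e.begin(), e.end());
    for (size_t i = 0; i < fs[j].size(); ++i) fs[j][i] -= 1;  // 1- to 0-based
  }

  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> a(n_rxn);
  std::vector<double> times;
  std::vector<double> states;
  double t = 0.0;
  double n_events = 0.0;

  if (record) {
    times.push_back(0.0);
    states.insert(states.end(), x.begin(), x.end());
  }

  RNGScope scope;
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < n_rxn; ++j) {
      double aj = k[j];
      for (size_t i = 0; i < fs[j].size(); ++i) {
        double v = x[fs[j][i]];
        int ex = fe[j][i];
        for (int q = 0; q < ex; ++q) aj *= v;
      }
      if (!std::isfinite(aj) || aj < 0.0) {
        stop("non-finite or negative propensity in reaction %d", j + 1);
      }
      a[j] = aj;
      a0 += aj;
    }
    if (a0 <= 0.0) break;  // absorbing state

    double tau = -std::log(unif_rand()) / a0;
    if (t + tau > t_end) break;
    t += tau;

    double r = unif_rand() * a0;
    int j = 0;
    double cum = a[0];
    while (r > cum && j < n_rxn - 1) cum += a[++j];

    for (int i = 0; i < n_species; ++i) x[i] += stoich(i, j);

    n_events += 1.0;
    if (record) {
      times.push_back(t);
      states.insert(states.end(), x.begin(), x.end());
    }
    if (n_events >= max_events) {
      stop("SSA exceeded max_events (%.0f) before t_end; "
           "raise max_events or shorten the horizon", max_events);
    }
  }

  NumericVector final_state(x.begin(), x.end());
  List out = List::create(_["final"] = final_state,
                          _["n_events"] = n_events,
                          _["t_end"] = t_end);
  if (record) {
    int n_t = times.size();
    NumericMatrix sm(n_species, n_t);
    for (int c = 0; c < n_t; ++c)
      for (int i = 0; i < n_species; ++i)
        sm(i, c) = states[(size_t)c * n_species + i];
    out["times"] = NumericVector(times.begin(), times.end());
    out["states"] = sm;
  }
  return out;
}
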