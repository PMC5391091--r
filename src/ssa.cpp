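#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a mass-action
// network with at most two reactants and two products per reaction.
// Propensity of reaction j: c[j] * x[r1[j]] * (r2[j] >= 0 ? x[r2[j]] : 1).
// Bimolecular rate constants must already be scaled to propensity units
// (per molecule pair per second); external concentrations (ligand) are
// folded into c.  Uses R's RNG, so trajectories are reproducible via
// set.seed().  Inputs are copied into plain arrays: the loop runs ~1e7-1e8
// events per second, which the heavy parameter regimes need.
//
// Returns species counts sampled on the regular grid k*sample_dt: the
// state recorded at each sample time is the state just before the first
// event after it.

// [[Rcpp::export]]
IntegerMatrix ssa_run(IntegerVector x0, NumericVector c_in,
                      IntegerVector r1_in, IntegerVector r2_in,
                      IntegerVector p1_in, IntegerVector p2_in,
                      double t_end, double sample_dt) {
  const int ns = x0.size();
  const int nr = c_in.size();
  const int nsamp = (int)std::floor(t_end / sample_dt) + 1;

  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];
  std::vector<double> c(c_in.begin(), c_in.end());
  std::vector<int> r1(r1_in.begin(), r1_in.end());
  std::vector<int> r2(r2_in.begin(), r2_in.end());
  std::vector<int> p1(p1_in.begin(), p1_in.end());
  std::vector<int> p2(p2_in.begin(), p2_in.end());

  // dependency graph: which reactions' propensities touch species i
  std::vector<std::vector<int>> dep(ns);
  for (int j = 0; j < nr; ++j) {
    dep[r1[j]].push_back(j);
    if (r2[j] >= 0 && r2[j] != r1[j]) dep[r2[j]].push_back(j);
  }
  // reactions whose propensity may change after firing reaction j
  std::vector<std::vector<int>> affects(nr);
  for (int j = 0; j < nr; ++j) {
    std::vector<int> s;
    s.push_back(r1[j]);
    if (r2[j] >= 0) s.push_back(r2[j]);
    s.push_back(p1[j]);
    if (p2[j] >= 0) s.push_back(p2[j]);
    std::sort(s.begin(), s.end());
    s.erase(std::unique(s.begin(), s.end()), s.end());
    std::vector<int> ks;
    for (int sidx : s)
      for (int k : dep[sidx]) ks.push_back(k);
    std::sort(ks.begin(), ks.end());
    ks.erase(std::unique(ks.begin(), ks.end()), ks.end());
    affects[j] = ks;
  }

  std::vector<double> a(nr);
  auto prop = [&](int j) {
    double v = c[j] * x[r1[j]];
    if (r2[j] >= 0) v *= x[r2[j]];
    return v;
  };
  double atot = 0.0;
  for (int j = 0; j < nr; ++j) { a[j] = prop(j); atot += a[j]; }

  IntegerMatrix out(nsamp, ns);
  RNGScope scope;

  double t = 0.0;
  double t_next_sample = 0.0;
  int isamp = 0;
  long long steps_since_refresh = 0;
  const long long refresh_every = 1000000;  // guard against drift in atot

  while (true) {
    if (atot <= 0.0) {
      // absorbing state: remaining samples all equal the current state
      while (isamp < nsamp) {
        for (int i = 0; i < ns; ++i) out(isamp, i) = (int)x[i];
        ++isamp;
        }
      break;
    }
    double tnext = t - std::log(unif_rand()) / atot;
    if (tnext >= t_next_sample) {
      while (isamp < nsamp && t_next_sample <= tnext) {
        for (int i = 0; i < ns; ++i) out(isamp, i) = (int)x[i];
        ++isamp;
        t_next_sample = isamp * sample_dt;
      }
      if (isamp >= nsamp || tnext > t_end) break;
    }
    t = tnext;

    double u = unif_rand() * atot;
    int j = 0;
    double acc = a[0];
    while (u > acc && j < nr - 1) acc += a[++j];

    x[r1[j]] -= 1.0;
    if (r2[j] >= 0) x[r2[j]] -= 1.0;
    x[p1[j]] += 1.0;
    if (p2[j] >= 0) x[p2[j]] += 1.0;

    for (int k : affects[j]) {
      double anew = prop(k);
      atot += anew - a[k];
      a[k] = anew;
    }
    if (++steps_since_refresh >= refresh_every) {
      atot = 0.0;
      for (int k = 0; k < nr; ++k) atot += a[k];
      steps_since_refresh = 0;
    }
  }
  return out;
}
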