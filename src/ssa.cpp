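#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie stochastic simulation core.
//
// Repeatedly draws the waiting time to the next reaction from
// Exponential(a0(x)) with a0 = sum_j a_j(x), picks reaction j with
// probability a_j(x)/a0(x), and applies the stoichiometric update
// x <- x + R_j. The propensity is a_j = k_j * h_j(x) with h_j the
// product over reactant species of choose(x_m, nu_m), so a_j = 0
// whenever any reactant is insufficient and species counts can never
// go negative. Uses R's RNG, so set.seed() on the R side makes runs
// reproducible.
//
// [[Rcpp::export]]
List ssa_core(NumericVector x0, double t_end, IntegerMatrix stoich,
              IntegerMatrix reactant, NumericVector k,
              double max_events) {
  const int m = stoich.nrow();
  const int r = stoich.ncol();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> times;
  std::vector<int> fired;
  // per-reaction (species index, multiplicity) lists
  std::vector<std::vector<std::pair<int, int> > > re(r);
  for (int j = 0; j < r; ++j)
    for (int i = 0; i < m; ++i)
      if (reactant(i, j) > 0) re[j].push_back(std::make_pair(i, reactant(i, j)));
  std::vector<double> a(r);
  double t = 0.0;
  bool frozen = false, truncated = false;
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < r; ++j) {
      double h = 1.0;
      for (size_t q = 0; q < re[j].size(); ++q) {
        const double X = x[re[j][q].first];
        const int nu = re[j][q].second;
        if (X < nu) { h = 0.0; break; }
        for (int s = 0; s < nu; ++s) h *= (X - s) / (s + 1);
      }
      a[j] = k[j] * h;
      a0 += a[j];
    }
    if (a0 <= 0.0) { frozen = true; break; }
    t += R::rexp(1.0 / a0);
    if (t > t_end) break;
    const double u = R::unif_rand() * a0;
    double cum = 0.0;
    int j = 0;
    for (; j < r - 1; ++j) {
      cum += a[j];
      if (u <= cum) break;
    }
    for (int i = 0; i < m; ++i) x[i] += stoich(i, j);
    times.push_back(t);
    fired.push_back(j + 1);
    if ((double)times.size() >= max_events) { truncated = true; break; }
  }
  return List::create(_["times"] = wrap(times), _["reactions"] = wrap(fired),
                      _["frozen"] = frozen, _["truncated"] = truncated,
                      _["state"] = NumericVector(x.begin(), x.end()));
}
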