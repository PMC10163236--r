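#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time chain simulation shared by simulate_markov_chain() and
// kmc_simulate(). Row-wise cumulative probabilities are precomputed once;
// each step draws R in [0,1) and jumps to the first column j with R < S[i,j],
// the cumulative-distribution selection rule. Uses R's RNG so set.seed()
// governs reproducibility.

// [[Rcpp::export]]
IntegerVector chain_simulate_cpp(NumericMatrix T, int n_steps, int start) {
  int n = T.nrow();
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += T(i, j);
      S(i, j) = acc;
    }
    S(i, n - 1) = 1.0; // guard against rounding
  }
  IntegerVector out(n_steps);
  int state = start - 1; // 0-based internally
  out[0] = start;
  for (int t = 1; t < n_steps; ++t) {
    double r = unif_rand();
    int j = 0;
    while (j < n - 1 && r >= S(state, j)) ++j;
    state = j;
    out[t] = state + 1;
  }
  return out;
}

// Sample first-passage times from a start state into an absorbing target set.
// Returns the number of lag steps taken to first hit the target. Used as the
// empirical oracle against the mean-first-passage-time formula.

// [[Rcpp::export]]
NumericVector first_passage_cpp(NumericMatrix T, int start, LogicalVector in_target,
                                int n_passages, double max_steps) {
  int n = T.nrow();
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += T(i, j);
      S(i, j) = acc;
    }
    S(i, n - 1) = 1.0;
  }
  NumericVector out(n_passages);
  for (int p = 0; p < n_passages; ++p) {
    int state = start - 1;
    double steps = 0.0;
    while (steps < max_steps) {
      double r = unif_rand();
      int j = 0;
      while (j < n - 1 && r >= S(state, j)) ++j;
      state = j;
      steps += 1.0;
      if (in_target[state]) break;
    }
    out[p] = steps;
  }
  return out;
}
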