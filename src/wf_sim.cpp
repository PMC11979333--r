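// Wright-Fisher inner loop: mutation (Poisson per generation over all
// gene copies) followed by fitness-proportional resampling of the 2N
// copies (genic selection, no dominance). Codon states are 1..61; the
// mutation lookup tables map (codon, position x alternative-base) to the
// resulting codon (0 = stop), the log-fitness increment, and a mutation
// class used for logging. Uses R's RNG so runs are reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// pop: L x 2N codon states; logw: per-copy log fitness; labels: lineage
// labels (length 0 disables tracking); mu: per-base per-generation rate.
// The 61 x 9 lookup tables index (codon, position x alternative base):
// mut_to gives the target codon (0 = stop), mut_dlogw the log-fitness
// increment, mut_class the mutation class (0 stop, 1 synonymous neutral,
// 2 synonymous selected, 3 nonsynonymous), mut_cum cumulative choice
// probabilities.
// [[Rcpp::export]]
List cpp_wf_evolve(arma::imat pop, arma::vec logw, arma::ivec labels,
                   const int n_gens, const double mu,
                   const arma::imat& mut_to, const arma::mat& mut_dlogw,
                   const arma::imat& mut_class, const arma::mat& mut_cum,
                   const bool stop_lethal, const bool stop_on_coalescence) {
  const int L = pop.n_rows;
  const int n_copies = pop.n_cols;
  const bool track = labels.n_elem > 0;
  arma::ivec mut_counts(4, arma::fill::zeros);
  const double lambda = (double)n_copies * 3.0 * (double)L * mu;
  arma::imat newpop(L, n_copies);
  arma::vec neww(n_copies);
  arma::ivec newlab(track ? n_copies : 0);
  int gens_done = 0;
  bool coalesced = false;

  for (int gen = 0; gen < n_gens; ++gen) {
    // mutation
    int n_mut = (int)R::rpois(lambda);
    for (int m = 0; m < n_mut; ++m) {
      int i = (int)(R::unif_rand() * n_copies); if (i >= n_copies) i = n_copies - 1;
      int j = (int)(R::unif_rand() * L);        if (j >= L) j = L - 1;
      int c = pop(j, i) - 1;
      double u = R::unif_rand();
      int k = 0;
      while (k < 8 && u > mut_cum(c, k)) ++k;
      int to = mut_to(c, k);
      if (to == 0) {                       // mutation creates a stop codon
        mut_counts[0] += 1;
        if (stop_lethal) logw[i] = -arma::datum::inf;
        continue;                          // forbidden: rejected outright
      }
      pop(j, i) = to;
      logw[i] += mut_dlogw(c, k);
      mut_counts[mut_class(c, k)] += 1;
    }
    // selection + drift: resample copies proportional to fitness
    double mx = logw.max();
    if (!std::isfinite(mx)) stop("population extinct: all copies have zero fitness");
    arma::vec w = arma::exp(logw - mx);
    double tot = arma::accu(w);
    if (!(tot > 0)) stop("population extinct: all copies have zero fitness");
    arma::vec cw = arma::cumsum(w) / tot;
    for (int i = 0; i < n_copies; ++i) {
      double u = R::unif_rand();
      int lo = 0, hi = n_copies - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (u <= cw[mid]) hi = mid; else lo = mid + 1;
      }
      newpop.col(i) = pop.col(lo);
      neww[i] = logw[lo] - mx;
      if (track) newlab[i] = labels[lo];
    }
    pop = newpop;
    logw = neww;
    if (track) labels = newlab;
    ++gens_done;
    if (track && stop_on_coalescence) {
      coalesced = true;
      for (int i = 1; i < n_copies; ++i) {
        if (labels[i] != labels[0]) { coalesced = false; break; }
      }
      if (coalesced) break;
    }
  }
  return List::create(_["pop"] = pop, _["logw"] = logw, _["labels"] = labels,
                      _["mut_counts"] = mut_counts, _["gens_done"] = gens_done,
                      _["coalesced"] = coalesced);
}
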