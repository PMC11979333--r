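// Likelihood kernels for MSS codon models.
//
// Transition matrices are formed per branch as P(t) = U diag(exp(d t)) Vt,
// where (U, d, Vt) come from the symmetrized eigendecomposition of the
// scaled reversible generator. Tip codons enter as state indices
// (1..nstate) or 0 for missing (gap/ambiguous) codons, which are
// marginalized. Per-pattern scaling guards against underflow.
//
// The partition-fitness kernel (cpp_fit_partition) exists because the
// genetic-algorithm model search evaluates thousands of candidate rate
// partitions, each requiring a small constrained optimization over the
// shared class rates and one branch-length scaler per gene.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct GeneData {
  arma::imat edge;       // nedge x 2, postorder, 1-based
  arma::imat tipstates;  // ntip x npat, 0 = missing
  arma::vec weights;
  arma::vec blens;       // plug-in branch lengths
  arma::vec theta;       // 6 exchangeabilities (AC AG AT CG CT GT)
  arma::mat pi;          // 3 x 4 position frequencies
  double beta;
  int nnode;
  int root;
};

struct Eigensys {
  arma::mat U, Vt;
  arma::vec d, pi_cod;
};

// ---- pruning core ---------------------------------------------------------

static double prune_ll(const Eigensys& es, const GeneData& g,
                       const arma::vec& blens, arma::rowvec* per_pattern) {
  const int nstate = es.U.n_rows;
  const int ntip = g.tipstates.n_rows;
  const int npat = g.tipstates.n_cols;
  const int nedge = g.edge.n_rows;

  std::vector<arma::mat> partial(g.nnode + 1);
  arma::mat scalelog(g.nnode + 1, npat, arma::fill::zeros);
  std::vector<bool> touched(g.nnode + 1, false);
  arma::mat P(nstate, nstate), C(nstate, npat);

  for (int e = 0; e < nedge; ++e) {
    const int parent = g.edge(e, 0);
    const int child  = g.edge(e, 1);
    const double t = blens[e];
    if (!(t >= 0.0) || !std::isfinite(t))
      stop("non-finite or negative branch length on edge %d", e + 1);
    P = es.U.each_row() % arma::exp(es.d.t() * t);
    P = P * es.Vt;
    if (!P.is_finite())
      stop("non-finite transition probabilities on edge %d", e + 1);
    P.clamp(0.0, arma::datum::inf);

    bool internal_child = child > ntip;
    if (internal_child) {
      C = P * partial[child];
      scalelog.row(parent) += scalelog.row(child);
    } else {
      for (int j = 0; j < npat; ++j) {
        const int s = g.tipstates(child - 1, j);
        if (s == 0) C.col(j).ones();
        else        C.col(j) = P.col(s - 1);
      }
    }
    // underflow guard: tip contributions are bounded by 1, so rescaling
    // is only needed where products accumulate (internal children)
    if (internal_child) {
      arma::rowvec m = arma::max(C, 0);
      m.replace(0.0, 1.0);
      C.each_row() /= m;
      scalelog.row(parent) += arma::log(m);
    }

    if (!touched[parent]) { partial[parent] = C; touched[parent] = true; }
    else                  { partial[parent] %= C; }
  }

  arma::rowvec site_lik = es.pi_cod.t() * partial[g.root];
  double total = 0.0;
  for (int j = 0; j < npat; ++j) {
    double lg = (site_lik[j] > 0.0)
      ? std::log(site_lik[j]) + scalelog(g.root, j)
      : -arma::datum::inf;
    if (per_pattern) (*per_pattern)[j] = lg;
    total += lg * g.weights[j];
  }
  return total;
}

// ---- generator construction ----------------------------------------------

// Build the scaled reversible generator for given theta/pi/alpha/beta and
// return its symmetric eigendecomposition factors.
static Eigensys build_eigen(const arma::imat& transitions,
                            const arma::imat& codon_nt,
                            const arma::vec& theta, const arma::mat& pi,
                            const arma::vec& alpha, const double beta) {
  const int nstate = codon_nt.n_rows;
  arma::mat Q(nstate, nstate, arma::fill::zeros);
  const int nT = transitions.n_rows;
  for (int k = 0; k < nT; ++k) {
    const int from = transitions(k, 0) - 1;
    const int to   = transitions(k, 1) - 1;
    const int pos  = transitions(k, 2) - 1;
    const int nt   = transitions(k, 3) - 1;
    const int ti   = transitions(k, 4) - 1;
    const bool syn = transitions(k, 5) == 1;
    const double mult = syn ? alpha[transitions(k, 6) - 1] : beta;
    Q(from, to) = mult * theta[ti] * pi(pos, nt);
  }
  arma::vec pi_cod(nstate);
  for (int i = 0; i < nstate; ++i) {
    pi_cod[i] = pi(0, codon_nt(i, 0) - 1) * pi(1, codon_nt(i, 1) - 1) *
                pi(2, codon_nt(i, 2) - 1);
  }
  pi_cod /= arma::accu(pi_cod);
  Q.diag() = -arma::sum(Q, 1);
  const double flux = arma::dot(pi_cod, -Q.diag());
  if (!(flux > 0)) stop("degenerate rate matrix: zero substitution flux");
  Q /= (flux / 3.0);   // one branch-length unit = one substitution per nt site

  arma::vec dh = arma::sqrt(arma::clamp(pi_cod, 1e-300, arma::datum::inf));
  arma::mat S = Q;
  S.each_col() %= dh;
  S.each_row() /= dh.t();
  S = 0.5 * (S + S.t());
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, S);
  Eigensys es;
  es.U = evec.each_col() / dh;
  es.Vt = evec.t();
  es.Vt.each_row() %= dh.t();
  es.d = eval;
  es.pi_cod = pi_cod;
  return es;
}

// ---- 1-D maximizer --------------------------------------------------------

// Safeguarded bracket + golden-section maximization of f over x (log scale
// handled by the caller), warm-started at x0.
template <typename F>
static double golden_max(F f, double x0, double step, double lo_bound,
                         double hi_bound, double tol, int max_evals,
                         double* fbest_out) {
  const double gr = 0.6180339887498949;
  auto clampx = [&](double x) { return std::min(std::max(x, lo_bound), hi_bound); };
  double x1 = clampx(x0);
  double f1 = f(x1);
  double lo = clampx(x1 - step), hi = clampx(x1 + step);
  double flo = (lo < x1) ? f(lo) : f1;
  double fhi = (hi > x1) ? f(hi) : f1;
  int used = 3;
  while (flo > f1 && lo > lo_bound && used < max_evals) {
    hi = x1; fhi = f1; x1 = lo; f1 = flo;
    lo = clampx(x1 - (hi - x1) * 2.0);
    flo = f(lo); ++used;
  }
  while (fhi > f1 && hi < hi_bound && used < max_evals) {
    lo = x1; flo = f1; x1 = hi; f1 = fhi;
    hi = clampx(x1 + (x1 - lo) * 2.0);
    fhi = f(hi); ++used;
  }
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double fc1 = f(c1), fc2 = f(c2);
  used += 2;
  while ((b - a) > tol && used < max_evals) {
    if (fc1 >= fc2) { b = c2; c2 = c1; fc2 = fc1; c1 = b - gr * (b - a); fc1 = f(c1); }
    else            { a = c1; c1 = c2; fc1 = fc2; c2 = a + gr * (b - a); fc2 = f(c2); }
    ++used;
  }
  double xb = (fc1 >= fc2) ? c1 : c2;
  double fb = std::max(fc1, fc2);
  if (f1 > fb) { xb = x1; fb = f1; }
  if (fbest_out) *fbest_out = fb;
  return xb;
}

// Quadratic-refinement maximizer for smooth 1-D objectives: symmetric
// triple around the warm start, safeguarded Newton step from the fitted
// parabola, one shrink-and-repeat. Falls back to uphill walking when the
// triple is not concave.
template <typename F>
static double newton1d_max(F f, double x0, double h, double lo, double hi,
                           double tol, int max_evals, double* fbest_out) {
  auto clampx = [&](double x) { return std::min(std::max(x, lo), hi); };
  double xb = clampx(x0);
  double fb = f(xb);
  int used = 1;
  while (used + 3 <= max_evals) {
    double xl = clampx(xb - h), xr = clampx(xb + h);
    double fl = (xl < xb) ? f(xl) : fb;
    double fr = (xr > xb) ? f(xr) : fb;
    used += 2;
    if (fl > fb || fr > fb) {            // not bracketed: walk uphill
      if (fl >= fr) { xb = xl; fb = fl; } else { xb = xr; fb = fr; }
      h *= 2.0;
      continue;
    }
    double denom = fl - 2.0 * fb + fr;
    if (denom < -1e-12) {
      double delta = 0.5 * h * (fl - fr) / denom;
      delta = std::min(std::max(delta, -h), h);
      double xn = clampx(xb + delta);
      double fn = f(xn);
      ++used;
      if (fn >= fb) { xb = xn; fb = fn; }
      if (std::fabs(delta) < tol || h < tol) break;
    } else {
      if (h < tol) break;
    }
    h = std::max(h / 3.0, tol * 0.9);
  }
  if (fbest_out) *fbest_out = fb;
  return xb;
}

// ---- exported wrappers ----------------------------------------------------

// [[Rcpp::export]]
List cpp_phylo_loglik(const arma::mat& U, const arma::vec& d,
                      const arma::mat& Vt, const arma::vec& blens,
                      const arma::imat& edge, const arma::imat& tipstates,
                      const arma::vec& weights, const arma::vec& rootfreq,
                      const int nnode_total, const int root) {
  GeneData g;
  g.edge = edge; g.tipstates = tipstates; g.weights = weights;
  g.blens = blens; g.nnode = nnode_total; g.root = root;
  Eigensys es;
  es.U = U; es.d = d; es.Vt = Vt; es.pi_cod = rootfreq;
  arma::rowvec per_pattern(tipstates.n_cols);
  double total = prune_ll(es, g, blens, &per_pattern);
  return List::create(_["logL"] = total,
                      _["per_pattern"] = NumericVector(per_pattern.begin(),
                                                       per_pattern.end()));
}

static GeneData gene_from_list(const List& gl) {
  GeneData g;
  g.edge = as<arma::imat>(gl["edge"]);
  g.tipstates = as<arma::imat>(gl["tipstates"]);
  g.weights = as<arma::vec>(gl["weights"]);
  g.blens = as<arma::vec>(gl["blens"]);
  g.theta = as<arma::vec>(gl["theta"]);
  g.pi = as<arma::mat>(gl["pi"]);
  g.beta = as<double>(gl["beta"]);
  g.nnode = as<int>(gl["nnode"]);
  g.root = as<int>(gl["root"]);
  return g;
}

// Fit the shared class rates (reference class pinned at 1) and one
// branch-length scaler per gene, holding each gene's theta, pi, beta and
// relative branch lengths at their plug-in values. `cls` assigns each
// synonymous pair to a class in 1..K; class 1 is the reference.
// [[Rcpp::export]]
List cpp_fit_partition(const List& genes, const arma::imat& transitions,
                       const arma::imat& codon_nt, const arma::ivec& cls,
                       const int K, const arma::vec& init_rates,
                       const arma::vec& init_scalers, const int n_rounds,
                       const double rate_tol, const double scaler_tol,
                       const double log_lb, const double log_ub,
                       const bool mean_one, const bool opt_scalers) {
  const int G = genes.size();
  const int D = cls.n_elem;
  std::vector<GeneData> gd(G);
  for (int g = 0; g < G; ++g) gd[g] = gene_from_list(genes[g]);

  arma::vec rates = init_rates;        // length K, rates[0] == 1 (reference)
  arma::vec scalers = init_scalers;    // length G
  std::vector<Eigensys> eig(G);
  long evals = 0;

  arma::vec alpha(D);
  auto refresh_eigens = [&]() {
    for (int i = 0; i < D; ++i) alpha[i] = rates[cls[i] - 1];
    // mean-one identification: evaluate on the renormalized rate map, so
    // the pinned reference coordinate is a parameterization, not a bound
    if (mean_one) alpha /= arma::mean(alpha);
    for (int g = 0; g < G; ++g) {
      eig[g] = build_eigen(transitions, codon_nt, gd[g].theta, gd[g].pi,
                           alpha, gd[g].beta);
    }
  };
  auto total_ll_current = [&]() {
    double ll = 0.0;
    for (int g = 0; g < G; ++g) {
      ll += prune_ll(eig[g], gd[g], gd[g].blens * scalers[g], nullptr);
      ++evals;
    }
    return ll;
  };

  refresh_eigens();
  double ll = total_ll_current();

  for (int round = 0; round < n_rounds; ++round) {
    // class rates, one at a time (reference class stays at 1)
    for (int k = 1; k < K; ++k) {
      auto f = [&](double lr) {
        rates[k] = std::exp(lr);
        refresh_eigens();
        return total_ll_current();
      };
      double best;
      double lr = newton1d_max(f, std::log(rates[k]), 0.25, log_lb, log_ub,
                               rate_tol, 9, &best);
      rates[k] = std::exp(lr);
    }
    refresh_eigens();
    if (!opt_scalers) {
      double ll_new = total_ll_current();
      double gain = ll_new - ll;
      ll = ll_new;
      if (round > 0 && gain < 1e-3) break;
      continue;
    }
    // per-gene branch-length scalers (eigens fixed)
    for (int g = 0; g < G; ++g) {
      auto f = [&](double ls) {
        ++evals;
        return prune_ll(eig[g], gd[g], gd[g].blens * std::exp(ls), nullptr);
      };
      double best;
      double ls = golden_max(f, std::log(scalers[g]), 0.15, std::log(0.01),
                             std::log(100.0), scaler_tol, 40, &best);
      scalers[g] = std::exp(ls);
    }
    double ll_new = total_ll_current();
    double gain = ll_new - ll;
    ll = ll_new;
    if (round > 0 && gain < 1e-3) break;
  }

  return List::create(_["logL"] = ll, _["rates"] = rates,
                      _["scalers"] = scalers, _["evals"] = (double)evals);
}

// One-shot objective for the R-level optimizers: build the scaled
// generator for (theta, pi, alpha, beta), eigendecompose, and run the
// pruning pass with the given branch lengths.
// [[Rcpp::export]]
double cpp_model_loglik(const arma::imat& edge, const arma::imat& tipstates,
                        const arma::vec& weights, const int nnode,
                        const int root, const arma::imat& transitions,
                        const arma::imat& codon_nt, const arma::vec& theta,
                        const arma::mat& pi, const arma::vec& alpha,
                        const double beta, const arma::vec& blens) {
  GeneData g;
  g.edge = edge; g.tipstates = tipstates; g.weights = weights;
  g.blens = blens; g.nnode = nnode; g.root = root;
  Eigensys es = build_eigen(transitions, codon_nt, theta, pi, alpha, beta);
  return prune_ll(es, g, blens, nullptr);
}

// Total log-likelihood for fixed shared rates and scalers (used for the
// null model and for validation paths).
// [[Rcpp::export]]
double cpp_partition_loglik(const List& genes, const arma::imat& transitions,
                            const arma::imat& codon_nt, const arma::ivec& cls,
                            const arma::vec& rates, const arma::vec& scalers) {
  const int G = genes.size();
  const int D = cls.n_elem;
  arma::vec alpha(D);
  for (int i = 0; i < D; ++i) alpha[i] = rates[cls[i] - 1];
  double ll = 0.0;
  for (int g = 0; g < G; ++g) {
    GeneData gd = gene_from_list(genes[g]);
    Eigensys es = build_eigen(transitions, codon_nt, gd.theta, gd.pi, alpha,
                              gd.beta);
    ll += prune_ll(es, gd, gd.blens * scalers[g], nullptr);
  }
  return ll;
}
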