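---
title: "Multiclass synonymous substitution models: methods and design"
author: "mssmodels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiclass synonymous substitution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Standard codon substitution models of the Muse–Gaut (MG94) family assume
that all synonymous exchanges proceed at a single rate. Selection on codon
usage — driven by translational efficiency, mRNA structure, or other
forces — violates this assumption: synonymous codon pairs differ in how
freely they are exchanged over evolutionary time. Multiclass synonymous
substitution (MSS) models relax the assumption by giving classes of
synonymous codon pairs their own relative rates, estimated from
codon-aware alignments by phylogenetic maximum likelihood while
controlling for the usual confounders (phylogeny, nucleotide substitution
biases, unequal codon frequencies).

# The substitution model

The state space is the 61 sense codons of the universal genetic code.
The instantaneous rate from sense codon $x$ to sense codon $y$ is

* $\alpha_{xy}\,\theta_{nm}\,\pi_{p,m}$ for a one-step synonymous change,
* $\beta\,\theta_{nm}\,\pi_{p,m}$ for a one-step nonsynonymous change,
* $0$ when $x$ and $y$ differ at more than one nucleotide position,

where $n \to m$ is the nucleotide exchange at codon position $p$,
$\theta$ are the six symmetric GTR-style nucleotide exchangeabilities
with $\theta_{AG} = 1$ as the identifiability anchor (only products of
rates and times are estimable), and $\pi_{p,m}$ is the equilibrium
frequency of the target nucleotide at position $p$. The stationary
distribution is the product measure of the position frequencies
restricted to sense codons, the process is time-reversible, and the
generator is rescaled so that one unit of branch length equals one
expected substitution per *nucleotide* site (the per-codon flux is 3),
matching how tree lengths are conventionally reported for these data.

There are 67 unordered one-step synonymous pairs in the universal code
(`enumerate_syn_pairs()`), spanning 18 amino acids; 9 amino acids
contribute more than one pair. The model hierarchy is:

| model        | synonymous rates                  | extra parameters |
|--------------|-----------------------------------|------------------|
| MG94         | $\alpha \equiv 1$                 | 0                |
| a priori     | one rate per predefined class, reference class fixed at 1 | $K-1$ |
| SynREV       | one rate per amino acid           | 17 (18 rates, mean constrained) |
| SynREVCodon  | one rate per codon pair           | 66 (67 rates, mean constrained) |

For SynREV and SynREVCodon the mean of the 67 pair-level rates is
constrained to 1, so $\beta$ retains its interpretation as the gene-wide
$dN/dS$ ($\omega$). For a priori partitions the reference class is pinned
at rate 1 and $\omega$ is measured relative to that neutral rate. A
well-known bookkeeping wrinkle: SynREVCodon has 66 identifiable relative
rates, while the conventional likelihood-ratio test against MG94 is
quoted with 67 degrees of freedom. Records carry both numbers
(`n_free_alpha` and `df_printed`); `lrt()` defaults to the conventional
df (17 for SynREV, 67 for SynREVCodon).

## Equilibrium frequencies: CF3x4

Position-specific nucleotide frequencies are estimated by the corrected
F3x4 (CF3x4) estimator: the raw per-position frequencies are biased
because stop codons are excluded from the state space, so we solve (by
9-parameter least squares on softmax-parameterized rows) for the
frequency table whose product measure, conditioned on sense codons,
reproduces the observed per-position frequencies. With a stop-free code
the correction is the identity. Least squares was chosen over a
likelihood criterion for the correction objective; at the sample sizes
where the two differ materially the frequencies are too noisy to matter
either way. Frequencies are estimated once per alignment and held fixed
during optimization, as is standard for this model family.

# Likelihood machinery

`log_likelihood()` implements Felsenstein pruning over the 61-state
space. Because the process is reversible, the generator is symmetrized
by the stationary distribution and eigendecomposed once per parameter
value; each branch then needs one matrix product to form
$P(t) = U e^{\Lambda t} V^{T}$. Site patterns are compressed (identical
columns evaluated once; results are identical to uncompressed
evaluation, which the test suite checks by duplicating columns). Codons
containing gaps or ambiguity characters are treated as fully missing and
marginalized, so adding an all-gap sequence leaves the likelihood
unchanged. Per-pattern rescaling guards against underflow where partial
likelihoods accumulate. The heavy kernels live in C++ (RcppArmadillo),
as is usual for phylogenetic packages; the R-level path
(`q_eigen()` + pruning) and the single-call C++ objective are checked
against each other and against brute-force state enumeration on
three-taxon toys.

`simulate_alignment()` draws root codons from the stationary
distribution and child states from $P(t)$ down the tree; fixed seeds
give bitwise-identical output.

# Fitting

`fit_model()` optimizes, in log space with box constraints
($[10^{-6}, 100]$ for rates, $[10^{-8}, 10]$ for branch lengths), the
branch lengths, the five free exchangeabilities, $\beta$, and whatever
synonymous rates the specification requires. Starting values come from
a nucleotide-level GTR fit (phangorn), followed by a cheap tree-scaler +
$\beta$ pre-stage that typically cuts the main quasi-Newton run to a
third of its cold-start iterations; non-convergence triggers jittered
restarts (up to 3 starts) and is flagged in the record, never silent.

Three profiles trade thoroughness for speed:

* `"full"` — everything re-optimized (the default; used for $\omega$
  estimation and anywhere an honest MG94 maximum is needed);
* `"fast"` — MG94 only: branch lengths and exchangeabilities are taken
  from the nucleotide GTR stage and only a tree scaler and $\beta$ are
  re-optimized under the codon likelihood. This is the plug-in provider
  for large model searches, where only the *relative* fit of candidate
  rate maps matters and all candidates share the same plug-ins;
* `"plugin"` — MSS fits on top of a frozen MG94 fit: class rates,
  $\beta$ and one tree scaler are optimized by coordinate descent whose
  first evaluation coincides with the MG94 plug-in itself, which makes
  the nesting monotonicity MG94 $\subseteq$ SynREV $\subseteq$
  SynREVCodon hold by construction up to optimizer tolerance.

`joint_fit()` implements the fully shared model (FSM): one set of
synonymous rates maximizing the summed likelihood over $G$ genes, with
each gene's exchangeabilities, frequencies, $\omega$ and *relative*
branch lengths frozen at its own MG94 estimates and one free
multiplicative branch-length scaler per gene. The mean-one constraint is
imposed by renormalizing the candidate rate map inside the objective, so
the pinned reference coordinate is a parameterization rather than a
restriction. The record reports the LRT against the MG94 baseline (which
is exactly the plug-in fit itself) and the AIC improvement per
alignment, counting the shared rates plus the per-gene scalers as the
added parameters.

# The genetic-algorithm search

`ga_search()` learns the partition of the 67 pairs into $M$ rate classes
with a CHC-style genetic algorithm. A partition is encoded by a
67-dimensional class vector; to remove label redundancy every vector is
kept in canonical, class-sorted form (the first occurrence of class 0
precedes the first occurrence of class 1, and so on), and every distinct
canonical vector is fitted exactly once (a cache serves re-encounters).

The five steps: (1) fit MG94 per gene and freeze branch lengths and
nucleotide rates at those estimates for the whole search; (2) draw P
unique random canonical vectors and score each by BIC summed over genes,
with sample size the total number of characters (sequences x sites;
nucleotide sites by default, switchable to codons); (3) create P
offspring by free recombination — each element from either of two random
parents with probability 1/2 — and keep the P most fit of parents plus
offspring; (4) when the relative fitness range falls below `f_rel` or no
new models have entered the population for `f_stagnant` generations,
mutagenize every individual except the most fit one (each element
changed with probability `mu`); (5) stop after `g_conv` consecutive
generations without a BIC improvement of at least `delta_bic`. Defaults:
P = 32, `f_rel` = 1e-6, `f_stagnant` = 25, `mu` = 0.20, `delta_bic` =
0.01, `g_conv` = 100.

Because branch lengths and nucleotide rates are frozen in step 1, the
fitness evaluation optimizes only the $M-1$ free class rates (the class
containing the first pair is the reference, pinned at 1 — a cosmetic
choice, since reporting uses rank-based labels). Freezing the per-gene
$\omega$ at its MG94 estimate as well keeps the search tractable and
mirrors the joint fitter's plug-in philosophy. Note that the generator
is always renormalized to unit expected substitution rate, so candidate
rate maps cannot trade off against overall branch length; this is what
makes the frozen-branch-length fitness well behaved.

`model_average()` turns the full set of evaluated models into per-pair
category supports: each model receives weight
$\exp((\min \mathrm{BIC} - \mathrm{BIC}_m)/2)$, normalized; within a
model the class rates are ranked, smallest labeled SELECTED, largest
NEUTRAL, intermediates INT 1, INT 2, ...; the weights accrue per pair
per category. An assignment is ambiguous when no category reaches 0.90
of the total weight. `classification_metrics()` scores an assignment
against a known truth by the 2x2 selected/neutral table (each pair goes
to whichever of the two categories has more support), the Matthews
correlation coefficient, and a two-sided Fisher exact test.

# The forward Wright–Fisher simulator

The inference stack assumes a reversible Markov process with symmetric
synonymous rates. Directional selection on codon usage violates that
assumption — the waiting time to a favored codon is shorter than the
reverse — so model validation uses data from an explicitly non-reversible
forward simulator (`run_simulation()`).

A diploid population of N individuals (2N gene copies, single locus, no
recombination) evolves one generation at a time: Poisson mutation with
mean $3 L \mu$ per copy (uniform over sites and the three alternative
bases unless a bias matrix is supplied), then resampling of all 2N
copies with probability proportional to multiplicative fitness (genic
selection — "no dominance" implemented exactly for small s).
Per-amino-acid preference schemes partition codons into one or two
classes: within-class synonymous changes are neutral, cross-class
changes carry $\pm s_{syn}$ by direction, every nonsynonymous change
carries $s_{nonsyn}$, and mutations creating stops are lethal (carrier
fitness 0) or, optionally, rejected outright. Defaults follow the
validation design: N = 500, L = 300 codons, $\mu = 1.6\times10^{-5}$ per
base per generation, $2Ns_{nonsyn} = -10$.

A run executes two burn-ins — a fixed $200N$ generations to reach
mutation–selection–drift equilibrium, then however long it takes for all
2N copies to descend from a single copy present at the first burn-in's
end (tracked by lineage labels) — followed by a split phase with 10
population-splitting events (each split duplicates the parent population
at size N) and final sampling of one random gene copy per terminal
population. The default split schedule spaces the splits evenly along
the ancestral lineage so that the 11-tip ladder has depth 10,000 and
total length 64,000 generations (including the pre-first-split stem);
the exact timings are a configurable input, since the canonical schedule
is a supplementary detail that varies between studies.

Substitutions are logged per edge of the true population tree by
comparing consensus sequences at the flanking events (the sampled copy
itself at the tips) and classified per synonymous pair; multi-nucleotide
codon differences are tallied separately rather than decomposed.
"Effective synonymous sites" are defined as the sum over nucleotide
sites of the fraction of their one-step mutations that are synonymous
and within-neutral-class, evaluated on the founder sequence at the start
of the split phase; under that definition a neutral run's expected
substitutions per effective synonymous site equal $\mu \times$ (total
tree length in generations) $\approx 1.02$ at the default parameters,
consistent with the order-of-magnitude figure (~1.7) quoted for this
design, whose printed value depends on an unpublished site-counting
convention. The package reports the fraction-based definition and makes
no attempt to reverse-engineer the printed one.

Two design points matter when running the simulator at reduced N (as the
test suite does, for runtime):

* *Burn-in length.* The time for codon usage to equilibrate is governed
  by the favored-direction fixation flux, which at fixed $2Ns$ is nearly
  independent of N (~20k generations at these rates). At N = 500 the
  default $200N$ burn-in comfortably exceeds it; at N = 50 it does not,
  so scaled-down runs either lengthen `burnin1_factor` or seed the
  ancestor from `equilibrium_ancestor_freqs()`, the low-mutation-limit
  stationary frequencies (disfavored codons down-weighted by
  $e^{-2\cdot 2Ns}$). The latter emulates the original design, where
  ancestors are drawn from real gene frequencies that already carry
  codon-usage bias.
* *Scheme observability.* The built-in 25-selected / 42-neutral scheme
  (`default_selection_scheme()`) disfavors a single codon per split
  amino acid. This is deliberate: if a disfavored class contained two
  exchangeable codons, the pair between them would be "neutral" by
  construction yet effectively unobservable once selection has purged
  both codons, and no method could classify it from sequence data. With
  single-codon disfavored classes every neutral pair lies within the
  common, favored class and stays informative.

# Covariate operators

Two independent covariates of selection on codon usage are supported.
Per-pair synonymous SNP densities: within each gene the SNP count of a
pair divided by the count of its amino acid, then a plain (unweighted)
mean across genes. tRNA decoding pools: per-anticodon abundances
(counts per million; tRNA genes are of near-constant length, so no
length normalization) are expanded additively — inosine-modified
wobble-A anticodons (Ala, Pro, Arg, Ser, Leu, Val, Ile, Thr families)
add their abundance to the synonymous A- and C-ending codon pools;
queuosine-modified wobble-G anticodons of His/Asp/Asn/Tyr add theirs to
the cognate U-ending codons; the six codons still lacking a decoder
(UUU, AGU, UGU, CGG, GGG, GGU) are assigned the pool of their
wobble-rule partner (UUC, AGC, UGC, CGA, GGA, GGC). The per-pair
covariate is the larger pool over the smaller (ratio >= 1, symmetric,
scale-invariant); pairs with missing pools are dropped rather than
imputed. `rank_correlation()` gives Spearman's rho with a two-sided
p-value over the shared pairs.

# Numerical choices and tolerances

* Transition matrices via symmetric eigendecomposition of the
  pi-symmetrized generator (valid because the model is reversible);
  round-off negatives in $P(t)$ are clamped at 0.
* Rates are optimized in log space, bounds $[10^{-6}, 100]$; a rate
  estimate at the lower bound means "no substitutions of this class
  observed".
* The coordinate-descent kernels use bracketed golden-section and
  safeguarded quadratic (Newton) refinement with warm starts; the GA
  fitness uses looser line-search tolerances (~0.04 on the log scale)
  than the reporting fitters, which is far below the BIC differences
  that drive model selection.
* Discretization of a fitted rate map into a two-class a priori model
  (`make_discretized_model()`) labels the top `floor(f * 67)` pairs
  neutral (10 at f = 0.15), with ties broken by stable pair index.
* The stable pair order is lexicographic by (amino acid, codon1,
  codon2); the canonical class-vector form makes partition encodings
  unique and cacheable.
* Degenerate inputs: empty alignments, frequency tables with zero rows,
  all-zero generators, extinct simulated populations, and infeasible
  split schedules all raise immediate errors naming the offending input.

# What the tests do and do not show

The test suite builds all data in code: parametric simulations from the
package's own models (which is circular for *model* adequacy but exact
for *implementation* correctness, and is paired with brute-force oracles
for the likelihood, matrix construction, canonicalization, and the
population-genetic kernel) and forward simulations that are genuinely
misspecified relative to the inference model (non-reversible,
directional selection). Scaled-down study sizes are stated where used:
null-calibration runs use 25 replicate sets of 8 genes x 300 codons x 11
taxa with a small search budget (population 8, five generations);
forward-simulation recovery uses 20 genes at N = 50 with the equilibrium
ancestor seeding described above and a search budget of 1,400 distinct
models (`max_models`, a hard cap on fitness evaluations that makes the
search cost predictable); the omega-bias experiment uses 11-taxon
templates with 300-600 codons and tens of replicates per cell.

One statistical property of the search deserves note: on data simulated
under the null (rate-constant) model, an adaptive partition search can
always harvest some sampling noise — the best two-class split of 67
pair-level scores gains roughly 20 units of doubled log-likelihood
regardless of data volume, while the BIC penalty for its one extra
parameter is only around 11. A sufficiently exhaustive search would
therefore always report a nominal BIC improvement on null data; the
bounded searches used in practice (and in the tests) recover little of
this quantity, which is why the null calibration holds. The same effect
makes clean plug-ins matter: any systematic misfit in the frozen
branch lengths or exchangeabilities is replicated across genes and
becomes an easily harvested, spurious rate-class signal, which is why
the fast MG94 profile re-optimizes the exchangeabilities under the
codon likelihood rather than keeping nucleotide-level estimates. Real data differ in ways the generator
does not emulate: indels and alignment error, site-to-site and
branch-to-branch rate variation, context-dependent mutation, CpG
effects, and recombination within genes. Passing tests certify the
machinery and the qualitative phenomena (rate-class recovery, omega
bias under misspecification), not the biological adequacy of any model.

# Known limitations

* No site-to-site rate variation (no Gamma categories), no branch-site
  models, no heterotachy.
* Multi-nucleotide instantaneous changes are excluded by construction.
* Codon frequency estimators other than F3x4/CF3x4 (F1x4, F61) are not
  provided.
* The GA searches a fixed number of classes M; it does not select M.
* IUPAC ambiguity in tip codons is treated as fully missing rather than
  partially resolved.
* The simulator models a single locus without recombination or
  demographic change beyond the split schedule.
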