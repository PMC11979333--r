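#' @useDynLib mssmodels, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' @noRd
#' Precompute the pruning inputs for one gene: postorder edge list, tip
#' codon states (0 = missing), and compressed site patterns with weights.
prep_gene <- function(aln, tree, code = genetic_code_table()) {
  mach <- codon_machinery(code)
  tree <- match_tree_alignment(read_tree(tree), aln)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  states <- matrix(0L, ntip, aln$n_codons)
  for (i in seq_len(ntip)) {
    cod <- codon_split(aln$seqs[[tree$tip.label[i]]])
    s <- match(cod, mach$sense)
    s[is.na(s)] <- 0L
    states[i, ] <- s
  }
  key <- apply(states, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  pattern_index <- match(key, key[uniq])
  list(tree = tree, edge = tree$edge, blens = tree$edge.length,
       tipstates = states[, uniq, drop = FALSE],
       weights = as.numeric(tabulate(pattern_index, nbins = sum(uniq))),
       pattern_index = pattern_index, ntip = ntip,
       nnode_total = ntip + tree$Nnode, root = ntip + 1L,
       n_chars = ntip * aln$n_codons * 3L, n_codons = aln$n_codons)
}

#' @noRd
#' Log-likelihood for a prepped gene given an eigensystem and branch
#' lengths (already multiplied by any scaler).
gene_loglik <- function(prep, eig, blens = prep$blens) {
  cpp_phylo_loglik(eig$U, eig$d, eig$Vt, blens, prep$edge, prep$tipstates,
                   prep$weights, eig$pi, prep$nnode_total, prep$root)
}

#' @noRd
#' Optimizer objective: generator construction, eigendecomposition and
#' pruning in a single C++ call.
model_loglik_fast <- function(prep, mach, theta, pi, alpha, beta, blens) {
  cpp_model_loglik(prep$edge, prep$tipstates, prep$weights, prep$nnode_total,
                   prep$root, mach$transitions, mach$codon_nt,
                   as.numeric(theta), pi, alpha, beta, blens)
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over the sense-codon state space, with transition
#' matrices `exp(t Q)` from the scaled reversible generator, the root
#' weighted by the model's stationary distribution, and gap/ambiguous
#' codons marginalized. Site patterns are compressed internally; results
#' are identical to uncompressed evaluation.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` or Newick path; tip labels must cover the
#'   alignment taxa.
#' @param model A `codon_model`.
#' @return List of class `likelihood_result`: `logL` and `per_site_logL`
#'   (vector over codon sites).
#' @export
log_likelihood <- function(aln, tree, model) {
  prep <- prep_gene(aln, tree, code = model$code)
  eig <- q_eigen(model)
  res <- gene_loglik(prep, eig)
  structure(list(logL = res$logL,
                 per_site_logL = res$per_pattern[prep$pattern_index]),
            class = "likelihood_result")
}

#' Simulate a codon alignment along a tree
#'
#' Root codons are drawn from the model's stationary distribution and
#' child states from `exp(t Q)` down the tree. Reproducible under a fixed
#' seed.
#'
#' @param tree A `phylo` (branch lengths in expected substitutions per
#'   nucleotide site) or Newick path.
#' @param model A `codon_model`.
#' @param n_codons Number of codon sites (> 0).
#' @param seed Optional integer seed.
#' @return A `codon_alignment` over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, model, n_codons, seed = NULL) {
  if (length(n_codons) != 1L || is.na(n_codons) || n_codons <= 0) {
    stop("n_codons must be a positive count")
  }
  n_codons <- as.integer(n_codons)
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(read_tree(tree), "postorder")
  ntip <- length(tree$tip.label)
  eig <- q_eigen(model)
  nstate <- length(eig$pi)
  node_states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
  root <- ntip + 1L
  node_states[root, ] <- sample.int(nstate, n_codons, replace = TRUE,
                                    prob = eig$pi)
  for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    P <- (eig$U * rep(exp(eig$d * t), each = nstate)) %*% eig$Vt
    P[P < 0] <- 0
    ps <- node_states[parent, ]
    cs <- integer(n_codons)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(nstate, length(idx), replace = TRUE, prob = P[s, ])
    }
    node_states[child, ] <- cs
  }
  sense <- model$mach$sense
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(sense[node_states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- tree$tip.label
  codon_alignment(seqs, check = FALSE, code = model$code)
}
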