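NUC_PAIRS <- c("AC", "AG", "AT", "CG", "CT", "GT")

.machinery_cache <- new.env(parent = emptyenv())

#' @noRd
#' Precomputed state machinery for a genetic code: sense codons, their
#' amino acids, the synonymous pair table, and the list of one-step
#' transitions (from-state, to-state, position, target nucleotide,
#' nucleotide-pair index, synonymous pair index or NA).
codon_machinery <- function(code = genetic_code_table()) {
  key <- paste0(code$name, "|", paste(code$codon_to_aa, collapse = ""))
  hit <- .machinery_cache[[key]]
  if (!is.null(hit)) return(hit)
  sense <- sense_codons(code)
  nstate <- length(sense)
  aa <- code$codon_to_aa[sense]
  pairs <- enumerate_syn_pairs(code)
  state_of <- stats::setNames(seq_len(nstate), sense)
  chars <- do.call(rbind, strsplit(sense, ""))
  tr <- list()
  for (i in seq_len(nstate)) {
    for (p in 1:3) {
      for (m in NUCS[NUCS != chars[i, p]]) {
        ys <- chars[i, ]; ys[p] <- m
        y <- paste(ys, collapse = "")
        j <- state_of[y]
        if (is.na(j)) next   # stop codon: rate 0, state excluded
        n <- chars[i, p]
        tidx <- match(paste(sort(c(n, m)), collapse = ""), NUC_PAIRS)
        syn <- aa[i] == aa[j]
        pidx <- if (syn) {
          key2 <- paste(sort(c(sense[i], y)), collapse = ":")
          pairs[key2, "index"]
        } else NA_integer_
        tr[[length(tr) + 1L]] <- c(i, j, p, match(m, NUCS), tidx,
                                   as.integer(syn), pidx)
      }
    }
  }
  trm <- do.call(rbind, tr)
  colnames(trm) <- c("from", "to", "pos", "nt", "theta_idx", "syn", "pair_idx")
  out <- list(code = code, sense = sense, nstate = nstate, aa = aa,
              pairs = pairs, D = nrow(pairs), transitions = trm,
              codon_chars = chars,
              codon_nt = matrix(match(chars, NUCS), nrow = nstate))
  .machinery_cache[[key]] <- out
  out
}

#' Estimate position-specific equilibrium nucleotide frequencies
#'
#' `F3x4` returns the raw per-codon-position nucleotide proportions.
#' `CF3x4` corrects them for the exclusion of stop codons: it finds the
#' 3x4 frequency table whose product measure, conditioned on sense codons,
#' reproduces the observed per-position frequencies (9-parameter least
#' squares, solved numerically). With a stop-free code the correction is
#' the identity and `CF3x4 == F3x4`.
#'
#' @param aln A `codon_alignment` (or named character vector).
#' @param method `"CF3x4"` (default) or `"F3x4"`.
#' @param code Genetic code.
#' @return 3x4 matrix (rows = codon positions, columns = A,C,G,T), each
#'   row summing to 1.
#' @export
estimate_frequencies <- function(aln, method = c("CF3x4", "F3x4"),
                                 code = genetic_code_table()) {
  method <- match.arg(method)
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln, check = FALSE)
  counts <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), NUCS))
  for (s in aln$seqs) {
    cod <- codon_split(s)
    cod <- cod[!grepl("[^ACGT]", cod)]
    if (!length(cod)) next
    m <- do.call(rbind, strsplit(cod, ""))
    for (p in 1:3) {
      tb <- table(factor(m[, p], levels = NUCS))
      counts[p, ] <- counts[p, ] + as.numeric(tb)
    }
  }
  if (sum(counts) == 0) stop("alignment contains no unambiguous codons")
  obs <- counts / rowSums(counts)
  if (method == "F3x4") return(obs)
  if (all(code$codon_to_aa != "*")) return(obs)  # no conditioning needed
  cf3x4_correct(obs, code)
}

#' @noRd
#' Position frequencies p such that the product measure over codons,
#' conditioned on sense codons, has per-position marginals equal to obs.
cf3x4_correct <- function(obs, code) {
  mach <- codon_machinery(code)
  nt <- mach$codon_nt   # nstate x 3, nucleotide index per position
  implied <- function(p) {
    f <- p[cbind(1L, nt[, 1])] * p[cbind(2L, nt[, 2])] * p[cbind(3L, nt[, 3])]
    f <- f / sum(f)
    out <- matrix(0, 3, 4)
    for (pos in 1:3) {
      out[pos, ] <- vapply(1:4, function(k) sum(f[nt[, pos] == k]), 0)
    }
    out
  }
  to_p <- function(x) {
    z <- matrix(x, 3, 3)
    e <- cbind(exp(z), 1)
    e / rowSums(e)
  }
  objective <- function(x) sum((implied(to_p(x)) - obs)^2)
  start <- as.vector(log(pmax(obs[, 1:3], 1e-8) / pmax(obs[, 4], 1e-8)))
  fit <- stats::nlminb(start, objective,
                       control = list(iter.max = 500, eval.max = 1000))
  p <- to_p(fit$par)
  dimnames(p) <- dimnames(obs)
  p
}

#' Construct a fully specified MSS codon substitution model
#'
#' Bundles the nucleotide exchangeabilities (GTR-style, `theta["AG"]`
#' anchored at 1), position-specific target-nucleotide frequencies,
#' per-pair synonymous rates alpha, and the shared nonsynonymous rate
#' beta. With all alpha equal to 1 this is the standard MG94xREV model
#' and beta is the gene-wide dN/dS (omega).
#'
#' @param theta Named nonnegative vector over the 6 unordered nucleotide
#'   pairs `c("AC","AG","AT","CG","CT","GT")`; `theta["AG"]` must be 1.
#' @param pi 3x4 matrix of position frequencies (rows sum to 1).
#' @param alpha Either a single value recycled over all pairs (1 =
#'   MG94xREV) or a vector of length D (67 for the universal code), in
#'   stable pair order or named by pair label.
#' @param beta Nonsynonymous relative rate (>= 0).
#' @param constraint How alpha is identified: `"mean_one"` (SynREV-style,
#'   mean over the D pairs equals 1), `"reference_one"` (a designated
#'   class is pinned at 1), or `"fixed"` (alpha taken as given).
#' @param code Genetic code.
#' @return A `codon_model` object.
#' @export
codon_model <- function(theta = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1),
                        pi = matrix(0.25, 3, 4, dimnames = list(paste0("pos", 1:3), NUCS)),
                        alpha = 1, beta = 1,
                        constraint = c("fixed", "mean_one", "reference_one"),
                        code = genetic_code_table()) {
  constraint <- match.arg(constraint)
  mach <- codon_machinery(code)
  theta <- theta[NUC_PAIRS]
  if (any(is.na(theta)) || any(theta < 0)) {
    stop("theta must be nonnegative over the 6 nucleotide pairs AC,AG,AT,CG,CT,GT")
  }
  if (abs(theta[["AG"]] - 1) > 1e-12) stop("identifiability requires theta[AG] == 1")
  pi <- as.matrix(pi)
  if (!all(dim(pi) == c(3, 4)) || any(pi < 0) ||
      any(abs(rowSums(pi) - 1) > 1e-6)) {
    stop("pi must be a 3x4 matrix of frequencies with rows summing to 1")
  }
  dimnames(pi) <- list(paste0("pos", 1:3), NUCS)
  if (length(alpha) == 1L) alpha <- rep(alpha, mach$D)
  if (!is.null(names(alpha))) alpha <- alpha[mach$pairs$pair]
  if (length(alpha) != mach$D || any(is.na(alpha)) || any(alpha < 0)) {
    stop(sprintf("alpha must be nonnegative, of length 1 or %d", mach$D))
  }
  names(alpha) <- mach$pairs$pair
  if (constraint == "mean_one" && abs(mean(alpha) - 1) > 1e-9) {
    stop("mean_one constraint violated: mean(alpha) != 1")
  }
  if (length(beta) != 1L || is.na(beta) || beta < 0) stop("beta must be a single nonnegative value")
  structure(list(code = code, mach = mach, theta = theta, pi = pi,
                 alpha = alpha, beta = beta, constraint = constraint),
            class = "codon_model")
}

#' Build the unscaled instantaneous rate matrix
#'
#' Entry (x, y) for a one-step synonymous change is
#' `alpha[xy] * theta[nm] * pi[pos, m]`; for a one-step nonsynonymous
#' change it is `beta * theta[nm] * pi[pos, m]`; multistep entries are 0
#' and the diagonal makes rows sum to zero.
#'
#' @param model A `codon_model`.
#' @return 61x61 rate matrix over sense codons (dimnames = codons).
#' @export
build_q <- function(model) {
  mach <- model$mach
  tr <- mach$transitions
  mult <- ifelse(tr[, "syn"] == 1L, model$alpha[tr[, "pair_idx"]], model$beta)
  rate <- mult * model$theta[tr[, "theta_idx"]] *
    model$pi[cbind(tr[, "pos"], tr[, "nt"])]
  Q <- matrix(0, mach$nstate, mach$nstate,
              dimnames = list(mach$sense, mach$sense))
  Q[tr[, c("from", "to")]] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a codon model
#'
#' Codon frequencies proportional to the product of the position-specific
#' nucleotide frequencies over sense codons (the MG94 convention); this is
#' the left null vector of the rate matrix and the model is reversible
#' with respect to it.
#'
#' @param model A `codon_model`.
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
stationary_distribution <- function(model) {
  mach <- model$mach
  nt <- mach$codon_nt
  f <- model$pi[cbind(1L, nt[, 1])] * model$pi[cbind(2L, nt[, 2])] *
    model$pi[cbind(3L, nt[, 3])]
  stats::setNames(f / sum(f), mach$sense)
}

#' Scale a rate matrix to per-nucleotide-site branch-length units
#'
#' Divides Q so that the expected number of substitutions per nucleotide
#' site per unit branch length is 1 (the per-codon substitution flux is 3).
#'
#' @param model A `codon_model`.
#' @return List with `Q` (scaled matrix) and `factor` (the divisor:
#'   expected substitutions per codon site per unit time of the unscaled
#'   matrix, divided by 3).
#' @export
scale_q <- function(model) {
  Q <- build_q(model)
  pi_cod <- stationary_distribution(model)
  flux <- sum(pi_cod * (-diag(Q)))
  if (flux <= 0) stop("degenerate rate matrix: zero total substitution flux")
  factor <- flux / 3
  list(Q = Q / factor, factor = factor)
}

#' @noRd
#' Symmetrized eigendecomposition of the scaled generator. Returns the
#' factors needed to form P(t) = U exp(d t) Vt cheaply per branch.
q_eigen <- function(model) {
  sq <- scale_q(model)
  pi_cod <- stationary_distribution(model)
  d_half <- sqrt(pmax(pi_cod, 1e-300))
  S <- sq$Q * (d_half %o% (1 / d_half))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(U = es$vectors / d_half, d = es$values,
       Vt = t(es$vectors) * rep(d_half, each = length(d_half)),
       pi = pi_cod, scale_factor = sq$factor)
}
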