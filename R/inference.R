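#' @noRd
#' Resolve a model specification into a class assignment over the D
#' synonymous pairs. Class 1 always contains pair index 1 (the canonical
#' reference slot); for mean-one models the pin is removed by in-objective
#' renormalization, so it is a parameterization choice, not a restriction.
resolve_spec <- function(spec, mach) {
  D <- mach$D
  if (is.character(spec) && length(spec) == 1L) {
    name <- toupper(spec)
    if (name == "MG94") {
      return(list(name = "MG94", cls = rep(1L, D), K = 1L, n_free = 0L,
                  df_printed = 0L, constraint = "fixed"))
    }
    if (name == "SYNREV") {
      cls <- as.integer(factor(mach$pairs$aa, levels = unique(mach$pairs$aa)))
      return(list(name = "SynREV", cls = cls, K = max(cls),
                  n_free = max(cls) - 1L, df_printed = 17L,
                  constraint = "mean_one"))
    }
    if (name == "SYNREVCODON") {
      return(list(name = "SynREVCodon", cls = seq_len(D), K = D,
                  n_free = D - 1L, df_printed = 67L, constraint = "mean_one"))
    }
    stop(sprintf("unknown model spec '%s'", spec))
  }
  if (inherits(spec, "model_vector") || (is.numeric(spec) && length(spec) == D)) {
    v <- canonicalize_model_vector(spec)
    if (length(v) != D) stop(sprintf("a priori model vector must have length %d", D))
    K <- attr(v, "n_classes")
    return(list(name = sprintf("a_priori_%dclass", K), cls = as.integer(v) + 1L,
                K = K, n_free = K - 1L, df_printed = K - 1L,
                constraint = "reference_one"))
  }
  if (is.list(spec) && identical(spec$type, "fixed_alpha")) {
    alpha <- spec$alpha
    if (!is.null(names(alpha))) alpha <- alpha[mach$pairs$pair]
    if (length(alpha) != D || any(is.na(alpha)) || any(alpha < 0)) {
      stop(sprintf("fixed_alpha requires %d nonnegative rates", D))
    }
    return(list(name = if (!is.null(spec$name)) spec$name else "fixed_alpha",
                cls = rep(1L, D), K = 1L, n_free = 0L, df_printed = 0L,
                constraint = "fixed", alpha_fixed = as.numeric(alpha)))
  }
  stop("spec must be 'MG94', 'SynREV', 'SynREVCodon', a model vector, or list(type='fixed_alpha', alpha=...)")
}

fit_control_defaults <- function(control = list()) {
  defaults <- list(iter_max = 300L, rel_tol = 1e-7, max_restarts = 2L,
                   rate_lb = 1e-6, rate_ub = 100, blen_lb = 1e-8, blen_ub = 10,
                   gtr_maxit = 8L)
  defaults[names(control)] <- control
  defaults
}

#' @noRd
#' Nucleotide-level GTR starting values (branch lengths + exchangeabilities)
#' via phangorn; falls back to the input tree and uniform rates when the
#' nucleotide fit is not applicable (tiny trees, degenerate data).
gtr_init <- function(aln, tree, ctrl) {
  tree <- read_tree(tree)
  tree$edge.length[tree$edge.length <= 0] <- 1e-6
  out <- tryCatch({
    chm <- do.call(rbind, strsplit(aln$seqs[tree$tip.label], ""))
    rownames(chm) <- tree$tip.label
    dat <- phangorn::phyDat(chm, type = "DNA")
    fit0 <- suppressWarnings(phangorn::pml(tree, dat))
    fitg <- suppressWarnings(phangorn::optim.pml(
      fit0, model = "GTR", optEdge = TRUE, rearrangement = "none",
      control = phangorn::pml.control(trace = 0, maxit = ctrl$gtr_maxit)))
    th <- fitg$Q / fitg$Q[2]          # order AC AG AT CG CT GT; anchor AG
    names(th) <- NUC_PAIRS
    tr <- fitg$tree
    tr$edge.length[tr$edge.length < 1e-7] <- 1e-7
    list(tree = tr, theta = pmin(pmax(th, 0.02), 50))
  }, error = function(e) NULL)
  if (is.null(out)) {
    list(tree = tree, theta = stats::setNames(rep(1, 6), NUC_PAIRS))
  } else out
}

#' @noRd
#' Assemble a fit record with mean-one rescaling for reporting.
make_fit_record <- function(spec_info, mach, logL, theta, pi, alpha_raw, beta,
                            tree, scaler, n_params, sample_size, convergence) {
  if (spec_info$constraint == "mean_one") {
    c0 <- mean(alpha_raw)
    alpha <- alpha_raw / c0
    beta_rep <- beta / c0
  } else {
    alpha <- alpha_raw
    beta_rep <- beta
  }
  names(alpha) <- mach$pairs$pair
  structure(list(
    model_name = spec_info$name,
    logL = logL,
    n_params = n_params,
    AIC = -2 * logL + 2 * n_params,
    BIC = -2 * logL + n_params * log(sample_size),
    sample_size = sample_size,
    df_printed = spec_info$df_printed,
    n_free_alpha = spec_info$n_free,
    convergence = convergence,
    estimates = list(theta = theta, pi = pi, alpha = alpha, beta = beta_rep,
                     omega = beta_rep, tree = ape::write.tree(tree),
                     scaler = scaler)),
    class = "fit_record")
}

#' Fit an MSS codon model to one alignment by maximum likelihood
#'
#' Box-constrained quasi-Newton optimization (log-scale `nlminb`) of branch
#' lengths, the five free nucleotide exchangeabilities, the nonsynonymous
#' rate beta and the synonymous class rates required by the model
#' specification. Position frequencies come from CF3x4 and are held fixed.
#' For SynREV/SynREVCodon the rates are reported under the mean-one
#' constraint (so beta is the gene-wide dN/dS, omega); for a-priori
#' partitions the reference class is pinned at 1 and omega is relative to
#' that neutral rate.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` or Newick path.
#' @param spec `"MG94"`, `"SynREV"`, `"SynREVCodon"`, an a-priori class
#'   vector over the 67 pairs (see [canonicalize_model_vector()]), or
#'   `list(type = "fixed_alpha", alpha = <67 rates>)`.
#' @param code Genetic code.
#' @param pi Optional 3x4 position-frequency matrix; default CF3x4 from
#'   the alignment.
#' @param profile `"full"` optimizes everything; `"fast"` (MG94 only) takes
#'   branch lengths and exchangeabilities from a nucleotide-level GTR fit
#'   and optimizes only a tree scaler and beta under the codon model;
#'   `"plugin"` holds theta and relative branch lengths at values from
#'   `plugins` (an MG94 `fit_record`) and optimizes the class rates, beta
#'   and one tree scaler.
#' @param plugins An MG94 `fit_record` (required for `profile = "plugin"`).
#' @param control Optimizer control overrides (`iter_max`, `max_restarts`,
#'   rate bounds).
#' @return A `fit_record` with logL, parameter counts, AIC/BIC (BIC sample
#'   size = sequences x nucleotide sites) and all estimates.
#' @export
fit_model <- function(aln, tree, spec = "MG94", code = genetic_code_table(),
                      pi = NULL, profile = c("full", "fast", "plugin"),
                      plugins = NULL, control = list()) {
  profile <- match.arg(profile)
  ctrl <- fit_control_defaults(control)
  mach <- codon_machinery(code)
  spec_info <- resolve_spec(spec, mach)
  if (is.null(pi)) pi <- estimate_frequencies(aln, "CF3x4", code = code)
  sample_size <- length(aln$taxa) * aln$n_codons * 3L

  if (!is.null(spec_info$alpha_fixed)) {
    return(fit_fixed_alpha(aln, tree, spec_info, mach, pi, ctrl, code,
                           sample_size))
  }
  if (profile == "fast") {
    if (spec_info$name != "MG94") stop("profile 'fast' applies to MG94 only")
    return(fit_mg94_fast(aln, tree, spec_info, mach, pi, ctrl, code,
                         sample_size))
  }
  if (profile == "plugin") {
    if (is.null(plugins) || !inherits(plugins, "fit_record")) {
      stop("profile 'plugin' requires an MG94 fit_record in `plugins`")
    }
    return(fit_plugin(aln, tree, spec_info, mach, pi, ctrl, code, plugins,
                      sample_size))
  }
  fit_full(aln, tree, spec_info, mach, pi, ctrl, code, sample_size)
}

#' @noRd
fit_full <- function(aln, tree, spec_info, mach, pi, ctrl, code, sample_size) {
  init <- gtr_init(aln, read_tree(tree), ctrl)
  prep <- prep_gene(aln, init$tree, code = code)
  nedge <- nrow(prep$edge)
  K <- spec_info$K
  cls <- spec_info$cls
  lrate <- c(log(ctrl$rate_lb), log(ctrl$rate_ub))
  lblen <- c(log(ctrl$blen_lb), log(ctrl$blen_ub))
  fixed_theta <- ctrl$fix_theta          # optional: hold theta constant
  nth <- if (is.null(fixed_theta)) 5L else 0L

  unpack <- function(par) {
    par <- unname(par)
    blens <- exp(par[seq_len(nedge)])
    theta <- if (is.null(fixed_theta)) {
      c(AC = exp(par[nedge + 1]), AG = 1, AT = exp(par[nedge + 2]),
        CG = exp(par[nedge + 3]), CT = exp(par[nedge + 4]),
        GT = exp(par[nedge + 5]))
    } else fixed_theta
    beta <- exp(par[nedge + nth + 1])
    rates <- c(1, exp(par[nedge + nth + 1 + seq_len(K - 1)]))
    list(blens = blens, theta = theta, beta = beta, rates = rates)
  }
  negll <- function(par) {
    p <- unpack(par)
    -model_loglik_fast(prep, mach, p$theta[NUC_PAIRS], pi, p$rates[cls],
                       p$beta, p$blens)
  }
  start <- c(log(pmax(prep$blens, 1e-6)),
             if (is.null(fixed_theta))
               log(init$theta[c("AC", "AT", "CG", "CT", "GT")]),
             log(0.3), rep(0, K - 1))
  lower <- c(rep(lblen[1], nedge), rep(lrate[1], nth + 1 + K - 1))
  upper <- c(rep(lblen[2], nedge), rep(lrate[2], nth + 1 + K - 1))
  # warm start: a cheap tree-scaler + beta pre-stage cuts the main
  # optimization to a fraction of its cold-start iterations
  pre <- tryCatch(stats::nlminb(c(0, log(0.3)), function(q) {
    st <- start
    st[seq_len(nedge)] <- st[seq_len(nedge)] + q[1]
    st[nedge + nth + 1] <- q[2]
    negll(st)
  }, control = list(iter.max = 50)), error = function(e) NULL)
  if (!is.null(pre)) {
    start[seq_len(nedge)] <- start[seq_len(nedge)] + pre$par[1]
    start[nedge + nth + 1] <- pre$par[2]
    start <- pmin(pmax(start, lower), upper)
  }

  best <- NULL
  for (attempt in seq_len(ctrl$max_restarts + 1L)) {
    st <- if (attempt == 1L) start else start + stats::rnorm(length(start), 0, 0.3)
    opt <- tryCatch(
      stats::nlminb(st, negll, lower = lower, upper = upper,
                    control = list(iter.max = ctrl$iter_max,
                                   rel.tol = ctrl$rel_tol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
      best <- opt
    }
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("optimization failed for all starts")
  p <- unpack(best$par)
  tr <- prep$tree
  tr$edge.length <- p$blens
  n_params <- nedge + 5L + 1L + (K - 1L)
  make_fit_record(spec_info, mach, -best$objective, p$theta[NUC_PAIRS], pi,
                  p$rates[cls], p$beta, tr, 1, n_params, sample_size,
                  best$convergence)
}

#' @noRd
#' MG94 with relative branch lengths plugged in from the nucleotide GTR
#' stage; a tree scaler, beta and the exchangeabilities are re-optimized
#' under the codon likelihood (the nucleotide-level theta is systematically
#' off for coding data, which would otherwise leak into every downstream
#' plug-in fit).
fit_mg94_fast <- function(aln, tree, spec_info, mach, pi, ctrl, code,
                          sample_size) {
  init <- gtr_init(aln, read_tree(tree), ctrl)
  prep <- prep_gene(aln, init$tree, code = code)
  alpha <- rep(1, mach$D)
  negll <- function(ls, lb, lth) {
    theta <- c(AC = exp(lth[1]), AG = 1, AT = exp(lth[2]), CG = exp(lth[3]),
               CT = exp(lth[4]), GT = exp(lth[5]))
    -model_loglik_fast(prep, mach, theta, pi, alpha, exp(lb),
                       prep$blens * exp(ls))
  }
  lth <- unname(log(init$theta[c("AC", "AT", "CG", "CT", "GT")]))
  sb <- c(0, log(0.3))
  # staged optimization: (scaler, beta) -> theta -> (scaler, beta); each
  # block is low-dimensional and warm-started, which converges in a small
  # fraction of the joint problem's iterations
  lr <- c(log(ctrl$rate_lb), log(ctrl$rate_ub))
  for (pass in 1:2) {
    o1 <- stats::nlminb(sb, function(q) negll(q[1], q[2], lth),
                        lower = c(log(0.02), lr[1]), upper = c(log(50), lr[2]),
                        control = list(iter.max = 100))
    sb <- unname(o1$par)
    if (pass == 2) break
    o2 <- stats::nlminb(lth, function(q) negll(sb[1], sb[2], q),
                        lower = rep(lr[1], 5), upper = rep(lr[2], 5),
                        control = list(iter.max = 60, rel.tol = 1e-6))
    lth <- unname(o2$par)
  }
  theta <- c(AC = exp(lth[1]), AG = 1, AT = exp(lth[2]), CG = exp(lth[3]),
             CT = exp(lth[4]), GT = exp(lth[5]))
  tr <- prep$tree
  tr$edge.length <- prep$blens * exp(sb[1])
  n_params <- nrow(prep$edge) + 5L + 1L
  make_fit_record(spec_info, mach, -o1$objective, theta[NUC_PAIRS], pi,
                  rep(1, mach$D), exp(sb[2]), tr, 1, n_params, sample_size,
                  o1$convergence)
}

#' @noRd
#' Class rates + beta + one tree scaler, with theta and relative branch
#' lengths held at MG94 plug-in values. Alternates the coordinate-descent
#' rate/scaler kernel with a 1-D beta pass; the first kernel evaluation
#' coincides with the plug-in MG94 fit itself, so the plugin fit can never
#' fall below its MG94 baseline.
fit_plugin <- function(aln, tree, spec_info, mach, pi, ctrl, code, plugins,
                       sample_size) {
  ptree <- read_tree(ape::read.tree(text = plugins$estimates$tree))
  prep <- prep_gene(aln, ptree, code = code)
  theta <- as.numeric(plugins$estimates$theta[NUC_PAIRS])
  K <- spec_info$K
  cls <- spec_info$cls
  mean_one <- spec_info$constraint == "mean_one"
  pg <- list(list(edge = prep$edge, tipstates = prep$tipstates,
                  weights = prep$weights, blens = prep$blens, theta = theta,
                  pi = pi, beta = 1, nnode = prep$nnode_total,
                  root = prep$root))
  beta <- max(plugins$estimates$beta, 1e-5)
  rates <- rep(1, K)
  scaler <- 1
  ll <- -Inf
  n_rounds <- if (is.null(ctrl$plugin_rounds)) 3L else ctrl$plugin_rounds
  for (round in seq_len(n_rounds)) {
    pg[[1]]$beta <- beta
    res <- cpp_fit_partition(pg, mach$transitions, mach$codon_nt,
                             as.integer(cls), as.integer(K), rates, scaler,
                             1L, 5e-3, 1e-3, log(ctrl$rate_lb),
                             log(ctrl$rate_ub), mean_one, TRUE)
    rates <- as.numeric(res$rates)
    scaler <- as.numeric(res$scalers)
    alpha <- rates[cls]
    if (mean_one) alpha <- alpha / mean(alpha)
    bl <- prep$blens * scaler
    ob <- stats::optimize(function(lb) {
      -model_loglik_fast(prep, mach, theta, pi, alpha, exp(lb), bl)
    }, lower = log(ctrl$rate_lb), upper = log(ctrl$rate_ub), tol = 1e-5)
    beta <- exp(ob$minimum)
    ll_new <- -ob$objective
    if (round > 1 && ll_new - ll < 1e-4) { ll <- ll_new; break }
    ll <- ll_new
  }
  alpha <- rates[cls]
  tr <- prep$tree
  tr$edge.length <- prep$blens * scaler
  n_params <- 2L + (K - 1L)
  make_fit_record(spec_info, mach, ll, stats::setNames(theta, NUC_PAIRS), pi,
                  alpha, beta, tr, scaler, n_params, sample_size, 0L)
}

#' @noRd
#' Fixed-alpha (empirical-style) model: optimize branch scaler + theta +
#' beta with the synonymous rate map taken as known constants.
fit_fixed_alpha <- function(aln, tree, spec_info, mach, pi, ctrl, code,
                            sample_size) {
  init <- gtr_init(aln, read_tree(tree), ctrl)
  prep <- prep_gene(aln, init$tree, code = code)
  alpha <- spec_info$alpha_fixed
  negll <- function(par) {
    par <- unname(par)
    theta <- c(AC = exp(par[2]), AG = 1, AT = exp(par[3]), CG = exp(par[4]),
               CT = exp(par[5]), GT = exp(par[6]))
    -model_loglik_fast(prep, mach, theta[NUC_PAIRS], pi, alpha, exp(par[7]),
                       prep$blens * exp(par[1]))
  }
  start <- c(0, log(init$theta[c("AC", "AT", "CG", "CT", "GT")]), log(0.3))
  opt <- stats::nlminb(start, negll,
                       lower = c(log(0.02), rep(log(ctrl$rate_lb), 6)),
                       upper = c(log(50), rep(log(ctrl$rate_ub), 6)),
                       control = list(iter.max = ctrl$iter_max))
  opt$par <- unname(opt$par)
  theta <- c(AC = exp(opt$par[2]), AG = 1, AT = exp(opt$par[3]),
             CG = exp(opt$par[4]), CT = exp(opt$par[5]), GT = exp(opt$par[6]))
  tr <- prep$tree
  tr$edge.length <- prep$blens * exp(opt$par[1])
  make_fit_record(spec_info, mach, -opt$objective, theta[NUC_PAIRS], pi, alpha,
                  exp(opt$par[7]), tr, exp(opt$par[1]), 7L, sample_size,
                  opt$convergence)
}

#' Rebuild a codon model from a fit record
#' @param record A `fit_record`.
#' @param code Genetic code.
#' @return A `codon_model` with the record's theta, pi, alpha and beta.
#' @export
as_codon_model <- function(record, code = genetic_code_table()) {
  est <- record$estimates
  codon_model(theta = unlist(est$theta)[NUC_PAIRS], pi = est$pi,
              alpha = unlist(est$alpha), beta = est$beta, code = code)
}

#' Likelihood ratio test between nested fits
#'
#' The statistic is `2 (logL_alt - logL_null)`, clamped at zero (a richer
#' model can come out marginally below its null within optimizer
#' tolerance; beyond tolerance a warning is raised). The p-value is the
#' upper chi-square tail with `df` degrees of freedom; the default df is
#' the difference of the models' conventional synonymous-rate df (17 for
#' MG94 vs SynREV, 67 for MG94 vs SynREVCodon).
#'
#' @param null,alt `fit_record`s for nested models on the same data.
#' @param df Degrees of freedom; default from the records.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(null, alt, df = NULL) {
  if (is.null(df)) df <- alt$df_printed - null$df_printed
  if (df <= 0) stop("df must be positive (is `alt` the richer model?)")
  stat <- 2 * (alt$logL - null$logL)
  if (stat < -1e-4 * max(1, abs(null$logL))) {
    warning(sprintf("alternative logL below null (%.6g < %.6g); statistic clamped at 0",
                    alt$logL, null$logL))
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' @noRd
#' Build the per-gene plug-in structures consumed by the C++ partition
#' fitter: pruning inputs plus frozen theta/pi/beta/branch lengths from
#' each gene's MG94 fit.
build_plugin_genes <- function(genes, mg94_fits, code) {
  lapply(seq_along(genes), function(i) {
    rec <- mg94_fits[[i]]
    ptree <- read_tree(ape::read.tree(text = rec$estimates$tree))
    prep <- prep_gene(genes[[i]]$aln, ptree, code = code)
    list(edge = prep$edge, tipstates = prep$tipstates, weights = prep$weights,
         blens = prep$blens, theta = as.numeric(rec$estimates$theta[NUC_PAIRS]),
         pi = rec$estimates$pi, beta = rec$estimates$beta,
         nnode = prep$nnode_total, root = prep$root, n_chars = prep$n_chars)
  })
}

#' Joint (fully shared) MSS fit across multiple genes
#'
#' Estimates a single set of synonymous class rates from G genes by
#' maximum likelihood while holding each gene's nucleotide
#' exchangeabilities, position frequencies, omega and relative branch
#' lengths at its MG94 plug-in estimates; each gene receives one free
#' multiplicative branch-length scaler. Reports the LRT against the MG94
#' baseline (the plug-in fits themselves) and the AIC improvement per
#' alignment.
#'
#' @param genes A list of genes (`list(aln=, tree=)` each, e.g. from
#'   [read_filelist()]).
#' @param spec `"SynREV"`, `"SynREVCodon"`, or an a-priori class vector.
#' @param code Genetic code.
#' @param step1 Profile for the per-gene MG94 fits (`"full"` or `"fast"`).
#' @param control Optimizer control overrides.
#' @return A `joint_fit_record`.
#' @export
joint_fit <- function(genes, spec = "SynREV", code = genetic_code_table(),
                      step1 = c("full", "fast"), control = list()) {
  step1 <- match.arg(step1)
  mach <- codon_machinery(code)
  spec_info <- resolve_spec(spec, mach)
  if (spec_info$K < 2L) stop("joint_fit requires a model with at least 2 rate classes")
  keep <- vapply(genes, function(g) {
    v <- validate_for_analysis(g$aln, code = code)
    if (!v$accept) warning(sprintf("gene excluded: %s", paste(v$reasons, collapse = "; ")))
    v$accept
  }, logical(1))
  genes <- genes[keep]
  if (!length(genes)) stop("no genes passed validation")
  G <- length(genes)

  mg94 <- lapply(genes, function(g) {
    fit_model(g$aln, g$tree, "MG94", code = code, profile = step1,
              control = control)
  })
  pg <- build_plugin_genes(genes, mg94, code)
  mean_one <- spec_info$constraint == "mean_one"
  res <- cpp_fit_partition(pg, mach$transitions, mach$codon_nt,
                           spec_info$cls, spec_info$K, rep(1, spec_info$K),
                           rep(1, G), 6L, 1e-5, 1e-5, log(1e-6), log(100),
                           mean_one, TRUE)
  alpha <- res$rates[spec_info$cls]
  if (mean_one) alpha <- alpha / mean(alpha)
  names(alpha) <- mach$pairs$pair
  baseline_logL <- sum(vapply(mg94, `[[`, 0, "logL"))
  test <- list(statistic = max(0, 2 * (res$logL - baseline_logL)),
               df = spec_info$df_printed)
  test$p_value <- stats::pchisq(test$statistic, test$df, lower.tail = FALSE)
  n_extra <- spec_info$n_free + G   # shared rates + per-gene scalers
  delta_aic <- (2 * (res$logL - baseline_logL) - 2 * n_extra) / G
  sample_size <- sum(vapply(pg, `[[`, 0, "n_chars"))
  structure(list(
    model_name = paste0("joint_", spec_info$name),
    alpha = alpha, logL = res$logL, baseline_logL = baseline_logL,
    lrt = test, delta_aic_per_alignment = delta_aic,
    n_free_alpha = spec_info$n_free, sample_size = sample_size,
    per_gene = data.frame(
      gene = seq_len(G),
      scaler = as.numeric(res$scalers),
      omega = vapply(mg94, function(r) r$estimates$omega, 0),
      logL_mg94 = vapply(mg94, `[[`, 0, "logL"))),
    class = "joint_fit_record")
}

#' Discretize a fitted synonymous rate map into a two-class a-priori model
#'
#' The pairs whose rates fall in the top fraction (by value) are labeled
#' neutral and become the reference class (rate pinned at 1); all other
#' pairs share a single estimated rate. Ties are broken by stable pair
#' index. The neutral count is `floor(top_fraction * D)` (at least 1).
#'
#' @param alpha Named or positional vector of D synonymous rates.
#' @param top_fraction Proportion in (0, 1); e.g. 0.15 labels the fastest
#'   15 percent of pairs neutral.
#' @return A canonical `model_vector` with attributes `neutral_pairs`
#'   (indices) and `neutral_class` (its canonical class label).
#' @export
make_discretized_model <- function(alpha, top_fraction = 0.15) {
  if (length(top_fraction) != 1L || is.na(top_fraction) ||
      top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must lie strictly between 0 and 1")
  }
  D <- length(alpha)
  n_top <- max(1L, floor(top_fraction * D))
  ord <- order(-as.numeric(alpha), seq_len(D))   # ties by stable pair index
  neutral <- sort(ord[seq_len(n_top)])
  v <- integer(D)
  v[neutral] <- 1L
  out <- canonicalize_model_vector(v)
  attr(out, "neutral_pairs") <- neutral
  attr(out, "neutral_class") <- as.integer(out[neutral[1]])
  out
}

#' Relative-bias experiment for gene-wide dN/dS estimation
#'
#' Simulates replicate alignments under each template's generating models
#' and refits them with each fitter; reports, per generator-fitter cell,
#' the mean and variance of the relative bias `(omega_hat - omega_true) /
#' omega_true` pooled over templates and replicates, and the severe-bias
#' rate: the share of templates whose true omega falls outside the
#' [2.5%, 97.5%] quantile range of that template's omega estimates.
#'
#' @param templates List of templates, each `list(tree=, n_codons=,
#'   models=)` where `models` is a named list of `codon_model`s keyed by
#'   generator name (e.g. `"MG94"`, `"SynREVCodon"`).
#' @param generators,fitters Character vectors of model names.
#' @param reps Replicates per template-generator cell (>= 2).
#' @param seed Integer seed.
#' @param fit_profile Profile passed to [fit_model()] for MG94 fitters
#'   (`"full"` or `"fast"`); MSS fitters always use the plugin profile on
#'   top of an MG94 fit.
#' @param control Optimizer control overrides.
#' @return List with `table` (data frame of generator, fitter, mean_bias,
#'   var_bias, severe_rate) and `draws` (per-replicate omega estimates).
#' @export
relative_bias_experiment <- function(templates, generators = "MG94",
                                     fitters = "MG94", reps = 10, seed = 1,
                                     fit_profile = "full", control = list()) {
  if (reps < 2) stop("reps must be at least 2")
  draws <- list()
  set.seed(seed)
  sim_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                 length(templates) * length(generators) * reps),
                      nrow = reps)
  cell <- 0L
  for (ti in seq_along(templates)) {
    tmpl <- templates[[ti]]
    for (gen in generators) {
      cell <- cell + 1L
      model <- tmpl$models[[gen]]
      if (is.null(model)) stop(sprintf("template %d has no generating model '%s'", ti, gen))
      omega_true <- model$beta / mean(model$alpha)
      for (r in seq_len(reps)) {
        sim <- simulate_alignment(tmpl$tree, model, tmpl$n_codons,
                                  seed = sim_seeds[r, cell])
        mg94_fit <- NULL
        for (fit_name in fitters) {
          if (toupper(fit_name) == "MG94") {
            rec <- fit_model(sim, tmpl$tree, "MG94", profile = fit_profile,
                             control = control)
            mg94_fit <- rec
          } else {
            if (is.null(mg94_fit)) {
              mg94_fit <- fit_model(sim, tmpl$tree, "MG94",
                                    profile = fit_profile, control = control)
            }
            rec <- fit_model(sim, tmpl$tree, fit_name, profile = "plugin",
                             plugins = mg94_fit, control = control)
          }
          draws[[length(draws) + 1L]] <- data.frame(
            template = ti, generator = gen, fitter = fit_name, rep = r,
            omega_true = omega_true, omega_hat = rec$estimates$omega)
        }
      }
    }
  }
  draws <- do.call(rbind, draws)
  draws$rel_bias <- (draws$omega_hat - draws$omega_true) / draws$omega_true
  cells <- unique(draws[, c("generator", "fitter")])
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- draws[draws$generator == cells$generator[i] &
               draws$fitter == cells$fitter[i], ]
    severe <- vapply(split(d, d$template), function(dt) {
      q <- stats::quantile(dt$omega_hat, c(0.025, 0.975), names = FALSE)
      dt$omega_true[1] < q[1] || dt$omega_true[1] > q[2]
    }, logical(1))
    data.frame(generator = cells$generator[i], fitter = cells$fitter[i],
               mean_bias = mean(d$rel_bias), var_bias = stats::var(d$rel_bias),
               severe_rate = mean(severe))
  }))
  rownames(tab) <- NULL
  list(table = tab, draws = draws)
}
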