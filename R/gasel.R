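#' CHC genetic-algorithm configuration
#'
#' Defaults are the standard settings of the partition search: population
#' size 32, minimum relative fitness diversity 1e-6, stagnation limit 25
#' generations, mutation probability 0.20 per element, minimum BIC
#' improvement 0.01, and convergence after 100 generations without
#' improvement.
#'
#' @param P Population size (models per generation).
#' @param f_rel Minimum relative fitness range before cataclysmic
#'   mutation triggers.
#' @param f_stagnant Consecutive generations without new models entering
#'   the population before mutation triggers.
#' @param mu Per-element mutation probability during cataclysmic
#'   mutation.
#' @param delta_bic Minimum generation-to-generation BIC improvement that
#'   resets the termination counter.
#' @param g_conv Consecutive generations without sufficient improvement
#'   to terminate.
#' @param M Number of synonymous rate classes searched over (>= 2).
#' @param seed Optional integer seed.
#' @param max_generations Hard cap on generations (Inf = none).
#' @param max_models Hard cap on the number of distinct models fitted
#'   (Inf = none); the search stops at the end of the generation in which
#'   the budget is exhausted.
#' @param step1_control Optimizer control overrides for the per-gene MG94
#'   fits of step 1.
#' @param fit_rounds Coordinate-optimization rounds per fitness
#'   evaluation.
#' @param rate_tol,scaler_tol Convergence tolerances (log scale) of the
#'   within-fitness optimizations.
#' @param step1 Profile of the per-gene MG94 fits providing the plug-in
#'   branch lengths and nucleotide rates (`"fast"` or `"full"`).
#' @param char_units BIC sample-size units: `"nucleotide"` counts
#'   sequences x nucleotide sites (default), `"codon"` counts sequences x
#'   codon sites.
#' @return A `ga_config` list.
#' @export
ga_config <- function(P = 32, f_rel = 1e-6, f_stagnant = 25, mu = 0.20,
                      delta_bic = 0.01, g_conv = 100, M = 2, seed = NULL,
                      max_generations = Inf, max_models = Inf,
                      fit_rounds = 1,
                      rate_tol = 0.04, scaler_tol = 0.015,
                      step1 = c("fast", "full"), step1_control = list(),
                      char_units = c("nucleotide", "codon")) {
  if (M < 2) stop("M (number of rate classes) must be at least 2")
  structure(list(P = as.integer(P), f_rel = f_rel,
                 f_stagnant = as.integer(f_stagnant), mu = mu,
                 delta_bic = delta_bic, g_conv = as.integer(g_conv),
                 M = as.integer(M), seed = seed,
                 max_generations = max_generations,
                 max_models = max_models, step1_control = step1_control,
                 fit_rounds = as.integer(fit_rounds), rate_tol = rate_tol,
                 scaler_tol = scaler_tol, step1 = match.arg(step1),
                 char_units = match.arg(char_units)),
            class = "ga_config")
}

#' @noRd
vec_key <- function(v) paste(as.integer(v), collapse = ",")

#' @noRd
#' Fitness factory: BIC of a candidate partition over all genes. Branch
#' lengths and nucleotide rates stay frozen at their per-gene MG94 MLEs
#' (search Step 1); only the M-1 free class rates (reference class pinned
#' at 1) are optimized, by the C++ kernel. Every distinct canonical vector
#' is fitted once and cached.
make_ga_fitness <- function(plugin_genes, mach, sample_size, config) {
  cache <- new.env(parent = emptyenv())
  G <- length(plugin_genes)
  state <- new.env(parent = emptyenv())
  state$warm_rate <- 1
  fitness <- function(v) {
    v <- canonicalize_model_vector(v)
    key <- vec_key(v)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    K <- attr(v, "n_classes")
    res <- cpp_fit_partition(plugin_genes, mach$transitions, mach$codon_nt,
                             as.integer(v) + 1L, K,
                             c(1, rep(state$warm_rate, K - 1L)),
                             rep(1, G), config$fit_rounds,
                             config$rate_tol, config$scaler_tol,
                             log(1e-6), log(100), FALSE, FALSE)
    n_params <- K - 1L
    rec <- list(vector = as.integer(v), K = K, logL = res$logL,
                bic = -2 * res$logL + n_params * log(sample_size),
                n_params = n_params, rates = as.numeric(res$rates))
    cache[[key]] <- rec
    if (K > 1L) state$warm_rate <- exp(mean(log(pmax(res$rates[-1], 1e-6))))
    rec
  }
  list(fitness = fitness, cache = cache)
}

#' One generation of the CHC search: recombination + elitist selection
#'
#' Generates P offspring by free recombination (each element of the child
#' taken from either of two randomly chosen parents with probability 1/2,
#' then canonicalized), pools parents and offspring, and keeps the P most
#' fit distinct models. The best model is always preserved and the worst
#' retained fitness never deteriorates.
#'
#' @param population List of individuals, each `list(vector=, fitness=)`
#'   with `vector` a canonical class vector and `fitness` its BIC.
#' @param fitness_fn Function mapping a class vector to its BIC.
#' @param config A `ga_config` (supplies P).
#' @return List with `population` (next generation, sorted by fitness)
#'   and `new_keys` (keys of offspring that entered the population).
#' @export
ga_step <- function(population, fitness_fn, config) {
  P <- config$P
  n <- length(population)
  prev_keys <- vapply(population, function(x) vec_key(x$vector), "")
  offspring <- vector("list", P)
  for (i in seq_len(P)) {
    idx <- if (n >= 2) sample.int(n, 2) else c(1L, 1L)
    v1 <- population[[idx[1]]]$vector
    v2 <- population[[idx[2]]]$vector
    pick <- stats::runif(length(v1)) < 0.5
    child <- canonicalize_model_vector(ifelse(pick, v1, v2))
    offspring[[i]] <- list(vector = as.integer(child),
                           fitness = fitness_fn(child)$bic)
  }
  pool <- c(population, offspring)
  keys <- vapply(pool, function(x) vec_key(x$vector), "")
  pool <- pool[!duplicated(keys)]
  ord <- order(vapply(pool, `[[`, 0, "fitness"))
  keep <- pool[ord[seq_len(min(P, length(pool)))]]
  new_keys <- setdiff(vapply(keep, function(x) vec_key(x$vector), ""),
                      prev_keys)
  list(population = keep, new_keys = new_keys)
}

#' CHC genetic-algorithm search over synonymous rate-class partitions
#'
#' Implements the five-step search: (1) MG94 fits per gene freeze branch
#' lengths and nucleotide rates; (2) P unique random canonical vectors
#' are scored by BIC over all genes (sample size = total characters);
#' (3) each generation produces P offspring by free recombination and
#' keeps the P most fit of parents plus offspring; (4) when the relative
#' fitness range drops below `f_rel` or no new models have entered the
#' population for `f_stagnant` generations, every individual except the
#' most fit is mutagenized (each element changed with probability `mu`);
#' (5) the search stops after `g_conv` consecutive generations without a
#' `delta_bic` improvement. Every distinct model is fitted once;
#' re-encountered vectors are served from the cache.
#'
#' @param genes List of genes (`list(aln=, tree=)` each, e.g. from
#'   [read_filelist()]).
#' @param config A `ga_config`.
#' @param code Genetic code.
#' @return A `ga_run_record`: `models` (every model considered: canonical
#'   encoding, BIC, log-likelihood, class-rate MLEs), `best` (its key),
#'   `best_bic`, `null_bic` (single-class baseline under the same
#'   plug-ins), `delta_bic_null` (improvement of the best model over the
#'   baseline), `generations`, `termination`, and `sample_size`.
#' @export
ga_search <- function(genes, config = ga_config(),
                      code = genetic_code_table()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mach <- codon_machinery(code)
  D <- mach$D
  keep <- vapply(genes, function(g) {
    v <- validate_for_analysis(g$aln, code = code)
    if (!v$accept) warning(sprintf("gene excluded: %s",
                                   paste(v$reasons, collapse = "; ")))
    v$accept
  }, logical(1))
  genes <- genes[keep]
  if (!length(genes)) stop("no genes passed validation")

  # Step 1: per-gene MG94 plug-ins
  mg94 <- lapply(genes, function(g) {
    fit_model(g$aln, g$tree, "MG94", code = code, profile = config$step1,
              control = config$step1_control)
  })
  pg <- build_plugin_genes(genes, mg94, code)
  sample_size <- sum(vapply(pg, `[[`, 0, "n_chars")) /
    (if (config$char_units == "codon") 3 else 1)

  ff <- make_ga_fitness(pg, mach, sample_size, config)
  fitness_fn <- ff$fitness
  null_rec <- fitness_fn(rep(0L, D))

  # Step 2: P unique random canonical vectors
  pop <- list()
  seen <- character(0)
  tries <- 0L
  P <- config$P
  while (length(pop) < P && tries < 200L * config$P) {
    tries <- tries + 1L
    v <- canonicalize_model_vector(sample.int(config$M, D, replace = TRUE) - 1L)
    key <- vec_key(v)
    if (key %in% seen) next
    seen <- c(seen, key)
    pop[[length(pop) + 1L]] <- list(vector = as.integer(v),
                                    fitness = fitness_fn(v)$bic)
  }
  if (length(pop) < P) {
    warning(sprintf("only %d unique models available; reducing P from %d",
                    length(pop), P))
    P <- length(pop)
    config$P <- P
  }

  best_bic <- min(vapply(pop, `[[`, 0, "fitness"))
  no_improve <- 0L
  stagnant <- 0L
  generation <- 0L
  termination <- "max_generations"

  while (generation < config$max_generations) {
    generation <- generation + 1L
    step <- ga_step(pop, fitness_fn, config)
    pop <- step$population
    stagnant <- if (length(step$new_keys)) 0L else stagnant + 1L

    # Step 4: cataclysmic mutation when too inbred
    fits <- vapply(pop, `[[`, 0, "fitness")
    rel_range <- (max(fits) - min(fits)) / max(abs(min(fits)), 1e-12)
    if (rel_range < config$f_rel || stagnant >= config$f_stagnant) {
      elite <- which.min(fits)
      for (i in seq_along(pop)) {
        if (i == elite) next
        v <- pop[[i]]$vector
        flip <- stats::runif(D) < config$mu
        if (any(flip)) {
          v[flip] <- vapply(v[flip], function(cur) {
            sample(setdiff(seq_len(config$M) - 1L, cur), 1L)
          }, integer(1))
        }
        v <- canonicalize_model_vector(v)
        pop[[i]] <- list(vector = as.integer(v), fitness = fitness_fn(v)$bic)
      }
      keys <- vapply(pop, function(x) vec_key(x$vector), "")
      pop <- pop[!duplicated(keys)]
      stagnant <- 0L
    }

    # Step 5: termination on lack of BIC improvement
    new_best <- min(vapply(pop, `[[`, 0, "fitness"))
    if (best_bic - new_best >= config$delta_bic) {
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    best_bic <- min(best_bic, new_best)
    if (no_improve >= config$g_conv) {
      termination <- "converged"
      break
    }
    if (length(ls(ff$cache)) >= config$max_models) {
      termination <- "model_budget"
      break
    }
  }

  models <- as.list(ff$cache)
  bics <- vapply(models, `[[`, 0, "bic")
  best_key <- names(models)[which.min(bics)]
  structure(list(models = unname(models[order(bics)]),
                 best = models[[best_key]],
                 best_bic = min(bics),
                 null_bic = null_rec$bic,
                 delta_bic_null = null_rec$bic - min(bics),
                 generations = generation,
                 termination = termination,
                 sample_size = sample_size,
                 n_genes = length(genes),
                 config = unclass(config)),
            class = "ga_run_record")
}

#' @noRd
#' Rank-based category labels for K class rates: smallest = SELECTED,
#' largest = NEUTRAL, intermediates INT 1, INT 2, ... by rank.
rate_categories <- function(rates) {
  K <- length(rates)
  if (K == 1L) return("NEUTRAL")
  labels <- character(K)
  ord <- order(rates, seq_len(K))
  labels[ord[1]] <- "SELECTED"
  labels[ord[K]] <- "NEUTRAL"
  if (K > 2L) labels[ord[2:(K - 1)]] <- paste("INT", seq_len(K - 2L))
  labels
}

#' BIC-weight model averaging of a GA run
#'
#' Every model considered receives an Akaike-style weight
#' `exp((min BIC - BIC)/2)`, normalized to sum 1. Within each model the
#' class rates are ranked smallest ("SELECTED") to largest ("NEUTRAL"),
#' intermediates labeled "INT k", and each pair inherits its class label;
#' the weights accrue per pair per category. An assignment is flagged
#' ambiguous when no category reaches 0.90 of the total weight.
#'
#' @param record A `ga_run_record` (or any list with a `models` element
#'   of `list(vector=, bic=, rates=)` entries).
#' @param ambiguity_threshold Support below which a pair is ambiguous.
#' @return An `averaged_assignment`: `weights` (pairs x categories
#'   matrix), `category` (argmax label per pair), `support`, `ambiguous`.
#' @export
model_average <- function(record, ambiguity_threshold = 0.90) {
  models <- record$models
  if (!length(models)) stop("no models to average")
  D <- length(models[[1]]$vector)
  Kmax <- max(vapply(models, function(m) length(m$rates), 0L))
  levels <- c("SELECTED", if (Kmax > 2) paste("INT", seq_len(Kmax - 2L)),
              "NEUTRAL")
  bics <- vapply(models, `[[`, 0, "bic")
  w <- exp((min(bics) - bics) / 2)
  w <- w / sum(w)
  weights <- matrix(0, D, length(levels), dimnames = list(NULL, levels))
  for (m in seq_along(models)) {
    cats <- rate_categories(models[[m]]$rates)[models[[m]]$vector + 1L]
    for (lv in unique(cats)) {
      rows <- cats == lv
      weights[rows, lv] <- weights[rows, lv] + w[m]
    }
  }
  support <- apply(weights, 1, max)
  category <- colnames(weights)[apply(weights, 1, which.max)]
  structure(list(weights = weights, category = category, support = support,
                 ambiguous = support < ambiguity_threshold,
                 model_weights = w),
            class = "averaged_assignment")
}

#' Classification metrics against a known selected/neutral truth
#'
#' Places each pair in the selected or neutral class by which of the two
#' categories received more model-averaged support, builds the 2x2
#' contingency table against the truth, and reports the Matthews
#' correlation coefficient, the two-sided Fisher exact p-value, and the
#' number of ambiguously assigned pairs (support below the ambiguity
#' threshold).
#'
#' @param truth Named character vector over pairs with values
#'   `"selected"`/`"neutral"` (a subset of pairs restricts the comparison
#'   with a warning).
#' @param inferred An `averaged_assignment`, or a character vector of
#'   `"selected"`/`"neutral"` calls.
#' @param pairs Optional pair labels aligning `inferred` rows to `truth`
#'   names (default: the universal-code pair table order).
#' @return List with `table` (2x2: inferred x truth), `mcc`, `fisher_p`,
#'   `n_ambiguous`.
#' @export
classification_metrics <- function(truth, inferred,
                                   pairs = enumerate_syn_pairs()$pair) {
  if (inherits(inferred, "averaged_assignment")) {
    sel <- inferred$weights[, "SELECTED"]
    neu <- inferred$weights[, "NEUTRAL"]
    calls <- ifelse(sel > neu, "selected", "neutral")
    ambiguous <- inferred$ambiguous
  } else {
    calls <- as.character(inferred)
    ambiguous <- rep(FALSE, length(calls))
  }
  names(calls) <- pairs[seq_along(calls)]
  if (!all(names(truth) %in% names(calls))) {
    stop("truth refers to pairs absent from the inferred assignment")
  }
  if (length(truth) < length(calls)) {
    warning("truth covers a subset of pairs; restricting the comparison")
  }
  calls <- calls[names(truth)]
  tp <- sum(calls == "selected" & truth == "selected")
  fp <- sum(calls == "selected" & truth == "neutral")
  fn <- sum(calls == "neutral" & truth == "selected")
  tn <- sum(calls == "neutral" & truth == "neutral")
  tab <- matrix(c(tp, fn, fp, tn), 2, 2,
                dimnames = list(inferred = c("selected", "neutral"),
                                truth = c("selected", "neutral")))
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  fisher_p <- stats::fisher.test(tab)$p.value
  list(table = tab, mcc = mcc, fisher_p = fisher_p,
       n_ambiguous = sum(ambiguous[match(names(truth), pairs)]))
}
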