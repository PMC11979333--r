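#' Configuration for the forward Wright-Fisher codon simulator
#'
#' Defaults follow the validation design for MSS models: a diploid
#' population of N = 500 carrying a 300-codon gene, per-base mutation rate
#' 1.6e-5 per generation, all nonsynonymous mutations deleterious with
#' 2Ns = -10 (s = -0.01), a first burn-in of 200 N generations, a second
#' burn-in until all 2N gene copies coalesce to a single founder, then 10
#' population-splitting events yielding 11 populations on a tree of depth
#' 10,000 and total length 64,000 generations.
#'
#' @param N Diploid population size.
#' @param L Gene length in codons.
#' @param mu Per-base per-generation mutation rate.
#' @param s_nonsyn Selection coefficient of every nonsynonymous mutation.
#' @param s_syn Selection coefficient magnitude for cross-class synonymous
#'   mutations (favored direction +s_syn, reverse -s_syn); 0 = all
#'   synonymous changes neutral.
#' @param syn_scheme Per-amino-acid partition of codons into 1 or 2
#'   preference classes (named list: amino acid -> list of codon vectors,
#'   favored class first). Default: one class per amino acid when
#'   `s_syn == 0`, otherwise [default_selection_scheme()].
#' @param n_splits Number of population splitting events.
#' @param tree_depth Generations from the first split opportunity to
#'   sampling (root-to-tip depth of the true tree).
#' @param total_tree_length Total branch length of the true tree in
#'   generations; the default even spacing of splits is solved to match.
#' @param split_schedule Optional data frame with columns `generation`
#'   and `pop` (population index to split), overriding the even default.
#' @param burnin1_factor First burn-in length in units of N generations.
#' @param stop_codons `"lethal"` (mutation occurs, carrier fitness 0) or
#'   `"forbidden"` (mutation rejected).
#' @param ancestor_freqs Codon frequencies for the ancestral sequence
#'   (default uniform over sense codons).
#' @param mutation_bias Optional 4x4 relative-rate matrix (A,C,G,T) over
#'   base changes; default uniform across the 3 alternatives.
#' @param seed Optional integer seed.
#' @param code Genetic code.
#' @return A `fwdsim_config` list; includes the bookkeeping fields
#'   `two_Ns_nonsyn = 2*N*s_nonsyn` and `two_Ns_syn = 2*N*s_syn`.
#' @export
fwdsim_config <- function(N = 500, L = 300, mu = 1.6e-5, s_nonsyn = -0.01,
                          s_syn = 0, syn_scheme = NULL, n_splits = 10,
                          tree_depth = 10000, total_tree_length = 64000,
                          split_schedule = NULL, burnin1_factor = 200,
                          stop_codons = c("lethal", "forbidden"),
                          ancestor_freqs = NULL, mutation_bias = NULL,
                          seed = NULL, code = genetic_code_table()) {
  stop_codons <- match.arg(stop_codons)
  if (is.null(syn_scheme)) {
    syn_scheme <- if (s_syn == 0) neutral_scheme(code) else
      default_selection_scheme(code)
  }
  if (is.null(split_schedule)) {
    split_schedule <- even_split_schedule(n_splits, tree_depth,
                                          total_tree_length)
  } else {
    split_schedule <- as.data.frame(split_schedule)
    if (!all(c("generation", "pop") %in% names(split_schedule))) {
      stop("split_schedule needs columns 'generation' and 'pop'")
    }
    if (any(split_schedule$generation < 0) ||
        any(split_schedule$generation > tree_depth) ||
        is.unsorted(split_schedule$generation)) {
      stop("split schedule inconsistent with tree depth")
    }
  }
  structure(list(N = N, L = as.integer(L), mu = mu, s_nonsyn = s_nonsyn,
                 s_syn = s_syn, syn_scheme = syn_scheme,
                 split_schedule = split_schedule, tree_depth = tree_depth,
                 burnin1_factor = burnin1_factor, stop_codons = stop_codons,
                 ancestor_freqs = ancestor_freqs,
                 mutation_bias = mutation_bias, seed = seed, code = code,
                 two_Ns_nonsyn = 2 * N * s_nonsyn,
                 two_Ns_syn = 2 * N * s_syn),
            class = "fwdsim_config")
}

#' @noRd
#' Evenly spaced splits of the ancestral population at times k*c, with c
#' solved so that the (n_splits+1)-tip ladder has the requested depth and
#' total branch length.
even_split_schedule <- function(n_splits, depth, total) {
  if (n_splits == 0) {
    return(data.frame(generation = numeric(0), pop = integer(0)))
  }
  sum_times <- (n_splits + 1) * depth - total
  c0 <- sum_times * 2 / (n_splits * (n_splits + 1))
  gens <- round(c0 * seq_len(n_splits))
  if (any(gens < 0) || any(gens > depth) || is.unsorted(gens)) {
    stop("no even split schedule achieves this depth/total length; supply split_schedule")
  }
  data.frame(generation = gens, pop = 1L)
}

#' One preference class per amino acid: all synonymous changes neutral
#' @param code Genetic code.
#' @return A scheme list usable as `syn_scheme`.
#' @export
neutral_scheme <- function(code = genetic_code_table()) {
  sense <- sense_codons(code)
  aa <- code$codon_to_aa[sense]
  lapply(split(sense, aa), function(cods) list(cods))
}

#' Built-in two-class codon preference scheme (25 selected / 42 neutral pairs)
#'
#' Each split amino acid disfavors a single codon, so every neutral
#' (within-class) pair lies inside the common, favored class and remains
#' observable when codon usage equilibrates under selection: the five
#' simple four-fold amino acids (Ala, Gly, Pro, Thr, Val) disfavor their
#' A-ending codon (3 cross-class pairs each, 3 within-favored neutral
#' pairs); Ile disfavors ATA (2 cross-class pairs); eight of the nine
#' two-fold amino acids (Cys, Asp, Glu, Phe, His, Lys, Asn, Gln) split
#' into their two codons (1 cross-class pair each, favored =
#' alphabetically first). Tyr, Leu, Arg, Ser, Met and Trp keep a single
#' neutral class. Under the universal code this yields exactly 25
#' selected (cross-class) and 42 neutral synonymous codon pairs.
#'
#' @param code Genetic code.
#' @return A scheme list usable as `syn_scheme`.
#' @export
default_selection_scheme <- function(code = genetic_code_table()) {
  scheme <- neutral_scheme(code)
  fourfold <- c("A", "G", "P", "T", "V")
  twofold <- c("C", "D", "E", "F", "H", "K", "N", "Q")
  for (a in fourfold) {
    cods <- scheme[[a]][[1]]
    last <- substr(cods, 3, 3)
    scheme[[a]] <- list(cods[last != "A"], cods[last == "A"])
  }
  for (a in twofold) {
    cods <- sort(scheme[[a]][[1]])
    scheme[[a]] <- list(cods[1], cods[2])   # favored = first alphabetically
  }
  scheme[["I"]] <- list(c("ATC", "ATT"), "ATA")
  scheme
}

#' Truth classes for synonymous pairs under a preference scheme
#' @param scheme A `syn_scheme` list.
#' @param code Genetic code.
#' @return Named character vector over the D pairs: `"selected"` (codons
#'   in different preference classes) or `"neutral"`.
#' @export
scheme_pair_classes <- function(scheme, code = genetic_code_table()) {
  pairs <- enumerate_syn_pairs(code)
  out <- vapply(seq_len(nrow(pairs)), function(i) {
    cl <- scheme[[pairs$aa[i]]]
    if (length(cl) < 2L) return("neutral")
    in1 <- c(pairs$codon1[i], pairs$codon2[i]) %in% cl[[1]]
    if (xor(in1[1], in1[2])) "selected" else "neutral"
  }, character(1))
  stats::setNames(out, pairs$pair)
}

#' Selection coefficient of a one-step codon change
#'
#' Nonsynonymous changes take `s_nonsyn`; synonymous changes within a
#' preference class are neutral; cross-class changes take `+s_syn` in the
#' favored direction and `-s_syn` in the reverse; changes creating a stop
#' codon return -1 (lethal).
#'
#' @param x,y Codons differing at exactly one position.
#' @param config A `fwdsim_config`.
#' @return The selection coefficient s.
#' @export
fitness_effect <- function(x, y, config) {
  cls <- classify_substitution(x, y, config$code)
  if (cls == "identical") stop("x and y must differ")
  if (cls == "multistep") stop("fitness_effect is defined for one-step changes")
  if (cls == "involves_stop") return(-1)
  if (cls == "nonsynonymous_one_step") return(config$s_nonsyn)
  aa <- config$code$codon_to_aa[[x]]
  cl <- config$syn_scheme[[aa]]
  if (length(cl) < 2L) return(0)
  x1 <- x %in% cl[[1]]; y1 <- y %in% cl[[1]]
  if (x1 == y1) return(0)
  if (y1) config$s_syn else -config$s_syn   # class 1 is the favored class
}

#' @noRd
#' Per-codon mutation lookup tables for the C++ generation kernel:
#' 61 x 9 matrices over (position, alternative base) giving the target
#' codon (0 = stop), log-fitness increment, mutation class and cumulative
#' choice probabilities.
fwdsim_tables <- function(config) {
  cached <- attr(config, "tables")
  if (!is.null(cached)) return(cached)
  code <- config$code
  mach <- codon_machinery(code)
  sense <- mach$sense
  n <- length(sense)
  mut_to <- matrix(0L, n, 9)
  mut_dlogw <- matrix(0, n, 9)
  mut_class <- matrix(0L, n, 9)
  mut_prob <- matrix(1 / 9, n, 9)
  bias <- config$mutation_bias
  for (i in seq_len(n)) {
    chars <- strsplit(sense[i], "")[[1]]
    k <- 0L
    for (p in 1:3) {
      alts <- NUCS[NUCS != chars[p]]
      for (b in alts) {
        k <- k + 1L
        ys <- chars; ys[p] <- b
        y <- paste(ys, collapse = "")
        if (!is.null(bias)) mut_prob[i, k] <- bias[chars[p], b]
        if (code$codon_to_aa[[y]] == "*") next   # mut_to stays 0
        mut_to[i, k] <- match(y, sense)
        s <- fitness_effect(sense[i], y, config)
        mut_dlogw[i, k] <- log1p(s)
        mut_class[i, k] <- if (code$codon_to_aa[[y]] != code$codon_to_aa[[sense[i]]]) {
          3L
        } else if (s == 0) 1L else 2L
      }
    }
  }
  mut_prob <- mut_prob / rowSums(mut_prob)
  tables <- list(mut_to = mut_to, mut_dlogw = mut_dlogw,
                 mut_class = mut_class,
                 mut_cum = t(apply(mut_prob, 1, cumsum)),
                 n_syn_neutral = rowSums(mut_class == 1L))
  tables
}

#' Low-mutation-limit equilibrium codon frequencies under a preference scheme
#'
#' Approximate stationary codon frequencies of the simulator's selection
#' regime: within each amino acid, codons of the favored class share equal
#' weight and unfavored-class codons are down-weighted by the classic
#' fixed-state factor `exp(-2 * 2Ns)` (the relative time a site spends
#' fixed for the disfavored allele in the low-mutation limit). Useful for
#' seeding ancestors near mutation-selection-drift equilibrium, emulating
#' the codon-usage bias of real gene sequences.
#'
#' @param config A `fwdsim_config`.
#' @return Named codon frequency vector over sense codons (sums to 1).
#' @export
equilibrium_ancestor_freqs <- function(config) {
  sense <- sense_codons(config$code)
  aa <- config$code$codon_to_aa[sense]
  w <- stats::setNames(rep(1, length(sense)), sense)
  gamma <- 2 * abs(config$two_Ns_syn)
  for (a in names(config$syn_scheme)) {
    cl <- config$syn_scheme[[a]]
    if (length(cl) < 2L) next
    w[cl[[2]]] <- exp(-gamma)
  }
  w / sum(w)
}

#' Draw an ancestral codon sequence
#'
#' @param freqs Named codon frequency vector (sense codons; any mass on a
#'   stop codon is an error). `NULL` = uniform over sense codons.
#' @param L Length in codons.
#' @param seed Optional integer seed.
#' @param code Genetic code.
#' @return A nucleotide string of length 3L with no stop codons.
#' @export
make_ancestor <- function(freqs = NULL, L, seed = NULL,
                          code = genetic_code_table()) {
  if (!is.null(seed)) set.seed(seed)
  sense <- sense_codons(code)
  if (is.null(freqs)) freqs <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
  stops <- setdiff(names(freqs), sense)
  if (any(freqs[stops] > 0)) stop("ancestor frequencies put mass on stop codons")
  freqs <- freqs[names(freqs) %in% sense]
  if (any(freqs < 0) || sum(freqs) <= 0) stop("invalid codon frequencies")
  draws <- sample(names(freqs), L, replace = TRUE, prob = freqs)
  paste(draws, collapse = "")
}

#' @noRd
seq_to_states <- function(seq, mach) {
  s <- match(codon_split(seq), mach$sense)
  if (any(is.na(s))) stop("sequence contains stop or invalid codons")
  as.integer(s)
}

#' Advance a Wright-Fisher population by one or more generations
#'
#' Each generation applies Poisson mutation (mean `3 L mu` per gene copy,
#' uniform over sites and the three alternative bases unless a bias matrix
#' is configured) followed by resampling of all 2N copies with probability
#' proportional to multiplicative fitness (genic selection).
#'
#' @param state List with `pop` (L x 2N integer codon-state matrix),
#'   `logw` (per-copy log fitness) and optional `labels` (lineage labels).
#' @param config A `fwdsim_config`.
#' @param n_gens Number of generations to advance.
#' @param stop_on_coalescence Stop early once all labels agree.
#' @return Updated state list (adds `mut_counts`, `gens_done`,
#'   `coalesced`).
#' @export
wright_fisher_generation <- function(state, config, n_gens = 1,
                                     stop_on_coalescence = FALSE) {
  tb <- fwdsim_tables(config)
  labels <- if (is.null(state$labels)) integer(0) else as.integer(state$labels)
  res <- cpp_wf_evolve(state$pop, state$logw, labels, as.integer(n_gens),
                       config$mu, tb$mut_to, tb$mut_dlogw, tb$mut_class,
                       tb$mut_cum, config$stop_codons == "lethal",
                       stop_on_coalescence)
  out <- list(pop = res$pop, logw = as.numeric(res$logw),
              labels = if (length(res$labels)) as.integer(res$labels) else NULL,
              mut_counts = as.integer(res$mut_counts),
              gens_done = res$gens_done, coalesced = res$coalesced)
  out
}

#' @noRd
#' Column-wise modal codon state (consensus sequence) of a population.
pop_consensus <- function(pop) {
  apply(pop, 1, function(r) {
    tb <- tabulate(r, nbins = 64)
    which.max(tb)
  })
}

#' Run a forward Wright-Fisher simulation with population splits
#'
#' Executes the full design: burn-in 1 (`burnin1_factor * N` generations),
#' burn-in 2 (until all 2N copies descend from a single copy present at
#' the end of burn-in 1), then the split schedule (each split duplicates
#' the parent population at size N), and final sampling of one random gene
#' copy per terminal population. Substitutions are logged per edge of the
#' true population tree by comparing consensus sequences at the flanking
#' events (the sampled copy at the tips), and classified per synonymous
#' pair.
#'
#' @param config A `fwdsim_config`.
#' @return A `fwdsim_result`: `alignment` (one sequence per population),
#'   `tree` (true split genealogy, branch lengths in generations),
#'   `per_pair_subs` (named counts of one-step synonymous substitutions
#'   per pair), `sub_counts` and `mut_counts` (totals by class),
#'   `eff_syn_sites`, `subs_per_eff_syn_site`, `founder` (sequence at the
#'   start of the split phase), and `config`.
#' @export
run_simulation <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mach <- codon_machinery(config$code)
  tb <- fwdsim_tables(config)
  n_copies <- 2L * config$N
  anc <- make_ancestor(config$ancestor_freqs, config$L, code = config$code)
  states <- seq_to_states(anc, mach)
  state <- list(pop = matrix(states, config$L, n_copies),
                logw = rep(0, n_copies), labels = NULL)

  # burn-in 1: reach mutation-selection-drift equilibrium
  state <- wright_fisher_generation(state, config,
                                    n_gens = config$burnin1_factor * config$N)
  # burn-in 2: single common ancestor among the copies present now
  state$labels <- seq_len(n_copies)
  state <- wright_fisher_generation(state, config,
                                    n_gens = 1000L * config$N,
                                    stop_on_coalescence = TRUE)
  if (!state$coalesced) stop("burn-in 2 failed to coalesce; increase the cap")
  state$labels <- NULL

  # split phase
  sched <- config$split_schedule
  n_pops_final <- nrow(sched) + 1L
  pops <- list(state)
  founder <- pop_consensus(state$pop)
  edge_start <- list(list(t = 0, cons = founder))
  splits <- list()   # (time, parent pop, child pop)
  per_pair <- stats::setNames(rep(0, mach$D), mach$pairs$pair)
  sub_counts <- c(syn_neutral = 0, syn_selected = 0, nonsyn = 0, multi = 0)
  mut_counts <- c(stop = 0, syn_neutral = 0, syn_selected = 0, nonsyn = 0)

  count_diffs <- function(a, b) {
    diff <- which(a != b)
    for (j in diff) {
      x <- mach$sense[a[j]]; y <- mach$sense[b[j]]
      cls <- classify_substitution(x, y, config$code)
      if (cls == "synonymous_one_step") {
        key <- paste(sort(c(x, y)), collapse = ":")
        per_pair[key] <<- per_pair[[key]] + 1
        s <- fitness_effect(x, y, config)
        if (s == 0) sub_counts["syn_neutral"] <<- sub_counts[["syn_neutral"]] + 1
        else sub_counts["syn_selected"] <<- sub_counts[["syn_selected"]] + 1
      } else if (cls == "nonsynonymous_one_step") {
        sub_counts["nonsyn"] <<- sub_counts[["nonsyn"]] + 1
      } else {
        sub_counts["multi"] <<- sub_counts[["multi"]] + 1
      }
    }
  }

  t_now <- 0
  events <- rbind(sched, data.frame(generation = config$tree_depth, pop = NA))
  for (ev in seq_len(nrow(events))) {
    dt <- events$generation[ev] - t_now
    if (dt > 0) {
      for (p in seq_along(pops)) {
        pops[[p]] <- wright_fisher_generation(pops[[p]], config, n_gens = dt)
        mut_counts <- mut_counts + pops[[p]]$mut_counts
      }
      t_now <- events$generation[ev]
    }
    if (is.na(events$pop[ev])) break
    p <- events$pop[ev]
    cons <- pop_consensus(pops[[p]]$pop)
    count_diffs(edge_start[[p]]$cons, cons)
    q <- length(pops) + 1L
    pops[[q]] <- pops[[p]]           # split: duplicate the population
    edge_start[[p]] <- list(t = t_now, cons = cons)
    edge_start[[q]] <- list(t = t_now, cons = cons)
    splits[[length(splits) + 1L]] <- list(t = t_now, parent = p, child = q)
  }

  # sample one random copy per population; close the tip edges
  seqs <- character(length(pops))
  for (p in seq_along(pops)) {
    copy <- sample.int(ncol(pops[[p]]$pop), 1L)
    samp <- pops[[p]]$pop[, copy]
    count_diffs(edge_start[[p]]$cons, samp)
    seqs[p] <- paste(mach$sense[samp], collapse = "")
  }
  names(seqs) <- paste0("pop_", seq_along(pops))
  aln <- codon_alignment(seqs, check = FALSE, code = config$code)

  eff <- sum(tb$n_syn_neutral[founder]) / 3
  structure(list(
    alignment = aln,
    tree = split_tree(splits, length(pops), config$tree_depth),
    per_pair_subs = per_pair, sub_counts = sub_counts,
    mut_counts = mut_counts, eff_syn_sites = eff,
    subs_per_eff_syn_site = unname(sub_counts["syn_neutral"]) / eff,
    founder = paste(mach$sense[founder], collapse = ""),
    n_populations = length(pops), config = config),
    class = "fwdsim_result")
}

#' @noRd
#' Newick construction from the recorded split events (ladder or any
#' schedule): recursively, a population's subtree after time t0 is split
#' at its next recorded event.
split_tree <- function(splits, n_pops, depth) {
  times <- vapply(splits, `[[`, 0, "t")
  build <- function(p, t0) {
    mine <- which(vapply(splits, function(s) s$parent == p, TRUE) & times >= t0)
    if (!length(mine)) {
      return(sprintf("pop_%d:%g", p, depth - t0))
    }
    k <- mine[which.min(times[mine])]
    s <- splits[[k]]
    sprintf("(%s,%s):%g", build(p, s$t + 1e-9), build(s$child, s$t + 1e-9),
            s$t - t0)
  }
  nw <- if (n_pops == 1L) sprintf("(pop_1:%g);", depth) else
    paste0(build(1L, 0), ";")
  ape::read.tree(text = nw)
}
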