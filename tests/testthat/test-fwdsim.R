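test_that("configuration bookkeeping keeps 2Ns exact and schedules consistent", {
  cfg <- fwdsim_config(N = 500)
  expect_equal(cfg$two_Ns_nonsyn, 2 * 500 * -0.01)
  expect_equal(cfg$two_Ns_nonsyn, -10)
  expect_equal(cfg$L, 300L)
  expect_equal(cfg$mu, 1.6e-5)
  expect_equal(nrow(cfg$split_schedule), 10L)
  # even default: 11 terminal populations, depth 10k, total 64k generations
  gens <- cfg$split_schedule$generation
  expect_true(all(gens > 0 & gens < 10000) && !is.unsorted(gens))
  expect_equal(10000 + sum(10000 - gens), 64000, tolerance = 10)
  expect_error(fwdsim_config(split_schedule = data.frame(generation = 20000,
                                                         pop = 1)),
               "inconsistent")
})

test_that("the built-in selection scheme has 25 selected and 42 neutral pairs", {
  truth <- scheme_pair_classes(default_selection_scheme())
  expect_length(truth, 67)
  expect_equal(sum(truth == "selected"), 25)
  expect_equal(sum(truth == "neutral"), 42)
  expect_true(all(scheme_pair_classes(neutral_scheme()) == "neutral"))
})

test_that("fitness effects follow the sign rules", {
  cfg <- fwdsim_config(N = 500, s_syn = 0.005)
  expect_equal(fitness_effect("AAA", "ACA", cfg), -0.01)   # nonsynonymous
  expect_equal(fitness_effect("GCC", "GCT", cfg), 0)       # within favored class
  expect_equal(fitness_effect("GCA", "GCC", cfg), 0.005)   # toward favored
  expect_equal(fitness_effect("GCC", "GCA", cfg), -0.005)  # away from favored
  expect_equal(fitness_effect("TGG", "TGA", cfg), -1)      # creates a stop
  expect_error(fitness_effect("AAA", "AAA", cfg), "differ")
  expect_error(fitness_effect("AAA", "CCA", cfg), "one-step")
})

test_that("ancestral sequences follow the requested codon frequencies", {
  expect_equal(make_ancestor(c(ATG = 1), 5), "ATGATGATGATGATG")
  expect_identical(make_ancestor(NULL, 50, seed = 3),
                   make_ancestor(NULL, 50, seed = 3))
  expect_error(make_ancestor(c(ATG = 0.5, TAA = 0.5), 5), "stop")
  # uniform draw: all 61 codons within 3 SE of 1/61 at L = 30000
  s <- make_ancestor(NULL, 30000, seed = 4)
  counts <- table(factor(mssmodels:::codon_split(s), levels = sense_codons()))
  p <- 1 / 61
  se <- sqrt(p * (1 - p) / 30000)
  expect_true(all(abs(as.numeric(counts) / 30000 - p) < 4 * se))
})

test_that("neutral drift fixes a lineage with probability k/2N", {
  # 2N = 20 copies, no mutation, no selection: track a label starting at
  # k copies until coalescence; compare to the k/2N oracle
  cfg <- fwdsim_config(N = 10, L = 2, mu = 0, seed = NULL)
  for (k in c(5, 15)) {
    set.seed(100 + k)
    fixed <- replicate(450, {
      state <- list(pop = matrix(1L, 2, 20), logw = rep(0, 20),
                    labels = c(rep(1L, k), rep(2L, 20 - k)))
      out <- wright_fisher_generation(state, cfg, n_gens = 5000,
                                      stop_on_coalescence = TRUE)
      out$labels[1] == 1L
    })
    p_hat <- mean(fixed)
    p0 <- k / 20
    expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 450))
  }
})

test_that("a beneficial copy fixes at the diffusion-approximation rate", {
  # one copy with fitness 1+s among 2N = 100: P(fix) = (1-e^(-2s))/(1-e^(-4Ns))
  cfg <- fwdsim_config(N = 50, L = 2, mu = 0, seed = NULL)
  s <- 0.05
  p_theory <- (1 - exp(-2 * s)) / (1 - exp(-4 * 50 * s))
  set.seed(321)
  fixed <- replicate(900, {
    state <- list(pop = matrix(1L, 2, 100), logw = c(log(1 + s), rep(0, 99)),
                  labels = c(1L, rep(2L, 99)))
    out <- wright_fisher_generation(state, cfg, n_gens = 20000,
                                    stop_on_coalescence = TRUE)
    out$labels[1] == 1L
  })
  expect_lt(abs(mean(fixed) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / 900))
})

test_that("generation stepping is seed-reproducible", {
  cfg <- fwdsim_config(N = 20, seed = NULL)
  anc <- mssmodels:::seq_to_states(make_ancestor(NULL, 300, seed = 5),
                                   mssmodels:::codon_machinery())
  run_once <- function() {
    set.seed(77)
    state <- list(pop = matrix(anc, 300, 40), logw = rep(0, 40))
    wright_fisher_generation(state, cfg, n_gens = 200)$pop
  }
  expect_identical(run_once(), run_once())
})

test_that("a zero-depth split schedule yields identical sequences", {
  cfg <- fwdsim_config(N = 10, L = 30, tree_depth = 0, total_tree_length = 0,
                       n_splits = 3,
                       split_schedule = data.frame(generation = c(0, 0, 0),
                                                   pop = 1),
                       burnin1_factor = 5, seed = 9)
  res <- run_simulation(cfg)
  expect_equal(res$n_populations, 4L)
  expect_length(unique(res$alignment$seqs), 1L)
})

test_that("population count after k splits is k+1 and the tree is returned", {
  cfg <- fwdsim_config(N = 10, L = 50, n_splits = 4, tree_depth = 400,
                       total_tree_length = 1400, burnin1_factor = 10,
                       seed = 15)
  res <- run_simulation(cfg)
  expect_equal(res$n_populations, 5L)
  expect_equal(length(res$tree$tip.label), 5L)
  expect_s3_class(res$alignment, "codon_alignment")
  expect_equal(res$alignment$n_codons, 50L)
})

test_that("strong synonymous selection suppresses cross-class substitutions", {
  base <- function(seed, s) {
    cfg <- fwdsim_config(N = 30, s_syn = s, s_nonsyn = -0.1,
                         n_splits = 4, tree_depth = 4000,
                         total_tree_length = 14000, burnin1_factor = 300,
                         seed = seed)
    if (s > 0) cfg$ancestor_freqs <- equilibrium_ancestor_freqs(cfg)
    run_simulation(cfg)
  }
  sel <- vapply(1:2, function(i) {
    r <- base(400 + i, 0.1)   # 2Ns = 6
    (r$sub_counts[["syn_selected"]] / 25) / (r$sub_counts[["syn_neutral"]] / 42)
  }, 0)
  neu <- vapply(1:2, function(i) {
    r <- base(500 + i, 0)
    truth <- scheme_pair_classes(default_selection_scheme())
    sum(r$per_pair_subs[truth == "selected"]) / 25 /
      (sum(r$per_pair_subs[truth == "neutral"]) / 42)
  }, 0)
  expect_lt(mean(sel), 0.5 * mean(neu))
})

test_that("burn-in 2 leaves a single surviving founder label", {
  cfg <- fwdsim_config(N = 15, L = 20, mu = 1e-5, seed = NULL)
  set.seed(31)
  state <- list(pop = matrix(3L, 20, 30), logw = rep(0, 30), labels = 1:30)
  out <- wright_fisher_generation(state, cfg, n_gens = 10000,
                                  stop_on_coalescence = TRUE)
  expect_true(out$coalesced)
  expect_length(unique(out$labels), 1L)
})
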