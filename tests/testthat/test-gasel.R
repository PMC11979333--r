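test_that("category labeling reproduces the three-class worked example", {
  record <- list(models = list(list(vector = c(0L, 1L, 1L, 2L, 0L, 2L),
                                    bic = 100, rates = c(1, 0.8, 1.4))))
  av <- model_average(record)
  expect_equal(av$category,
               c("INT 1", "SELECTED", "SELECTED", "NEUTRAL", "INT 1",
                 "NEUTRAL"))
  expect_true(all(av$support == 1))
  expect_false(any(av$ambiguous))
})

test_that("BIC weights follow exp(-deltaBIC/2) normalization", {
  record <- list(models = list(
    list(vector = c(0L, 1L), bic = 10, rates = c(1, 0.5)),
    list(vector = c(0L, 0L), bic = 12, rates = 1)))
  av <- model_average(record)
  expect_equal(unname(av$model_weights), c(0.7311, 0.2689), tolerance = 1e-4)
  # single model: weight 1, nothing ambiguous
  av1 <- model_average(list(models = record$models[1]))
  expect_equal(unname(av1$model_weights), 1)
  expect_false(any(av1$ambiguous))
  # weights per pair always sum to 1
  expect_equal(unname(rowSums(av$weights)), rep(1, 2))
  expect_error(model_average(list(models = list())), "no models")
})

test_that("recombination children lie in the canonical recombinant set", {
  fitness_fn <- function(v) list(bic = sum(as.integer(v)))   # deterministic
  pop <- list(list(vector = c(0L, 0L, 1L), fitness = 1),
              list(vector = c(0L, 1L, 0L), fitness = 1))
  cfg <- ga_config(P = 8, seed = NULL)
  allowed <- c("0,0,0", "0,0,1", "0,1,0", "0,1,1")
  set.seed(5)
  for (rep in 1:10) {
    nxt <- ga_step(pop, fitness_fn, cfg)$population
    keys <- vapply(nxt, function(x) paste(x$vector, collapse = ","), "")
    expect_true(all(keys %in% allowed))
  }
  # identical parents produce the identical child
  same <- list(list(vector = c(0L, 1L, 1L), fitness = 1),
               list(vector = c(0L, 1L, 1L), fitness = 1))
  nxt <- ga_step(same, fitness_fn, cfg)$population
  expect_true(all(vapply(nxt, function(x)
    identical(x$vector, c(0L, 1L, 1L)), TRUE)))
})

test_that("elitist selection never degrades the retained population", {
  # offspring are all strictly worse: population must stay unchanged
  fitness_fn <- function(v) {
    key <- paste(as.integer(v), collapse = ",")
    list(bic = if (key %in% c("0,0,1", "0,1,0")) 1 else 100)
  }
  pop <- list(list(vector = c(0L, 0L, 1L), fitness = 1),
              list(vector = c(0L, 1L, 0L), fitness = 1))
  cfg <- ga_config(P = 2)
  set.seed(11)
  for (rep in 1:5) {
    nxt <- ga_step(pop, fitness_fn, cfg)$population
    expect_setequal(vapply(nxt, function(x) paste(x$vector, collapse = ","), ""),
                    c("0,0,1", "0,1,0"))
  }
})

test_that("classification metrics reproduce the strong-selection table math", {
  # printed 2x2 table at the strongest selection level: TP=24, FN=1, FP=0,
  # TN=42 gives MCC 0.97 to two decimals
  pairs <- enumerate_syn_pairs()$pair
  truth <- stats::setNames(c(rep("selected", 25), rep("neutral", 42)), pairs)
  calls <- truth
  calls[25] <- "neutral"   # one selected pair missed
  cm <- classification_metrics(truth, calls)
  expect_equal(unname(cm$table["selected", "selected"]), 24)
  expect_equal(unname(cm$table["neutral", "selected"]), 1)
  expect_equal(unname(cm$table["selected", "neutral"]), 0)
  expect_equal(unname(cm$table["neutral", "neutral"]), 42)
  expect_equal(round(cm$mcc, 2), 0.97)
  expect_lt(cm$fisher_p, 1e-10)

  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$mcc, 1)
  expect_lt(perfect$fisher_p, 1e-15)
})

test_that("MCC of a random split against its own permutation centers at 0", {
  pairs <- enumerate_syn_pairs()$pair
  truth <- stats::setNames(c(rep("selected", 25), rep("neutral", 42)), pairs)
  set.seed(14)
  mccs <- replicate(200, {
    classification_metrics(truth, sample(truth))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("fitness caching fits each distinct canonical vector exactly once", {
  m <- fixture_mg94_model()
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,(c:0.08,d:0.12):0.04);")
  genes <- lapply(1:2, function(i)
    list(aln = simulate_alignment(tr, m, 60, seed = 700 + i), tree = tr))
  mg94 <- lapply(genes, function(g) fit_model(g$aln, g$tree, "MG94",
                                              profile = "fast"))
  pg <- mssmodels:::build_plugin_genes(genes, mg94, genetic_code_table())
  mach <- mssmodels:::codon_machinery()
  counter <- local({
    n <- 0L
    ff <- mssmodels:::make_ga_fitness(pg, mach, 4 * 180 * 2, ga_config(P = 4))
    orig <- environment(ff$fitness)$cache
    list(ff = ff, cache = orig)
  })
  v1 <- c(rep(0L, 30), rep(1L, 37))
  r1 <- counter$ff$fitness(v1)
  r2 <- counter$ff$fitness(v1)                      # cache hit
  r3 <- counter$ff$fitness(1L - v1)                 # same partition, relabeled
  expect_identical(r1, r2)
  expect_identical(r1$bic, r3$bic)
  expect_length(ls(counter$cache), 1L)
})

test_that("a searched two-class partition with engineered signal is found", {
  # one pair's substitutions deleted from the data entirely: the search
  # must put that pair in the slow class with overwhelming support
  m <- fixture_mg94_model()
  a <- rep(1, 67)
  a[5] <- 1e-6                                   # pair 5 never substitutes
  gen <- codon_model(theta = m$theta, pi = m$pi, alpha = a, beta = 0.25)
  tr <- fixture_tree11()
  genes <- lapply(1:3, function(i)
    list(aln = simulate_alignment(tr, gen, 500, seed = 810 + i), tree = tr))
  run <- ga_search(genes, ga_config(P = 10, g_conv = 4, f_stagnant = 3,
                                    max_generations = 15, seed = 12,
                                    step1 = "fast"))
  av <- model_average(run)
  expect_equal(av$category[5], "SELECTED")
  expect_gte(av$weights[5, "SELECTED"], 0.9)
  expect_gt(run$delta_bic_null, 2)
})

test_that("search configuration defaults match the standard settings", {
  cfg <- ga_config()
  expect_equal(cfg$P, 32L)
  expect_equal(cfg$f_rel, 1e-6)
  expect_equal(cfg$f_stagnant, 25L)
  expect_equal(cfg$mu, 0.20)
  expect_equal(cfg$delta_bic, 0.01)
  expect_equal(cfg$g_conv, 100L)
  expect_error(ga_config(M = 1), "at least 2")
})
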