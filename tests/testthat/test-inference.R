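test_that("ML branch length matches a grid-search oracle on a tiny fit", {
  # two taxa, theta and pi fixed: the only structural parameters are the
  # two branch lengths (only their sum is identifiable) and beta
  m <- fixture_mg94_model()
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  aln <- simulate_alignment(tr, m, 120, seed = 21)
  fit <- fit_model(aln, tr, "MG94", pi = m$pi,
                   control = list(fix_theta = m$theta, max_restarts = 0))
  fitted_tree <- ape::read.tree(text = fit$estimates$tree)
  t_hat <- sum(fitted_tree$edge.length)
  # 1-D oracle: grid over total length at the fitted beta
  prep <- mssmodels:::prep_gene(aln, tr)
  mach <- mssmodels:::codon_machinery()
  grid <- seq(0.05, 1, by = 5e-4)
  ll <- vapply(grid, function(t) {
    mssmodels:::model_loglik_fast(prep, mach, m$theta, m$pi, rep(1, 67),
                                  fit$estimates$beta,
                                  rep(t / 2, nrow(prep$edge)))
  }, 0)
  expect_equal(t_hat, grid[which.max(ll)], tolerance = 1e-3)
  expect_gte(fit$logL, max(ll) - 1e-4)
})

test_that("fit records satisfy the information-criterion identities", {
  rec <- fixture_mg94_fit()
  expect_equal(rec$AIC, -2 * rec$logL + 2 * rec$n_params)
  expect_equal(rec$BIC, -2 * rec$logL + rec$n_params * log(rec$sample_size))
  expect_equal(rec$sample_size, 11 * 300 * 3)
  expect_equal(rec$estimates$omega, rec$estimates$beta)
})

test_that("likelihood is monotone along the MG94/SynREV/SynREVCodon chain", {
  aln <- fixture_mg94_sim()
  tr <- fixture_tree11()
  mg94 <- fixture_mg94_fit()
  sr <- fit_model(aln, tr, "SynREV", profile = "plugin", plugins = mg94)
  src <- fit_model(aln, tr, "SynREVCodon", profile = "plugin", plugins = mg94)
  expect_gte(sr$logL, mg94$logL - 1e-4)
  expect_gte(src$logL, sr$logL - 1e-4)
  # mean-one reporting and the omega interpretation
  expect_equal(mean(sr$estimates$alpha), 1, tolerance = 1e-9)
  expect_equal(mean(src$estimates$alpha), 1, tolerance = 1e-9)
  # SynREV ties within-amino-acid rates
  pairs <- enumerate_syn_pairs()
  expect_true(all(tapply(sr$estimates$alpha, pairs$aa,
                         function(x) diff(range(x))) < 1e-12))
})

test_that("likelihood ratio tests use the chi-square upper tail", {
  rec <- function(ll, df) structure(list(logL = ll, df_printed = df),
                                    class = "fit_record")
  eq <- lrt(rec(-100, 0), rec(-100, 17))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$df, 17)
  one <- lrt(rec(-105, 0), rec(-100, 0), df = 1)
  expect_equal(one$statistic, 10)
  expect_equal(one$p_value, 1.565402e-3, tolerance = 1e-6)
  expect_warning(lrt(rec(-100, 0), rec(-101, 17)), "clamped")
  expect_error(lrt(rec(-100, 17), rec(-90, 0)), "df")
})

test_that("discretization labels the top fraction neutral with stable ties", {
  set.seed(8)
  a <- stats::setNames(runif(67, 0.2, 2), enumerate_syn_pairs()$pair)
  v <- make_discretized_model(a, 0.15)
  neutral <- attr(v, "neutral_pairs")
  expect_length(neutral, 10)   # floor(67 * 0.15)
  expect_true(all(a[neutral] >= max(a[-neutral])))
  expect_equal(attr(v, "n_classes"), 2L)
  # degenerate ties: resolved by stable pair index, count preserved
  v2 <- make_discretized_model(rep(1, 67), 0.15)
  expect_identical(attr(v2, "neutral_pairs"), 1:10)
  expect_error(make_discretized_model(a, 1.0), "between 0 and 1")
  expect_error(make_discretized_model(a, 0), "between 0 and 1")
})

test_that("a fixed-alpha (empirical) model fit keeps the rates constant", {
  aln <- fixture_mg94_sim()
  tr <- fixture_tree11()
  a <- fixture_dispersed_model()$alpha
  rec <- fit_model(aln, tr, list(type = "fixed_alpha", alpha = a,
                                 name = "joint_codon_empirical"))
  expect_equal(unname(rec$estimates$alpha), unname(a))
  expect_equal(rec$n_free_alpha, 0L)
  expect_equal(rec$model_name, "joint_codon_empirical")
})

test_that("joint fit with one gene agrees with the single-gene plugin fit", {
  aln <- fixture_mg94_sim()
  tr <- fixture_tree11()
  jf <- joint_fit(list(list(aln = aln, tree = tr)), "SynREV", step1 = "full")
  single <- fit_model(aln, tr, "SynREV", profile = "plugin",
                      plugins = fixture_mg94_fit())
  keep <- single$estimates$alpha > 2e-6 & jf$alpha > 2e-6
  expect_gt(sum(keep), 50)
  expect_equal(unname(jf$alpha[keep]), unname(single$estimates$alpha[keep]),
               tolerance = 0.05)
  expect_s3_class(jf, "joint_fit_record")
  expect_equal(nrow(jf$per_gene), 1L)
})

test_that("genes failing validation are excluded from joint fits with warning", {
  aln <- fixture_mg94_sim()
  tr <- fixture_tree11()
  bad <- codon_alignment(c(a = "ATGAAA", b = "ATGAAG", c = "ATGAAA"),
                         check = FALSE)
  expect_warning(
    jf <- joint_fit(list(list(aln = aln, tree = tr),
                         list(aln = bad, tree = tr)), "SynREV",
                    step1 = "fast"),
    "excluded")
  expect_equal(nrow(jf$per_gene), 1L)
  expect_error(suppressWarnings(
    joint_fit(list(list(aln = bad, tree = tr)), "SynREV")), "no genes")
})

test_that("omega bias ordering holds when generating under dispersed rates", {
  # data from a dispersed SynREVCodon process: the MG94 fit inflates omega
  # most, SynREV less, SynREVCodon least (slightly deflated)
  gen <- fixture_dispersed_model()
  tr <- fixture_tree11()
  omega_true <- gen$beta / mean(gen$alpha)
  bias <- matrix(NA_real_, 5, 3,
                 dimnames = list(NULL, c("MG94", "SynREV", "SynREVCodon")))
  for (r in 1:5) {
    sim <- simulate_alignment(tr, gen, 300, seed = 870 + r)
    mg94 <- fit_model(sim, tr, "MG94", profile = "full")
    sr <- fit_model(sim, tr, "SynREV", profile = "plugin", plugins = mg94,
                    control = list(plugin_rounds = 2))
    src <- fit_model(sim, tr, "SynREVCodon", profile = "plugin",
                     plugins = mg94, control = list(plugin_rounds = 2))
    bias[r, ] <- (c(mg94$estimates$omega, sr$estimates$omega,
                    src$estimates$omega) - omega_true) / omega_true
  }
  m <- colMeans(bias)
  expect_gt(m[["MG94"]], m[["SynREV"]])
  expect_gt(m[["MG94"]], m[["SynREVCodon"]])
  expect_gt(m[["MG94"]], 0)
  # separating the two MSS fitters' small residual biases from each other
  # needs replicate counts beyond unit-test scale; the strong contrasts
  # against the rate-constant fit are what the property pins down
})

test_that("joint fits detect shared amino-acid rate variation and stay
           calibrated on homogeneous data", {
  tr <- fixture_tree11()
  # shared SynREV truth with dispersed amino-acid rates
  pairs <- enumerate_syn_pairs()
  set.seed(55)
  aa_rate <- stats::setNames(exp(runif(18, log(0.3), log(3))),
                             unique(pairs$aa))
  a <- unname(aa_rate[pairs$aa]); a <- a / mean(a)
  gen <- codon_model(theta = fixture_theta(), pi = fixture_pi(), alpha = a,
                     beta = 0.3, constraint = "mean_one")
  genes <- lapply(1:5, function(i)
    list(aln = simulate_alignment(tr, gen, 250, seed = 910 + i), tree = tr))
  jf <- joint_fit(genes, "SynREV", step1 = "fast")
  expect_lt(jf$lrt$p_value, 0.05)
  expect_gt(stats::cor(jf$alpha, a, method = "spearman"), 0.7)

  # MG94-generated genes: shared rate estimates within 3 SE of 1
  genes0 <- lapply(1:4, function(i)
    list(aln = simulate_alignment(tr, fixture_mg94_model(), 250,
                                  seed = 930 + i), tree = tr))
  jf0 <- joint_fit(genes0, "SynREV", step1 = "fast")
  cls <- as.integer(factor(pairs$aa, levels = unique(pairs$aa)))
  class_rates <- tapply(jf0$alpha, cls, mean)
  # observed-information SEs on the log class rates (scalers held fixed)
  mg94 <- lapply(genes0, function(g) fit_model(g$aln, g$tree, "MG94",
                                               profile = "fast"))
  pg <- mssmodels:::build_plugin_genes(genes0, mg94, genetic_code_table())
  mach <- mssmodels:::codon_machinery()
  scalers <- jf0$per_gene$scaler
  # with per-gene beta frozen at the plug-ins, the unnormalized rates are
  # identifiable, so the observed information is nonsingular
  obj <- function(lr) {
    -mssmodels:::cpp_partition_loglik(pg, mach$transitions, mach$codon_nt,
                                      cls, exp(lr), scalers)
  }
  H <- stats::optimHess(log(as.numeric(class_rates)), obj)
  se <- sqrt(diag(solve(H)))
  z <- abs(log(as.numeric(class_rates))) / se
  expect_gte(mean(z <= 3), 0.9)
})
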