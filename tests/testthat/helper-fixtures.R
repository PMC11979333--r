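# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Drosophila-like 11-taxon tree, total length ~0.5 substitutions/nt site
fixture_tree11 <- function() memo("tree11", {
  set.seed(1810)
  tr <- ape::rtree(11)
  tr$edge.length <- tr$edge.length * (0.5 / sum(tr$edge.length))
  tr
})

fixture_theta <- function() c(AC = 0.6, AG = 1, AT = 0.35, CG = 0.5,
                              CT = 1.1, GT = 0.4)

fixture_pi <- function() {
  matrix(c(.30, .20, .28, .22,
           .28, .24, .22, .26,
           .22, .30, .24, .24), 3, 4, byrow = TRUE,
         dimnames = list(paste0("pos", 1:3), c("A", "C", "G", "T")))
}

# MG94 generating model (omega = 0.25)
fixture_mg94_model <- function() memo("mg94_model", {
  codon_model(theta = fixture_theta(), pi = fixture_pi(), alpha = 1,
              beta = 0.25)
})

# SynREVCodon generating model: dispersed rates, log-uniform in [0.25, 4],
# mean-normalized
fixture_dispersed_model <- function(seed = 404) memo(paste0("disp", seed), {
  set.seed(seed)
  a <- exp(stats::runif(67, log(0.25), log(4)))
  a <- a / mean(a)
  codon_model(theta = fixture_theta(), pi = fixture_pi(), alpha = a,
              beta = 0.25, constraint = "mean_one")
})

# a random valid model for property checks
random_model <- function(seed) {
  set.seed(seed)
  th <- exp(stats::runif(6, -1, 1)); th[2] <- 1
  names(th) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  pim <- matrix(stats::rgamma(12, 5, 1), 3, 4)
  pim <- pim / rowSums(pim)
  codon_model(theta = th, pi = pim, alpha = exp(stats::runif(67, -1, 1)),
              beta = exp(stats::runif(1, -2, 0)))
}

# simulated MG94 alignment + its full MG94 fit (expensive; shared)
fixture_mg94_sim <- function() memo("mg94_sim", {
  simulate_alignment(fixture_tree11(), fixture_mg94_model(), 300, seed = 2024)
})

fixture_mg94_fit <- function() memo("mg94_fit", {
  fit_model(fixture_mg94_sim(), fixture_tree11(), "MG94", profile = "full")
})
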