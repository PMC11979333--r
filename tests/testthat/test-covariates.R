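test_that("SNP density is count over residue count, averaged across genes", {
  d <- snp_density(list(c("AAA:AAG" = 2)), list(c(K = 10)))
  expect_equal(unname(d[["AAA:AAG"]]), 0.2)
  # linear in counts
  d2 <- snp_density(list(c("AAA:AAG" = 6)), list(c(K = 10)))
  expect_equal(unname(d2[["AAA:AAG"]]), 3 * d[["AAA:AAG"]])
  # plain mean across genes
  d3 <- snp_density(list(c("AAA:AAG" = 2), c("AAA:AAG" = 4)),
                    list(c(K = 10), c(K = 10)))
  expect_equal(unname(d3[["AAA:AAG"]]), 0.3)
  # zero SNPs everywhere -> all densities zero
  z <- snp_density(list(c("AAA:AAG" = 0, "GCA:GCC" = 0)),
                   list(c(K = 5, A = 7)))
  expect_true(all(z == 0))
  expect_error(snp_density(list(c("AAA:AAG" = 1)), list(c(K = 0))),
               "no K residues")
})

test_that("a density fixture built from preset rates recovers their order", {
  pairs <- enumerate_syn_pairs()
  set.seed(5)
  alpha <- exp(runif(67, -1, 1))
  genes <- lapply(1:6, function(g) {
    aa_n <- stats::setNames(sample(30:60, 18), unique(pairs$aa))
    snp <- round(alpha * aa_n[pairs$aa] * 0.2 + rpois(67, 0.5))
    list(snp = stats::setNames(snp, pairs$pair), aa = aa_n)
  })
  d <- snp_density(lapply(genes, `[[`, "snp"), lapply(genes, `[[`, "aa"))
  rc <- rank_correlation(d, stats::setNames(alpha, pairs$pair))
  expect_gt(rc$rho, 0.9)
})

test_that("tRNA wobble assignments copy the designated partner pools", {
  raw <- c(GAA = 40, GCT = 12, GCA = 7, CCG = 9, TCC = 5, GCC = 11)
  # GAA decodes TTC (Phe); GCT -> AGC (Ser); GCA -> TGC (Cys);
  # TCG? CCG -> CGG is an anticodon whose codon is CGG? rev-comp(CCG)=CGG
  pools <- build_trna_pools(raw)
  ab <- pools$abundance
  expect_equal(ab[["TTT"]], ab[["TTC"]])   # Phe via wobble rule
  expect_equal(ab[["AGT"]], ab[["AGC"]])   # Ser
  expect_equal(ab[["TGT"]], ab[["TGC"]])   # Cys
  expect_equal(pools$provenance[["TTT"]], "wobble_assigned")
})

test_that("CGG/GGG/GGT receive the pools of CGA/GGA/GGC", {
  raw <- c(TCG = 20,   # decodes CGA (Arg)
           TCC = 15,   # decodes GGA (Gly)
           GCC = 9)    # decodes GGC (Gly)
  pools <- build_trna_pools(raw)
  ab <- pools$abundance
  expect_equal(ab[["CGG"]], ab[["CGA"]])
  expect_equal(ab[["GGG"]], ab[["GGA"]])
  expect_equal(ab[["GGT"]], ab[["GGC"]])
})

test_that("inosine expansion adds the wobble-A abundance to A/C-ending codons", {
  raw <- c(AGC = 30)   # Ala anticodon, wobble A: cognate GCT
  pools <- build_trna_pools(raw)
  ab <- pools$abundance
  expect_equal(ab[["GCT"]], 30)            # direct (A wobble covers U-ending)
  expect_equal(ab[["GCA"]], 30)            # inosine expansion
  expect_equal(ab[["GCC"]], 30)
  expect_equal(pools$provenance[["GCA"]], "inosine_expanded")
  expect_false("GCG" %in% names(ab))       # G-ending not covered by inosine
})

test_that("queuosine expansion covers the U-ending codons of His/Asp/Asn/Tyr", {
  raw <- c(GTG = 18)   # His anticodon, wobble G: cognate CAC
  pools <- build_trna_pools(raw)
  expect_equal(pools$abundance[["CAT"]], 18)
  expect_equal(pools$provenance[["CAT"]], "queuosine_expanded")
})

test_that("a synthetic covering input leaves whole amino acids fully pooled", {
  # one anticodon per inosine family + queuosine families + 2-fold families
  raw <- c(AGC = 10, AGG = 11, ACG = 12, AGA = 13, AAG = 14, AAC = 15,
           AAT = 16, AGT = 17,                 # inosine wobble-A set
           GTG = 5, GTC = 6, GTT = 7, GTA = 8, # Gln? no: His Asp Asn Tyr
           GAA = 4, GCA = 3, TCG = 9, TCC = 2, GCC = 2.5)
  expect_warning(pools <- build_trna_pools(c(raw, XXX = 1)), "unknown")
  ab <- pools$abundance
  code <- genetic_code_table()
  aa <- code$codon_to_aa
  covered_aas <- unique(aa[names(ab)])
  for (a in c("A", "P", "R", "V", "T", "H", "D", "N", "Y", "F", "C")) {
    expect_true(a %in% covered_aas)
    if (a %in% c("A", "P", "V", "T")) {
      miss <- setdiff(names(aa)[aa == a], c(names(ab), "GCG", "CCG", "GTG",
                                            "ACG"))
      expect_length(miss, 0)
    }
  }
})

test_that("abundance ratios are max/min, symmetric and scale-invariant", {
  pairs <- enumerate_syn_pairs()
  pools <- structure(list(abundance = c(AAA = 4, AAG = 1, GCA = 3, GCC = 3),
                          provenance = NULL), class = "trna_pools")
  r <- abundance_ratio(pools, pairs)
  expect_equal(unname(r[["AAA:AAG"]]), 4)
  expect_equal(unname(r[["GCA:GCC"]]), 1)
  pools10 <- pools; pools10$abundance <- pools10$abundance * 10
  expect_equal(abundance_ratio(pools10, pairs), r, ignore_attr = TRUE)
  pools0 <- pools; pools0$abundance[["AAG"]] <- 0
  expect_warning(r0 <- abundance_ratio(pools0, pairs), "zero-abundance")
  expect_false("AAA:AAG" %in% names(r0))
})

test_that("rank correlation matches the exact rank formula and edge cases", {
  a <- stats::setNames(1:10, paste0("p", 1:10))
  expect_equal(rank_correlation(a, a)$rho, 1)
  expect_equal(rank_correlation(a, -a)$rho, -1)
  b <- a; b[c(4, 5)] <- b[c(5, 4)]   # one adjacent swap
  rho_oracle <- 1 - 6 * sum((rank(a) - rank(b))^2) / (10 * (10^2 - 1))
  expect_equal(rank_correlation(a, b)$rho, rho_oracle)
  expect_error(rank_correlation(a[1:4], a[1:4]), "fewer than 5")
  expect_error(rank_correlation(a, stats::setNames(rep(1, 10), names(a))),
               "constant")
})

test_that("high decoder-pool imbalance tracks low fitted synonymous rates", {
  # construct pools whose per-pair abundance ratio is ~1/alpha of a
  # dispersed generating model, simulate, refit, and check the sign of the
  # rank correlation between fitted rates and ratios
  gen <- fixture_dispersed_model()
  tr <- fixture_tree11()
  sim <- simulate_alignment(tr, gen, 450, seed = 2718)
  mg94 <- fit_model(sim, tr, "MG94", profile = "fast")
  rec <- fit_model(sim, tr, "SynREVCodon", profile = "plugin", plugins = mg94,
                   control = list(plugin_rounds = 2))
  ratios <- stats::setNames(1 / pmin(gen$alpha, 1), names(gen$alpha))
  rc <- rank_correlation(rec$estimates$alpha, ratios)
  expect_lt(rc$rho, 0)
  expect_lt(rc$p_value, 0.01)
})
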