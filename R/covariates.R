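#' Per-pair synonymous SNP density across genes
#'
#' For each gene the density of a synonymous codon pair is its SNP count
#' divided by the count of the corresponding amino acid in that gene;
#' densities are then averaged across genes (plain mean) per pair.
#'
#' @param per_gene_counts List over genes of named numeric vectors: SNP
#'   count per pair label (`"AAA:AAG"` style).
#' @param per_gene_aa_counts List over genes of named numeric vectors:
#'   residue count per amino-acid symbol.
#' @param code Genetic code.
#' @return Named numeric vector over the pairs present in the input:
#'   mean SNP density per pair.
#' @export
snp_density <- function(per_gene_counts, per_gene_aa_counts,
                        code = genetic_code_table()) {
  if (length(per_gene_counts) != length(per_gene_aa_counts)) {
    stop("per-gene SNP and amino-acid count lists must have equal length")
  }
  pairs <- enumerate_syn_pairs(code)
  dens <- lapply(seq_along(per_gene_counts), function(g) {
    cnt <- per_gene_counts[[g]]
    aan <- per_gene_aa_counts[[g]]
    if (any(cnt < 0) || any(aan < 0)) stop("counts must be nonnegative")
    bad <- setdiff(names(cnt), pairs$pair)
    if (length(bad)) stop(sprintf("unknown pair label(s): %s",
                                  paste(bad, collapse = ", ")))
    vapply(names(cnt), function(p) {
      aa <- pairs[p, "aa"]
      na <- if (aa %in% names(aan)) aan[[aa]] else 0
      if (na == 0) {
        if (cnt[[p]] > 0) stop(sprintf(
          "gene %d: %d SNPs for pair %s but no %s residues", g, cnt[[p]], p, aa))
        return(NA_real_)
      }
      cnt[[p]] / na
    }, 0)
  })
  all_pairs <- unique(unlist(lapply(dens, names)))
  out <- vapply(all_pairs, function(p) {
    vals <- unlist(lapply(dens, function(d) d[[p]]))
    mean(vals, na.rm = TRUE)
  }, 0)
  out[pairs$pair[pairs$pair %in% names(out)]]
}

# Anticodons whose wobble A is modified to inosine in eukaryotes
# (decoding expands to U-, C- and A-ending codons).
INOSINE_ANTICODONS <- c("AGC", "AGG", "ACG", "AGA", "AAG", "AAC", "AAT", "AGT")
# Amino acids whose wobble-G anticodons carry queuosine (decoding expands
# from the cognate C-ending codon to the U-ending codon).
QUEUOSINE_AAS <- c("H", "D", "N", "Y")
# Wobble-rule assignments for the codons left without a direct decoder:
# each target codon receives the pool of its listed partner.
WOBBLE_ASSIGN <- c(TTT = "TTC", AGT = "AGC", TGT = "TGC",
                   CGG = "CGA", GGG = "GGA", GGT = "GGC")

#' @noRd
revcomp_codon <- function(anticodon) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(anticodon, "")[[1]]]), collapse = "")
}

#' Build per-codon tRNA decoding pools from anticodon abundances
#'
#' Starts from normalized per-anticodon transcript counts (counts per
#' million; no length normalization). Expansion happens additively and in
#' order: (1) inosine-modified wobble-A anticodons add their abundance to
#' the pools of the synonymous A- and C-ending codons (the A wobble
#' already serves the U-ending codon); (2) queuosine-modified wobble-G
#' anticodons of His/Asp/Asn/Tyr add their abundance to the cognate
#' U-ending codon; (3) the six wobble-rule assignments give UUU, AGU,
#' UGU, CGG, GGG and GGU the pool of their designated partner codon.
#'
#' @param raw Named numeric vector: normalized count per anticodon
#'   (DNA or RNA letters).
#' @param code Genetic code.
#' @return A `trna_pools` object: list with `abundance` (named vector
#'   over covered codons) and `provenance` (one of `direct`,
#'   `inosine_expanded`, `queuosine_expanded`, `wobble_assigned`).
#' @export
build_trna_pools <- function(raw, code = genetic_code_table()) {
  names(raw) <- toupper(gsub("U", "T", names(raw)))
  if (any(raw < 0)) stop("anticodon counts must be nonnegative")
  known <- grepl("^[ACGT]{3}$", names(raw))
  if (any(!known)) {
    warning(sprintf("skipping unknown anticodon(s): %s",
                    paste(names(raw)[!known], collapse = ", ")))
    raw <- raw[known]
  }
  sense <- sense_codons(code)
  aa <- code$codon_to_aa
  abundance <- stats::setNames(numeric(0), character(0))
  provenance <- character(0)
  add <- function(codon, amount, how) {
    if (!codon %in% names(abundance)) {
      abundance[[codon]] <<- 0
      provenance[[codon]] <<- how
    }
    abundance[[codon]] <<- abundance[[codon]] + amount
  }
  # direct cognate codons
  for (ac in names(raw)) {
    codon <- revcomp_codon(ac)
    if (!codon %in% sense) {
      warning(sprintf("anticodon %s decodes a stop codon; skipped", ac))
      next
    }
    add(codon, raw[[ac]], "direct")
  }
  # inosine expansion: add to synonymous A- and C-ending codons
  for (ac in intersect(INOSINE_ANTICODONS, names(raw))) {
    cognate <- revcomp_codon(ac)            # U-ending codon
    stem <- substr(cognate, 1, 2)
    for (end in c("A", "C")) {
      target <- paste0(stem, end)
      if (target %in% sense && aa[[target]] == aa[[cognate]]) {
        add(target, raw[[ac]], "inosine_expanded")
      }
    }
  }
  # queuosine expansion: wobble-G anticodons of His/Asp/Asn/Tyr also
  # decode the U-ending codon
  for (ac in names(raw)) {
    if (substr(ac, 1, 1) != "G") next
    cognate <- revcomp_codon(ac)            # C-ending codon
    if (!cognate %in% sense || !aa[[cognate]] %in% QUEUOSINE_AAS) next
    target <- paste0(substr(cognate, 1, 2), "T")
    if (target %in% sense && aa[[target]] == aa[[cognate]]) {
      add(target, raw[[ac]], "queuosine_expanded")
    }
  }
  # wobble-rule assignments for the remaining undecoded codons
  for (target in names(WOBBLE_ASSIGN)) {
    donor <- WOBBLE_ASSIGN[[target]]
    if (target %in% names(abundance) || !donor %in% names(abundance)) next
    abundance[[target]] <- abundance[[donor]]
    provenance[[target]] <- "wobble_assigned"
  }
  structure(list(abundance = abundance, provenance = provenance),
            class = "trna_pools")
}

#' Decoder-pool abundance ratio per synonymous pair
#'
#' The ratio is always the more abundant decoder pool over the less
#' abundant one (>= 1 by construction, symmetric in the pair's codons).
#' Pairs with a missing or zero-abundance pool are omitted with a
#' warning.
#'
#' @param pools A `trna_pools` object.
#' @param pairs A `syn_pair_table` (default: universal code).
#' @return Named numeric vector of ratios over the covered pairs.
#' @export
abundance_ratio <- function(pools, pairs = enumerate_syn_pairs()) {
  ab <- pools$abundance
  out <- numeric(0)
  dropped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    c1 <- pairs$codon1[i]; c2 <- pairs$codon2[i]
    if (!c1 %in% names(ab) || !c2 %in% names(ab)) {
      dropped <- c(dropped, pairs$pair[i]); next
    }
    a <- ab[[c1]]; b <- ab[[c2]]
    if (min(a, b) <= 0) {
      warning(sprintf("pair %s omitted: zero-abundance pool", pairs$pair[i]))
      next
    }
    out[[pairs$pair[i]]] <- max(a, b) / min(a, b)
  }
  if (length(dropped)) {
    attr(out, "missing_pairs") <- dropped
  }
  out
}

#' Spearman rank correlation between two per-pair covariates
#'
#' @param a,b Named numeric vectors keyed by pair label; the correlation
#'   uses the shared pairs (at least 5 required).
#' @return List with `rho`, `p_value`, `n` (shared pairs).
#' @export
rank_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 5) stop("fewer than 5 shared pairs")
  x <- as.numeric(a[shared]); y <- as.numeric(b[shared])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant covariate")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}
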