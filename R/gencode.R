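#' Genetic code tables
#'
#' Returns a genetic code table mapping all 64 codons to one-letter amino
#' acid symbols (`*` for stop). The built-in universal (standard) code is
#' taken from [Biostrings::GENETIC_CODE]; alternate codes can be supplied
#' as a two-column text table of (codon, amino acid) via [read_code_table()].
#'
#' @param name Code identifier; only `"universal"` is built in.
#' @return An object of class `genetic_code`: a named list with `name` and
#'   `codon_to_aa` (named character vector of length 64).
#' @export
#' @examples
#' code <- genetic_code_table()
#' sum(code$codon_to_aa == "*") # 3 stops
genetic_code_table <- function(name = "universal") {
  if (!identical(name, "universal")) {
    stop("only the 'universal' code is built in; use read_code_table() for others")
  }
  new_genetic_code(name, Biostrings::GENETIC_CODE)
}

new_genetic_code <- function(name, codon_to_aa) {
  codon_to_aa <- toupper(gsub("U", "T", codon_to_aa))
  names(codon_to_aa) <- toupper(gsub("U", "T", names(codon_to_aa)))
  all64 <- all_codons()
  if (length(codon_to_aa) != 64L || !setequal(names(codon_to_aa), all64)) {
    stop("malformed code table: exactly the 64 codons must be mapped")
  }
  codon_to_aa <- codon_to_aa[all64]
  aas <- unique(codon_to_aa[codon_to_aa != "*"])
  if (!all(aas %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("malformed code table: unknown amino-acid symbol")
  }
  structure(list(name = name, codon_to_aa = codon_to_aa),
            class = "genetic_code")
}

#' Read a genetic code from a two-column text table
#'
#' @param path Path to a whitespace- or tab-delimited file with columns
#'   codon and amino-acid symbol (`*` = stop), one row per codon.
#' @param name Identifier for the resulting code.
#' @return A `genetic_code` object.
#' @export
read_code_table <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("code table must have two columns: codon, amino acid")
  new_genetic_code(name, stats::setNames(tab[[2]], tab[[1]]))
}

NUCS <- c("A", "C", "G", "T")

all_codons <- function() {
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

#' Sense codons of a genetic code
#' @param code A `genetic_code` object.
#' @return Character vector of sense (non-stop) codons, alphabetical.
#' @export
sense_codons <- function(code = genetic_code_table()) {
  names(code$codon_to_aa)[code$codon_to_aa != "*"]
}

#' Enumerate one-step synonymous codon pairs
#'
#' Builds the catalogue of unordered codon pairs \{x, y\} that encode the
#' same amino acid and differ at exactly one nucleotide position. These
#' pairs index the per-class synonymous rates of MSS models; the universal
#' code yields 67 pairs. Pairs are sorted lexicographically by
#' (amino acid, codon1, codon2) with codon1 < codon2, giving every pair a
#' stable index used by model vectors and rate maps.
#'
#' @param code A `genetic_code` object.
#' @return A `syn_pair_table`: data frame with columns `codon1`, `codon2`,
#'   `aa`, `pair` (label `"XXX:YYY"`), and `index` (1-based stable index).
#' @export
#' @examples
#' sp <- enumerate_syn_pairs()
#' nrow(sp)                      # 67 for the universal code
#' sum(sp$aa == "L")             # 9 leucine pairs
enumerate_syn_pairs <- function(code = genetic_code_table()) {
  sense <- sense_codons(code)
  aa <- code$codon_to_aa
  out <- list()
  for (x in sense) {
    xs <- strsplit(x, "")[[1]]
    for (p in 1:3) {
      for (n in NUCS[NUCS != xs[p]]) {
        ys <- xs; ys[p] <- n
        y <- paste(ys, collapse = "")
        if (x < y && aa[[y]] != "*" && aa[[y]] == aa[[x]]) {
          out[[length(out) + 1L]] <- c(x, y, aa[[x]])
        }
      }
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(codon1 = m[, 1], codon2 = m[, 2], aa = m[, 3],
                   stringsAsFactors = FALSE)
  df <- df[order(df$aa, df$codon1, df$codon2), , drop = FALSE]
  df$pair <- paste0(df$codon1, ":", df$codon2)
  df$index <- seq_len(nrow(df))
  rownames(df) <- df$pair
  class(df) <- c("syn_pair_table", "data.frame")
  df
}

#' Classify the relationship between two codons
#'
#' Mirrors the row structure of the instantaneous rate definition: one-step
#' synonymous and one-step nonsynonymous changes have nonzero rate, all
#' multi-nucleotide changes have rate zero, and changes to or from a stop
#' codon are outside the sense-codon state space.
#'
#' @param x,y Length-3 nucleotide strings (ACGT).
#' @param code A `genetic_code` object.
#' @return One of `"identical"`, `"synonymous_one_step"`,
#'   `"nonsynonymous_one_step"`, `"multistep"`, `"involves_stop"`.
#' @export
#' @examples
#' classify_substitution("AGC", "AGT") # synonymous_one_step
#' classify_substitution("TCC", "AGC") # multistep
classify_substitution <- function(x, y, code = genetic_code_table()) {
  x <- toupper(x); y <- toupper(y)
  if (nchar(x) != 3L || nchar(y) != 3L ||
      grepl("[^ACGT]", x) || grepl("[^ACGT]", y)) {
    stop("codons must be length-3 ACGT strings")
  }
  aa <- code$codon_to_aa
  if (aa[[x]] == "*" || aa[[y]] == "*") return("involves_stop")
  if (x == y) return("identical")
  ndiff <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  if (ndiff > 1L) return("multistep")
  if (aa[[x]] == aa[[y]]) "synonymous_one_step" else "nonsynonymous_one_step"
}

#' Canonicalize a rate-class assignment vector
#'
#' A partition of the D synonymous pairs into M rate classes is encoded by
#' an integer vector with entries in `[0, M)`. Many vectors encode the same
#' partition; the canonical ("class-sorted") representative is the one in
#' which the first occurrence of class 0 precedes the first occurrence of
#' class 1, and so on. For example `(1,0,0,1,0)` and `(0,1,1,0,1)` encode
#' the same two-block partition and the latter is canonical.
#'
#' @param v Integer vector of nonnegative class labels.
#' @return A `model_vector`: integer vector (0-based classes, canonical)
#'   with attribute `n_classes` = number of distinct classes.
#' @export
#' @examples
#' canonicalize_model_vector(c(1, 0, 0, 1, 0)) # 0 1 1 0 1
canonicalize_model_vector <- function(v) {
  v <- as.integer(v)
  if (any(is.na(v)) || any(v < 0L)) stop("class labels must be nonnegative integers")
  if (length(v) == 0L) {
    return(structure(integer(0), n_classes = 0L, class = "model_vector"))
  }
  first <- unique(v)           # classes in order of first occurrence
  relab <- match(v, first) - 1L
  structure(relab, n_classes = length(first), class = "model_vector")
}

#' Number of rate classes in a model vector
#' @param v A `model_vector` or plain integer vector.
#' @return Integer count of distinct classes.
#' @export
n_rate_classes <- function(v) length(unique(as.integer(v)))
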