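#' Construct a codon alignment object
#'
#' @param seqs Named character vector of aligned nucleotide sequences
#'   (equal lengths, multiple of 3; gaps `-` and ambiguity codes allowed).
#' @param check Validate frame and in-frame stop codons (default `TRUE`).
#' @param code Genetic code used for the stop-codon check.
#' @return A `codon_alignment`: list with `taxa`, `seqs`, `n_codons`.
#' @export
codon_alignment <- function(seqs, check = TRUE, code = genetic_code_table()) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  nms <- make.unique(names(seqs))
  seqs <- toupper(gsub("U", "T", as.character(seqs)))
  names(seqs) <- nms
  lens <- nchar(seqs)
  if (check) {
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[lens != lens[1]][1]
      stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                   bad, nchar(seqs[[bad]]), lens[1]))
    }
    if (lens[1] %% 3L != 0L) {
      stop(sprintf("alignment length %d is not a multiple of 3", lens[1]))
    }
    stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
    for (nm in names(seqs)) {
      cod <- codon_split(seqs[[nm]])
      hit <- which(cod %in% stops)
      if (length(hit)) {
        stop(sprintf("in-frame stop codon %s at codon %d of record '%s'",
                     cod[hit[1]], hit[1], nm))
      }
    }
  }
  structure(list(taxa = names(seqs), seqs = seqs,
                 n_codons = as.integer(lens[1] %/% 3L)),
            class = "codon_alignment")
}

codon_split <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Read a codon-aware alignment from FASTA
#'
#' Accepts plain FASTA, or FASTA with the gene tree embedded after the
#' sequence records as one or more Newick lines (a layout used by
#' multi-gene file lists); the embedded tree, if any, is attached as the
#' `tree` attribute.
#'
#' @param path FASTA file path.
#' @param code Genetic code for validation.
#' @return A `codon_alignment` (with attribute `tree`, a `phylo`, when a
#'   tree is embedded in the file).
#' @export
read_codon_alignment <- function(path, code = genetic_code_table()) {
  lines <- readLines(path, warn = FALSE)
  is_nwk <- !grepl("^>", lines) & grepl("^\\s*\\(", lines)
  fasta_lines <- lines[!is_nwk]
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(fasta_lines, tf)
  ss <- Biostrings::readBStringSet(tf)
  if (length(ss) == 0L) stop(sprintf("no FASTA records in '%s'", path))
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  aln <- codon_alignment(seqs, check = TRUE, code = code)
  if (any(is_nwk)) {
    attr(aln, "tree") <- ape::read.tree(text = paste(lines[is_nwk], collapse = ""))
  }
  aln
}

#' Write a codon alignment to FASTA
#' @param aln A `codon_alignment`.
#' @param path Output file path.
#' @export
write_codon_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(path)
}

#' Apply alignment-level analysis filters
#'
#' Checks the filters that can be evaluated from an alignment alone:
#' nucleotide length a multiple of 3, at least 4 sequences, and no
#' in-frame stop codons. Returns the decision and reasons rather than
#' erroring, so callers can log rejections.
#'
#' @param aln A `codon_alignment` (or named character vector of sequences).
#' @param code Genetic code.
#' @return List with `accept` (logical) and `reasons` (character vector).
#' @export
validate_for_analysis <- function(aln, code = genetic_code_table()) {
  if (!inherits(aln, "codon_alignment")) {
    aln <- tryCatch(codon_alignment(aln, check = FALSE),
                    error = function(e) stop(conditionMessage(e)))
  }
  reasons <- character(0)
  lens <- nchar(aln$seqs)
  if (length(unique(lens)) != 1L) {
    reasons <- c(reasons, "ragged sequence lengths")
  } else if (lens[1] %% 3L != 0L) {
    reasons <- c(reasons, sprintf("length %d not a multiple of 3", lens[1]))
  }
  if (length(aln$seqs) < 4L) {
    reasons <- c(reasons, sprintf("fewer than 4 sequences (%d)", length(aln$seqs)))
  }
  stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
  if (length(unique(lens)) == 1L && lens[1] %% 3L == 0L) {
    for (nm in aln$taxa) {
      if (any(codon_split(aln$seqs[[nm]]) %in% stops)) {
        reasons <- c(reasons, sprintf("stop codon in record '%s'", nm))
      }
    }
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Read a phylogeny from a Newick file
#'
#' Branch lengths are required to be nonnegative; missing or `NA` lengths
#' are replaced by `default_blen` (they are starting values that the
#' optimizer refines). Units are expected substitutions per nucleotide
#' site.
#'
#' @param path Newick file path (or a `phylo` object, returned as-is after
#'   branch-length filling).
#' @param default_blen Initial value for missing branch lengths.
#' @return An `ape` `phylo` object.
#' @export
read_tree <- function(path, default_blen = 0.1) {
  tree <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("could not parse Newick in '%s'", path))
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_blen, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- default_blen
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Match a tree to an alignment
#'
#' Tips absent from the alignment are pruned with a warning; an alignment
#' taxon absent from the tree is an error.
#'
#' @param tree A `phylo`.
#' @param aln A `codon_alignment`.
#' @return The pruned `phylo`.
#' @export
match_tree_alignment <- function(tree, aln) {
  missing_tax <- setdiff(aln$taxa, tree$tip.label)
  if (length(missing_tax)) {
    stop(sprintf("taxa in alignment but not in tree: %s",
                 paste(missing_tax, collapse = ", ")))
  }
  extra <- setdiff(tree$tip.label, aln$taxa)
  if (length(extra)) {
    warning(sprintf("pruning %d tree tip(s) absent from alignment: %s",
                    length(extra), paste(extra, collapse = ", ")))
    tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Read a gene file list
#'
#' One gene per line: either `alignment<TAB>tree` (paired files) or a
#' single path to a file holding the alignment with its tree embedded
#' after the FASTA records.
#'
#' @param path Text file path.
#' @param code Genetic code.
#' @return List of genes; each element is `list(aln = codon_alignment,
#'   tree = phylo, source = path(s))`.
#' @export
read_filelist <- function(path, code = genetic_code_table()) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    base <- dirname(path)
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    aln <- read_codon_alignment(resolve(parts[1]), code = code)
    tree <- if (length(parts) >= 2L) {
      read_tree(resolve(parts[2]))
    } else {
      tr <- attr(aln, "tree")
      if (is.null(tr)) stop(sprintf("no tree for gene '%s' (embed one or use a TAB-separated pair)", parts[1]))
      read_tree(tr)
    }
    list(aln = aln, tree = match_tree_alignment(tree, aln), source = parts)
  })
}

#' Serialize a fit, joint-fit or GA-run record to JSON
#'
#' GA-run records include every model considered (canonical encoding, BIC,
#' synonymous-rate MLEs); the matching [read_results()] restores the
#' record losslessly.
#'
#' @param record A `fit_record`, `joint_fit_record`, or `ga_run_record`.
#' @param path Output path.
#' @export
write_results <- function(record, path) {
  cls <- intersect(class(record), c("fit_record", "joint_fit_record", "ga_run_record"))
  if (!length(cls)) stop("record must be a fit_record, joint_fit_record or ga_run_record")
  if (identical(cls[1], "ga_run_record") && length(record$models) == 0L) {
    stop("empty GA run: no models evaluated")
  }
  # jsonlite writes named atomic vectors as bare arrays; promote them to
  # objects (and data frames to column lists) so names survive the trip
  prep <- function(x) {
    if (is.data.frame(x)) return(lapply(as.list(x), prep))
    if (is.list(x)) return(lapply(x, prep))
    if (is.atomic(x) && !is.null(names(x)) && length(x) > 1L) return(as.list(x))
    x
  }
  payload <- list(record_class = cls[1], record = prep(unclass(record)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a results record written by [write_results()]
#' @param path JSON file path.
#' @return The restored record with its original class.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  rec <- payload$record
  cls <- payload$record_class
  unvec <- function(x, mode = "double") {
    out <- unlist(x)
    storage.mode(out) <- mode
    out
  }
  if (identical(cls, "fit_record")) {
    est <- rec$estimates
    est$theta <- unvec(est$theta)
    est$alpha <- unvec(est$alpha)
    est$pi <- matrix(as.numeric(unlist(est$pi)), nrow = 3,
                     dimnames = list(paste0("pos", 1:3), NUCS))
    rec$estimates <- est
  } else if (identical(cls, "joint_fit_record")) {
    rec$alpha <- unvec(rec$alpha)
    rec$per_gene <- as.data.frame(lapply(rec$per_gene, unlist))
  } else if (identical(cls, "ga_run_record")) {
    rec$models <- lapply(rec$models, function(m) {
      m$vector <- unvec(m$vector, "integer")
      m$rates <- unvec(m$rates)
      m
    })
    if (!is.null(rec[["best"]])) {
      rec[["best"]]$vector <- unvec(rec[["best"]]$vector, "integer")
      rec[["best"]]$rates <- unvec(rec[["best"]]$rates)
    }
  }
  structure(rec, class = cls)
}
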