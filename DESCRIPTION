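Package: mssmodels
Title: Multiclass Synonymous Substitution Models for Codon Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codon substitution models in which each class of synonymous
    change receives its own relative rate (multiclass synonymous
    substitution, MSS, models), fitted by phylogenetic maximum likelihood
    per gene and jointly across genes. Includes the MG94xREV-based rate
    matrix construction with CF3x4 equilibrium frequencies, a CHC genetic
    algorithm that learns the partition of synonymous codon pairs into
    rate classes with BIC-weight model averaging, a forward Wright-Fisher
    population simulator of codon sequences under selection on synonymous
    codon usage, and covariate operators (per-codon-pair SNP densities and
    tRNA decoding-pool abundance ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
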