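Package: lncorf
Title: Emergence, Retention and Selection of De Novo Genes Born from lncRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the origination of protein-coding genes from
    ancestral long non-coding RNAs in primates. The package implements the
    three stages of the analysis: emergence (ORF presence/absence calls from
    codon-level alignments, detection of common ancestral disablers, and
    parsimony dating of ORF age on a species tree), retention (GC and
    fragile-codon characterization, a neutral event-driven simulator of ORF
    interruption yielding half-life estimates, and the ORF survival
    probability under neutrality), and selection (per-region nucleotide
    diversity and Watterson's theta, synonymous/nonsynonymous site
    classification including pseudo-sites on non-coding orthologs,
    piN/piS, unfolded derived-allele spectra with bootstrap confidence
    intervals, and Monte Carlo exon/intron constraint tests). A seeded
    synthetic-data module generates complete fixture bundles (sequences,
    orthologs evolved on a phylogeny, polymorphism panels under neutral or
    purifying-selection frequency spectra, and expression matrices) so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    ape,
    Biostrings,
    vcfR,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
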