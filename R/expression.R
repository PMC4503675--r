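# Expression-evidence stage: RPKM, empirical background thresholds from
# intergenic regions, relative expression against flanking regions, splicing
# junction support, and cross-tissue profile correlation.

#' Reads per kilobase per million mapped reads
#'
#' `read_count * 1e9 / (library_size * region_length)`.
#'
#' @param read_count Non-negative read counts (vectorized).
#' @param region_length Region length in bp (`> 0`).
#' @param library_size Total mapped reads in the library (`> 0`).
#' @return RPKM values.
#' @export
rpkm <- function(read_count, region_length, library_size) {
  if (any(region_length <= 0)) stop("region_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  read_count * 1e9 / (library_size * region_length)
}

#' Build an intergenic expression background model
#'
#' Holds the RPKM values of randomly selected intergenic regions (target
#' sample size 10,000) against which candidate expression levels are judged.
#'
#' @param intergenic_rpkms Numeric vector of background RPKMs.
#' @param tissue Optional tissue label.
#' @return Object of class `background_model`.
#' @export
background_model <- function(intergenic_rpkms, tissue = NA_character_) {
  if (!length(intergenic_rpkms)) stop("background model needs at least one value")
  structure(list(tissue = tissue, intergenic_rpkms = as.numeric(intergenic_rpkms)),
            class = "background_model")
}

#' Empirical p-value of an expression level against the background
#'
#' Fraction of intergenic background RPKMs at least as large as the query
#' value, with the (k+1)/(N+1) pseudo-count correction. Monotone
#' non-increasing in the query value; a value of 0 gives p = 1.
#'
#' @param model A [background_model()].
#' @param value Query RPKM (vectorized).
#' @return Empirical p-values in (0, 1\].
#' @export
background_p <- function(model, value) {
  stopifnot(inherits(model, "background_model"))
  N <- length(model$intergenic_rpkms)
  vapply(value, function(v) (sum(model$intergenic_rpkms >= v) + 1) / (N + 1),
         numeric(1))
}

#' Expression filter over tissues
#'
#' A gene is called expressed when its maximum RPKM across tissues strictly
#' exceeds the cutoff (0.5 for focal-species gene expression; ortholog
#' transcription calls use 0.2 against the intergenic background). Breadth is
#' the number of tissues above the cutoff.
#'
#' @param rpkms Named numeric vector of per-tissue RPKMs.
#' @param cutoff Strict RPKM cutoff.
#' @return List with `expressed`, `breadth`, `top_tissue`.
#' @export
expression_filter <- function(rpkms, cutoff = 0.5) {
  if (!length(rpkms)) stop("need at least one tissue")
  above <- rpkms > cutoff
  list(expressed = any(above), breadth = sum(above),
       top_tissue = names(rpkms)[which.max(rpkms)])
}

#' Relative expression of a genic region against its flanks
#'
#' `gene / (gene + upstream + downstream)`, where the flanking regions have
#' length equal to the genic region. Equal levels give exactly 1/3.
#'
#' @param gene_rpkm,upstream_rpkm,downstream_rpkm Non-negative RPKMs.
#' @return Fraction in \[0, 1\], `NA` (flagged by warning) when all are 0.
#' @export
relative_expression <- function(gene_rpkm, upstream_rpkm, downstream_rpkm) {
  if (any(c(gene_rpkm, upstream_rpkm, downstream_rpkm) < 0))
    stop("RPKM values must be >= 0")
  tot <- gene_rpkm + upstream_rpkm + downstream_rpkm
  out <- ifelse(tot > 0, gene_rpkm / tot, NA_real_)
  if (anyNA(out)) warning("relative expression undefined where all levels are 0")
  out
}

#' Fraction of splicing junctions with read support
#'
#' @param junction_counts Per-junction spliced-read counts.
#' @param min_reads Minimum supporting reads (default 1).
#' @return Supported fraction.
#' @export
junction_support <- function(junction_counts, min_reads = 1) {
  if (!length(junction_counts)) stop("junction table is empty")
  mean(junction_counts >= min_reads)
}

#' Spearman correlation of tissue expression profiles
#'
#' Rank correlation (ties mid-ranked) between tissue columns of a gene x
#' tissue RPKM matrix, computed on pairwise complete rows. Constant columns
#' yield `NA` with a warning.
#'
#' @param mat Numeric matrix (genes x tissues) with column names.
#' @param pairs Optional 2-column character matrix of tissue pairs; default
#'   all pairs.
#' @return Correlation matrix (or a tibble of requested pairs).
#' @export
tissue_profile_correlation <- function(mat, pairs = NULL) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  cc <- suppressWarnings(cor(mat, method = "spearman",
                             use = "pairwise.complete.obs"))
  const <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && all(x == x[1])
  })
  if (any(const)) {
    warning("constant tissue columns have undefined rank correlation: ",
            paste(colnames(mat)[const], collapse = ", "))
    cc[const, ] <- NA; cc[, const] <- NA
    diag(cc) <- ifelse(const, NA, diag(cc))
  }
  if (is.null(pairs)) return(cc)
  tibble(tissue_a = pairs[, 1], tissue_b = pairs[, 2],
         rho = cc[cbind(pairs[, 1], pairs[, 2])])
}
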