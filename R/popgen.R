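# Selection stage: polymorphism levels by genomic region, site
# classification (including pseudo-sites on non-coding orthologs), piN/piS,
# unfolded derived-allele frequency spectra with bootstrap confidence
# intervals, and Monte Carlo exon/intron constraint tests.

#' Per-site nucleotide diversity (pi)
#'
#' Sum over biallelic sites of the unbiased per-site heterozygosity
#' `2 p (1-p) n/(n-1)` (p = derived or alt allele frequency; the expression
#' is symmetric in p), divided by the surveyed site count `L`.
#'
#' @param variants Variant tibble (needs columns `ac` or `derived_count`, and
#'   `n`). May have zero rows.
#' @param L Number of surveyed sites (monomorphic included).
#' @return pi per site.
#' @export
nucleotide_diversity <- function(variants, L) {
  if (length(L) != 1 || is.na(L) || L <= 0) stop("L must be a positive site count")
  if (!nrow(variants)) return(0)
  cnt <- if ("derived_count" %in% names(variants) &&
             !anyNA(variants$derived_count)) variants$derived_count else variants$ac
  p <- cnt / variants$n
  sum(2 * p * (1 - p) * variants$n / (variants$n - 1)) / L
}

#' Watterson's theta per site
#'
#' `theta_w = S / (a L)` with `a = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S Number of segregating sites.
#' @param n Number of sampled chromosomes (`>= 2`).
#' @param L Number of surveyed sites.
#' @return theta_w per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("n must be >= 2")
  if (L <= 0) stop("L must be > 0")
  S / (harmonic_number(n - 1) * L)
}

harmonic_number <- function(k) sum(1 / seq_len(k))

#' Classify variants into synonymous/nonsynonymous/noncoding site classes
#'
#' Variants inside the CDS are placed in their codon via the region's frame
#' anchor; the alternative allele is substituted and the amino acid compared
#' (a change creating a stop codon is nonsynonymous, flagged as nonsense).
#' Variants outside the CDS are `noncoding`. When `pseudo = TRUE` (a
#' non-coding ortholog whose pseudo-CDS is defined by codon-level alignment
#' with the coding query), the coding labels become `pseudo_synonymous` /
#' `pseudo_nonsynonymous`.
#'
#' @param variants Variant tibble with `pos`, `ref`, `alt` (0-based positions).
#' @param region A [region_annotation()].
#' @param cds The (pseudo-)CDS as a [coding_sequence()], in transcription
#'   order.
#' @param pseudo Label coding sites as pseudo-sites.
#' @return The input tibble with added columns `site_class` and `nonsense`.
#' @export
classify_variants <- function(variants, region, cds, pseudo = FALSE) {
  stopifnot(inherits(region, "region_annotation"),
            inherits(cds, "coding_sequence"))
  tab <- codon_table()
  cds_iv <- region$intervals[region$intervals$class == "CDS", , drop = FALSE]
  minus <- nrow(cds_iv) > 0 && cds_iv$strand[1] == "-"
  cds_pos <- cds_genomic_positions(cds_iv)
  cods <- codons_of(cds$seq)
  cls <- rep("noncoding", nrow(variants))
  nonsense <- rep(FALSE, nrow(variants))
  idx <- match(variants$pos, cds_pos)
  inside <- which(!is.na(idx))
  for (k in inside) {
    i <- idx[k]
    cod_i <- (i - 1) %/% 3 + 1
    off <- (i - 1) %% 3 + 1
    cod <- cods[cod_i]
    alt <- variants$alt[k]
    ref <- variants$ref[k]
    if (minus) { alt <- revcomp(alt); ref <- revcomp(ref) }
    if (grepl("N", cod) || !alt %in% BASES) {
      cls[k] <- "unclassifiable"
      next
    }
    # the reference codon base should match the variant ref where supplied
    mut <- cod
    substr(mut, off, off) <- alt
    aa0 <- tab$code[[cod]]
    aa1 <- if (mut %in% tab$stops) "*" else tab$code[[mut]]
    if (cod %in% tab$stops) {
      cls[k] <- "unclassifiable"
    } else if (identical(aa0, aa1)) {
      cls[k] <- "synonymous"
    } else {
      cls[k] <- "nonsynonymous"
      nonsense[k] <- aa1 == "*"
    }
  }
  if (pseudo) {
    cls[cls == "synonymous"] <- "pseudo_synonymous"
    cls[cls == "nonsynonymous"] <- "pseudo_nonsynonymous"
  }
  variants$site_class <- cls
  variants$nonsense <- nonsense
  variants
}

# genomic positions (0-based) of CDS bases in transcription order
cds_genomic_positions <- function(cds_iv) {
  if (!nrow(cds_iv)) return(numeric(0))
  minus <- cds_iv$strand[1] == "-"
  o <- order(cds_iv$start, decreasing = minus)
  pos <- unlist(lapply(o, function(i) {
    p <- seq(cds_iv$start[i], cds_iv$end[i] - 1)
    if (minus) rev(p) else p
  }))
  pos
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), ""))
}

#' piN/piS from classified variants
#'
#' Diversity at nonsynonymous sites divided by the fractional nonsynonymous
#' site count of the CDS (counting-method sites, see [ng86_site_counts()]),
#' over the analogous synonymous quantity. With site-count denominators the
#' neutral expectation of the ratio is 1.
#'
#' @param variants Variant tibble with a `site_class` column (see
#'   [classify_variants()]); pseudo-classes are accepted.
#' @param cds The reference (pseudo-)CDS supplying site-count denominators.
#' @return List with `pi_n`, `pi_s`, `ratio` (`NA` with
#'   `flag = "undefined_ratio"` when `pi_s` is 0).
#' @export
pn_ps_ratio <- function(variants, cds) {
  if (!"site_class" %in% names(variants)) stop("variants must be classified first")
  sites <- ng86_site_counts(cds)
  vn <- variants[variants$site_class %in% c("nonsynonymous", "pseudo_nonsynonymous"), ]
  vs <- variants[variants$site_class %in% c("synonymous", "pseudo_synonymous"), ]
  pi_n <- nucleotide_diversity(vn, sites[["N"]])
  pi_s <- nucleotide_diversity(vs, sites[["S"]])
  if (pi_s == 0)
    return(list(pi_n = pi_n, pi_s = pi_s, ratio = NA_real_,
                flag = "undefined_ratio"))
  list(pi_n = pi_n, pi_s = pi_s, ratio = pi_n / pi_s, flag = NULL)
}

#' Unfolded derived-allele frequency spectrum with bootstrap CIs
#'
#' Proportions of polymorphic sites by derived-allele count (1..n-1),
#' restricted to polarizable sites. Bootstrap resamples sites with
#' replacement; per-bin standard deviations and 2.5/97.5 percentile
#' intervals are reported. Sites genotyped in more than `n` chromosomes are
#' projected down hypergeometrically; sites with fewer are dropped and
#' counted.
#'
#' @param variants Variant tibble with `derived_count` and `n` columns, or a
#'   bare integer vector of derived counts (then `n` must be given).
#' @param n Number of chromosomes of the spectrum.
#' @param B Bootstrap replicates (0 skips the bootstrap).
#' @param seed Optional seed (used for both projection and bootstrap).
#' @return Object of class `sfs_spectrum`: `n`, `counts`, `proportions`,
#'   `sd`, `ci_low`, `ci_high`, `n_sites`, `n_dropped`, `n_unpolarizable`.
#' @export
daf_spectrum <- function(variants, n = NULL, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_unpol <- 0L
  if (is.data.frame(variants)) {
    if ("aa_status" %in% names(variants)) {
      n_unpol <- sum(variants$aa_status != "polarized")
      variants <- variants[variants$aa_status == "polarized", , drop = FALSE]
    }
    dc <- variants$derived_count
    ns <- variants$n
    if (is.null(n)) n <- max(ns)
  } else {
    dc <- variants
    if (is.null(n)) stop("n must be supplied with a bare count vector")
    ns <- rep(n, length(dc))
  }
  keep <- !is.na(dc) & ns >= n
  n_dropped <- sum(!keep)
  dc <- dc[keep]; ns <- ns[keep]
  # hypergeometric projection to n chromosomes for over-genotyped sites
  proj <- ns > n
  if (any(proj)) dc[proj] <- rhyper(sum(proj), dc[proj], ns[proj] - dc[proj], n)
  seg <- dc > 0 & dc < n
  dc <- dc[seg]
  if (!length(dc)) stop("empty spectrum: no polarizable segregating sites")
  counts <- tabulate(dc, nbins = n - 1)
  props <- counts / sum(counts)
  sd_b <- ci_lo <- ci_hi <- rep(NA_real_, n - 1)
  if (B > 0) {
    boot <- matrix(0, nrow = B, ncol = n - 1)
    for (b in seq_len(B)) {
      res <- dc[sample.int(length(dc), length(dc), replace = TRUE)]
      boot[b, ] <- tabulate(res, nbins = n - 1) / length(res)
    }
    sd_b <- apply(boot, 2, sd)
    ci_lo <- apply(boot, 2, quantile, 0.025)
    ci_hi <- apply(boot, 2, quantile, 0.975)
  }
  structure(list(n = n, counts = counts, proportions = props, sd = sd_b,
                 ci_low = ci_lo, ci_high = ci_hi, n_sites = length(dc),
                 n_dropped = n_dropped, n_unpolarizable = n_unpol),
            class = "sfs_spectrum")
}

#' @exportS3Method base::print
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("<sfs_spectrum> n = %d chromosomes, %d sites (%d unpolarizable excluded)\n",
              x$n, x$n_sites, x$n_unpolarizable))
  print(head(tibble(derived_count = seq_len(x$n - 1),
                    proportion = x$proportions, sd = x$sd), 10))
  invisible(x)
}

#' One-sided test for excess of rare derived variants
#'
#' Two-proportion test (normal approximation, no continuity correction) on
#' the lowest-frequency class: is the proportion of sites with derived count
#' `<= rare_max` larger in spectrum `a` than in `b`? An excess of rare
#' nonsynonymous variants relative to synonymous ones signals purifying
#' selection.
#'
#' @param spec_a,spec_b [daf_spectrum()] objects with identical `n`.
#' @param rare_max Largest derived count treated as "rare" (default 1:
#'   singletons).
#' @return List with `p_value`, `prop_a`, `prop_b`, and the counts.
#' @export
excess_rare_test <- function(spec_a, spec_b, rare_max = 1) {
  stopifnot(inherits(spec_a, "sfs_spectrum"), inherits(spec_b, "sfs_spectrum"))
  if (spec_a$n != spec_b$n) stop("spectra have different n")
  xa <- sum(spec_a$counts[seq_len(rare_max)]); na <- sum(spec_a$counts)
  xb <- sum(spec_b$counts[seq_len(rare_max)]); nb <- sum(spec_b$counts)
  if (xa + xb == 0) stop("rare class empty in both spectra")
  pa <- xa / na; pb <- xb / nb
  pp <- (xa + xb) / (na + nb)
  se <- sqrt(pp * (1 - pp) * (1 / na + 1 / nb))
  z <- if (se == 0) 0 else (pa - pb) / se
  list(p_value = stats::pnorm(z, lower.tail = FALSE),
       prop_a = pa, prop_b = pb, rare_a = xa, total_a = na,
       rare_b = xb, total_b = nb)
}

#' Monte Carlo test for exonic polymorphism deficit
#'
#' Under the null, the observed polymorphic sites are distributed between
#' exonic and intronic sequence in proportion to their lengths. The observed
#' exonic variant count is compared to `n_sims` simulated placements; the
#' one-sided p-value (deficit) uses the (k+1)/(N+1) estimator, so it is
#' always in (0, 1].
#'
#' @param variants Variant tibble with `pos` (0-based).
#' @param region A [region_annotation()] with exonic (CDS/UTR or exon) and
#'   intron intervals.
#' @param n_sims Number of Monte Carlo placements.
#' @param seed Optional seed.
#' @return List with `p_value`, `observed_exonic`, `expected_exonic`, `k`,
#'   `exon_len`, `intron_len`.
#' @export
exon_intron_mc_test <- function(variants, region, n_sims = 10000, seed = NULL) {
  stopifnot(inherits(region, "region_annotation"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  iv <- region$intervals
  exon_iv <- iv[iv$class == "exon", , drop = FALSE]
  if (!nrow(exon_iv)) exon_iv <- iv[iv$class %in% c("CDS", "UTR"), , drop = FALSE]
  intr_iv <- iv[iv$class == "intron", , drop = FALSE]
  exon_len <- sum(exon_iv$end - exon_iv$start)
  intron_len <- sum(intr_iv$end - intr_iv$start)
  if (exon_len <= 0 || intron_len <= 0)
    stop("both exonic and intronic lengths must be > 0")
  in_iv <- function(pos, ivs) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(ivs)))
      hit <- hit | (pos >= ivs$start[i] & pos < ivs$end[i])
    hit
  }
  in_exon <- in_iv(variants$pos, exon_iv)
  in_intr <- in_iv(variants$pos, intr_iv)
  k <- sum(in_exon | in_intr)
  if (k < 1) stop("no variants in exonic or intronic regions")
  obs <- sum(in_exon)
  p_exon <- exon_len / (exon_len + intron_len)
  sims <- rbinom(n_sims, k, p_exon)
  list(p_value = (sum(sims <= obs) + 1) / (n_sims + 1),
       observed_exonic = obs, expected_exonic = k * p_exon, k = k,
       exon_len = exon_len, intron_len = intron_len)
}

#' Polymorphism levels by genomic region
#'
#' pi and Watterson's theta per site for each region class of a gene.
#'
#' @param variants Variant tibble with `pos` and `n`.
#' @param region A [region_annotation()].
#' @param n Chromosome count used for theta (defaults to the modal `n` of the
#'   variants).
#' @return Tibble with columns `region`, `pi`, `theta_w`, `S`, `L`, `n`.
#' @export
diversity_by_region <- function(variants, region, n = NULL) {
  stopifnot(inherits(region, "region_annotation"))
  if (is.null(n)) {
    tb <- table(variants$n)
    n <- as.integer(names(tb)[which.max(tb)])
  }
  iv <- region$intervals
  out <- lapply(unique(iv$class), function(cl) {
    ivs <- iv[iv$class == cl, , drop = FALSE]
    L <- sum(ivs$end - ivs$start)
    hit <- rep(FALSE, nrow(variants))
    for (i in seq_len(nrow(ivs)))
      hit <- hit | (variants$pos >= ivs$start[i] & variants$pos < ivs$end[i])
    v <- variants[hit, , drop = FALSE]
    tibble(region = cl, pi = nucleotide_diversity(v, L),
           theta_w = watterson_theta(nrow(v), n, L),
           S = nrow(v), L = L, n = n)
  })
  bind_rows(out)
}

#' Normalize per-region diversity estimates by the intronic value
#'
#' @param estimates Tibble from [diversity_by_region()] including an
#'   `intron` row.
#' @param column Which column to normalize (`"pi"` or `"theta_w"`).
#' @return The input with an added `normalized` column (intron maps to 1).
#' @export
normalize_by_intron <- function(estimates, column = "pi") {
  if (!"intron" %in% estimates$region) stop("no intron estimate to normalize by")
  ref <- estimates[[column]][estimates$region == "intron"][1]
  if (is.na(ref) || ref == 0)
    stop("undefined normalization: intronic value is 0")
  estimates$normalized <- estimates[[column]] / ref
  estimates
}
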