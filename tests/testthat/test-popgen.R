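test_that("pi matches brute-force all-pairs oracles on small fixtures", {
  expect_equal(nucleotide_diversity(tibble::tibble(ac = integer(), n = integer()),
                                    100), 0)
  # one site, n = 4, derived count 2, L = 100
  v <- tibble::tibble(derived_count = 2L, ac = 2L, n = 4L)
  hap <- matrix(0, 4, 1); hap[1:2, 1] <- 1
  expect_equal(nucleotide_diversity(v, 100), oracle_pi(hap, 100))
  expect_equal(nucleotide_diversity(v, 100), 0.006667, tolerance = 1e-4)

  # two haplotypes differing at 1 of 10 sites
  v2 <- tibble::tibble(derived_count = 1L, ac = 1L, n = 2L)
  expect_equal(nucleotide_diversity(v2, 10), 0.1)

  # random 8-haplotype fixture: exact agreement with all-pairs counting
  set.seed(3)
  L <- 50
  hap <- matrix(rbinom(8 * L, 1, 0.3), nrow = 8)
  seg <- which(colSums(hap) > 0 & colSums(hap) < 8)
  v3 <- tibble::tibble(derived_count = colSums(hap)[seg],
                       ac = colSums(hap)[seg], n = 8L)
  expect_equal(nucleotide_diversity(v3, L), oracle_pi(hap, L))
})

test_that("Watterson's theta matches the harmonic formula", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(3, 5, 100), 3 / (sum(1 / (1:4)) * 100))
  expect_equal(watterson_theta(3, 5, 100), 0.0144, tolerance = 1e-4)
  expect_equal(watterson_theta(1, 2, 1), 1)
  expect_error(watterson_theta(1, 1, 10), "n must")
})

simple_region <- function(strand = "+") {
  region_annotation("g", tibble::tibble(
    contig = "c",
    start = c(100, 0, 109),
    end = c(109, 100, 200),
    strand = strand,
    class = c("CDS", "intron", "intron")),
    complete_orf = TRUE)
}

test_that("site classification follows the codon table", {
  region <- simple_region()
  cds <- coding_sequence("ATGGATTGA") # CDS occupies positions 100..108
  # codon 2 = GAT (Asp): third position T->C -> GAC (Asp) = synonymous;
  # first position G->A -> AAT (Asn) = nonsynonymous; pos 50 is intronic
  v <- tibble::tibble(pos = c(105, 103, 50),
                      ref = c("T", "G", "G"),
                      alt = c("C", "A", "T"))
  out <- classify_variants(v, region, cds)
  expect_equal(out$site_class, c("synonymous", "nonsynonymous", "noncoding"))
  expect_false(any(out$nonsense))

  # a change creating a stop codon is nonsynonymous with the nonsense flag
  cds2 <- coding_sequence("ATGTGGTAA")
  out2 <- classify_variants(tibble::tibble(pos = 104, ref = "G", alt = "A"),
                            region, cds2) # TGG -> TAG
  expect_equal(out2$site_class, "nonsynonymous")
  expect_true(out2$nonsense)

  # pseudo labels for non-coding orthologs
  outp <- classify_variants(v, region, cds, pseudo = TRUE)
  expect_equal(outp$site_class,
               c("pseudo_synonymous", "pseudo_nonsynonymous", "noncoding"))
})

test_that("classification is invariant under strand flip", {
  set.seed(8)
  cds <- generate_sequence(n_codons = 32, gc = 0.5, ensure_orf = TRUE)
  L <- nchar(cds$seq)
  plus <- region_annotation("g", tibble::tibble(
    contig = "c", start = 100, end = 100 + L, strand = "+", class = "CDS"))
  minus <- region_annotation("g", tibble::tibble(
    contig = "c", start = 100, end = 100 + L, strand = "-", class = "CDS"))
  # a variant at coding offset k on the plus strand corresponds to genomic
  # position 100 + L - 1 - k on the minus strand with complemented alleles
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(cds$seq, "")[[1]]
  for (k in c(0, 5, 31, 60)) {
    ref <- bases[k + 1]
    alt <- sample(setdiff(names(comp), ref), 1)
    vp <- tibble::tibble(pos = 100 + k, ref = ref, alt = alt)
    vm <- tibble::tibble(pos = 100 + L - 1 - k, ref = comp[[ref]],
                         alt = comp[[alt]])
    expect_equal(classify_variants(vp, plus, cds)$site_class,
                 classify_variants(vm, minus, cds)$site_class)
  }
})

test_that("piN/piS uses counting-method site denominators", {
  cds <- coding_sequence("ATGGATTGA")
  v <- tibble::tibble(derived_count = c(2L, 3L), ac = c(2L, 3L), n = 10L,
                      site_class = c("synonymous", "synonymous"))
  r <- pn_ps_ratio(v, cds)
  expect_equal(r$ratio, 0)
  expect_equal(r$pi_n, 0)

  v2 <- tibble::tibble(derived_count = 2L, ac = 2L, n = 10L,
                       site_class = "nonsynonymous")
  r2 <- pn_ps_ratio(v2, cds)
  expect_true(is.na(r2$ratio))
  expect_equal(r2$flag, "undefined_ratio")
})

test_that("DAF spectrum counts, projects and bootstraps correctly", {
  sp <- daf_spectrum(c(1L, 1L, 2L, 3L), n = 4, B = 0)
  expect_equal(sp$proportions, c(0.5, 0.25, 0.25))

  # single site: degenerate bootstrap CI of width 0
  sp1 <- daf_spectrum(c(2L), n = 4, B = 100, seed = 1)
  expect_equal(sp1$ci_low, sp1$ci_high)

  # unpolarizable sites are excluded and counted
  v <- tibble::tibble(derived_count = c(1L, 2L, NA), n = 4L,
                      aa_status = c("polarized", "polarized", "unpolarizable"))
  spv <- daf_spectrum(v, n = 4, B = 0)
  expect_equal(spv$n_sites, 2)
  expect_equal(spv$n_unpolarizable, 1)

  expect_error(daf_spectrum(integer(0), n = 4, B = 0), "empty")
})

test_that("neutral spectra follow the 1/i law within bootstrap CIs", {
  set.seed(12)
  f <- expected_sfs(4, 0)
  dc <- sample.int(3, 10000, replace = TRUE, prob = f / sum(f))
  sp <- daf_spectrum(dc, n = 4, B = 1000, seed = 13)
  expected <- c(6, 3, 2) / 11
  expect_true(all(expected >= sp$ci_low & expected <= sp$ci_high))
})

test_that("rare-variant excess test behaves at both extremes", {
  mk <- function(singletons, total, n = 100) {
    counts <- c(singletons, total - singletons)
    daf_spectrum(rep(c(1L, 2L), counts), n = 3, B = 0)
  }
  same <- excess_rare_test(mk(50, 100), mk(50, 100))
  expect_equal(same$p_value, 0.5)
  strong <- excess_rare_test(mk(80, 100), mk(50, 100))
  expect_lt(strong$p_value, 0.01)
  expect_error(excess_rare_test(mk(50, 100), daf_spectrum(1L, n = 4, B = 0)),
               "different n")
})

test_that("Monte Carlo exonic-deficit p matches the exact binomial tail", {
  region <- region_annotation("g", tibble::tibble(
    contig = "c", start = c(0, 100), end = c(100, 1000), strand = "+",
    class = c("exon", "intron")))
  v <- tibble::tibble(pos = seq(150, 950, length.out = 10)) # all intronic
  mc <- exon_intron_mc_test(v, region, n_sims = 10000, seed = 5)
  exact <- pbinom(0, 10, 0.1)
  expect_equal(exact, 0.9^10)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1e-4)
  expect_equal(mc$observed_exonic, 0)

  # all variants exonic: upper-end p for the deficit test
  v2 <- tibble::tibble(pos = seq(1, 99, length.out = 50))
  mc2 <- exon_intron_mc_test(v2, region, n_sims = 2000, seed = 6)
  expect_gt(mc2$p_value, 0.99)
  expect_lte(mc2$p_value, 1)
  expect_gt(mc$p_value, 0) # (k+1)/(N+1) keeps p in (0, 1]
})

test_that("intron normalization maps intron to 1 and scales the rest", {
  est <- tibble::tibble(region = c("intron", "CDS"), pi = c(0.001, 0.0005),
                        theta_w = c(0.001, 0.0004), S = c(10, 2),
                        L = c(1000, 400), n = 10)
  out <- normalize_by_intron(est)
  expect_equal(out$normalized[out$region == "intron"], 1)
  expect_equal(out$normalized[out$region == "CDS"], 0.5)
  expect_error(normalize_by_intron(est[est$region == "CDS", ]), "intron")
})

test_that("neutral panels equalize pi and theta and match per-region oracles", {
  set.seed(21)
  region <- region_annotation("g", tibble::tibble(
    contig = "c", start = 0, end = 50000, strand = "+", class = "intron"))
  n <- 20
  f <- expected_sfs(n, 0)
  S <- 10000
  v <- tibble::tibble(pos = sample.int(50000, S) - 1,
                      derived_count = sample.int(n - 1, S, replace = TRUE,
                                                 prob = f / sum(f)),
                      n = n)
  v$ac <- v$derived_count
  d <- diversity_by_region(v, region)
  expect_equal(d$S, S)
  expect_lt(abs(d$pi / d$theta_w - 1), 0.15)
})
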