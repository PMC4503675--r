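test_that("sequence generation hits the GC target and the ORF constraints", {
  s <- generate_sequence(length_bp = 30000, gc = 0.5, seed = 1)
  expect_true(gc_content(s) >= 0.48 && gc_content(s) <= 0.52)

  cds <- generate_sequence(n_codons = 1000, gc = 0.6, ensure_orf = TRUE, seed = 2)
  expect_s3_class(cds, "coding_sequence")
  cods <- substring(cds$seq, seq(1, nchar(cds$seq) - 3, 3),
                    seq(3, nchar(cds$seq) - 3, 3))
  expect_false(any(cods %in% c("TAA", "TAG", "TGA"))) # no internal stops
  expect_equal(substr(cds$seq, 1, 3), "ATG")
  expect_lt(abs(gc_content(cds$seq) - 0.6), 0.02)

  expect_identical(generate_sequence(n_codons = 50, seed = 9, ensure_orf = TRUE)$seq,
                   generate_sequence(n_codons = 50, seed = 9, ensure_orf = TRUE)$seq)
  expect_error(generate_sequence(length_bp = 10, gc = 1.5), "gc")
})

test_that("zero branch lengths leave all tips identical to the ancestor", {
  anc <- generate_sequence(n_codons = 60, gc = 0.5, ensure_orf = TRUE, seed = 3)
  tr <- "(((((human:0,chimp:0):0,gorilla:0):0,orangutan:0):0,macaque:0):0,mouse:0);"
  ev <- evolve_orthologs(anc, tr, seed = 4)
  expect_true(all(ev$tips == anc$seq))
  for (a in ev$alignments) expect_true(all(a$rows$event == "match"))
})

test_that("tip-ancestor substitution counts match the Poisson expectation", {
  anc <- generate_sequence(n_codons = 500, gc = 0.5, ensure_orf = TRUE, seed = 5)
  yrs <- 50e6
  tr <- sprintf("(human:%g,macaque:%g);", yrs, yrs)
  mu <- 1.25e-9
  L <- nchar(anc$seq)
  diffs <- vapply(1:10, function(i) {
    ev <- evolve_orthologs(anc, tr, seed = 100 + i)
    sum(strsplit(ev$tips[["macaque"]], "")[[1]] != strsplit(anc$seq, "")[[1]])
  }, numeric(1))
  lambda <- mu * yrs * L # raw mutation events on the macaque path
  # observed differences sit below raw events (multiple hits); 3 SD window
  expect_lt(abs(mean(diffs) - lambda * (1 - lambda / L)), 3 * sqrt(lambda / 10) + 3)
})

test_that("injected ancestral disablers reach every non-query tip", {
  anc <- generate_sequence(n_codons = 120, gc = 0.55, ensure_orf = TRUE, seed = 6)
  anc$gene_id <- "g"
  tr <- ape::read.tree(text = default_species_tree())
  outg <- setdiff(tr$tip.label, "human")
  ev <- evolve_orthologs(anc, tr,
                         disablers = list(list(kind = "premature_stop",
                                               position = 60, clade = outg)),
                         enforce_query_orf = TRUE, seed = 7)
  for (sp in outg) {
    st <- assess_orf(ev$alignments[[sp]])
    expect_true(60 %in% st$disruptions$position)
    expect_false(st$present)
  }
  # query tip keeps an intact ORF
  expect_no_error(coding_sequence(ev$tips[["human"]]))

  # noiseless run: disabler recovery is exact
  tr0 <- "(((((human:0,chimp:0):0,gorilla:0):0,orangutan:0):0,macaque:0):0,mouse:0);"
  ev0 <- evolve_orthologs(anc, tr0,
                          disablers = list(list(kind = "premature_stop",
                                                position = 60, clade = outg)),
                          seed = 8)
  sts <- lapply(ev0$alignments, assess_orf)
  cd <- detect_common_disablers(sts)
  expect_true(cd$newly_originated)
  expect_true(all(cd$shared$position == 60))
})

test_that("selection SFS sampler matches its numerically integrated target", {
  n <- 12
  for (g in c(-25, -10, -1, 0)) {
    f <- expected_sfs(n, g)
    p <- f / sum(f)
    set.seed(200 - g)
    draws <- sample.int(n - 1, 1e5, replace = TRUE, prob = p)
    emp <- tabulate(draws, n - 1) / 1e5
    expect_lt(sum(abs(emp - p)) / 2, 0.03) # total variation
  }
  # neutral limit is exactly the 1/i law
  expect_equal(expected_sfs(6, 0), 1 / (1:5))
  # purifying selection skews toward singletons
  f0 <- expected_sfs(134, 0); f10 <- expected_sfs(134, -10)
  expect_gt(f10[1] / sum(f10), f0[1] / sum(f0))
})

test_that("polymorphism simulation respects classes, spectra and seeds", {
  ps <- polymorphism_preset("neutral-only", seed = 31, scale = 0.2)
  v <- ps$variants
  expect_true(all(v$aa == v$ref)) # reference taken as ancestral: unfolded
  expect_true(all(v$derived_count >= 1 & v$derived_count <= ps$n - 1))
  # the pipeline's classifier reproduces the generator's truth on CDS sites
  vc <- classify_variants(v, ps$region, ps$cds)
  coding <- vc$true_class %in% c("synonymous", "nonsynonymous")
  expect_equal(vc$site_class[coding], vc$true_class[coding])

  # singleton fraction near the neutral expectation
  f <- expected_sfs(ps$n, 0)
  p1 <- f[1] / sum(f)
  expect_lt(abs(mean(v$derived_count == 1) - p1), 0.05)

  # byte-identical VCF under the same seed
  ps1 <- polymorphism_preset("neutral-only", seed = 31, scale = 0.05)
  ps2 <- polymorphism_preset("neutral-only", seed = 31, scale = 0.05)
  v1 <- simulate_polymorphism(ps1$region, ps1$cds, ps1$n, ps1$sites, seed = 5,
                              genotypes = TRUE)
  v2 <- simulate_polymorphism(ps2$region, ps2$cds, ps2$n, ps2$sites, seed = 5,
                              genotypes = TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  write_variants(v1, f1); write_variants(v2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("expression generator controls correlation and background rate", {
  g <- paste0("g", 1:40)
  a <- generate_expression_matrix(g, noise_sd = 0, seed = 41)
  b <- generate_expression_matrix(g, profile = a$profile, noise_sd = 0, seed = 42)
  expect_equal(suppressWarnings(cor(a$rpkm[, 1], b$rpkm[, 1], method = "spearman")), 1)

  bg <- background_model(a$background)
  expect_lt(abs(background_p(bg, 0.2) - 0.02), 0.01)

  c1 <- generate_expression_matrix(g, seed = 43)
  c2 <- generate_expression_matrix(g, seed = 43)
  expect_identical(c1$rpkm, c2$rpkm)
})

test_that("fixture bundles are reproducible and schema-stable", {
  d1 <- file.path(tempdir(), "fb1"); d2 <- file.path(tempdir(), "fb2")
  d3 <- file.path(tempdir(), "fb3")
  unlink(c(d1, d2, d3), recursive = TRUE)
  b1 <- make_fixture_bundle(d1, seed = 5, panel_scale = 0.05)
  b2 <- make_fixture_bundle(d2, seed = 5, panel_scale = 0.05)
  b3 <- make_fixture_bundle(d3, seed = 6, panel_scale = 0.05)
  expect_identical(b1$manifest$md5, b2$manifest$md5) # bit-reproducible
  expect_identical(b1$manifest$file, b3$manifest$file) # same schema
  expect_false(all(b1$manifest$md5 == b3$manifest$md5)) # different content
  # manifest lists every emitted file with its checksum
  files <- setdiff(list.files(d1, recursive = TRUE), "MANIFEST.tsv")
  expect_setequal(b1$manifest$file, files)
})
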