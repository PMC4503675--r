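test_that("alignment-quality filter uses strict thresholds", {
  mk <- function(cov, id, L = 100) {
    n_aln <- round(cov * L)
    n_match <- round(id * n_aln)
    rows <- tibble::tibble(
      query_codon_index = seq_len(n_aln),
      query_codon = "AAA",
      subject_codon = c(rep("AAA", n_match), rep("AAC", n_aln - n_match)),
      event = c(rep("match", n_match), rep("substitution", n_aln - n_match)),
      indel_nt = NA_real_)
    codon_alignment("g", "human", "chimp", rows, L)
  }
  expect_true(filter_alignment_quality(mk(0.8, 0.6)))
  expect_false(filter_alignment_quality(mk(0.70, 0.6)))   # coverage exactly 0.70
  expect_false(filter_alignment_quality(mk(0.9, 0.50)))   # identity exactly 0.50
})

test_that("ORF assessment applies the 70% maximum-continuous-ORF rule", {
  q <- strrep("AAA", 100)
  # single premature stop at codon 50 -> longest segment 50 -> absent
  s <- paste0(strrep("AAA", 49), "TAA", strrep("AAA", 50))
  st <- assess_orf(pair_alignment(q, s))
  expect_false(st$present)
  expect_equal(st$max_intact_fraction, 0.50)
  expect_equal(st$disruptions$kind, "premature_stop")
  expect_equal(st$disruptions$position, 50)

  # single stop at codon 20 -> longest segment 80 -> present
  s <- paste0(strrep("AAA", 19), "TGA", strrep("AAA", 80))
  st <- assess_orf(pair_alignment(q, s))
  expect_true(st$present)
  expect_equal(st$max_intact_fraction, 0.80)

  # no disruptions -> present with the aligned fraction
  st <- assess_orf(pair_alignment(q, q))
  expect_true(st$present)
  expect_equal(st$max_intact_fraction, 1)
  expect_equal(nrow(st$disruptions), 0)
})

test_that("frameshifting indels disrupt; in-frame indels do not", {
  q <- strrep("AAA", 100)
  aln <- pair_alignment(q, q)
  rows <- dplyr::bind_rows(aln$rows,
    tibble::tibble(query_codon_index = 50L, query_codon = "AAA",
                   subject_codon = NA_character_, event = "deletion",
                   indel_nt = 1))
  a2 <- codon_alignment("g", "human", "chimp", rows[order(rows$query_codon_index), ], 100)
  st <- assess_orf(a2)
  expect_false(st$present)
  expect_equal(st$disruptions$kind, "frameshift_indel")

  rows$indel_nt[rows$event == "deletion"] <- 3
  a3 <- codon_alignment("g", "human", "chimp", rows[order(rows$query_codon_index), ], 100)
  expect_true(assess_orf(a3)$present)
})

test_that("ORF assessment is monotone: extra disruptions never restore presence", {
  q <- strrep("AAA", 100)
  s_one <- paste0(strrep("AAA", 19), "TGA", strrep("AAA", 80))
  base <- assess_orf(pair_alignment(q, s_one))
  expect_true(base$present)
  # add a second stop splitting the long segment
  s_two <- paste0(strrep("AAA", 19), "TGA", strrep("AAA", 40), "TAA",
                  strrep("AAA", 39))
  more <- assess_orf(pair_alignment(q, s_two))
  expect_false(more$present)
  expect_lte(more$max_intact_fraction, base$max_intact_fraction)
})

test_that("common-disabler detection needs a shared position and kind", {
  q <- strrep("AAA", 100)
  stop_at <- function(p) paste0(strrep("AAA", p - 1), "TAA",
                                strrep("AAA", 100 - p))
  # ORF-disabling stops (central, so the 70% rule calls the ORF absent)
  st_chimp <- assess_orf(pair_alignment(q, stop_at(50), ssp = "chimp"))
  st_mac50 <- assess_orf(pair_alignment(q, stop_at(50), ssp = "macaque"))
  st_mac40 <- assess_orf(pair_alignment(q, stop_at(40), ssp = "macaque"))

  cd <- detect_common_disablers(list(chimp = st_chimp, macaque = st_mac50))
  expect_true(cd$newly_originated)
  expect_equal(cd$shared$position, 50)

  # same kind at different positions is no common ancestral disabler
  cd2 <- detect_common_disablers(list(chimp = st_chimp, macaque = st_mac40))
  expect_false(cd2$newly_originated)
  expect_equal(nrow(cd2$shared), 0)

  expect_error(detect_common_disablers(list(chimp = st_chimp)),
               "insufficient")
})

test_that("parsimony age assignment reproduces the label scheme", {
  sp <- c("human", "chimp", "gorilla", "orangutan", "macaque", "mouse")
  pres <- function(on) setNames(sp %in% on, sp)

  a <- assign_age(pres("human"))
  expect_equal(a$age_label, "H")
  expect_equal(a$inferred_losses, character(0))
  expect_false(a$ambiguous)

  a <- assign_age(pres(c("human", "chimp")))
  expect_equal(a$age_label, "H-C")
  expect_equal(a$species_label, "H-C")
  expect_false(a$ambiguous)

  # gorilla absent inside the origin clade: loss inferred, both labels kept
  a <- assign_age(pres(c("human", "chimp", "orangutan")))
  expect_equal(a$age_label, "H-C-G-O")
  expect_equal(a$species_label, "H-C-O")
  expect_equal(a$inferred_losses, "gorilla")

  a <- assign_age(pres(c("human", "chimp", "gorilla", "orangutan", "macaque")))
  expect_equal(a$age_label, "pre-hominoid")

  expect_error(assign_age(pres("chimp")), "query")
})

test_that("full-clade presence vectors give zero losses and no ambiguity", {
  sp <- c("human", "chimp", "gorilla", "orangutan", "macaque", "mouse")
  clades <- list(c("human"), c("human", "chimp"),
                 c("human", "chimp", "gorilla"),
                 c("human", "chimp", "gorilla", "orangutan"),
                 c("human", "chimp", "gorilla", "orangutan", "macaque"))
  for (cl in clades) {
    a <- assign_age(setNames(sp %in% cl, sp))
    expect_equal(a$inferred_losses, character(0))
    expect_false(a$ambiguous)
  }
})

test_that("dN/dS counting handles degenerate and hand-counted cases", {
  q <- "ATGGATCTG"
  # identical sequences: dN = dS = 0, ratio undefined
  r <- merged_dnds(pair_alignment(q, q))
  expect_true(is.na(r$dnds))
  expect_equal(r$flag, "undefined_ratio")

  # one synonymous difference only: CTG -> CTA (Leu -> Leu)
  r <- merged_dnds(pair_alignment(q, "ATGGATCTA"))
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$dnds, 0)

  # merged over a single-element list equals the per-gene value
  r1 <- merged_dnds(list(pair_alignment(q, "ATGGATCTA")))
  expect_equal(r1$dnds, r$dnds)
})

test_that("neutral divergence gives a merged dN/dS near 1", {
  set.seed(77)
  n_cod <- 10000
  alns <- lapply(1:4, function(i) {
    q <- random_orf(n_cod)
    q_body <- substr(q, 1, 3 * n_cod) # drop terminal stop
    b <- strsplit(q_body, "")[[1]]
    hit <- runif(length(b)) < 0.04
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    pair_alignment(q_body, paste(b, collapse = ""), gene = paste0("g", i))
  })
  r <- merged_dnds(alns)
  expect_lt(abs(r$dnds - 1), 0.1)
})
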