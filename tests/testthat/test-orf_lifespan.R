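toy_orf <- function() coding_sequence("ATGTGGTAA")

test_that("zero mutation rates censor every replicate", {
  m <- mutation_model(point_rate = 0, indel_rate = 0)
  t <- simulate_interruption_time(toy_orf(), m, n = 5, seed = 1)
  expect_true(all(is.infinite(t)))
})

test_that("the simulator is deterministic under a seed", {
  t1 <- simulate_interruption_time(toy_orf(), n = 50, seed = 123)
  t2 <- simulate_interruption_time(toy_orf(), n = 50, seed = 123)
  expect_identical(t1, t2)
  hl1 <- half_life(toy_orf(), n_replicates = 100, seed = 7)
  hl2 <- half_life(toy_orf(), n_replicates = 100, seed = 7)
  expect_identical(hl1$t_half, hl2$t_half)
})

test_that("simulator agrees with an independent plain-R re-implementation", {
  n <- 3000
  hl <- half_life(toy_orf(), n_replicates = n, seed = 21)
  set.seed(22)
  oracle <- replicate(n, oracle_interruption_time("ATGTGGTAA", 1.25e-9, 0.1e-9))
  se <- function(x) 1.2533 * sd(x) / sqrt(length(x)) # SE of a median
  tol <- 2 * sqrt(se(hl$interruption_times)^2 + se(oracle)^2)
  expect_lt(abs(hl$t_half - median(oracle)), tol)
})

test_that("simulator agrees with a discrete-time simulator at scaled rates", {
  # 10-codon ORF, rates scaled up so one 'year' step carries ~1e-4 events
  orf <- random_orf(9, seed = 31)
  mu <- 2e-6; nu <- 1.6e-7
  n <- 2000
  t_ev <- simulate_interruption_time(coding_sequence(orf),
                                     mutation_model(mu, nu), n = n,
                                     seed = 32, horizon = 1e9)
  set.seed(33)
  t_dt <- replicate(n, oracle_discrete_time(orf, mu, nu))
  se <- function(x) 1.2533 * sd(x) / sqrt(length(x))
  tol <- 2 * sqrt(se(t_ev)^2 + se(t_dt)^2)
  expect_lt(abs(median(t_ev) - median(t_dt)), tol)
})

test_that("pure-indel interruption times are exactly exponential (KS)", {
  # with point_rate = 0 the composition is stationary and the interruption
  # process is Poisson with rate L * indel_rate
  orf <- random_orf(49, seed = 41)
  m <- mutation_model(point_rate = 0, indel_rate = 0.1e-9)
  t <- simulate_interruption_time(coding_sequence(orf), m, n = 5000, seed = 42)
  rate <- nchar(orf) * 0.1e-9
  ks <- suppressWarnings(ks.test(t, "pexp", rate))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("half-life roughly halves when ORF length doubles", {
  set.seed(51)
  base <- random_orf(100)
  body <- substr(base, 4, nchar(base) - 3)
  dbl <- paste0("ATG", body, body, substr(base, nchar(base) - 2, nchar(base)))
  t1 <- half_life(coding_sequence(base), n_replicates = 3000, seed = 52)$t_half
  t2 <- half_life(coding_sequence(dbl), n_replicates = 3000, seed = 53)$t_half
  expect_gt(t2 / t1, 0.4)
  expect_lt(t2 / t1, 0.6)
})

test_that("GC-rich ORFs outlive AT-rich ORFs of equal length", {
  wins <- vapply(1:5, function(i) {
    gc_rich <- generate_sequence(n_codons = 150, gc = 0.7, ensure_orf = TRUE,
                                 seed = 60 + i)
    at_rich <- generate_sequence(n_codons = 150, gc = 0.3, ensure_orf = TRUE,
                                 seed = 70 + i)
    t_gc <- half_life(gc_rich, n_replicates = 1000, seed = 80 + i)$t_half
    t_at <- half_life(at_rich, n_replicates = 1000, seed = 90 + i)$t_half
    t_gc > t_at
  }, logical(1))
  expect_true(all(wins))
})

test_that("half-life is monotone non-increasing in rates and length", {
  t_mu <- vapply(c(0.5e-9, 1.25e-9, 3e-9), function(mu)
    half_life(generate_sequence(n_codons = 80, gc = 0.5, ensure_orf = TRUE,
                                seed = 1),
              mutation_model(point_rate = mu), n_replicates = 1500,
              seed = 100)$t_half, numeric(1))
  expect_true(all(diff(t_mu) < 0))
  t_nu <- vapply(c(0.05e-9, 0.1e-9, 0.4e-9), function(nu)
    half_life(generate_sequence(n_codons = 80, gc = 0.5, ensure_orf = TRUE,
                                seed = 1),
              mutation_model(indel_rate = nu), n_replicates = 1500,
              seed = 101)$t_half, numeric(1))
  expect_true(all(diff(t_nu) < 0))
  t_len <- vapply(c(50, 100, 200), function(L)
    half_life(generate_sequence(n_codons = L, gc = 0.5, ensure_orf = TRUE,
                                seed = 2),
              n_replicates = 1500, seed = 102)$t_half, numeric(1))
  expect_true(all(diff(t_len) < 0))
})

test_that("survival probability matches the closed form and its limits", {
  out <- survival_probability(1e6, 1e6)
  expect_equal(out$lambda, 0.5)
  expect_equal(out$p, 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_equal(survival_probability(0, 1e6)$p, exp(-1), tolerance = 1e-12)
  expect_lt(survival_probability(1e9, 1e6)$p, 1e-12) # T -> Inf limit
  expect_error(survival_probability(1e6, 0), "t_half")
  expect_error(survival_probability(-1, 1e6), "T must")
})

test_that("survival probability is monotone in T and t_half; max at lambda=1", {
  th <- 5e6
  p_T <- survival_probability(seq(0, 5e7, length.out = 20), th)$p
  expect_true(all(diff(p_T) < 0))
  p_th <- vapply(seq(1e6, 1e8, length.out = 20), function(t)
    survival_probability(1e7, t)$p, numeric(1))
  expect_true(all(diff(p_th) > 0))
  lam <- seq(0.01, 1, length.out = 100)
  expect_equal(which.max(lam * exp(-lam)), 100)
})

test_that("half-life is flagged undefined when mostly censored", {
  m <- mutation_model(point_rate = 1e-12, indel_rate = 0)
  hl <- half_life(coding_sequence("ATGGGGTAA"), m, n_replicates = 200,
                  seed = 1, horizon = 1e8)
  expect_true(is.na(hl$t_half))
  expect_gte(hl$censored_fraction, 0.5)
})
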