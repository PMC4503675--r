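# Neutral-evolution simulator of ORF interruption, half-life estimation and
# the survival-probability formula. An ORF under no functional constraint is
# eventually destroyed by a premature stop codon or a frame-disrupting indel;
# the half-life t1/2 is the time by which half of the simulation replicates
# are interrupted.

#' Define a neutral mutation model
#'
#' Rates are per single site per year. The defaults are the point and
#' insertion/deletion rates of 1.25 and 0.1 per site per billion years used
#' for primate neutral sequence evolution.
#'
#' @param point_rate Point substitution rate per site per year.
#' @param indel_rate Indel event rate per site per year.
#' @param kappa Transition/transversion weight (1 = uniform substitution).
#' @param indel_length `"fixed1"` (every indel is 1 bp and frameshifts) or
#'   `"geometric"` (length 1 + Geom, indels with length divisible by 3 do not
#'   interrupt).
#' @param geometric_mean Mean indel length for the geometric option.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(point_rate = 1.25e-9, indel_rate = 0.1e-9,
                           kappa = 1, indel_length = c("fixed1", "geometric"),
                           geometric_mean = 3) {
  if (point_rate < 0 || indel_rate < 0) stop("mutation rates must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  indel_length <- match.arg(indel_length)
  structure(list(point_rate = point_rate, indel_rate = indel_rate,
                 kappa = kappa, indel_length = indel_length,
                 geometric_mean = geometric_mean),
            class = "mutation_model")
}

seq_to_int <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES) - 1L
  if (anyNA(m)) stop("sequence has characters outside A,C,G,T")
  m
}

#' Simulate the neutral interruption time of an ORF
#'
#' Event-driven simulation: waiting times are exponential with total rate
#' `L * (point_rate + indel_rate)`; each event picks a site uniformly. The
#' ORF is interrupted when a non-terminal codon becomes a stop codon or when
#' a frameshifting indel lands inside it. Loss of the terminal stop codon is
#' not an interruption (mirroring the identification rule, which names only
#' frame-disrupting indels and premature stops). Replicates still intact at
#' the horizon are censored (`Inf`).
#'
#' @param cds A [coding_sequence()] including its terminal stop.
#' @param model A [mutation_model()].
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @param horizon Censoring horizon in years.
#' @return Numeric vector of `n` interruption times in years (`Inf` =
#'   censored).
#' @export
simulate_interruption_time <- function(cds, model = mutation_model(), n = 1,
                                       seed = NULL, horizon = 1e10) {
  stopifnot(inherits(cds, "coding_sequence"), inherits(model, "mutation_model"))
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
      stop("seed must be a single integer")
    set.seed(as.integer(seed))
  }
  orf_interruption_times_cpp(
    seq_to_int(cds$seq), model$point_rate, model$indel_rate, model$kappa,
    horizon, cds$includes_terminal_stop,
    if (model$indel_length == "fixed1") 0L else 1L, model$geometric_mean,
    as.integer(n))
}

#' Estimate the neutral half-life of an ORF
#'
#' The half-life is the time required for the ORF to be interrupted in
#' one-half of the simulation replicates (the median interruption time, with
#' censored replicates counted as exceeding the horizon). When half or more
#' of the replicates are censored the half-life is undefined and flagged.
#'
#' @inheritParams simulate_interruption_time
#' @param n_replicates Number of replicates (default 20000, minimum 100).
#' @return Object of class `lifespan_estimate` with fields `t_half`,
#'   `n_replicates`, `interruption_times`, `censored_fraction`.
#' @export
half_life <- function(cds, model = mutation_model(), n_replicates = 20000,
                      seed = NULL, horizon = 1e10) {
  if (n_replicates < 100) stop("n_replicates must be >= 100")
  times <- simulate_interruption_time(cds, model, n = n_replicates,
                                      seed = seed, horizon = horizon)
  cf <- mean(is.infinite(times))
  t_half <- if (cf >= 0.5) NA_real_ else median(times)
  structure(list(t_half = t_half, n_replicates = n_replicates,
                 interruption_times = times, censored_fraction = cf),
            class = "lifespan_estimate")
}

#' @exportS3Method base::print
print.lifespan_estimate <- function(x, ...) {
  cat("<lifespan_estimate> t1/2 =",
      if (is.na(x$t_half)) "undefined (>= 50% censored)"
      else sprintf("%.3g years", x$t_half),
      sprintf("(%d replicates, %.1f%% censored)\n",
              x$n_replicates, 100 * x$censored_fraction))
  invisible(x)
}

#' Probability of an ORF remaining intact under neutrality
#'
#' Evaluates the survival equation `p = lambda * exp(-lambda)` with
#' `lambda = (1/2)^(T / t_half)`, where `T` is the time since the lineage
#' divergence and `t_half` the neutral ORF half-life. The formula is a
#' minimal probability: at `T = 0` it evaluates to `exp(-1)`, not 1.
#'
#' @param T Years since divergence (vectorized, `>= 0`).
#' @param t_half Neutral half-life in years (`> 0`).
#' @return Tibble with columns `T`, `lambda`, `p`.
#' @export
survival_probability <- function(T, t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0)) stop("t_half must be > 0")
  if (any(T < 0)) stop("T must be >= 0")
  lambda <- 0.5^(T / t_half)
  tibble(T = T, lambda = lambda, p = lambda * exp(-lambda))
}
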