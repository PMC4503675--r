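# Expected unfolded site frequency spectrum under genic selection
# (Wright-Fisher diffusion). The density of derived-allele frequency q for a
# site with scaled selection coefficient gamma (= 2Ns; 0 neutral, negative
# deleterious) is proportional to
#   f(q; gamma) = (1 - exp(-2 gamma (1-q))) / ((1 - exp(-2 gamma)) q (1-q)),
# which reduces to 1/q as gamma -> 0. Binomial sampling of n chromosomes
# gives the expected spectrum; the neutral limit is the familiar 1/i law.

#' Expected site frequency spectrum under genic selection
#'
#' Returns the (unnormalized) expected number of sites with derived count
#' `i = 1..n-1`, up to a common mutation-supply factor. For `gamma = 0` this
#' is exactly `1/i`; for `gamma != 0` each entry is obtained by numerical
#' integration of the binomial-sampled diffusion density. Results are
#' memoized per `(n, gamma)`.
#'
#' @param n Number of sampled chromosomes (`>= 2`).
#' @param gamma Scaled selection coefficient (negative = deleterious).
#' @return Numeric vector of length `n - 1`.
#' @export
expected_sfs <- function(n, gamma = 0) {
  if (n < 2) stop("n must be >= 2")
  key <- paste0("sfs_", n, "_", gamma)
  if (!is.null(.lncorf_cache[[key]])) return(.lncorf_cache[[key]])
  i_seq <- seq_len(n - 1)
  if (gamma == 0) {
    out <- 1 / i_seq
  } else {
    denom <- 1 - exp(-2 * gamma)
    out <- vapply(i_seq, function(i) {
      integrand <- function(q) {
        stats::dbinom(i, n, q) * (1 - exp(-2 * gamma * (1 - q))) /
          (denom * q * (1 - q))
      }
      integrate(integrand, 0, 1, rel.tol = 1e-9,
                subdivisions = 500L)$value
    }, numeric(1))
  }
  .lncorf_cache[[key]] <- out
  out
}

# ratio of total segregating-site mass under selection vs neutrality;
# multiplies the neutral-expected segregating site count of a class
sfs_mass_factor <- function(n, gamma) {
  sum(expected_sfs(n, gamma)) / sum(expected_sfs(n, 0))
}
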