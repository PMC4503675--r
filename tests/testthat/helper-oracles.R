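# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# brute-force fragile-codon enumeration over the 61 sense codons
oracle_fragile_codons <- function() {
  all_codons <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES),
                      1, paste, collapse = "")
  sense <- setdiff(all_codons, ORACLE_STOPS)
  hits <- vapply(sense, function(cod) {
    any(vapply(ORACLE_STOPS, function(st)
      sum(strsplit(cod, "")[[1]] != strsplit(st, "")[[1]]) == 1, logical(1)))
  }, logical(1))
  sort(sense[hits])
}

# all-pairs mean pairwise differences per site from a haplotype 0/1 matrix
oracle_pi <- function(hap, L) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n, 2) / L
}

# plain-R event-driven ORF interruption simulator (independent of src/)
oracle_interruption_time <- function(seq, mu, nu, horizon = 1e10) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  t <- 0
  repeat {
    t <- t + rexp(1, L * (mu + nu))
    if (t > horizon) return(Inf)
    if (runif(1) < nu / (mu + nu)) return(t)
    j <- sample.int(L, 1)
    b[j] <- sample(setdiff(ORACLE_BASES, b[j]), 1)
    cod <- (j - 1) %/% 3
    if (cod < L / 3 - 1) {
      c3 <- paste(b[(3 * cod + 1):(3 * cod + 3)], collapse = "")
      if (c3 %in% ORACLE_STOPS) return(t)
    }
  }
}

# discrete-time (1-"year" Bernoulli steps) simulator; rates per site per
# step, intended to be run with small rates scaled up. Steps with no event
# are skipped geometrically, which is exactly the Bernoulli process.
oracle_discrete_time <- function(seq, mu, nu, max_steps = 1e7) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  p_event <- 1 - (1 - (mu + nu))^L
  t <- 0
  repeat {
    t <- t + 1 + rgeom(1, p_event)
    if (t > max_steps) return(Inf)
    if (runif(1) < nu / (mu + nu)) return(t)
    j <- sample.int(L, 1)
    b[j] <- sample(setdiff(ORACLE_BASES, b[j]), 1)
    cod <- (j - 1) %/% 3
    if (cod < L / 3 - 1) {
      c3 <- paste(b[(3 * cod + 1):(3 * cod + 3)], collapse = "")
      if (c3 %in% ORACLE_STOPS) return(t)
    }
  }
}

# Spearman rho via the explicit rank formula with mid-ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# build a codon_alignment from two equal-length in-frame sequences
pair_alignment <- function(q, s, gene = "g", qsp = "human", ssp = "subject") {
  qc <- substring(q, seq(1, nchar(q), 3), seq(3, nchar(q), 3))
  sc <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  rows <- tibble::tibble(
    query_codon_index = seq_along(qc), query_codon = qc, subject_codon = sc,
    event = ifelse(qc == sc, "match", "substitution"), indel_nt = NA_real_)
  codon_alignment(gene, qsp, ssp, rows, length(qc))
}

# random ORF string (sense codons only) for quick fixtures
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- character(n_codons - 1)
  for (i in seq_along(body)) {
    repeat {
      cod <- paste(sample(ORACLE_BASES, 3, replace = TRUE), collapse = "")
      if (!cod %in% ORACLE_STOPS) break
    }
    body[i] <- cod
  }
  paste0("ATG", paste(body, collapse = ""), sample(ORACLE_STOPS, 1))
}
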