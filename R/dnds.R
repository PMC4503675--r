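# Nei-Gojobori (1986)-style counting of synonymous and nonsynonymous sites
# and differences, with Jukes-Cantor correction. Mutations creating a stop
# codon are counted as nonsynonymous (nonsense substitutions), consistent
# with the binary site classification used elsewhere in the package.

# fractional synonymous site count per sense codon (memoized)
syn_sites_per_codon <- function(table = codon_table()) {
  if (!is.null(.lncorf_cache$syn_sites)) return(.lncorf_cache$syn_sites)
  sense <- names(table$code)[!(names(table$code) %in% table$stops)]
  s <- vapply(sense, function(cod) {
    aa <- table$code[[cod]]
    tot <- 0
    for (pos in 1:3) {
      syn <- 0L
      for (b in setdiff(BASES, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (identical(table$code[[mut]], aa)) syn <- syn + 1L
      }
      tot <- tot + syn / 3
    }
    tot
  }, numeric(1))
  .lncorf_cache$syn_sites <- s
  s
}

#' Synonymous and nonsynonymous site counts of a CDS
#'
#' Fractional site counts in the counting-method sense: at each codon
#' position, the synonymous fraction is the share of the three possible
#' changes that preserve the amino acid. Used as the denominators of piN/piS
#' and dN/dS. Terminal stop and codons containing `N` are excluded.
#'
#' @param cds A [coding_sequence()] or a character vector of codons.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
ng86_site_counts <- function(cds) {
  cods <- if (inherits(cds, "coding_sequence")) sense_codons(cds) else cds
  tab <- codon_table()
  cods <- cods[!grepl("N", cods) & !(cods %in% tab$stops)]
  s <- syn_sites_per_codon(tab)
  S <- sum(s[cods])
  c(S = S, N = 3 * length(cods) - S)
}

# average synonymous/nonsynonymous differences between two codons over all
# mutational pathways (pathways through stop codons are retained; a step to
# or from a stop is a nonsense step and counts as nonsynonymous)
codon_pair_diffs <- function(c1, c2, table = codon_table()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  paths <- if (d == 1) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    perms(pos)
  }
  aa_of <- function(cod) if (cod %in% table$stops) "*" else table$code[[cod]]
  sd_tot <- nd_tot <- 0
  for (path in paths) {
    cur <- c1
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (identical(aa_of(cur), aa_of(nxt)) && aa_of(cur) != "*")
        sd_tot <- sd_tot + 1 else nd_tot <- nd_tot + 1
      cur <- nxt
    }
  }
  c(sd = sd_tot / length(paths), nd = nd_tot / length(paths))
}

# raw counts for one aligned codon pair list
dnds_counts <- function(query_codons, subject_codons) {
  tab <- codon_table()
  keep <- !grepl("[^ACGT]", query_codons) & !grepl("[^ACGT]", subject_codons) &
    !(query_codons %in% tab$stops)
  q <- query_codons[keep]; s <- subject_codons[keep]
  sq <- syn_sites_per_codon(tab)
  # site counts averaged over the two sequences; subject stops contribute as
  # fully nonsynonymous positions (0 synonymous sites)
  s_sites_subject <- ifelse(s %in% tab$stops, 0, sq[s])
  S <- (sum(sq[q]) + sum(s_sites_subject)) / 2
  N <- 3 * length(q) - S
  diffs <- mapply(function(a, b) codon_pair_diffs(a, b, tab), q, s)
  if (length(q) == 0) diffs <- matrix(0, 2, 0, dimnames = list(c("sd", "nd")))
  c(S = S, N = N, Sd = sum(diffs["sd", ]), Nd = sum(diffs["nd", ]))
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Merged dN/dS across codon alignments by the counting method
#'
#' Pools observed synonymous/nonsynonymous differences and fractional site
#' counts across all supplied alignments, applies the Jukes-Cantor multiple-
#' hit correction per class, and returns the ratio. With a single alignment
#' this is the per-gene dN/dS.
#'
#' @param alignments A [codon_alignment()] or list of them. Each must carry
#'   query codons (see [codon_alignment()]).
#' @return List with `dN`, `dS`, `dnds` (`NA` with `flag = "undefined_ratio"`
#'   when pooled dS is 0), and the pooled counts `N`, `S`, `Nd`, `Sd`.
#' @export
merged_dnds <- function(alignments) {
  if (inherits(alignments, "codon_alignment")) alignments <- list(alignments)
  if (!length(alignments)) stop("need at least one alignment")
  tot <- c(S = 0, N = 0, Sd = 0, Nd = 0)
  for (aln in alignments) {
    stopifnot(inherits(aln, "codon_alignment"))
    rows <- aln$rows[aln$rows$event %in% c("match", "substitution"), , drop = FALSE]
    if (!nrow(rows)) next
    tot <- tot + dnds_counts(rows$query_codon, rows$subject_codon)[names(tot)]
  }
  if (tot[["S"]] + tot[["N"]] == 0) stop("no aligned codons in input")
  pS <- tot[["Sd"]] / tot[["S"]]
  pN <- tot[["Nd"]] / tot[["N"]]
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  if (is.na(dS) || dS == 0) {
    return(list(dN = dN, dS = dS, dnds = NA_real_, flag = "undefined_ratio",
                N = tot[["N"]], S = tot[["S"]], Nd = tot[["Nd"]], Sd = tot[["Sd"]]))
  }
  list(dN = dN, dS = dS, dnds = dN / dS, flag = NULL,
       N = tot[["N"]], S = tot[["S"]], Nd = tot[["Nd"]], Sd = tot[["Sd"]])
}
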