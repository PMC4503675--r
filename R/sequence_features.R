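# GC-content and fragile-codon characterization of ORFs. Stop codons are
# AT-rich, so GC-rich ORFs carry fewer codons one mutation away from a stop
# and are less susceptible to nonsense mutations.

BASES <- c("A", "C", "G", "T")

#' The standard genetic code used throughout the package
#'
#' All loci analysed are nuclear, so only NCBI translation table 1 is
#' supported: 64 codons, 61 sense codons, and the three stops TAA, TAG, TGA.
#'
#' @return A list with `code` (named character vector codon -> amino acid,
#'   stops encoded as `"*"`) and `stops` (the three stop codons).
#' @export
codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  stopifnot(length(code) == 64, length(stops) == 3)
  list(code = code, stops = stops)
}

#' Construct a coding sequence
#'
#' @param seq DNA string, length divisible by 3.
#' @param gene_id,species Optional identifiers.
#' @param includes_terminal_stop If `TRUE` the last codon must be a stop and
#'   no internal stop codon may be present.
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(seq, gene_id = NA_character_, species = NA_character_,
                            includes_terminal_stop = TRUE) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("coding sequence has characters outside A,C,G,T,N")
  if (nchar(seq) == 0 || nchar(seq) %% 3 != 0)
    stop("coding sequence length must be a positive multiple of 3")
  cods <- codons_of(seq)
  tab <- codon_table()
  if (includes_terminal_stop) {
    if (!cods[length(cods)] %in% tab$stops)
      stop("terminal codon is not a stop codon")
    internal <- cods[-length(cods)]
    if (any(internal %in% tab$stops))
      stop("internal stop codon at codon ",
           which(internal %in% tab$stops)[1])
  }
  structure(list(gene_id = gene_id, species = species, seq = seq,
                 includes_terminal_stop = includes_terminal_stop),
            class = "coding_sequence")
}

#' @exportS3Method base::print
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence>", x$gene_id, "-", nchar(x$seq) / 3, "codons",
      if (x$includes_terminal_stop) "(incl. terminal stop)" else "", "\n")
  invisible(x)
}

# split a DNA string into codons
codons_of <- function(seq) {
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# sense codons of a coding_sequence: drop terminal stop if flagged
sense_codons <- function(cds) {
  cods <- codons_of(cds$seq)
  if (cds$includes_terminal_stop) cods <- cods[-length(cods)]
  cods
}

#' GC content of a DNA sequence
#'
#' Fraction (G+C)/(A+C+G+T); `N` bases are excluded from both numerator and
#' denominator.
#'
#' @param seq DNA string (A, C, G, T, N).
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence has characters outside A,C,G,T,N")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  denom <- sum(ch != "N")
  if (denom == 0) stop("GC content undefined: empty or all-N sequence")
  sum(ch %in% c("G", "C")) / denom
}

#' GC content at third codon positions (GC3)
#'
#' Computed over third positions of sense codons only (terminal stop and any
#' codon containing `N` excluded).
#'
#' @param cds A [coding_sequence()].
#' @return Fraction in \[0, 1\].
#' @export
gc3 <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  tab <- codon_table()
  cods <- sense_codons(cds)
  cods <- cods[!grepl("N", cods) & !(cods %in% tab$stops)]
  if (!length(cods)) stop("GC3 undefined: no sense codons")
  third <- substr(cods, 3, 3)
  mean(third %in% c("G", "C"))
}

#' Enumerate fragile codons
#'
#' A fragile codon is a sense codon convertible to a stop codon by a single
#' point mutation. Under the standard code there are 18 such codons.
#'
#' @param table Codon table as returned by [codon_table()].
#' @return Character vector of fragile codons (sorted).
#' @export
fragile_codons <- function(table = codon_table()) {
  if (!is.null(.lncorf_cache$fragile)) return(.lncorf_cache$fragile)
  sense <- names(table$code)[!(names(table$code) %in% table$stops)]
  is_fragile <- vapply(sense, function(cod) {
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (mut %in% table$stops) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  .lncorf_cache$fragile <- sort(sense[is_fragile])
  .lncorf_cache$fragile
}

#' Fraction of fragile codons in an ORF
#'
#' Proportion of sense codons that are one point mutation away from a stop.
#' The terminal stop codon (if present) is excluded from both counts, as are
#' codons containing `N`.
#'
#' @param cds A [coding_sequence()].
#' @return Fraction in \[0, 1\].
#' @export
fragile_codon_fraction <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  tab <- codon_table()
  cods <- sense_codons(cds)
  cods <- cods[!grepl("N", cods) & !(cods %in% tab$stops)]
  if (!length(cods)) stop("fragile-codon fraction undefined: no sense codons")
  mean(cods %in% fragile_codons(tab))
}

#' Count single-mutation opportunities to create a stop codon
#'
#' Unlike [fragile_codon_fraction()], which counts each fragile codon once,
#' this counts every (site, alternative base) pair that would convert a sense
#' codon into a stop. It is the quantity entering the analytic nonsense-
#' mutation hazard of the lifespan module.
#'
#' @param cds A [coding_sequence()].
#' @return Non-negative integer count.
#' @export
stop_mutation_opportunities <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  tab <- codon_table()
  cods <- sense_codons(cds)
  cods <- cods[!grepl("N", cods) & !(cods %in% tab$stops)]
  opp <- opportunities_per_codon(tab)
  sum(opp[cods])
}

# memoized per-codon count of stop-creating single changes
opportunities_per_codon <- function(table = codon_table()) {
  if (!is.null(.lncorf_cache$opp)) return(.lncorf_cache$opp)
  sense <- names(table$code)[!(names(table$code) %in% table$stops)]
  opp <- vapply(sense, function(cod) {
    k <- 0L
    for (pos in 1:3) for (b in setdiff(BASES, substr(cod, pos, pos))) {
      mut <- cod
      substr(mut, pos, pos) <- b
      if (mut %in% table$stops) k <- k + 1L
    }
    k
  }, integer(1))
  .lncorf_cache$opp <- opp
  opp
}
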