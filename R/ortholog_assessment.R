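# Emergence stage: decide ORF presence/absence in outgroup species from
# codon-level alignments, detect common ancestral disablers, and date the
# ORF by parsimony on the species tree.

#' Construct a codon-level pairwise alignment
#'
#' The alignment is an ordered table of events in query (reference CDS) codon
#' coordinates. Each row is one of:
#' \describe{
#'   \item{match / substitution}{`query_codon_index`, `query_codon`,
#'     `subject_codon` populated; `indel_nt` is `NA`.}
#'   \item{deletion}{bases missing from the subject at this query codon;
#'     `indel_nt` gives the deleted length in nucleotides.}
#'   \item{insertion}{extra subject bases after this query codon; `indel_nt`
#'     gives the inserted length.}
#' }
#' Coverage is the fraction of query codons aligned to subject sequence
#' (match or substitution rows); identity is the fraction of those that
#' match.
#'
#' @param gene_id,query_species,subject_species Identifiers.
#' @param rows Tibble with columns `query_codon_index` (1-based), `query_codon`,
#'   `subject_codon`, `event`, `indel_nt`.
#' @param query_len_codons Length of the query ORF in codons (stop excluded).
#' @return Object of class `codon_alignment` with computed `coverage` and
#'   `identity`.
#' @export
codon_alignment <- function(gene_id, query_species, subject_species, rows,
                            query_len_codons) {
  stopifnot(is.data.frame(rows))
  need <- c("query_codon_index", "query_codon", "subject_codon", "event")
  if (!all(need %in% names(rows)))
    stop("alignment rows missing columns: ",
         paste(setdiff(need, names(rows)), collapse = ", "))
  if (!"indel_nt" %in% names(rows)) rows$indel_nt <- NA_real_
  ok_ev <- c("match", "substitution", "insertion", "deletion")
  if (!all(rows$event %in% ok_ev)) stop("unknown alignment event")
  idx <- rows$query_codon_index[!is.na(rows$query_codon_index)]
  if (is.unsorted(idx, strictly = FALSE))
    stop("query codon indices must be non-decreasing")
  aligned <- rows$event %in% c("match", "substitution")
  ali_idx <- unique(rows$query_codon_index[aligned])
  if (anyDuplicated(rows$query_codon_index[aligned]))
    stop("query codon indices must be strictly increasing over aligned rows")
  coverage <- length(ali_idx) / query_len_codons
  identity <- if (any(aligned)) mean(rows$event[aligned] == "match") else 0
  structure(list(gene_id = gene_id, query_species = query_species,
                 subject_species = subject_species, rows = as_tibble(rows),
                 query_len_codons = query_len_codons,
                 coverage = coverage, identity = identity),
            class = "codon_alignment")
}

#' @exportS3Method base::print
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s: %s vs %s (%d rows, coverage %.2f, identity %.2f)\n",
              x$gene_id, x$query_species, x$subject_species,
              nrow(x$rows), x$coverage, x$identity))
  invisible(x)
}

#' Write / read the codon-alignment exchange format
#'
#' A TSV with a `#`-prefixed metadata header (gene, species, query length)
#' and columns `query_codon_index`, `query_codon`, `subject_codon`, `event`,
#' `indel_nt`.
#'
#' @param aln A [codon_alignment()].
#' @param path File path.
#' @return `read_codon_alignment` returns the reconstructed alignment.
#' @export
write_codon_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#gene_id=%s\tquery_species=%s\tsubject_species=%s\tquery_len_codons=%d",
                     aln$gene_id, aln$query_species, aln$subject_species,
                     aln$query_len_codons), con)
  writeLines(paste(c("query_codon_index", "query_codon", "subject_codon",
                     "event", "indel_nt"), collapse = "\t"), con)
  r <- aln$rows
  writeLines(paste(ifelse(is.na(r$query_codon_index), ".", r$query_codon_index),
                   ifelse(is.na(r$query_codon), ".", r$query_codon),
                   ifelse(is.na(r$subject_codon), ".", r$subject_codon),
                   r$event,
                   ifelse(is.na(r$indel_nt), ".", r$indel_nt), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_codon_alignment
#' @export
read_codon_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_line <- sub("^#", "", lines[1])
  kv <- strsplit(strsplit(meta_line, "\t")[[1]], "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.table(text = lines[-1], sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = ".")
  rows <- tibble(query_codon_index = as.integer(df$query_codon_index),
                 query_codon = df$query_codon,
                 subject_codon = df$subject_codon,
                 event = df$event,
                 indel_nt = as.numeric(df$indel_nt))
  codon_alignment(meta[["gene_id"]], meta[["query_species"]],
                  meta[["subject_species"]], rows,
                  as.integer(meta[["query_len_codons"]]))
}

#' Alignment-quality filter
#'
#' High-quality alignments require coverage strictly above 70% and identity
#' strictly above 50%; values exactly at the thresholds fail.
#'
#' @param aln A [codon_alignment()].
#' @param min_coverage,min_identity Thresholds (strict inequalities).
#' @return Logical.
#' @export
filter_alignment_quality <- function(aln, min_coverage = 0.7, min_identity = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"))
  aln$coverage > min_coverage && aln$identity > min_identity
}

#' Assess ORF existence in an outgroup from a codon alignment
#'
#' Disruptions are premature stop codons in the subject (substitution rows
#' whose subject codon is a stop) and frameshifting indels (indel rows whose
#' length is not a multiple of 3). The ORF is regarded as non-existent when
#' at least one disruption is present and the maximum continuous ORF between
#' consecutive disruptions, measured in query codons, is shorter than
#' `min_fraction` (70%) of the query ORF length.
#'
#' @param aln A [codon_alignment()] that passed the quality filter.
#' @param query_len_codons Query ORF length in codons; defaults to the
#'   alignment's.
#' @param min_fraction Intact-fraction threshold (absent when strictly below).
#' @return Object of class `orf_status`: `species`, `present`, `disruptions`
#'   (tibble `kind`, `position`, `detail`), `max_intact_fraction`.
#' @export
assess_orf <- function(aln, query_len_codons = aln$query_len_codons,
                       min_fraction = 0.7) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(query_len_codons) || query_len_codons <= 0)
    stop("query_len_codons must be positive")
  tab <- codon_table()
  r <- aln$rows
  stops <- r$event == "substitution" & r$subject_codon %in% tab$stops
  fs <- r$event %in% c("insertion", "deletion") &
    !is.na(r$indel_nt) & (r$indel_nt %% 3 != 0)
  disruptions <- bind_rows(
    tibble(kind = rep("premature_stop", sum(stops)),
           position = r$query_codon_index[stops],
           detail = r$subject_codon[stops]),
    tibble(kind = rep("frameshift_indel", sum(fs)),
           position = r$query_codon_index[fs],
           detail = as.character(r$indel_nt[fs])))
  if (nrow(disruptions)) disruptions <- arrange(disruptions, position)
  if (nrow(disruptions) == 0) {
    mif <- aln$coverage
    present <- TRUE
  } else {
    cuts <- sort(unique(disruptions$position))
    seg <- diff(c(0, cuts, query_len_codons + 1)) - 1
    mif <- max(seg) / query_len_codons
    present <- mif >= min_fraction
  }
  structure(list(species = aln$subject_species, present = present,
                 disruptions = disruptions, max_intact_fraction = mif),
            class = "orf_status")
}

#' @exportS3Method base::print
print.orf_status <- function(x, ...) {
  cat(sprintf("<orf_status> %s: %s (%d disruptions, max intact %.2f)\n",
              x$species, if (x$present) "present" else "absent",
              nrow(x$disruptions), x$max_intact_fraction))
  invisible(x)
}

#' Detect common ancestral disablers
#'
#' A common ancestral disabler is a mutation disrupting the ORF in multiple
#' (at least `min_species`) outgroup species at the same query-codon position
#' with the same kind. Such sharing marks the disabler as ancestral by
#' parsimony, i.e. the gene is newly originated rather than an old dying
#' gene.
#'
#' @param statuses Named list of [assess_orf()] results.
#' @param outgroups Character vector naming the outgroup species considered.
#' @param min_species Minimum number of ORF-absent outgroup species that must
#'   share a disruption (default 2).
#' @return List with `shared` (tibble of shared disruptions with an
#'   `n_species` column) and `newly_originated` (logical).
#' @export
detect_common_disablers <- function(statuses, outgroups = names(statuses),
                                    min_species = 2) {
  statuses <- statuses[intersect(names(statuses), outgroups)]
  if (length(statuses) < 2)
    stop("insufficient evidence: need disruption data from >= 2 outgroups")
  absent <- statuses[!vapply(statuses, `[[`, logical(1), "present")]
  if (length(absent) < min_species)
    return(list(shared = tibble(kind = character(), position = integer(),
                                n_species = integer()),
                newly_originated = FALSE))
  all_d <- bind_rows(lapply(names(absent), function(sp) {
    d <- absent[[sp]]$disruptions
    if (nrow(d)) mutate(d[, c("kind", "position")], species = sp) else
      tibble(kind = character(), position = integer(), species = character())
  }))
  if (!nrow(all_d))
    return(list(shared = tibble(kind = character(), position = integer(),
                                n_species = integer()),
                newly_originated = FALSE))
  shared <- all_d %>%
    dplyr::distinct(.data$kind, .data$position, .data$species) %>%
    count(.data$kind, .data$position, name = "n_species") %>%
    filter(.data$n_species >= min_species)
  list(shared = shared, newly_originated = nrow(shared) > 0)
}

#' The default primate + rodent species tree
#'
#' Branch lengths are in years, with approximate divergence times of 6 My
#' (human-chimpanzee), 9 My (gorilla), 16 My (orangutan), 25 My (macaque)
#' and 90 My (mouse).
#' @return Newick string.
#' @export
default_species_tree <- function() {
  paste0("(((((human:6e6,chimp:6e6):3e6,gorilla:9e6):7e6,orangutan:16e6):9e6,",
         "macaque:25e6):65e6,mouse:90e6);")
}

#' Assign ORF age by parsimony
#'
#' Dollo parsimony: a single origination event at the most recent common
#' ancestor of all ORF-present species, with losses inferred for absent
#' species inside that clade. The result is flagged ambiguous when an
#' equally parsimonious multiple-gain scenario has the same event count.
#'
#' @param presence Named logical vector, species -> ORF present.
#' @param tree Newick string or `ape::phylo` containing all names in
#'   `presence`.
#' @param query Name of the focal species (must be present).
#' @return List with `origin_clade` (tip names of the origin clade),
#'   `age_label` (`"H"`, `"H-C"`, `"H-C-G"`, `"H-C-G-O"` or
#'   `"pre-hominoid"`), `species_label` (initial-list over the present great
#'   apes, e.g. `"H-C-O"`), `inferred_losses`, `ambiguous`.
#' @export
assign_age <- function(presence, tree = default_species_tree(), query = "human") {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!all(names(presence) %in% tree$tip.label))
    stop("presence vector names species missing from the tree")
  if (!isTRUE(presence[[query]]))
    stop("query species '", query, "' must have an intact ORF")
  present_sp <- names(presence)[presence]
  ntip <- length(tree$tip.label)
  if (length(present_sp) == 1) {
    clade_tips <- query
  } else {
    mrca <- ape::getMRCA(tree, present_sp)
    clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  }
  # species inside the origin clade scored absent (only scored species count)
  scored <- intersect(clade_tips, names(presence))
  losses <- scored[!presence[scored]]
  # event counts: Dollo = 1 gain + (# maximal absent clades inside origin),
  # alternative = independent gains (# maximal present clades), no losses
  n_clades <- function(state_tips) {
    if (!length(state_tips)) return(0L)
    # count maximal monophyletic groups of state_tips within the tree
    remaining <- state_tips
    k <- 0L
    while (length(remaining)) {
      tip <- remaining[1]
      node <- which(tree$tip.label == tip)
      best <- node
      repeat {
        parent <- tree$edge[tree$edge[, 2] == best, 1]
        if (!length(parent)) break
        desc <- tip_descendants(tree, parent)
        scored_desc <- intersect(desc, names(presence))
        if (all(scored_desc %in% state_tips)) best <- parent else break
      }
      clade <- if (best <= ntip) tree$tip.label[best] else tip_descendants(tree, best)
      remaining <- setdiff(remaining, clade)
      k <- k + 1L
    }
    k
  }
  n_loss_clades <- n_clades(losses)
  n_gain_clades <- n_clades(present_sp)
  ambiguous <- n_loss_clades > 0 && n_gain_clades == (1 + n_loss_clades)

  hominoid <- c("human", "chimp", "gorilla", "orangutan")
  lab_map <- c(human = "H", chimp = "H-C", gorilla = "H-C-G",
               orangutan = "H-C-G-O")
  deepest <- intersect(clade_tips, hominoid)
  age_label <- if (length(setdiff(clade_tips, hominoid)) > 0) "pre-hominoid"
  else lab_map[[hominoid[max(match(deepest, hominoid))]]]
  initials <- c(human = "H", chimp = "C", gorilla = "G", orangutan = "O")
  sp_lab <- paste(initials[hominoid[hominoid %in% present_sp]], collapse = "-")
  list(origin_clade = clade_tips, age_label = age_label,
       species_label = sp_lab, inferred_losses = losses,
       ambiguous = ambiguous)
}

# tips descending from a node (node may be a tip index)
tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  tree$tip.label[tips]
}
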