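# Seeded generators for every input the pipeline consumes: GC-controlled
# sequences, orthologs evolved on a phylogeny with injected ORF disablers,
# polymorphism panels drawn from neutral or selection-skewed frequency
# spectra, expression matrices with an intergenic background, and a complete
# fixture bundle on disk.

#' Generate a random DNA sequence with controlled GC content
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`. With `ensure_orf = TRUE` the
#' result is a valid ORF: it starts with ATG, internal stop codons are
#' resampled, and a terminal stop codon is appended.
#'
#' @param n_codons Length in codons (sense codons; the terminal stop is
#'   appended on top when `ensure_orf`). Alternatively give `length_bp`.
#' @param length_bp Length in bp (ignored when `n_codons` is given).
#' @param gc Target GC fraction in \[0, 1\].
#' @param ensure_orf Return a [coding_sequence()] instead of a plain string.
#' @param seed Optional seed.
#' @return DNA string, or a [coding_sequence()] when `ensure_orf`.
#' @export
generate_sequence <- function(n_codons = NULL, length_bp = NULL, gc = 0.5,
                              ensure_orf = FALSE, seed = NULL) {
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(k) paste(sample(BASES, k, replace = TRUE, prob = probs),
                            collapse = "")
  if (!ensure_orf) {
    if (is.null(length_bp)) length_bp <- 3 * n_codons
    if (is.null(length_bp) || length_bp < 1) stop("need a positive length")
    return(draw(length_bp))
  }
  if (is.null(n_codons) || n_codons < 2)
    stop("an ORF needs at least 2 sense codons")
  tab <- codon_table()
  body <- codons_of(draw(3 * (n_codons - 1)))
  while (any(bad <- body %in% tab$stops))
    body[bad] <- codons_of(draw(3 * sum(bad)))
  stop_cod <- sample(tab$stops, 1)
  coding_sequence(paste0("ATG", paste(body, collapse = ""), stop_cod),
                  includes_terminal_stop = TRUE)
}

# apply k point substitutions (kappa-weighted) to a base vector; positions
# carrying an injected disabler are protected so that disablers persist in
# every descendant at the same aligned position. With constrained = TRUE,
# substitutions that create an internal stop, destroy the start codon or
# destroy the terminal stop are rejected (purifying constraint).
mutate_bases <- function(bases, k, kappa = 1, constrained = FALSE,
                         protected = integer(0), terminal_stop = TRUE) {
  L <- length(bases)
  ncod <- L %/% 3
  stops <- c("TAA", "TAG", "TGA")
  if (k <= 0) return(bases)
  sites <- sample.int(L, k, replace = TRUE)
  w <- c(kappa, 1, 1)
  for (j in sites) {
    if (((j - 1) %/% 3 + 1) %in% protected) next
    b <- bases[j]
    trans <- BASES[(match(b, BASES) - 1 + 2) %% 4 + 1]
    alts <- c(trans, setdiff(BASES, c(b, trans)))
    nb <- sample(alts, 1, prob = w)
    if (constrained) {
      cod_i <- (j - 1) %/% 3
      old <- bases[j]
      bases[j] <- nb
      cod <- paste(bases[(3 * cod_i + 1):(3 * cod_i + 3)], collapse = "")
      internal <- cod_i < ncod - 1 || !terminal_stop
      viol <- (internal && cod %in% stops) ||
        (!internal && terminal_stop && !(cod %in% stops)) ||
        (cod_i == 0 && cod != "ATG")
      if (viol) bases[j] <- old
    } else {
      bases[j] <- nb
    }
  }
  bases
}

#' Evolve orthologous sequences along a species tree
#'
#' The ancestor sits at the root; point substitutions accrue along each
#' branch as a Poisson process with the model's point rate (branch lengths
#' in years). Indels are introduced only as injected disablers, so the codon
#' register is shared across tips and the emitted alignments are exact.
#' Injected disabler positions are protected from later substitution, so
#' every descendant of the injection branch carries the disabler at the same
#' aligned codon.
#'
#' @param ancestor A [coding_sequence()] or DNA string (length divisible
#'   by 3).
#' @param tree Newick string or `ape::phylo`, branch lengths in years.
#' @param model A [mutation_model()] (its point rate and kappa are used).
#' @param disablers List of disablers, each
#'   `list(kind = "premature_stop"|"frameshift_indel", position = <codon>,
#'   clade = <tip names>)`. A disabler whose clade is all tips except one is
#'   applied at the root and reverted on the excluded tip's terminal branch.
#' @param constrained Evolve under purifying constraint (no ORF-disrupting
#'   substitutions anywhere on the tree).
#' @param query Focal species used as alignment query.
#' @param enforce_query_orf Rewrite the query tip into an intact ORF
#'   (restore ATG, resample internal stops, restore the terminal stop) —
#'   the ORF-creating mutations of the focal lineage.
#' @param seed Optional seed.
#' @return List with `tips` (named DNA strings, indels applied),
#'   `tip_codon_register` (named codon-register strings before indel
#'   removal), `alignments` (named list of [codon_alignment()] of query vs
#'   each other tip) and `disablers` (as applied).
#' @export
evolve_orthologs <- function(ancestor, tree = default_species_tree(),
                             model = mutation_model(), disablers = NULL,
                             constrained = FALSE, query = "human",
                             enforce_query_orf = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  seq0 <- if (inherits(ancestor, "coding_sequence")) ancestor$seq else toupper(ancestor)
  if (nchar(seq0) %% 3 != 0) stop("ancestor length must be a multiple of 3")
  terminal_stop <- if (inherits(ancestor, "coding_sequence"))
    ancestor$includes_terminal_stop else TRUE
  L <- nchar(seq0)
  ncod_all <- L %/% 3
  n_sense <- ncod_all - as.integer(terminal_stop)
  tab <- codon_table()
  ntip <- length(tree$tip.label)
  root <- ntip + 1

  # resolve disablers to (branch-to-node, revert-tip) form
  root_bases <- strsplit(seq0, "")[[1]]
  applied <- list()
  inject_at <- rep(list(list()), ntip + tree$Nnode) # per-node disabler list
  revert_at <- rep(list(list()), ntip)
  for (d in disablers %||% list()) {
    if (is.null(d$position) || d$position < 1 || d$position > n_sense)
      stop("disabler position outside the ORF")
    tips <- d$clade
    if (!all(tips %in% tree$tip.label)) stop("unknown clade tip in disabler")
    excl <- setdiff(tree$tip.label, tips)
    if (length(tips) == 1) {
      node <- which(tree$tip.label == tips)
    } else if (length(excl) == 0) {
      node <- root
    } else {
      node <- ape::getMRCA(tree, tips)
      if (!setequal(tip_descendants(tree, node), tips)) {
        if (length(excl) == 1) {
          node <- root
          ti <- which(tree$tip.label == excl)
          revert_at[[ti]] <- c(revert_at[[ti]], list(d))
        } else stop("disabler clade is not monophyletic")
      }
    }
    inject_at[[node]] <- c(inject_at[[node]], list(d))
  }

  apply_disabler <- function(bases, d) {
    cod_i <- d$position - 1
    if (d$kind == "premature_stop") {
      bases[(3 * cod_i + 1):(3 * cod_i + 3)] <- strsplit(sample(tab$stops, 1), "")[[1]]
    }
    bases
  }

  # depth-first evolution; state = list(bases, protected codons, indels)
  states <- vector("list", ntip + tree$Nnode)
  st0 <- list(bases = root_bases, protected = integer(0), indels = list())
  for (d in inject_at[[root]]) {
    if (d$kind == "premature_stop") st0$bases <- apply_disabler(st0$bases, d)
    else st0$indels <- c(st0$indels, list(d))
    st0$protected <- c(st0$protected, d$position)
  }
  states[[root]] <- st0
  # process edges in preorder (parents before children)
  ct <- ape::reorder.phylo(tree, "cladewise")
  edges <- ct$edge
  elen <- ct$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    st <- states[[parent]]
    k <- rpois(1, model$point_rate * elen[e] * L)
    st$bases <- mutate_bases(st$bases, k, model$kappa, constrained,
                             st$protected, terminal_stop)
    for (d in inject_at[[child]]) {
      if (d$kind == "premature_stop") st$bases <- apply_disabler(st$bases, d)
      else st$indels <- c(st$indels, list(d))
      st$protected <- c(st$protected, d$position)
    }
    if (child <= ntip && length(revert_at[[child]])) {
      for (d in revert_at[[child]]) {
        cod_i <- d$position - 1
        if (d$kind == "premature_stop") {
          # restore the ancestral sense codon
          bases0 <- strsplit(seq0, "")[[1]]
          st$bases[(3 * cod_i + 1):(3 * cod_i + 3)] <- bases0[(3 * cod_i + 1):(3 * cod_i + 3)]
        } else {
          st$indels <- Filter(function(x) !identical(x, d), st$indels)
        }
        st$protected <- setdiff(st$protected, d$position)
      }
    }
    states[[child]] <- st
  }

  tip_states <- states[seq_len(ntip)]
  names(tip_states) <- tree$tip.label

  if (enforce_query_orf) {
    st <- tip_states[[query]]
    b <- st$bases
    b[1:3] <- c("A", "T", "G")
    cods <- codons_of(paste(b, collapse = ""))
    idx <- which(cods[seq_len(n_sense)] %in% tab$stops)
    for (i in idx) {
      repeat {
        nc <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
        if (!nc %in% tab$stops) break
      }
      b[(3 * i - 2):(3 * i)] <- strsplit(nc, "")[[1]]
    }
    if (terminal_stop && !(paste(b[(L - 2):L], collapse = "") %in% tab$stops))
      b[(L - 2):L] <- strsplit(sample(tab$stops, 1), "")[[1]]
    st$bases <- b
    st$indels <- list()
    tip_states[[query]] <- st
  }

  register <- vapply(tip_states, function(st) paste(st$bases, collapse = ""), "")
  tips <- vapply(names(tip_states), function(sp) {
    st <- tip_states[[sp]]
    b <- st$bases
    drop <- unlist(lapply(st$indels, function(d) 3 * (d$position - 1) + 1))
    if (length(drop)) b <- b[-drop]
    paste(b, collapse = "")
  }, "")

  q_cods <- codons_of(register[[query]])
  alns <- list()
  for (sp in setdiff(tree$tip.label, query)) {
    s_cods <- codons_of(register[[sp]])
    rows <- tibble(query_codon_index = seq_len(n_sense),
                   query_codon = q_cods[seq_len(n_sense)],
                   subject_codon = s_cods[seq_len(n_sense)],
                   event = ifelse(q_cods[seq_len(n_sense)] ==
                                    s_cods[seq_len(n_sense)],
                                  "match", "substitution"),
                   indel_nt = NA_real_)
    for (d in tip_states[[sp]]$indels) {
      rows <- bind_rows(rows, tibble(query_codon_index = d$position,
                                     query_codon = q_cods[d$position],
                                     subject_codon = NA_character_,
                                     event = "deletion", indel_nt = 1))
    }
    rows <- arrange(rows, .data$query_codon_index, .data$event != "deletion")
    alns[[sp]] <- codon_alignment(
      gene_id = if (inherits(ancestor, "coding_sequence"))
        ancestor$gene_id else NA_character_,
      query_species = query, subject_species = sp,
      rows = rows, query_len_codons = n_sense)
  }
  list(tips = tips, tip_codon_register = register, alignments = alns,
       disablers = disablers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a polymorphism panel under neutral or purifying-selection spectra
#'
#' For each site class the number of segregating sites is Poisson with mean
#' equal to the neutral-expected count scaled by the selection mass factor,
#' and derived-allele counts are drawn from the expected spectrum
#' [expected_sfs()] for the class's `gamma`. Coding sites are placed on real
#' (position, alternative-allele) pairs whose classification matches the
#' class, so the pipeline's own classifier reproduces the truth; noncoding
#' sites are placed uniformly. The reference allele is taken as ancestral,
#' so the spectra are unfolded.
#'
#' @param region A [region_annotation()] with CDS/UTR/intron intervals.
#' @param cds The panel CDS as a [coding_sequence()].
#' @param n Number of sampled chromosomes.
#' @param sites Named vector of neutral-expected segregating-site counts per
#'   class (`synonymous`, `nonsynonymous`, `UTR`, `intron`).
#' @param gamma Named vector of scaled selection coefficients per class
#'   (classes not named are neutral).
#' @param seed Optional seed.
#' @param genotypes Attach per-sample diploid genotype strings (needed to
#'   write a VCF).
#' @return Variant tibble compatible with [read_variants()], with an extra
#'   `true_class` column.
#' @export
simulate_polymorphism <- function(region, cds, n, sites, gamma = c(), seed = NULL,
                                  genotypes = FALSE) {
  stopifnot(inherits(region, "region_annotation"),
            inherits(cds, "coding_sequence"))
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  catalog <- coding_site_catalog(region, cds)
  iv <- region$intervals
  out <- list()
  for (cl in names(sites)) {
    g <- if (cl %in% names(gamma)) gamma[[cl]] else 0
    S <- rpois(1, sites[[cl]] * sfs_mass_factor(n, g))
    if (S == 0) next
    if (cl %in% c("synonymous", "nonsynonymous")) {
      pool <- catalog[catalog$site_class == cl, , drop = FALSE]
      if (S > nrow(pool)) S <- nrow(pool)
      pick <- pool[sample.int(nrow(pool), S), , drop = FALSE]
      v <- tibble(contig = iv$contig[1], pos = pick$pos, ref = pick$ref,
                  alt = pick$alt, true_class = cl)
    } else {
      ivs <- iv[iv$class == cl, , drop = FALSE]
      if (!nrow(ivs)) stop("no intervals for class ", cl)
      all_pos <- unlist(lapply(seq_len(nrow(ivs)),
                               function(i) seq(ivs$start[i], ivs$end[i] - 1)))
      if (S > length(all_pos)) S <- length(all_pos)
      pos <- sample(all_pos, S)
      ref <- sample(BASES, S, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
      v <- tibble(contig = ivs$contig[1], pos = pos, ref = ref, alt = alt,
                  true_class = cl)
    }
    f <- expected_sfs(n, g)
    v$derived_count <- sample.int(n - 1, nrow(v), replace = TRUE,
                                  prob = f / sum(f))
    out[[cl]] <- v
  }
  v <- bind_rows(out)
  if (!nrow(v)) return(v)
  v <- arrange(v, .data$pos)
  v <- mutate(v, pos1 = .data$pos + 1, aa = .data$ref,
              aa_status = "polarized", n = !!n, ac = .data$derived_count)
  if (genotypes) {
    n_samp <- n %/% 2
    v$gt <- lapply(v$derived_count, function(i) {
      alleles <- integer(n)
      alleles[sample.int(n, i)] <- 1L
      paste0(alleles[seq(1, 2 * n_samp, 2)], "/", alleles[seq(2, 2 * n_samp, 2)])
    })
  }
  v[, c("contig", "pos", "pos1", "ref", "alt", "aa", "aa_status", "n", "ac",
        "derived_count", if (genotypes) "gt", "true_class")]
}

# every (CDS position, alternative allele) pair with its site class
coding_site_catalog <- function(region, cds) {
  tab <- codon_table()
  cds_iv <- region$intervals[region$intervals$class == "CDS", , drop = FALSE]
  pos <- cds_genomic_positions(cds_iv)
  cods <- codons_of(cds$seq)
  n_sense <- length(sense_codons(cds))
  rows <- list()
  ref_b <- strsplit(cds$seq, "")[[1]]
  for (off in 1:3) {
    idx <- seq(off, 3 * n_sense, by = 3) # coding-order base index
    cod_i <- (idx - 1) %/% 3 + 1
    cod <- cods[cod_i]
    for (b in BASES) {
      ok <- ref_b[idx] != b
      mut <- cod
      substr(mut, off, off) <- b
      aa0 <- unname(tab$code[cod])
      aa1 <- ifelse(mut %in% tab$stops, "*", unname(tab$code[mut]))
      cl <- ifelse(aa0 == aa1, "synonymous", "nonsynonymous")
      rows[[paste(off, b)]] <- tibble(pos = pos[idx][ok], ref = ref_b[idx][ok],
                                      alt = b, site_class = cl[ok])
    }
  }
  bind_rows(rows)
}

#' Preset polymorphism panels
#'
#' Fixed study conditions for the two populations contrasted by the
#' selection stage: a human-like panel (`"selection-strong"`, 134
#' chromosomes = 67 diploid individuals, purifying selection `gamma = -10`
#' on nonsynonymous sites) and a macaque-like panel (`"neutral-only"`, 164
#' chromosomes = 82 animals, fully neutral). The panel locus pools the
#' coding and non-coding sequence of a de novo gene catalog: 30 kb CDS
#' (GC 0.57), 20 kb UTR and 120 kb intron, with a neutral variant density of
#' 0.02 segregating sites per bp.
#'
#' @param name Preset name.
#' @param seed Seed for the panel CDS and the polymorphism draw.
#' @param scale Multiplier on the locus/site sizes (use < 1 for quick runs).
#' @return List with `region`, `cds`, `n`, `sites`, `gamma`, and the drawn
#'   `variants`.
#' @export
polymorphism_preset <- function(name = c("selection-strong", "neutral-only"),
                                seed = 1, scale = 1) {
  name <- match.arg(name)
  set.seed(as.integer(seed))
  cds_bp <- round(30000 * scale / 3) * 3
  utr_bp <- round(20000 * scale)
  intron_bp <- round(120000 * scale)
  cds <- generate_sequence(n_codons = cds_bp / 3 - 1, gc = 0.57, ensure_orf = TRUE)
  region <- region_annotation("panel", tibble(
    contig = "panel",
    start = c(0, cds_bp, cds_bp + utr_bp, 0),
    end = c(cds_bp, cds_bp + utr_bp, cds_bp + utr_bp + intron_bp, cds_bp + utr_bp),
    strand = "+",
    class = c("CDS", "UTR", "intron", "exon")))
  sc <- ng86_site_counts(cds)
  u <- 0.02
  sites <- c(synonymous = u * sc[["S"]], nonsynonymous = u * sc[["N"]],
             UTR = u * utr_bp, intron = u * intron_bp)
  n <- if (name == "selection-strong") 134L else 164L
  gamma <- if (name == "selection-strong") c(nonsynonymous = -10) else c()
  variants <- simulate_polymorphism(region, cds, n, sites, gamma)
  list(name = name, region = region, cds = cds, n = n, sites = sites,
       gamma = gamma, variants = variants)
}

#' Generate a tissue expression matrix and intergenic background
#'
#' Gene x tissue RPKMs are log-normal around a per-gene tissue profile;
#' passing the same `profile` again (e.g. for an orthologous species) yields
#' correlated tissue profiles, with `noise_sd` controlling the departure.
#' The intergenic background sample is drawn near zero with a configurable
#' fraction of draws exceeding 0.2 RPKM.
#'
#' @param genes Gene identifiers.
#' @param tissues Tissue names (default 17 human tissues).
#' @param profile Optional gene x tissue matrix of log-mean levels to reuse.
#' @param noise_sd Log-scale noise added on top of the profile.
#' @param n_background Background sample size (default 10,000).
#' @param background_exceed Fraction of background draws above 0.2 RPKM.
#' @param seed Optional seed.
#' @return List with `rpkm` (matrix), `profile` (log-mean matrix) and
#'   `background` (numeric vector).
#' @export
generate_expression_matrix <- function(genes, tissues = default_tissues(),
                                       profile = NULL, noise_sd = 0.25,
                                       n_background = 10000,
                                       background_exceed = 0.02, seed = NULL) {
  if (!length(genes) || !length(tissues)) stop("need >= 1 gene and tissue")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(profile)) {
    base <- rnorm(length(genes), 0, 1)
    profile <- outer(base, rep(0, length(tissues)), `+`) +
      matrix(rnorm(length(genes) * length(tissues), 0, 1),
             nrow = length(genes))
    dimnames(profile) <- list(genes, tissues)
  }
  noise <- if (noise_sd > 0)
    matrix(rnorm(length(profile), 0, noise_sd), nrow = nrow(profile)) else 0
  rpkm <- exp(profile + noise)
  dimnames(rpkm) <- dimnames(profile)
  rate <- -log(background_exceed) / 0.2
  background <- rexp(n_background, rate)
  list(rpkm = rpkm, profile = profile, background = background)
}

#' @rdname generate_expression_matrix
#' @export
default_tissues <- function() {
  c("Adipose", "Adrenal", "Blood", "Brain", "Breast", "Cerebellum", "Colon",
    "Heart", "Kidney", "Liver", "Lung", "Lymph_node", "Muscle", "Ovary",
    "Prostate", "Testes", "Thyroid")
}

#' Write a complete synthetic fixture bundle
#'
#' Creates, under `dir`, everything [run_pipeline()] needs: per-gene FASTA
#' and codon alignments for a panel of de novo-like genes (human-intact ORF
#' with a shared ancestral disabler in all outgroups), dying-gene decoys
#' (independent disablers at distinct positions) and deeply conserved
#' controls (ORF intact everywhere); the species tree; a gene-info table
#' with the construction truth; an expression matrix with intergenic
#' background; polymorphism panels (human-like with purifying selection on
#' nonsynonymous sites, macaque-like neutral) as VCF + BED + FASTA; and a
#' checksum manifest.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed; the bundle is bit-reproducible given the seed.
#' @param n_de_novo,n_dying,n_control Genes per class.
#' @param panel_scale Size multiplier for the polymorphism panels.
#' @param tree Species tree (newick, branch lengths in years).
#' @return Invisible list with the truth table and file paths.
#' @export
make_fixture_bundle <- function(dir, seed = 1, n_de_novo = 3, n_dying = 3,
                                n_control = 3, panel_scale = 0.1,
                                tree = default_species_tree()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  set.seed(as.integer(seed))
  phy <- ape::read.tree(text = tree)
  outgroups <- setdiff(phy$tip.label, "human")
  model <- mutation_model()

  specs <- bind_rows(
    tibble(true_class = "de_novo", gc = 0.57, i = seq_len(n_de_novo)),
    tibble(true_class = "dying", gc = 0.50, i = seq_len(n_dying)),
    tibble(true_class = "control", gc = 0.53, i = seq_len(n_control)))
  specs$gene_id <- sprintf("SYNG%02d_%s", seq_len(nrow(specs)), specs$true_class)
  specs$n_codons <- sample(100:300, nrow(specs), replace = TRUE)
  specs$disabler_pos <- NA_integer_

  human_seqs <- character(0)
  for (r in seq_len(nrow(specs))) {
    gid <- specs$gene_id[r]
    nc <- specs$n_codons[r]
    anc <- generate_sequence(n_codons = nc, gc = specs$gc[r], ensure_orf = TRUE)
    anc$gene_id <- gid
    central <- function(k = 1) sort(sample(seq(ceiling(0.35 * nc), floor(0.65 * nc)), k))
    dis <- switch(specs$true_class[r],
      de_novo = {
        p <- central(1)
        specs$disabler_pos[r] <- p
        list(list(kind = "premature_stop", position = p, clade = outgroups))
      },
      dying = {
        ps <- central(length(outgroups))
        lapply(seq_along(outgroups), function(k)
          list(kind = "premature_stop", position = ps[k], clade = outgroups[k]))
      },
      control = NULL)
    ev <- evolve_orthologs(anc, phy, model, disablers = dis,
                           constrained = specs$true_class[r] != "de_novo",
                           enforce_query_orf = specs$true_class[r] == "de_novo")
    human_seqs[gid] <- ev$tips[["human"]]
    for (sp in names(ev$alignments))
      write_codon_alignment(ev$alignments[[sp]],
                            file.path(dir, "alignments",
                                      paste0(gid, "_", sp, ".aln.tsv")))
  }
  write_fasta(human_seqs, file.path(dir, "cds_human.fasta"))
  writeLines(tree, file.path(dir, "tree.nwk"))

  # expression: all genes expressed so emergence rules drive the bundle truth
  em <- generate_expression_matrix(specs$gene_id)
  em$rpkm <- em$rpkm * 2 # keep maxima comfortably above the 0.5 cutoff
  expr <- data.frame(gene_id = rownames(em$rpkm), em$rpkm, check.names = FALSE)
  write.table(expr, file.path(dir, "expression_rpkm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(rpkm = em$background),
              file.path(dir, "background_rpkm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  info <- specs[, c("gene_id", "true_class", "n_codons", "gc", "disabler_pos")]
  info$peptide_count <- pmax(1L, rpois(nrow(info), 5))
  write.table(info, file.path(dir, "gene_info.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # polymorphism panels
  for (p in c("selection-strong", "neutral-only")) {
    tag <- if (p == "selection-strong") "human_panel" else "macaque_panel"
    ps <- polymorphism_preset(p, seed = seed + 1000, scale = panel_scale)
    ps$variants <- simulate_polymorphism(ps$region, ps$cds, ps$n, ps$sites,
                                         ps$gamma, genotypes = TRUE)
    write_variants(ps$variants, file.path(dir, paste0(tag, ".vcf")))
    iv <- ps$region$intervals
    write_bed(tibble(contig = iv$contig, start = iv$start, end = iv$end,
                     name = iv$class, score = NA, strand = iv$strand),
              file.path(dir, paste0(tag, ".bed")))
    write_fasta(setNames(ps$cds$seq, "panel_cds"),
                file.path(dir, paste0(tag, "_cds.fasta")))
  }

  files <- setdiff(list.files(dir, recursive = TRUE), "MANIFEST.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, truth = info, manifest = manifest))
}
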