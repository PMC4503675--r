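# Orchestration of the three stages over a fixture bundle directory:
# emergence -> sequence features / lifespan -> expression -> population
# genetics, with one first-failing exclusion rule recorded per gene.

#' Default pipeline configuration
#'
#' Thresholds and replicate counts used by [run_pipeline()]; all values can
#' be overridden by the `config` argument.
#'
#' @return Named list of defaults: alignment coverage (> 0.7) and identity
#'   (> 0.5), intact-ORF fraction (0.7), RPKM cutoffs (0.5 for gene
#'   expression, 0.2 for ortholog transcription), replicate counts (20,000
#'   lifespan, 10,000 Monte Carlo, 1,000 bootstrap), and per-age divergence
#'   times in years.
#' @export
pipeline_config <- function() {
  list(min_coverage = 0.7, min_identity = 0.5, orf_fraction = 0.7,
       rpkm_gene = 0.5, rpkm_background = 0.2,
       lifespan_replicates = 20000, mc_replicates = 10000,
       bootstrap_replicates = 1000,
       divergence_time = c(H = 6e6, `H-C` = 9e6, `H-C-G` = 16e6,
                           `H-C-G-O` = 25e6, `pre-hominoid` = 90e6))
}

#' Run the full trilogy pipeline on a fixture bundle
#'
#' Stages run in order: emergence (alignment quality, ORF assessment,
#' common-disabler detection, parsimony age), features (GC, GC3, fragile
#' codons), lifespan (neutral half-life and survival probability),
#' expression (cutoff filter), and popgen (per-region diversity, piN/piS,
#' Monte Carlo exon/intron test, derived-allele spectra on the bundled
#' panels). Every excluded gene records the first rule that fired. Results
#' are deterministic given `seed`.
#'
#' @param bundle_dir Directory written by [make_fixture_bundle()].
#' @param seed Master seed.
#' @param stages Character vector of stages to run (emergence is always
#'   run).
#' @param config Named list overriding entries of [pipeline_config()].
#' @param out_dir Optional directory for `report.tsv` and `log.jsonl`.
#' @return List with `report` (per-gene tibble), `popgen` (panel statistics,
#'   when run), `summary` (age-class counts of the de novo calls) and `log`
#'   (tibble of rule firings).
#' @export
run_pipeline <- function(bundle_dir, seed = 1,
                         stages = c("emergence", "features", "lifespan",
                                    "expression", "popgen"),
                         config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(pipeline_config(), config)
  set.seed(as.integer(seed))
  info <- as_tibble(read.table(file.path(bundle_dir, "gene_info.tsv"),
                               sep = "\t", header = TRUE))
  tree <- paste(readLines(file.path(bundle_dir, "tree.nwk")), collapse = "")
  human <- read_fasta(file.path(bundle_dir, "cds_human.fasta"))
  expr_df <- read.table(file.path(bundle_dir, "expression_rpkm.tsv"),
                        sep = "\t", header = TRUE, check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene_id
  aln_dir <- file.path(bundle_dir, "alignments")

  logs <- list()
  note <- function(gene, stage, rule, value) {
    logs[[length(logs) + 1]] <<- tibble(gene_id = gene, stage = stage,
                                        rule = rule,
                                        value = as.character(value))
  }

  rows <- list()
  for (r in seq_len(nrow(info))) {
    gid <- info$gene_id[r]
    cds <- coding_sequence(human[[gid]], gene_id = gid, species = "human")
    n_sense <- length(sense_codons(cds))
    aln_files <- list.files(aln_dir, pattern = paste0("^", gid, "_.*\\.aln\\.tsv$"),
                            full.names = TRUE)
    alns <- lapply(aln_files, read_codon_alignment)
    names(alns) <- vapply(alns, `[[`, "", "subject_species")
    pass <- vapply(alns, filter_alignment_quality, logical(1),
                   min_coverage = cfg$min_coverage,
                   min_identity = cfg$min_identity)
    for (sp in names(pass)[!pass]) note(gid, "emergence", "alignment_quality", sp)
    kept <- alns[pass]

    statuses <- lapply(kept, assess_orf, query_len_codons = n_sense,
                       min_fraction = cfg$orf_fraction)
    names(statuses) <- names(kept)
    presence <- c(human = TRUE,
                  vapply(statuses, `[[`, logical(1), "present"))
    absent_outgroups <- names(statuses)[!vapply(statuses, `[[`, logical(1),
                                                "present")]
    age <- assign_age(presence, tree, query = "human")

    exclusion <- NA_character_
    newly <- FALSE
    if (length(kept) < 2) {
      exclusion <- "alignment_quality"
    } else if (length(absent_outgroups) == 0) {
      exclusion <- "orf_present_in_outgroups"
    } else {
      cd <- detect_common_disablers(statuses)
      newly <- cd$newly_originated
      if (!newly) exclusion <- "no_common_disabler"
    }

    feats <- if ("features" %in% stages) {
      list(gc = gc_content(cds$seq), gc3 = gc3(cds),
           fragile = fragile_codon_fraction(cds))
    } else list(gc = NA_real_, gc3 = NA_real_, fragile = NA_real_)

    life <- list(t_half = NA_real_, lambda = NA_real_, p = NA_real_,
                 censored = NA_real_)
    if ("lifespan" %in% stages) {
      est <- half_life(cds, n_replicates = cfg$lifespan_replicates,
                       seed = seed + r)
      Tdiv <- cfg$divergence_time[[age$age_label]]
      sp <- if (!is.na(est$t_half)) survival_probability(Tdiv, est$t_half) else
        tibble(lambda = NA_real_, p = NA_real_)
      life <- list(t_half = est$t_half, lambda = sp$lambda, p = sp$p,
                   censored = est$censored_fraction)
    }

    expressed <- NA
    breadth <- NA_integer_
    top <- NA_character_
    if ("expression" %in% stages) {
      ef <- expression_filter(expr[gid, ], cutoff = cfg$rpkm_gene)
      expressed <- ef$expressed; breadth <- ef$breadth; top <- ef$top_tissue
      if (is.na(exclusion) && !expressed) exclusion <- "not_expressed"
    }
    peptide_ok <- !("peptide_count" %in% names(info)) ||
      info$peptide_count[r] > 0
    if (is.na(exclusion) && !peptide_ok) exclusion <- "no_peptide_evidence"

    is_de_novo <- is.na(exclusion) && newly &&
      (!("expression" %in% stages) || isTRUE(expressed))
    if (!is.na(exclusion)) note(gid, "emergence", "excluded", exclusion)

    rows[[gid]] <- tibble(
      gene_id = gid, classification = if (is_de_novo) "de_novo" else "excluded",
      exclusion_reason = exclusion, newly_originated = newly,
      age_label = age$age_label, species_label = age$species_label,
      age_ambiguous = age$ambiguous,
      n_outgroups_assessed = length(kept),
      n_outgroups_absent = length(absent_outgroups),
      gc = feats$gc, gc3 = feats$gc3, fragile_fraction = feats$fragile,
      t_half = life$t_half, lambda = life$lambda, survival_p = life$p,
      expressed = expressed, tissue_breadth = breadth, top_tissue = top)
  }
  report <- bind_rows(rows)

  popgen <- NULL
  if ("popgen" %in% stages) {
    popgen <- lapply(c(human = "human_panel", macaque = "macaque_panel"),
                     function(tag) {
      vcf <- file.path(bundle_dir, paste0(tag, ".vcf"))
      if (!file.exists(vcf)) return(NULL)
      analyze_panel(
        variants = read_variants(vcf),
        bed = read_bed(file.path(bundle_dir, paste0(tag, ".bed"))),
        cds_seq = read_fasta(file.path(bundle_dir, paste0(tag, "_cds.fasta")))[[1]],
        pseudo = tag == "macaque_panel",
        mc_replicates = cfg$mc_replicates,
        bootstrap_replicates = cfg$bootstrap_replicates,
        seed = seed)
    })
  }

  summary <- summarize_age_classes(report[report$classification == "de_novo", ])
  log_tbl <- if (length(logs)) bind_rows(logs) else
    tibble(gene_id = character(), stage = character(), rule = character(),
           value = character())

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(vapply(seq_len(nrow(log_tbl)), function(i)
      jsonlite::toJSON(as.list(log_tbl[i, ]), auto_unbox = TRUE),
      character(1)), file.path(out_dir, "log.jsonl"))
  }
  list(report = report, popgen = popgen, summary = summary, log = log_tbl)
}

#' Selection-stage statistics for one polymorphism panel
#'
#' Computes per-region diversity (normalized by intron), piN/piS from
#' classified sites, the Monte Carlo exonic-deficit test, derived-allele
#' spectra for (pseudo-)nonsynonymous vs (pseudo-)synonymous sites and the
#' rare-variant excess test.
#'
#' @param variants Variant tibble (as from [read_variants()] or
#'   [simulate_polymorphism()]).
#' @param bed Interval tibble whose `name` column holds the region class.
#' @param cds_seq Panel CDS sequence string.
#' @param pseudo Treat coding sites as pseudo-sites (non-coding ortholog).
#' @param mc_replicates,bootstrap_replicates Replicate counts.
#' @param seed Seed for the Monte Carlo test and bootstrap.
#' @return List with `diversity`, `pnps`, `mc`, `spectra`, `excess_rare`.
#' @export
analyze_panel <- function(variants, bed, cds_seq, pseudo = FALSE,
                          mc_replicates = 10000, bootstrap_replicates = 1000,
                          seed = 1) {
  region <- region_annotation("panel", tibble(
    contig = bed$contig, start = bed$start, end = bed$end,
    strand = bed$strand, class = bed$name))
  cds <- coding_sequence(cds_seq)
  variants <- classify_variants(variants, region, cds, pseudo = pseudo)
  div <- diversity_by_region(variants, region)
  div <- normalize_by_intron(div)
  pnps <- pn_ps_ratio(variants, cds)
  mc <- exon_intron_mc_test(variants, region, n_sims = mc_replicates,
                            seed = seed)
  ns_cls <- if (pseudo) "pseudo_nonsynonymous" else "nonsynonymous"
  s_cls <- if (pseudo) "pseudo_synonymous" else "synonymous"
  n_chrom <- max(variants$n)
  spec_n <- daf_spectrum(variants[variants$site_class == ns_cls, ],
                         n = n_chrom, B = bootstrap_replicates, seed = seed)
  spec_s <- daf_spectrum(variants[variants$site_class == s_cls, ],
                         n = n_chrom, B = bootstrap_replicates, seed = seed + 1)
  list(diversity = div, pnps = pnps, mc = mc,
       spectra = list(nonsynonymous = spec_n, synonymous = spec_s),
       excess_rare = excess_rare_test(spec_n, spec_s))
}

#' Count genes per age class
#'
#' Accepts either a pipeline report (column `age_label`) or a parsed gene
#' table (column `age_class`, e.g. the packaged 64-gene catalog).
#'
#' @param x Tibble.
#' @return List with `counts` (tibble label/n) and `total`.
#' @export
summarize_age_classes <- function(x) {
  col <- if ("age_class" %in% names(x)) "age_class" else
    if ("age_label" %in% names(x)) "age_label" else
      stop("no age_class/age_label column")
  counts <- count(x, label = .data[[col]])
  list(counts = counts, total = sum(counts$n))
}
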