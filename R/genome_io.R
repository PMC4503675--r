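# Readers/writers for the plain-text formats the pipeline touches, plus the
# shared coordinate model. All internal coordinates are 0-based half-open
# (BED convention); VCF positions (1-based) are converted at the boundary.

#' Construct a table of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based start
#' (inclusive), end exclusive. Strand must be `"+"` or `"-"`.
#'
#' @param contig Character vector of contig/chromosome identifiers.
#' @param start,end Non-negative integers, `end > start`.
#' @param strand `"+"` or `"-"` (recycled).
#' @param name Optional feature names.
#' @return A tibble with columns `contig`, `start`, `end`, `strand`, `name`.
#' @export
genomic_intervals <- function(contig, start, end, strand = "+", name = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0))
    stop("interval starts must be non-negative integers")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("interval %d is empty or inverted (start=%g, end=%g)",
                 bad[1], start[bad[1]], end[bad[1]]))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tibble(contig = as.character(contig), start = start, end = end,
         strand = strand, name = as.character(name))
}

#' Build a per-gene region annotation
#'
#' Groups intervals by region class (CDS, UTR, exon, intron, intergenic_flank)
#' for one gene, and records the position of the first CDS base (codon
#' position 1) so coding variants can be placed in frame.
#'
#' @param gene_id Gene identifier.
#' @param intervals A tibble of intervals with an extra `class` column; classes
#'   must be among `CDS`, `UTR`, `exon`, `intron`, `intergenic_flank`.
#' @param frame_anchor 0-based position of the first CDS base. Defaults to the
#'   smallest CDS start (plus strand) or largest CDS end - 1 (minus strand).
#' @param complete_orf If `TRUE` (default), require the summed CDS length to be
#'   divisible by 3.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(gene_id, intervals, frame_anchor = NULL,
                              complete_orf = TRUE) {
  stopifnot(is.data.frame(intervals), "class" %in% names(intervals))
  classes <- c("CDS", "UTR", "exon", "intron", "intergenic_flank")
  if (!all(intervals$class %in% classes))
    stop("unknown region class: ",
         paste(setdiff(unique(intervals$class), classes), collapse = ", "))
  cds <- intervals[intervals$class == "CDS", , drop = FALSE]
  if (complete_orf && nrow(cds) > 0 && sum(cds$end - cds$start) %% 3 != 0)
    stop("CDS intervals of a complete ORF must total a multiple of 3")
  # region classes must not overlap within the gene (exon is allowed to
  # contain CDS/UTR since it is their union)
  chk <- intervals[intervals$class != "exon", , drop = FALSE]
  if (nrow(chk) > 1) {
    o <- order(chk$contig, chk$start)
    s <- chk[o, ]
    same <- s$contig[-1] == s$contig[-nrow(s)]
    if (any(same & s$start[-1] < s$end[-nrow(s)]))
      stop("region classes overlap within gene ", gene_id)
  }
  if (is.null(frame_anchor) && nrow(cds) > 0) {
    frame_anchor <- if (cds$strand[1] == "+") min(cds$start) else max(cds$end) - 1
  }
  structure(list(gene_id = gene_id, intervals = as_tibble(intervals),
                 frame_anchor = frame_anchor),
            class = "region_annotation")
}

#' @exportS3Method base::print
print.region_annotation <- function(x, ...) {
  cat("<region_annotation>", x$gene_id, "\n")
  print(table(x$intervals$class))
  invisible(x)
}

#' Read a FASTA file
#'
#' A strict reader for the plain-text FASTA the pipeline consumes: sequences
#' are uppercased and restricted to the alphabet A, C, G, T, N. Malformed
#' headers or illegal characters raise an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA strings, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) < length(lines)]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA format error at line 1: expected '>' header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    ln <- which(hdr)[which(ids == "")[1]]
    stop("FASTA format error at line ", ln, ": empty header")
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  # records with no sequence lines at all
  if (length(seqs) < sum(hdr)) {
    missing <- setdiff(as.character(seq_len(sum(hdr))), names(seqs))
    seqs[missing] <- ""
    seqs <- seqs[as.character(seq_len(sum(hdr)))]
  }
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    # locate the offending line for the error message
    rec_lines <- which(!hdr & grp == i)
    off <- 0L
    for (ln in rec_lines) {
      w <- nchar(lines[ln])
      if (bad[i] <= off + w) break
      off <- off + w
    }
    stop("FASTA format error at line ", ln, ": illegal character '",
         substr(seqs[i], bad[i], bad[i]), "' in record ", ids[i])
  }
  setNames(as.character(seqs), ids)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' Coordinates are kept 0-based half-open exactly as in BED. Records with
#' `end <= start` raise an error with the record index.
#'
#' @param path Path to a tab-separated BED file.
#' @return Tibble with columns `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (missing optional columns filled with `NA`/`"+"`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character", quote = "")
  if (ncol(df) < 3) stop("BED format error: fewer than 3 columns")
  out <- tibble(
    contig = df[[1]],
    start  = as.numeric(df[[2]]),
    end    = as.numeric(df[[3]]),
    name   = if (ncol(df) >= 4) df[[4]] else NA_character_,
    score  = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_,
    strand = if (ncol(df) >= 6) df[[6]] else "+"
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$end <= out$start)
  if (length(bad))
    stop("BED format error in record ", bad[1], ": end <= start")
  if (!all(out$strand %in% c("+", "-")))
    stop("BED format error: strand must be '+' or '-'")
  out
}

#' Write intervals as BED
#' @param x Tibble as returned by [read_bed()] or [genomic_intervals()].
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$contig, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(x$name), ".", x$name),
                   if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0,
                   x$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a VCF-style polymorphism table
#'
#' Parses the VCF v4.x subset the pipeline uses (CHROM POS ID REF ALT QUAL
#' FILTER INFO\[AA=\] FORMAT GT). Positions are converted to the internal
#' 0-based model, multi-allelic records are decomposed into biallelic
#' records, and the ancestral-allele annotation (INFO field `AA=`) is used to
#' polarize each site. Sites whose ancestral allele matches neither observed
#' allele are flagged `"unpolarizable"` rather than dropped; sites lacking the
#' annotation are flagged `"missing"`. Genotypes must be diploid; missing
#' alleles reduce the chromosome count `n` for that site only.
#'
#' @param path Path to a plain-text or gzipped VCF.
#' @return Tibble with one row per biallelic record: `contig`, `pos` (0-based),
#'   `pos1` (original 1-based), `ref`, `alt`, `aa` (ancestral allele),
#'   `aa_status` (`"polarized"`, `"unpolarizable"` or `"missing"`), `n`
#'   (chromosomes genotyped), `ac` (alt allele count), `derived_count`
#'   (`NA` unless polarized), and `gt` (list column of per-sample genotype
#'   strings).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  aa_all <- sub("^.*(?:^|;)AA=([^;]+).*$", "\\1", info)
  aa_all[!grepl("(^|;)AA=", info)] <- NA_character_
  gt_mat <- if (ncol(v@gt) > 1) v@gt[, -1, drop = FALSE] else
    matrix(character(0), nrow = nrow(fix), ncol = 0)
  if (is.null(dim(gt_mat))) gt_mat <- matrix(gt_mat, nrow = nrow(fix))
  # strip FORMAT subfields beyond GT
  gt_mat[] <- sub(":.*$", "", gt_mat)

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt_mat[r, ]
    gts[is.na(gts)] <- "./." # fully missing genotypes
    parts <- strsplit(gts, "[/|]")
    pl <- lengths(parts)
    if (length(pl) && any(pl != 2))
      stop("VCF format error at ", fix[r, "CHROM"], ":", fix[r, "POS"],
           ": genotype ploidy != 2")
    alleles <- unlist(parts, use.names = FALSE)
    sub_rows <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      # decompose: allele == k -> derived(1); 0 -> ref; other alts & '.' -> missing
      a1 <- ifelse(alleles == "0", 0L, ifelse(alleles == as.character(k), 1L, NA_integer_))
      nn <- sum(!is.na(a1))
      ac <- sum(a1, na.rm = TRUE)
      aa <- toupper(aa_all[r])
      status <- if (is.na(aa) || aa %in% c(".", "N", "-")) "missing"
      else if (aa %in% c(fix[r, "REF"], alts[k])) "polarized"
      else "unpolarizable"
      dc <- if (status == "polarized") {
        if (aa == fix[r, "REF"]) ac else nn - ac
      } else NA_integer_
      sub_rows[[k]] <- tibble(
        contig = fix[r, "CHROM"],
        pos = as.numeric(fix[r, "POS"]) - 1,
        pos1 = as.numeric(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[k],
        aa = if (is.na(aa)) NA_character_ else aa,
        aa_status = status, n = nn, ac = ac, derived_count = dc,
        gt = list(gts))
    }
    rows[[r]] <- bind_rows(sub_rows)
  }
  bind_rows(rows)
}

#' Write a variant table as VCF
#'
#' Inverse of [read_variants()] for biallelic records: positions are converted
#' back to 1-based, the ancestral allele is emitted as `AA=` in INFO, and the
#' stored genotype strings are written per sample.
#'
#' @param variants Tibble as returned by [read_variants()].
#' @param path Output path.
#' @param sample_names Optional sample names (defaults to `S1..Sk`).
#' @export
write_variants <- function(variants, path, sample_names = NULL) {
  k <- if (nrow(variants)) length(variants$gt[[1]]) else 0
  if (is.null(sample_names)) sample_names <- if (k) paste0("S", seq_len(k)) else character(0)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (k) hdr <- c(hdr, "FORMAT", sample_names)
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(variants)) {
    info <- ifelse(is.na(variants$aa), ".", paste0("AA=", variants$aa))
    body <- paste(variants$contig,
                  format(variants$pos + 1, scientific = FALSE, trim = TRUE),
                  ".", variants$ref, variants$alt, ".", "PASS", info,
                  sep = "\t")
    if (k) {
      gts <- vapply(variants$gt, paste, "", collapse = "\t")
      body <- paste(body, "GT", gts, sep = "\t")
    }
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a gene table (Table-1-style TSV)
#'
#' Parses a tab-separated gene catalog with columns `gene_id`, `age_class`,
#' `orf_length_codons` (terminal stop excluded), `top_tissue`,
#' `tissue_breadth`, `peptide_count`. Age classes must match the grammar
#' `H(-[CGO])*` (H = human, C = chimpanzee, G = gorilla, O = orangutan).
#'
#' @param path Path to the TSV (header required).
#' @return Tibble of validated records.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("gene_id", "age_class", "orf_length_codons", "top_tissue",
            "tissue_breadth", "peptide_count")
  if (!all(need %in% names(df)))
    stop("gene table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- !grepl("^H(-[CGO])*$", df$age_class)
  if (any(bad))
    stop("gene table format error: invalid age class '",
         df$age_class[which(bad)[1]], "' for gene ", df$gene_id[which(bad)[1]])
  if (any(df$orf_length_codons <= 0))
    stop("gene table format error: non-positive ORF length for gene ",
         df$gene_id[which(df$orf_length_codons <= 0)[1]])
  as_tibble(df[, need])
}

#' Path to the packaged 64-gene hominoid catalog
#'
#' Returns the installed location of the transcription of the published
#' catalog of 64 hominoid-specific de novo genes (gene id, age class, ORF
#' length in codons, top tissue, tissue breadth, peptide count).
#' @return File path.
#' @export
denovo_gene_table_path <- function() {
  system.file("extdata", "denovo_genes_hominoid.tsv", package = "lncorf",
              mustWork = TRUE)
}

# --- coordinate converters ---------------------------------------------------

#' Convert between VCF (1-based) and internal/BED (0-based) positions
#' @param pos1 1-based positions.
#' @return 0-based positions.
#' @export
vcf_to_bed_pos <- function(pos1) pos1 - 1

#' @rdname vcf_to_bed_pos
#' @param pos0 0-based positions.
#' @export
bed_to_vcf_pos <- function(pos0) pos0 + 1
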