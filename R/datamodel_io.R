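# Data model and I/O: study loading, variant tables, haplotypes, exports.
#
# Conventions
#  - Alignments are character matrices (samples x aligned columns) over
#    {A,C,G,T,-,N}; IUPAC ambiguity codes are treated as missing (N).
#  - Coordinates are 0-based half-open internally and 1-based in every
#    report and in VCF output.
#  - A maximal run of gap columns with an identical presence/absence pattern
#    across samples is one indel polymorphism; indels are excluded from
#    per-site statistics but included in haplotype definitions.

#' Construct a locus alignment
#'
#' @param locus_id character scalar identifying the locus.
#' @param seqs character matrix, samples x aligned columns, rownames are
#'   sample ids; entries in \{A,C,G,T,-,N\} (lowercase and IUPAC ambiguity
#'   codes are normalized, ambiguity to N).
#' @param outgroup optional character vector of the same length as the
#'   alignment columns: an aligned outgroup sequence.
#' @return object of class \code{locus_alignment} with elements
#'   \code{locus_id}, \code{seqs}, \code{outgroup}, \code{length}.
#' @export
locus_alignment <- function(locus_id, seqs, outgroup = NULL) {
  stopifnot(is.matrix(seqs), nrow(seqs) >= 2, ncol(seqs) > 0)
  if (is.null(rownames(seqs))) stop("alignment rows must be named by sample id")
  seqs[] <- normalize_base(seqs)
  if (!is.null(outgroup)) {
    outgroup <- normalize_base(as.character(outgroup))
    if (length(outgroup) != ncol(seqs))
      stop("outgroup row not aligned to the same columns as locus ", locus_id)
  }
  structure(list(locus_id = locus_id, seqs = seqs, outgroup = outgroup,
                 length = ncol(seqs)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment>", x$locus_id, ":", nrow(x$seqs), "samples x",
      x$length, "bp", if (!is.null(x$outgroup)) "(+outgroup)", "\n")
  invisible(x)
}

#' Load a study from a JSON configuration
#'
#' The configuration (version 1) is a JSON object with fields:
#' \describe{
#'   \item{config_version}{integer, currently 1.}
#'   \item{samples}{path to a TSV with columns sample_id, taxon, population,
#'     region (region may be empty).}
#'   \item{loci}{array of objects \code{\{locus_id, fasta, outgroup_name\}};
#'     \code{outgroup_name} (optional, default "OUTGROUP") names the FASTA
#'     record holding the aligned outgroup sequence.}
#'   \item{annotation}{optional path to a TSV with columns locus_id, start,
#'     end, frame — 1-based inclusive coding intervals, frame in \{0,1,2\}.}
#'   \item{mtdna_loci}{optional array of locus_ids to treat as the
#'     non-recombining mitochondrial block.}
#' }
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config_path path to the JSON configuration.
#' @return object of class \code{study_data}: list with \code{alignments}
#'   (named list of \code{locus_alignment}), \code{samples} (data.frame),
#'   \code{annotation} (named list of interval data.frames), \code{mtdna_loci},
#'   \code{coverage} (per-locus sample coverage report, loci missing more than
#'   half the samples flagged).
#' @export
load_study <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = FALSE)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)

  if (is.null(cfg$loci) || length(cfg$loci) == 0) stop("config lists no loci")
  spath <- resolve(cfg$samples)
  if (!file.exists(spath)) stop("samples table not found: ", spath)
  samples <- utils::read.delim(spath, stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("sample_id", "taxon", "population")
  if (!all(need %in% names(samples)))
    stop("samples table must have columns sample_id, taxon, population")
  if (is.null(samples$region)) samples$region <- ""
  samples$region[is.na(samples$region)] <- ""
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata: ",
         samples$sample_id[duplicated(samples$sample_id)][1])

  alignments <- list()
  for (lc in cfg$loci) {
    lid <- lc$locus_id
    if (lid %in% names(alignments)) stop("duplicate locus_id: ", lid)
    fp <- resolve(lc$fasta)
    if (!file.exists(fp)) stop("FASTA not found for locus ", lid, ": ", fp)
    m <- read_alignment_fasta(fp)
    og_name <- lc$outgroup_name %||% "OUTGROUP"
    outgroup <- NULL
    if (og_name %in% rownames(m)) {
      outgroup <- m[og_name, ]
      m <- m[setdiff(rownames(m), og_name), , drop = FALSE]
    }
    missing_meta <- setdiff(rownames(m), samples$sample_id)
    if (length(missing_meta) > 0)
      stop("sample(s) in FASTA for locus ", lid,
           " absent from metadata: ", paste(missing_meta, collapse = ", "))
    alignments[[lid]] <- locus_alignment(lid, m, outgroup)
  }

  annotation <- list()
  if (!is.null(cfg$annotation)) {
    ap <- resolve(cfg$annotation)
    if (!file.exists(ap)) stop("annotation table not found: ", ap)
    ann <- utils::read.delim(ap, stringsAsFactors = FALSE)
    for (lid in unique(ann$locus_id)) {
      a <- ann[ann$locus_id == lid, , drop = FALSE]
      # 1-based inclusive on disk -> 0-based half-open internally
      annotation[[lid]] <- data.frame(start = a$start - 1L, end = a$end,
                                      frame = a$frame)
    }
  }

  n_samp <- nrow(samples)
  coverage <- data.frame(
    locus_id = names(alignments),
    n_samples = vapply(alignments, function(a) nrow(a$seqs), integer(1)),
    row.names = NULL)
  coverage$fraction <- coverage$n_samples / n_samp
  coverage$flagged <- coverage$fraction < 0.5

  structure(list(alignments = alignments, samples = samples,
                 annotation = annotation,
                 mtdna_loci = as.character(unlist(cfg$mtdna_loci)),
                 coverage = coverage, config_path = config_path),
            class = "study_data")
}

# Read an aligned FASTA into an upper-case character matrix.
read_alignment_fasta <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  m <- toupper(unclass(d))
  m[] <- normalize_base(m)
  m
}

#' Write a study back to disk (FASTA per locus + samples TSV + config JSON)
#'
#' Inverse of \code{\link{load_study}}: \code{load_study(write_study(x, dir))}
#' reproduces the alignments and metadata exactly.
#'
#' @param study a \code{study_data} object.
#' @param dir output directory (created if needed).
#' @return path of the written config JSON, invisibly usable with
#'   \code{load_study}.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- list()
  for (aln in study$alignments) {
    fn <- paste0(aln$locus_id, ".fasta")
    m <- aln$seqs
    if (!is.null(aln$outgroup)) {
      m <- rbind(m, OUTGROUP = aln$outgroup)
    }
    write_fasta(m, file.path(dir, fn))
    loci[[length(loci) + 1]] <- list(locus_id = aln$locus_id, fasta = fn)
  }
  utils::write.table(study$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(config_version = 1L, samples = "samples.tsv", loci = loci)
  if (length(study$mtdna_loci) > 0) cfg$mtdna_loci <- as.list(study$mtdna_loci)
  if (length(study$annotation) > 0) {
    ann <- do.call(rbind, lapply(names(study$annotation), function(lid) {
      a <- study$annotation[[lid]]
      data.frame(locus_id = lid, start = a$start + 1L, end = a$end,
                 frame = a$frame)
    }))
    utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg$annotation <- "annotation.tsv"
  }
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path)
}

write_fasta <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
}

#' Build a variant table for a sample subset
#'
#' Calls SNPs on nucleotide states (gaps and N are missing for SNP calling)
#' and collapses maximal gap runs with identical presence/absence patterns
#' into single indel events.
#'
#' @param aln a \code{locus_alignment}.
#' @param subset character vector of sample ids (default: all samples).
#' @return object of class \code{variant_table}: list with \code{sites}
#'   (data.frame: position 0-based, type, alleles, counts, n_called,
#'   minor_count, maf, is_singleton, is_informative, ancestral,
#'   derived_count), \code{geno} (samples x SNP-columns character matrix),
#'   \code{n} (subset size), \code{locus_id}, \code{n_snps}, \code{n_indels}.
#' @export
build_variant_table <- function(aln, subset = NULL) {
  m <- aln$seqs
  if (!is.null(subset)) {
    missing <- setdiff(subset, rownames(m))
    if (length(missing) > 0) stop("subset samples not in alignment: ",
                                  paste(missing, collapse = ", "))
    m <- m[subset, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("variant calling needs at least 2 samples")

  n <- nrow(m)
  # vectorized column classification: per-base counts across all columns
  base_counts <- vapply(.BASES, function(b) colSums(m == b),
                        numeric(ncol(m)))
  if (ncol(m) == 1)
    base_counts <- matrix(base_counts, nrow = 1,
                          dimnames = list(NULL, .BASES))
  n_alleles <- rowSums(base_counts > 0)
  snp_cols <- which(n_alleles >= 2)
  sites <- NULL
  if (length(snp_cols) > 0) {
    info <- vapply(snp_cols, function(j) {
      cnt_all <- base_counts[j, ]
      ord <- order(-cnt_all, names(cnt_all))
      keep <- cnt_all[ord] > 0
      cnt <- cnt_all[ord][keep]
      c(n_called = sum(cnt), minor = unname(cnt[2]), min = min(cnt),
        informative = sum(cnt >= 2) >= 2)
    }, c(n_called = 0, minor = 0, min = 0, informative = 0))
    strs <- vapply(snp_cols, function(j) {
      cnt_all <- base_counts[j, ]
      ord <- order(-cnt_all, names(cnt_all))
      keep <- cnt_all[ord] > 0
      c(paste(names(cnt_all)[ord][keep], collapse = ","),
        paste(as.integer(cnt_all[ord][keep]), collapse = ","))
    }, character(2))
    sites <- data.frame(
      position = snp_cols - 1L, type = "SNP",
      alleles = strs[1, ], counts = strs[2, ],
      n_called = as.integer(info["n_called", ]),
      minor_count = as.integer(info["minor", ]),
      maf = info["minor", ] / info["n_called", ],
      is_singleton = info["min", ] == 1,
      is_informative = info["informative", ] == 1,
      ancestral = NA_character_, derived_count = NA_integer_,
      stringsAsFactors = FALSE)
  }

  # indel events: maximal gap-column runs with identical gap pattern
  gap <- m == "-"
  poly_gap_col <- which(apply(gap, 2, function(g) any(g) && !all(g)))
  indels <- list()
  if (length(poly_gap_col) > 0) {
    runs <- split(poly_gap_col,
                  cumsum(c(1, diff(poly_gap_col) != 1)))
    for (r in runs) {
      # split a contiguous run further wherever the gap pattern changes
      pat <- apply(gap[, r, drop = FALSE], 2, paste, collapse = "")
      sub <- split(r, cumsum(c(1, pat[-1] != pat[-length(pat)])))
      for (s in sub) {
        carriers <- sum(gap[, s[1]])
        cnt <- sort(c(carriers, n - carriers), decreasing = TRUE)
        indels[[length(indels) + 1]] <- data.frame(
          position = s[1] - 1L, type = "indel",
          alleles = paste0("-x", length(s), ",base"),
          counts = paste(cnt, collapse = ","),
          n_called = n, minor_count = cnt[2],
          maf = cnt[2] / n,
          is_singleton = cnt[2] == 1L,
          is_informative = cnt[2] >= 2,
          ancestral = NA_character_, derived_count = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }

  blocks <- c(if (!is.null(sites)) list(sites), indels)
  sites_df <- if (length(blocks)) {
    df <- do.call(rbind, blocks)
    df[order(df$position, df$type), , drop = FALSE]
  } else {
    data.frame(position = integer(0), type = character(0),
               alleles = character(0), counts = character(0),
               n_called = integer(0), minor_count = integer(0),
               maf = numeric(0), is_singleton = logical(0),
               is_informative = logical(0), ancestral = character(0),
               derived_count = integer(0))
  }
  rownames(sites_df) <- NULL
  geno <- m[, snp_cols, drop = FALSE]
  colnames(geno) <- as.character(snp_cols - 1L)
  structure(list(sites = sites_df, geno = geno, n = n,
                 locus_id = aln$locus_id,
                 n_snps = length(snp_cols),
                 n_indels = length(indels)),
            class = "variant_table")
}

#' Number of segregating sites in a variant table
#'
#' @param vt a \code{variant_table}.
#' @param indels one of \code{"count"} (indel events count toward the
#'   polymorphic-site total, the default dialect) or \code{"ignore"}.
#' @return integer count.
#' @export
segregating_sites <- function(vt, indels = c("count", "ignore")) {
  indels <- match.arg(indels)
  if (indels == "count") vt$n_snps + vt$n_indels else vt$n_snps
}

#' Polarize variants against an aligned outgroup
#'
#' The ancestral allele is the outgroup base where the outgroup carries one
#' of the segregating alleles; otherwise it is unknown (third-allele cases
#' are flagged). Derived counts are filled in where the ancestral state is
#' known.
#'
#' @param vt a \code{variant_table}.
#' @param outgroup aligned character vector covering the same columns.
#' @return the variant table with \code{ancestral}, \code{derived_count} and
#'   attribute \code{fraction_polarized} filled; third-allele sites carry
#'   \code{ancestral_flag == "third_allele"}.
#' @export
polarize_variants <- function(vt, outgroup) {
  outgroup <- normalize_base(as.character(outgroup))
  s <- vt$sites
  s$ancestral_flag <- NA_character_
  snp <- which(s$type == "SNP")
  for (i in snp) {
    pos <- s$position[i] + 1L
    if (pos > length(outgroup)) stop("outgroup shorter than alignment")
    og <- outgroup[pos]
    alleles <- strsplit(s$alleles[i], ",")[[1]]
    counts <- as.integer(strsplit(s$counts[i], ",")[[1]])
    if (og %in% alleles) {
      s$ancestral[i] <- og
      s$derived_count[i] <- sum(counts[alleles != og])
    } else if (og %in% .BASES) {
      s$ancestral_flag[i] <- "third_allele"
    }
  }
  vt$sites <- s
  attr(vt, "fraction_polarized") <-
    if (length(snp)) mean(!is.na(s$ancestral[snp])) else NA_real_
  vt
}

#' Extract haplotypes over the full locus
#'
#' Haplotypes are keyed on the complete aligned sequence including gaps, so
#' indel variation distinguishes haplotypes. Samples with more than
#' \code{max_missing} missing data at the locus are excluded.
#'
#' @param aln a \code{locus_alignment}.
#' @param subset sample ids (default all).
#' @param max_missing maximum tolerated fraction of N per sample (default 0.2).
#' @return object of class \code{haplotype_set}: list with \code{locus_id},
#'   \code{haplotypes} (distinct strings), \code{counts}, \code{freq},
#'   \code{n}, \code{n_haplotypes}, \code{F} (homozygosity sum p_i^2),
#'   \code{assignment} (sample -> haplotype index), \code{excluded}.
#' @export
extract_haplotypes <- function(aln, subset = NULL, max_missing = 0.2) {
  m <- aln$seqs
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  miss_frac <- rowMeans(m == "N")
  excluded <- rownames(m)[miss_frac > max_missing]
  m <- m[miss_frac <= max_missing, , drop = FALSE]
  if (nrow(m) < 1) stop("no samples left after missing-data filter")
  hap_str <- apply(m, 1, paste, collapse = "")
  tab <- table(hap_str)
  # deterministic order: by decreasing count then lexicographic
  tab <- tab[order(-as.integer(tab), names(tab))]
  freq <- as.numeric(tab) / sum(tab)
  structure(list(locus_id = aln$locus_id,
                 haplotypes = names(tab),
                 counts = as.integer(tab),
                 freq = freq,
                 n = nrow(m),
                 n_haplotypes = length(tab),
                 F = sum(freq^2),
                 assignment = match(hap_str, names(tab)),
                 excluded = excluded),
            class = "haplotype_set")
}

#' Export result tables, a run summary, and optional VCF output
#'
#' Writes each data.frame in \code{tables} as a TSV with deterministic column
#' order and fixed float precision, plus a \code{summary.json} recording
#' seeds and package version. Repeated calls with identical inputs produce
#' byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @param summary named list merged into the JSON summary (seeds, settings).
#' @param digits significant digits for numeric columns (default 6).
#' @return invisible character vector of files written.
#' @export
export_results <- function(tables, out_dir, summary = list(), digits = 6) {
  if (length(tables) == 0) stop("no result tables to export")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                   format = "g"))
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  info <- c(list(package = "pinepop",
                 version = as.character(utils::packageVersion("pinepop")),
                 tables = names(tables)),
            summary)
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(info, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(written, f))
}

#' Write SNPs of a variant table as a haploid VCF
#'
#' One record per SNP; sample genotypes are haploid allele indices; missing
#' data is ".". Positions are 1-based per VCF.
#'
#' @param vt a \code{variant_table}.
#' @param path output file.
#' @param chrom CHROM field value (default the locus id).
#' @return invisible path.
#' @export
write_variant_vcf <- function(vt, path, chrom = vt$locus_id) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- rownames(vt$geno)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pinepop",
               paste0("##contig=<ID=", chrom, ">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  snp <- vt$sites[vt$sites$type == "SNP", , drop = FALSE]
  for (i in seq_len(nrow(snp))) {
    pos0 <- snp$position[i]
    alleles <- strsplit(snp$alleles[i], ",")[[1]]
    col <- vt$geno[, as.character(pos0)]
    gt <- match(col, alleles) - 1L
    gt_chr <- ifelse(is.na(gt), ".", as.character(gt))
    writeLines(paste(c(chrom, pos0 + 1L, ".", alleles[1],
                       paste(alleles[-1], collapse = ","), ".", "PASS", ".",
                       "GT", gt_chr), collapse = "\t"), con)
  }
  invisible(path)
}
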