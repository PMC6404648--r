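# Between-group divergence: d_xy, Nei's net divergence, polymorphism and
# haplotype sharing, and Jukes-Cantor net distances between populations.

#' d_xy and Nei's net divergence between two groups
#'
#' d_xy is the mean between-group pairwise difference per site (pairwise
#' deletion over SNP columns); d_a = d_xy - (pi_1 + pi_2)/2.
#'
#' @param aln a \code{locus_alignment}.
#' @param group1,group2 sample id vectors (>= 2 each; a single-sequence
#'   group2 — e.g. an outgroup — is allowed with
#'   \code{allow_single = TRUE}, in which case pi_2 = 0 with a warning).
#' @param L effective length (default the alignment length).
#' @param allow_single permit |group2| = 1 (outgroup comparisons).
#' @return list with \code{d_xy}, \code{d_a}, \code{pi1}, \code{pi2}.
#' @export
net_divergence <- function(aln, group1, group2, L = aln$length,
                           allow_single = FALSE) {
  m <- aln$seqs
  if (length(group1) < 2) stop("group1 needs >= 2 samples")
  if (length(group2) < 2 && !allow_single)
    stop("group2 needs >= 2 samples (net divergence requires within-group pi)")
  vt_all <- build_variant_table(aln, c(group1, group2))
  geno <- vt_all$geno
  dmat <- pairwise_diff_matrix(geno)
  d_xy <- mean(dmat[group1, group2, drop = FALSE]) / L
  pi1 <- mean_pairwise_differences(geno[group1, , drop = FALSE]) / L
  pi2 <- if (length(group2) >= 2) {
    mean_pairwise_differences(geno[group2, , drop = FALSE]) / L
  } else {
    warning("single-sequence group2: using pi_2 = 0 for net divergence")
    0
  }
  list(d_xy = d_xy, d_a = d_xy - (pi1 + pi2) / 2, pi1 = pi1, pi2 = pi2)
}

#' Shared, exclusive and fixed polymorphic sites between two groups
#'
#' Shared sites are polymorphic in both groups, exclusive in exactly one;
#' fixed differences require both groups monomorphic for different alleles.
#'
#' @param vt1,vt2 \code{variant_table}s built on the same alignment for the
#'   two groups.
#' @param aln the common \code{locus_alignment} (needed to detect fixed
#'   differences at sites monomorphic within both groups).
#' @return list with counts \code{shared}, \code{exclusive_1},
#'   \code{exclusive_2}, \code{fixed} and the corresponding position vectors.
#' @export
polymorphism_sharing <- function(vt1, vt2, aln) {
  if (vt1$locus_id != vt2$locus_id)
    stop("variant tables come from different loci")
  p1 <- vt1$sites$position[vt1$sites$type == "SNP"]
  p2 <- vt2$sites$position[vt2$sites$type == "SNP"]
  shared <- intersect(p1, p2)
  ex1 <- setdiff(p1, p2)
  ex2 <- setdiff(p2, p1)
  g1 <- rownames(vt1$geno); g2 <- rownames(vt2$geno)
  m <- aln$seqs
  fixed <- integer(0)
  mono_cols <- setdiff(seq_len(ncol(m)) - 1L, union(p1, p2))
  for (pos in mono_cols) {
    a <- m[g1, pos + 1L]; b <- m[g2, pos + 1L]
    a <- unique(a[a %in% .BASES]); b <- unique(b[b %in% .BASES])
    if (length(a) == 1 && length(b) == 1 && a != b)
      fixed <- c(fixed, pos)
  }
  list(shared = length(shared), exclusive_1 = length(ex1),
       exclusive_2 = length(ex2), fixed = length(fixed),
       shared_pos = shared, exclusive_1_pos = ex1, exclusive_2_pos = ex2,
       fixed_pos = fixed)
}

#' Unique and shared haplotypes between two groups
#'
#' @param hs1,hs2 \code{haplotype_set}s for the same locus.
#' @return list with \code{shared}, \code{unique_1}, \code{unique_2} counts,
#'   the percentage of each group's haplotype pool that is unique, and the
#'   pooled frequencies of shared haplotypes.
#' @export
haplotype_sharing <- function(hs1, hs2) {
  shared <- intersect(hs1$haplotypes, hs2$haplotypes)
  u1 <- setdiff(hs1$haplotypes, hs2$haplotypes)
  u2 <- setdiff(hs2$haplotypes, hs1$haplotypes)
  list(shared = length(shared),
       unique_1 = length(u1), unique_2 = length(u2),
       pct_unique_1 = 100 * length(u1) / hs1$n_haplotypes,
       pct_unique_2 = 100 * length(u2) / hs2$n_haplotypes,
       shared_freq_1 = sum(hs1$freq[hs1$haplotypes %in% shared]),
       shared_freq_2 = sum(hs2$freq[hs2$haplotypes %in% shared]))
}

#' Jukes-Cantor distance from a raw proportion of differences
#' @param p proportion of differing sites (p < 0.75).
#' @return corrected distance d = -(3/4) log(1 - 4p/3).
#' @export
jc_distance <- function(p) {
  if (any(p >= 0.75)) stop("JC distance undefined at p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Net Jukes-Cantor distance matrix between populations
#'
#' SNP columns are concatenated across loci per sample (missing loci
#' contribute missing data); per sample pair, the raw mismatch proportion
#' under pairwise deletion is JC-corrected; the net distance between two
#' populations is the mean between-population distance minus the average of
#' the two within-population means.
#'
#' @param alignments named list of \code{locus_alignment}.
#' @param samples data.frame with sample_id and a grouping column.
#' @param group_col grouping column name (default "population").
#' @return list with \code{net} (symmetric net-distance matrix, zero
#'   diagonal), \code{between} (raw mean between/within matrix),
#'   \code{within} (named vector of within-group means).
#' @export
jc_population_distance <- function(alignments, samples,
                                   group_col = "population") {
  ids <- samples$sample_id
  groups <- stats::setNames(samples[[group_col]], ids)
  if (length(unique(groups)) < 2) stop("need at least 2 populations")
  # concatenate SNP columns across loci
  blocks <- lapply(alignments, function(aln) {
    vt <- build_variant_table(aln)
    g <- matrix("N", nrow = length(ids), ncol = ncol(vt$geno),
                dimnames = list(ids, NULL))
    common <- intersect(ids, rownames(vt$geno))
    g[common, ] <- vt$geno[common, , drop = FALSE]
    g
  })
  cat_geno <- do.call(cbind, blocks)
  n <- length(ids)
  diffs <- pairwise_diff_matrix(cat_geno)
  called <- matrix(cat_geno %in% .BASES, nrow = n) * 1
  both <- tcrossprod(called)
  p <- ifelse(both > 0, diffs / both, 0)
  if (any(p[upper.tri(p)] >= 0.75)) {
    bad <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)[1, ]
    stop("JC distance undefined (p >= 0.75) for pair ", ids[bad[1]], " - ",
         ids[bad[2]])
  }
  d <- jc_distance(p)
  dimnames(d) <- list(ids, ids)
  pops <- sort(unique(groups))
  within <- vapply(pops, function(p) {
    mem <- ids[groups == p]
    if (length(mem) < 2) return(0)
    sub <- d[mem, mem]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  between <- matrix(0, length(pops), length(pops),
                    dimnames = list(pops, pops))
  net <- between
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i == j) next
    mi <- ids[groups == pops[i]]; mj <- ids[groups == pops[j]]
    between[i, j] <- mean(d[mi, mj])
    net[i, j] <- between[i, j] - (within[i] + within[j]) / 2
  }
  list(net = net, between = between, within = within)
}
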