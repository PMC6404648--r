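# Evidence-matrix synthesis: combine all test outputs into a per-gene x
# taxon flag table and apply the candidate-gene rule.
#
# Flags: 1 interspecies F_ST significant; 2 among-population F_ST within
# taxon significant; 3 S_nn significant; 4 highly diverged SNPs at
# interspecific level (99% envelope); 5 outlier SNPs within taxon;
# 6 HEW and/or DHEW significant.

#' Build the evidence matrix
#'
#' Each input is optional (missing result types simply contribute no flags):
#' \describe{
#'   \item{interspecies_fst}{data.frame gene, taxon, other, p — per-gene
#'     F_ST p-value of taxon vs other.}
#'   \item{within_fst}{data.frame gene, taxon, p — among-population F_ST
#'     within the taxon.}
#'   \item{snn}{data.frame gene, taxon, group, p — S_nn per grouping.}
#'   \item{diverged_snps}{data.frame gene, taxon, other — SNPs beyond the
#'     99\% interspecific envelope (one row per flagged SNP).}
#'   \item{outlier_snps}{data.frame gene, taxon — within-taxon outlier SNPs.}
#'   \item{compound}{data.frame gene, taxon, hew, dhew (logical verdicts).}
#' }
#'
#' @param results named list with any of the elements above.
#' @param alpha_fst significance level for F_ST and S_nn flags (default
#'   0.01).
#' @param alpha_compound level already applied to the compound verdicts
#'   (recorded; default 0.05).
#' @return data.frame, one row per gene x taxon, logical columns
#'   \code{flag1}..\code{flag6}, annotation columns \code{ann1} (taxa),
#'   \code{ann3} (groups), \code{ann4} (taxa), \code{ann6} (tests), a
#'   compact \code{flags} string, and \code{n_flags}.
#' @export
build_evidence_matrix <- function(results, alpha_fst = 0.01,
                                  alpha_compound = 0.05) {
  keys <- list()
  add_key <- function(df) {
    if (!is.null(df) && nrow(df) > 0)
      keys[[length(keys) + 1]] <<- df[, c("gene", "taxon")]
  }
  for (nm in c("interspecies_fst", "within_fst", "snn", "diverged_snps",
               "outlier_snps", "compound")) add_key(results[[nm]])
  if (length(keys) == 0) {
    return(data.frame(gene = character(0), taxon = character(0)))
  }
  base <- unique(do.call(rbind, keys))
  base <- base[order(base$gene, base$taxon), , drop = FALSE]
  rownames(base) <- NULL
  m <- base
  m$flag1 <- m$flag2 <- m$flag3 <- m$flag4 <- m$flag5 <- m$flag6 <- FALSE
  m$ann1 <- m$ann3 <- m$ann4 <- m$ann6 <- ""

  key <- paste(m$gene, m$taxon, sep = "\r")
  idx_of <- function(df) match(paste(df$gene, df$taxon, sep = "\r"), key)

  r <- results$interspecies_fst
  if (!is.null(r) && nrow(r) > 0) {
    sig <- r[r$p < alpha_fst, , drop = FALSE]
    for (i in idx_unique <- unique(idx_of(sig))) {
      rows <- sig[idx_of(sig) == i, , drop = FALSE]
      m$flag1[i] <- TRUE
      m$ann1[i] <- paste(sort(unique(rows$other)), collapse = ",")
    }
  }
  r <- results$within_fst
  if (!is.null(r) && nrow(r) > 0) {
    sig <- r[r$p < alpha_fst, , drop = FALSE]
    m$flag2[idx_of(sig)] <- TRUE
  }
  r <- results$snn
  if (!is.null(r) && nrow(r) > 0) {
    sig <- r[r$p < alpha_fst, , drop = FALSE]
    for (i in unique(idx_of(sig))) {
      rows <- sig[idx_of(sig) == i, , drop = FALSE]
      m$flag3[i] <- TRUE
      m$ann3[i] <- paste(sort(unique(rows$group)), collapse = ",")
    }
  }
  r <- results$diverged_snps
  if (!is.null(r) && nrow(r) > 0) {
    for (i in unique(idx_of(r))) {
      rows <- r[idx_of(r) == i, , drop = FALSE]
      m$flag4[i] <- TRUE
      m$ann4[i] <- paste(sort(unique(rows$other)), collapse = ",")
    }
  }
  r <- results$outlier_snps
  if (!is.null(r) && nrow(r) > 0) m$flag5[unique(idx_of(r))] <- TRUE
  r <- results$compound
  if (!is.null(r) && nrow(r) > 0) {
    sig <- r[r$hew | r$dhew, , drop = FALSE]
    for (i in idx_of(sig)) {
      row <- sig[idx_of(sig) == i, , drop = FALSE][1, ]
      m$flag6[i] <- TRUE
      m$ann6[i] <- paste(c("HEW", "DHEW")[c(row$hew, row$dhew)],
                         collapse = ",")
    }
  }
  flag_cols <- paste0("flag", 1:6)
  m$n_flags <- rowSums(m[flag_cols])
  m$flags <- apply(m[flag_cols], 1, function(f)
    paste(which(f), collapse = ","))
  m <- m[m$n_flags > 0, , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "alpha_fst") <- alpha_fst
  attr(m, "alpha_compound") <- alpha_compound
  m
}

#' Candidate genes from the evidence matrix
#'
#' A candidate shows, within the same taxon, a compound neutrality signal
#' (flag 6) AND interspecific divergence (flag 1 or 4) AND a within-taxon
#' differentiation signal (flag 2, 3 or 5). A secondary table lists genes
#' with any within-taxon selection signal (flags 2, 3, 5 or 6) in more than
#' one taxon.
#'
#' @param matrix evidence matrix from \code{\link{build_evidence_matrix}}.
#' @return list with \code{candidates} (data.frame ordered by flag count
#'   descending then gene id) and \code{cross_taxon} (genes sharing a
#'   selection signal across taxa).
#' @export
candidate_genes <- function(matrix) {
  if (nrow(matrix) == 0) {
    return(list(candidates = matrix, cross_taxon = character(0)))
  }
  is_cand <- matrix$flag6 & (matrix$flag1 | matrix$flag4) &
    (matrix$flag2 | matrix$flag3 | matrix$flag5)
  cand <- matrix[is_cand, , drop = FALSE]
  cand <- cand[order(-cand$n_flags, cand$gene, cand$taxon), , drop = FALSE]
  rownames(cand) <- NULL
  sel <- matrix$flag2 | matrix$flag3 | matrix$flag5 | matrix$flag6
  per_gene <- tapply(matrix$taxon[sel], matrix$gene[sel],
                     function(x) length(unique(x)))
  cross <- sort(names(per_gene)[per_gene > 1])
  list(candidates = cand, cross_taxon = cross)
}
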