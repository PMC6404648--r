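# Pairwise linkage disequilibrium, Bonferroni-Fisher LD pruning, and the
# rho = 4Nc decay fit from r2 against distance.

#' Pairwise r2 and Fisher exact p between informative SNPs of one locus
#'
#' Only biallelic sites whose minor allele count is at least 2 enter; r2 is
#' the squared haplotype-frequency correlation on pairwise-complete samples
#' and the p-value is Fisher's exact test on the 2x2 haplotype table.
#'
#' @param vt a \code{variant_table}.
#' @param fisher compute Fisher exact p-values (default TRUE; FALSE leaves
#'   NA and is considerably faster when only r2 is needed).
#' @return data.frame with columns locus_id, pos_i, pos_j (0-based), dist
#'   (bp), r2, fisher_p, maf_i, maf_j; empty when fewer than two informative
#'   sites exist.
#' @export
pairwise_r2 <- function(vt, fisher = TRUE) {
  s <- vt$sites
  keep <- s$type == "SNP" & s$is_informative &
    vapply(strsplit(s$alleles, ","), length, integer(1)) == 2
  pos <- s$position[keep]
  maf <- s$maf[keep]
  empty <- data.frame(locus_id = character(0), pos_i = integer(0),
                      pos_j = integer(0), dist = integer(0), r2 = numeric(0),
                      fisher_p = numeric(0), maf_i = numeric(0),
                      maf_j = numeric(0))
  if (length(pos) < 2) return(empty)
  rows <- list()
  for (i in seq_len(length(pos) - 1)) {
    for (j in seq(i + 1, length(pos))) {
      a <- vt$geno[, as.character(pos[i])]
      b <- vt$geno[, as.character(pos[j])]
      ok <- a %in% .BASES & b %in% .BASES
      a <- a[ok]; b <- b[ok]
      if (length(a) < 2) next
      ta <- names(sort(table(a), decreasing = TRUE))
      tb <- names(sort(table(b), decreasing = TRUE))
      if (length(ta) < 2 || length(tb) < 2) next
      x <- as.integer(a == ta[1])
      y <- as.integer(b == tb[1])
      pA <- mean(x); pB <- mean(y); pAB <- mean(x & y)
      denom <- pA * (1 - pA) * pB * (1 - pB)
      if (denom == 0) next
      r2 <- (pAB - pA * pB)^2 / denom
      fp <- if (fisher) {
        stats::fisher.test(table(factor(x, 0:1), factor(y, 0:1)))$p.value
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        locus_id = vt$locus_id, pos_i = pos[i], pos_j = pos[j],
        dist = pos[j] - pos[i], r2 = r2, fisher_p = fp,
        maf_i = maf[i], maf_j = maf[j], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy LD pruning by Bonferroni-corrected Fisher tests
#'
#' While any retained pair is significant at alpha/m (m = number of tested
#' pairs), the member with more significant partners is dropped; ties drop
#' the lower-MAF site.
#'
#' @param pairs data.frame as returned by \code{\link{pairwise_r2}} (columns
#'   pos_i, pos_j, fisher_p, maf_i, maf_j; optionally locus_id, in which case
#'   sites are keyed "locus_id:pos").
#' @param alpha family-wise level before correction (default 0.05).
#' @return character vector of retained site keys.
#' @export
ld_prune <- function(pairs, alpha = 0.05) {
  if (nrow(pairs) == 0) return(character(0))
  key <- function(l, p) if (is.null(l)) as.character(p) else paste0(l, ":", p)
  ki <- key(pairs$locus_id, pairs$pos_i)
  kj <- key(pairs$locus_id, pairs$pos_j)
  maf <- c(stats::setNames(pairs$maf_i, ki), stats::setNames(pairs$maf_j, kj))
  maf <- maf[!duplicated(names(maf))]
  sites <- unique(c(ki, kj))
  thr <- alpha / nrow(pairs)
  sig <- pairs$fisher_p < thr
  repeat {
    live <- sig & ki %in% sites & kj %in% sites
    if (!any(live)) break
    counts <- table(c(ki[live], kj[live]))
    mx <- max(counts)
    cand <- names(counts)[counts == mx]
    drop <- cand[order(maf[cand], cand)][1]
    sites <- setdiff(sites, drop)
  }
  sites
}

#' Hill-Weir expected r2 with sample-size adjustment
#'
#' E[r2 | C, n] for C = rho x distance under the drift-recombination
#' equilibrium, including the finite-sample correction term.
#'
#' @param C scaled recombination distance rho x d (vectorized).
#' @param n haploid sample size.
#' @return expected r2.
#' @export
hill_weir_expected_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the per-bp recombination parameter rho from r2 decay
#'
#' Least-squares fit of observed r2 against the Hill-Weir expectation at
#' C = rho x distance, with rho constrained non-negative; the standard error
#' comes from a bootstrap over loci.
#'
#' @param pairs data.frame from \code{\link{pairwise_r2}} (pooled across
#'   loci; needs columns locus_id, dist, r2).
#' @param n haploid sample size used for the finite-sample correction.
#' @param bootstrap_reps bootstrap replicates over loci (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param rho_max upper bound of the search (default 1 per bp).
#' @return list with \code{rho} (per bp), \code{se}, \code{n_pairs},
#'   \code{rss}, \code{at_boundary} (TRUE when the optimum is at rho = 0).
#' @export
fit_rho <- function(pairs, n, bootstrap_reps = 1000, seed = NULL,
                    rho_max = 1) {
  if (nrow(pairs) < 10) stop("need at least 10 informative site pairs")
  obj <- function(rho, d, r2) sum((r2 - hill_weir_expected_r2(rho * d, n))^2)
  fit1 <- function(d, r2) {
    # log-spaced grid seed, then local polish
    grid <- c(0, 10^seq(-7, log10(rho_max), length.out = 60))
    vals <- vapply(grid, obj, numeric(1), d = d, r2 = r2)
    i <- which.min(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    if (lo == hi) return(lo)
    op <- stats::optimize(obj, c(lo, hi), d = d, r2 = r2, tol = 1e-10)
    if (op$objective <= vals[i]) op$minimum else grid[i]
  }
  rho <- fit1(pairs$dist, pairs$r2)
  loci <- unique(pairs$locus_id)
  boot <- with_seed(seed, {
    vapply(seq_len(bootstrap_reps), function(b) {
      pick <- sample(loci, length(loci), replace = TRUE)
      idx <- unlist(lapply(pick, function(l) which(pairs$locus_id == l)))
      fit1(pairs$dist[idx], pairs$r2[idx])
    }, numeric(1))
  })
  list(rho = rho, se = stats::sd(boot), n_pairs = nrow(pairs),
       rss = obj(rho, pairs$dist, pairs$r2),
       at_boundary = rho < 1e-12)
}

#' Ratio of recombination to mutation input
#'
#' @param fit result of \code{\link{fit_rho}} (per-bp rho).
#' @param theta_site per-site Watterson theta of the same sample.
#' @return rho/theta (numeric scalar).
#' @export
rho_theta_ratio <- function(fit, theta_site) {
  if (theta_site <= 0) stop("theta must be positive")
  fit$rho / theta_site
}
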