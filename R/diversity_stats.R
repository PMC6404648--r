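# Per-locus and multilocus diversity statistics.

#' Mean pairwise difference count between sequences
#'
#' Counts nucleotide differences over SNP columns with pairwise deletion
#' (a site enters a pair's comparison only when both samples carry a called
#' base) and averages over all sample pairs. This is the unnormalized
#' quantity k-bar; divide by sequence length for per-site diversity.
#'
#' @param geno character matrix, samples x SNP columns.
#' @return mean pairwise difference count (numeric scalar).
#' @export
mean_pairwise_differences <- function(geno) {
  n <- nrow(geno)
  if (n < 2) stop("need at least 2 sequences")
  if (ncol(geno) == 0) return(0)
  d <- pairwise_diff_matrix(geno)
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Pairwise difference-count matrix between sequences
#'
#' Counts, for every pair of rows, the SNP columns at which both carry a
#' called base and the bases differ (pairwise deletion). Computed through
#' per-base indicator cross-products, so it scales to full studies.
#'
#' @param geno character matrix, samples x SNP columns over \{A,C,G,T,-,N\}.
#' @return symmetric numeric matrix of difference counts, zero diagonal.
#' @export
pairwise_diff_matrix <- function(geno) {
  n <- nrow(geno)
  if (ncol(geno) == 0)
    return(matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno))))
  called <- matrix(geno %in% .BASES, nrow = n)
  both_called <- tcrossprod(called * 1)
  matches <- matrix(0, n, n)
  for (b in .BASES) {
    xb <- matrix(geno == b, nrow = n) * 1
    matches <- matches + tcrossprod(xb)
  }
  d <- both_called - matches
  dimnames(d) <- list(rownames(geno), rownames(geno))
  d
}

#' Nucleotide diversity pi
#'
#' Mean pairwise difference per site: k-bar over the selected SNP columns
#' divided by the effective length of the surveyed site class.
#'
#' @param vt a \code{variant_table}.
#' @param L_effective effective number of sites surveyed (total or silent).
#' @param positions optional integer vector of 0-based SNP positions to
#'   restrict to (e.g. silent sites); default: all SNPs.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(vt, L_effective, positions = NULL) {
  if (L_effective <= 0) stop("L_effective must be positive")
  if (vt$n < 2) stop("need at least 2 sequences")
  geno <- vt$geno
  if (!is.null(positions)) {
    keep <- colnames(geno) %in% as.character(positions)
    geno <- geno[, keep, drop = FALSE]
  }
  mean_pairwise_differences(geno) / L_effective
}

#' Watterson's theta per site
#'
#' theta_W = S / (a_{n-1} L) with a_{n-1} the harmonic number.
#'
#' @param S number of segregating sites.
#' @param n number of sequences.
#' @param L sequence length in bp.
#' @return theta_W per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("need at least 2 sequences")
  if (L <= 0) stop("L must be positive")
  S / (harmonic(n - 1) * L)
}

#' Haplotype diversity H_d with Nei's standard deviation
#'
#' H_d = (n/(n-1)) (1 - sum p_i^2); the sampling SD follows Nei (1987,
#' eq. 8.12), the estimator DnaSP reports.
#'
#' @param hs a \code{haplotype_set} (or any list with \code{freq}, \code{n}).
#' @return list with \code{Hd} and \code{sd}.
#' @export
haplotype_diversity <- function(hs) {
  n <- hs$n
  if (n < 2) stop("need at least 2 sequences")
  p <- hs$freq
  s2 <- sum(p^2)
  Hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(v, 0)))
}

#' Count of singleton sites
#'
#' A singleton site is one whose rarest allele appears exactly once.
#'
#' @param vt a \code{variant_table}.
#' @param indels \code{"count"} (include indel events, default) or
#'   \code{"ignore"}.
#' @return integer S_g.
#' @export
singleton_summary <- function(vt, indels = c("count", "ignore")) {
  indels <- match.arg(indels)
  s <- vt$sites
  if (indels == "ignore") s <- s[s$type == "SNP", , drop = FALSE]
  sum(s$is_singleton)
}

# Standard genetic code, codons over T,C,A,G in the canonical order.
.GENETIC_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

# Nei-Gojobori synonymous site count of one codon: for each position, the
# fraction of the three possible point changes that are synonymous.
codon_synonymous_sites <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  if (!all(bases %in% .BASES)) return(NA_real_)
  codon_t <- chartr("U", "T", codon)
  aa0 <- .GENETIC_CODE[[codon_t]]
  if (is.na(aa0) || aa0 == "*") return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("T", "C", "A", "G"), chartr("U", "T", bases[pos]))) {
      mut <- bases
      mut[pos] <- alt
      aa1 <- .GENETIC_CODE[[paste(chartr("U", "T", mut), collapse = "")]]
      if (!is.na(aa1) && aa1 == aa0) s <- s + 1 / 3
    }
  }
  s
}

#' Total and silent site lengths of a locus
#'
#' Silent sites are the noncoding columns plus the synonymous-site fraction
#' of coding columns, counted by the Nei-Gojobori method on the consensus
#' codons of the analysed samples. Codons containing gaps, missing data or
#' stop codons are skipped.
#'
#' @param aln a \code{locus_alignment}.
#' @param annot data.frame with columns \code{start}, \code{end} (0-based
#'   half-open alignment coordinates) and \code{frame} in \{0,1,2\}, or NULL
#'   for a fully noncoding locus.
#' @param subset sample ids used for the consensus (default all).
#' @return list with \code{L_total}, \code{L_silent}, \code{L_coding}.
#' @export
site_class_lengths <- function(aln, annot = NULL, subset = NULL) {
  L_total <- aln$length
  if (is.null(annot) || nrow(annot) == 0) {
    return(list(L_total = L_total, L_silent = L_total, L_coding = 0))
  }
  m <- aln$seqs
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  coding_cols <- logical(L_total)
  syn <- 0
  for (i in seq_len(nrow(annot))) {
    start <- annot$start[i]; end <- annot$end[i]; frame <- annot$frame[i]
    if (start < 0 || end > L_total || start >= end)
      stop("annotation interval outside locus ", aln$locus_id)
    if (!(frame %in% 0:2)) stop("frame must be 0, 1 or 2")
    cols <- seq(start + 1L, end)
    if (any(coding_cols[cols]))
      stop("overlapping coding intervals on locus ", aln$locus_id)
    coding_cols[cols] <- TRUE
    first_codon_col <- start + 1L + frame
    if ((end - (first_codon_col - 1L)) < 3) next
    codon_starts <- seq(first_codon_col, end - 2L, by = 3)
    for (cs in codon_starts) {
      cons <- apply(m[, cs:(cs + 2L), drop = FALSE], 2, consensus_base)
      ss <- codon_synonymous_sites(paste(cons, collapse = ""))
      if (!is.na(ss)) syn <- syn + ss
    }
  }
  list(L_total = L_total,
       L_silent = sum(!coding_cols) + syn,
       L_coding = sum(coding_cols))
}

consensus_base <- function(col) {
  b <- col[col %in% .BASES]
  if (length(b) == 0) return("N")
  tab <- sort(table(b), decreasing = TRUE)
  names(tab)[1]
}

# log P(S = s | theta_locus, n) under the neutral coalescent, Tavare's
# alternating-sum closed form; signed logsumexp guards against overflow.
log_prob_S_tavare <- function(s, theta, n) {
  i <- seq_len(n - 1)
  logterm <- lchoose(n - 1, i) + log(i / (theta + i)) +
    s * log(theta / (theta + i))
  sign <- (-1)^(i - 1)
  mx <- max(logterm)
  val <- sum(sign * exp(logterm - mx))
  if (val <= 0) return(-Inf)  # catastrophic cancellation guard
  mx + log(val)
}

# Vectorized Tavare log-probability across loci sharing one sample size:
# returns log P(S_l = s_l | thetaL_l, n) for vectors s, thetaL.
log_prob_S_tavare_vec <- function(s, thetaL, n) {
  i <- seq_len(n - 1)
  lch <- lchoose(n - 1, i)
  denom <- outer(i, thetaL, "+")            # (n-1) x loci
  core <- sweep(-log(denom), 2, log(thetaL), "+")  # log(thetaL/(thetaL+i))
  logterm <- lch + log(i) - log(denom) + sweep(core, 2, s, "*")
  sign <- (-1)^(i - 1)
  mx <- apply(logterm, 2, max)
  val <- colSums(sign * exp(sweep(logterm, 2, mx)))
  out <- ifelse(val > 0, mx + log(val), -Inf)
  out
}

# Monte-Carlo likelihood of S given theta: common random tree lengths drawn
# once, so the likelihood is smooth in theta across proposals.
log_prob_S_mc <- function(s, theta, tree_lengths) {
  log(mean(stats::dpois(s, theta * tree_lengths)) + 1e-300)
}

# Draw total tree lengths (4N units, E[length] = a_{n-1}) for the MC
# likelihood.
draw_tree_lengths <- function(n, reps) {
  k <- seq(n, 2)
  # T_k ~ Exp(rate k(k-1)); length contribution k * T_k
  lens <- matrix(stats::rexp(reps * length(k),
                             rate = rep(k * (k - 1), each = reps)),
                 nrow = reps)
  as.vector(lens %*% k)
}

#' Bayesian multilocus posterior for a shared per-site theta
#'
#' One per-site Watterson-type mutation parameter is shared across loci;
#' each locus contributes the closed-form probability of its segregating-site
#' count given theta x L and n under the neutral coalescent (Tavare's
#' alternating sum; a Monte-Carlo likelihood over simulated tree lengths with
#' common random numbers replaces it when n > 50 or S > 500). The prior is
#' uniform on log10(theta) over \code{prior}; sampling is Metropolis on
#' log10(theta).
#'
#' @param S integer vector of per-locus segregating-site counts.
#' @param n integer vector (or scalar) of per-locus sample sizes.
#' @param L numeric vector (or scalar) of per-locus lengths in bp.
#' @param prior log10-theta range, default c(-5, -1).
#' @param burn_in discarded iterations (default 5000).
#' @param samples retained iterations (default 100000).
#' @param proposal_sd random-walk SD on log10 theta (default 0.08).
#' @param mc_reps tree draws for the Monte-Carlo likelihood (default 10000).
#' @param seed RNG seed.
#' @return list with \code{median}, \code{ci} (95\% equal-tail credible
#'   interval), \code{mean}, \code{acceptance}, \code{ess}, \code{draws}
#'   (posterior sample of per-site theta).
#' @export
multilocus_theta_posterior <- function(S, n, L, prior = c(-5, -1),
                                       burn_in = 5000, samples = 100000,
                                       proposal_sd = 0.08, mc_reps = 10000,
                                       seed = NULL) {
  nloci <- length(S)
  stopifnot(nloci >= 1)
  n <- rep_len(n, nloci)
  L <- rep_len(L, nloci)
  if (any(n < 2)) stop("all loci need n >= 2")
  with_seed(seed, {
    use_mc <- n > 50 | S > 500
    tl <- lapply(seq_len(nloci), function(i)
      if (use_mc[i]) draw_tree_lengths(n[i], mc_reps) else NULL)
    cf_groups <- split(which(!use_mc), n[!use_mc])  # equal-n fast path
    mc_idx <- which(use_mc)
    loglik <- function(log10_theta) {
      th <- 10^log10_theta
      total <- 0
      for (grp in cf_groups) {
        total <- total + sum(log_prob_S_tavare_vec(
          S[grp], th * L[grp], n[grp[1]]))
      }
      for (i in mc_idx) {
        total <- total + log_prob_S_mc(S[i], th * L[i], tl[[i]])
      }
      total
    }
    cur <- mean(prior)
    cur_ll <- loglik(cur)
    total <- burn_in + samples
    draws <- numeric(samples)
    acc <- 0L
    steps <- stats::rnorm(total, 0, proposal_sd)
    us <- log(stats::runif(total))
    for (t in seq_len(total)) {
      prop <- cur + steps[t]
      if (prop >= prior[1] && prop <= prior[2]) {
        prop_ll <- loglik(prop)
        if (us[t] < prop_ll - cur_ll) {
          cur <- prop; cur_ll <- prop_ll; acc <- acc + 1L
        }
      }
      if (t > burn_in) draws[t - burn_in] <- cur
    }
    theta_draws <- 10^draws
    ac <- stats::acf(draws, lag.max = min(1000, samples - 1), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cutoff <- if (length(pos)) pos[1] else length(ac)
    ess <- samples / (1 + 2 * sum(ac[seq_len(cutoff)]))
    if (ess < 200)
      warning("multilocus theta posterior: effective sample size ", round(ess),
              " < 200; consider longer chains")
    list(median = stats::median(theta_draws),
         ci = unname(stats::quantile(theta_draws, c(0.025, 0.975))),
         mean = mean(theta_draws),
         acceptance = acc / total, ess = ess, draws = theta_draws)
  })
}

#' Per-locus diversity summary for one group of samples
#'
#' Convenience wrapper producing the per-locus rows of a Table-1-style
#' diversity summary: L, S, singletons, pi, haplotype count and diversity.
#'
#' @param alignments named list of \code{locus_alignment}.
#' @param subset sample ids belonging to the group.
#' @param annotations optional named list of annotation data.frames.
#' @return data.frame with one row per locus.
#' @export
diversity_summary <- function(alignments, subset, annotations = NULL) {
  rows <- lapply(alignments, function(aln) {
    sub <- intersect(subset, rownames(aln$seqs))
    if (length(sub) < 2) return(NULL)
    vt <- build_variant_table(aln, sub)
    hs <- extract_haplotypes(aln, sub)
    hd <- haplotype_diversity(hs)
    ann <- if (!is.null(annotations)) annotations[[aln$locus_id]] else NULL
    lens <- site_class_lengths(aln, ann, sub)
    data.frame(locus_id = aln$locus_id, n = vt$n,
               L_total = lens$L_total, L_silent = lens$L_silent,
               S = segregating_sites(vt), S_g = singleton_summary(vt),
               pi_total = nucleotide_diversity(vt, lens$L_total),
               n_haplotypes = hs$n_haplotypes,
               Hd = hd$Hd, Hd_sd = hd$sd,
               theta_w = watterson_theta(vt$n_snps, vt$n, lens$L_total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
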