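# Site-frequency-spectrum and haplotype neutrality tests with coalescent
# null distributions: Tajima's D, Fay & Wu's normalized H (Zeng et al. 2006
# variance), Ewens-Watterson, the compound HEW/DHEW tests, and the
# multilocus HKA polymorphism-divergence test.

#' Tajima's D from summary quantities
#'
#' @param n sample size.
#' @param S segregating sites (SNPs).
#' @param k_bar mean pairwise difference count.
#' @return D (NA when S = 0: the statistic is undefined).
#' @export
tajima_d_stat <- function(n, S, k_bar) {
  if (S == 0) return(NA_real_)
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  num <- k_bar - S / a1
  den <- sqrt(e1 * S + e2 * S * (S - 1))
  if (abs(num) < 1e-12) return(0)  # incl. n = 3, where Var(D) is exactly 0
  if (den <= 0) return(NA_real_)
  num / den
}

# pi-count and D from a derived-count (or folded-count) vector
k_bar_from_xi <- function(xi, n) sum(2 * xi * (n - xi)) / (n * (n - 1))

tajima_d_from_xi <- function(xi, n) {
  tajima_d_stat(n, length(xi), k_bar_from_xi(xi, n))
}

#' Tajima's D for a variant table, with a coalescent p-value
#'
#' The statistic uses SNPs only; the p-value compares the observed D with
#' D over \code{reps} fixed-S neutral coalescent simulations at the same n.
#'
#' @param vt a \code{variant_table}.
#' @param reps simulation replicates (default 1000; 0 skips the p-value).
#' @param seed RNG seed.
#' @return list with \code{D}, \code{S}, \code{k_bar}, \code{p_neg}
#'   (one-sided, D as small or smaller), \code{p_two} (two-sided).
#' @export
tajima_d <- function(vt, reps = 1000, seed = NULL) {
  S <- vt$n_snps
  k_bar <- mean_pairwise_differences(vt$geno)
  D <- tajima_d_stat(vt$n, S, k_bar)
  out <- list(D = D, S = S, k_bar = k_bar, p_neg = NA_real_,
              p_two = NA_real_)
  if (is.na(D) || reps == 0) return(out)
  null <- with_seed(seed, {
    vapply(seq_len(reps), function(r)
      tajima_d_from_xi(simulate_sfs(vt$n, "fixed_S", S = S), vt$n),
      numeric(1))
  })
  out$p_neg <- perm_pvalue(sum(null <= D), reps)
  p_pos <- perm_pvalue(sum(null >= D), reps)
  out$p_two <- min(1, 2 * min(out$p_neg, p_pos))
  out
}

#' Multilocus Tajima's D
#'
#' Observed mean D over loci with defined D; the null distribution is the
#' mean of per-locus D over loci each simulated under the fixed-S neutral
#' coalescent at its own n and S.
#'
#' @param loci data.frame with columns \code{n}, \code{S}, \code{D}.
#' @param reps coalescent replicates (default 1000).
#' @param seed RNG seed.
#' @return list with \code{mean_D}, \code{p_neg} (one-sided for a negative
#'   mean), \code{p_two}, \code{n_loci} (with defined D).
#' @export
multilocus_tajima <- function(loci, reps = 1000, seed = NULL) {
  use <- !is.na(loci$D) & loci$S > 0
  if (!any(use)) stop("all loci have S = 0: multilocus D undefined")
  loci <- loci[use, , drop = FALSE]
  obs <- mean(loci$D)
  null <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      mean(vapply(seq_len(nrow(loci)), function(i)
        tajima_d_from_xi(simulate_sfs(loci$n[i], "fixed_S", S = loci$S[i]),
                         loci$n[i]), numeric(1)))
    }, numeric(1))
  })
  p_neg <- perm_pvalue(sum(null <= obs), reps)
  p_pos <- perm_pvalue(sum(null >= obs), reps)
  list(mean_D = obs, p_neg = p_neg, p_two = min(1, 2 * min(p_neg, p_pos)),
       n_loci = nrow(loci))
}

# Fay & Wu / Zeng statistics from a polarized derived-count vector.
# Returns theta_pi, theta_H, theta_L, unnormalized H = theta_pi - theta_H,
# and the Zeng et al. (2006) normalized H based on theta_pi - theta_L.
fay_wu_stats <- function(xi, n) {
  S <- length(xi)
  if (S == 0) return(list(H = NA_real_, H_norm = NA_real_))
  theta_pi <- k_bar_from_xi(xi, n)
  theta_H <- sum(2 * xi^2) / (n * (n - 1))
  theta_L <- sum(xi) / (n - 1)
  a <- harmonic(n - 1); b <- harmonic2(n - 1)
  bn1 <- harmonic2(n)
  theta_w <- S / a
  theta2 <- S * (S - 1) / (a^2 + b)
  v <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * theta2
  list(theta_pi = theta_pi, theta_H = theta_H, theta_L = theta_L,
       H = theta_pi - theta_H,
       H_norm = if (v > 0) (theta_pi - theta_L) / sqrt(v) else NA_real_)
}

#' Fay & Wu's H with Zeng normalization and a coalescent p-value
#'
#' Sites without a known ancestral state are excluded. The p-value is
#' one-sided for negative H (excess of high-frequency derived alleles) from
#' fixed-S simulations, which are polarized by construction.
#'
#' @param vt a polarized \code{variant_table} (see
#'   \code{\link{polarize_variants}}).
#' @param reps simulation replicates (default 1000; 0 skips the p-value).
#' @param seed RNG seed.
#' @return list with \code{H} (unnormalized theta_pi - theta_H),
#'   \code{H_norm}, \code{n_polarized}, \code{p_neg}.
#' @export
fay_wu_h <- function(vt, reps = 1000, seed = NULL) {
  s <- vt$sites
  pol <- s$type == "SNP" & !is.na(s$ancestral)
  xi <- s$derived_count[pol]
  if (length(xi) == 0) {
    return(list(H = NA_real_, H_norm = NA_real_, n_polarized = 0L,
                p_neg = NA_real_))
  }
  st <- fay_wu_stats(xi, vt$n)
  out <- list(H = st$H, H_norm = st$H_norm, n_polarized = length(xi),
              p_neg = NA_real_)
  if (reps == 0 || is.na(st$H_norm)) return(out)
  null <- with_seed(seed, {
    vapply(seq_len(reps), function(r)
      fay_wu_stats(simulate_sfs(vt$n, "fixed_S", S = length(xi)),
                   vt$n)$H_norm, numeric(1))
  })
  out$p_neg <- perm_pvalue(sum(null <= st$H_norm, na.rm = TRUE), reps)
  out
}

# Solve E[k | theta, n] = k for the Ewens sampling formula,
# E[k] = sum_{i=0}^{n-1} theta/(theta+i).
solve_esf_theta <- function(k, n) {
  if (k <= 1) return(1e-8)
  if (k >= n) return(1e8)
  f <- function(th) sum(th / (th + 0:(n - 1))) - k
  stats::uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
}

# One Chinese-restaurant draw of a haplotype configuration; returns counts.
crp_draw <- function(n, theta) {
  counts <- integer(0)
  for (i in seq_len(n)) {
    if (length(counts) == 0) { counts <- 1L; next }
    p_new <- theta / (theta + i - 1)
    if (stats::runif(1) < p_new) counts <- c(counts, 1L)
    else {
      j <- sample.int(length(counts), 1, prob = counts)
      counts[j] <- counts[j] + 1L
    }
  }
  counts
}

#' Ewens-Watterson homozygosity test
#'
#' F = sum p_i^2 is compared with configurations from the Ewens sampling
#' formula conditional on (n, k): theta is solved from E[k | theta, n] = k
#' and Chinese-restaurant draws are retained when they produce exactly k
#' haplotypes. The p-value is one-sided for homozygosity excess,
#' Pr(F_null >= F_obs).
#'
#' @param hs a \code{haplotype_set} (uses \code{n}, \code{n_haplotypes},
#'   \code{F}).
#' @param reps retained null configurations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{F}, \code{k}, \code{p_high}, \code{degenerate}
#'   flag (k = 1 or k = n).
#' @export
ewens_watterson <- function(hs, reps = 1000, seed = NULL) {
  n <- hs$n; k <- hs$n_haplotypes
  if (n < 2) stop("need n >= 2")
  degenerate <- k == 1 || k == n
  null_F <- ewens_null_F(n, k, reps, seed)
  p <- perm_pvalue(sum(null_F >= hs$F - 1e-12), reps)
  list(F = hs$F, k = k, p_high = p, degenerate = degenerate)
}

# Null F draws under the Ewens sampling formula conditional on (n, k).
ewens_null_F <- function(n, k, reps, seed = NULL) {
  if (k == 1) return(rep(1, reps))
  if (k == n) return(rep(1 / n, reps))
  theta <- solve_esf_theta(k, n)
  with_seed(seed, {
    out <- numeric(reps)
    got <- 0L
    guard <- 0L
    while (got < reps) {
      cfg <- crp_draw(n, theta)
      guard <- guard + 1L
      if (length(cfg) == k) {
        got <- got + 1L
        out[got] <- sum((cfg / n)^2)
      }
      if (guard > reps * 1000)
        stop("conditional Ewens sampling failed to reach ", reps, " draws")
    }
    out
  })
}

# Simulate one neutral replicate of (D, H_norm, F) at sample size n.
# conditioning: fixed_theta (Poisson mutations at theta) or fixed_S.
simulate_dhf <- function(n, conditioning, theta = NULL, S = NULL) {
  g <- simulate_genealogy(n)
  mut <- mutate_infinite_sites(g, conditioning, theta = theta, S = S,
                               L = .Machine$integer.max %/% 2,
                               return_matrix = FALSE)
  xi <- mut$xi
  D <- tajima_d_from_xi(xi, n)
  Hn <- fay_wu_stats(xi, n)$H_norm
  # haplotype configuration from the mutation carrier sets
  if (length(mut$carriers) == 0) {
    Fhom <- 1
  } else {
    prof <- vapply(seq_len(n), function(i)
      paste(vapply(mut$carriers, function(cs) i %in% cs, logical(1)),
            collapse = ""), character(1))
    cfg <- table(prof)
    Fhom <- sum((as.numeric(cfg) / n)^2)
  }
  c(D = D, H = Hn, F = Fhom)
}

#' Compound HEW / DHEW neutrality tests
#'
#' Following the compound-test framework, the test rejects at level alpha
#' iff every component (HEW: normalized H and Ewens-Watterson F; DHEW:
#' Tajima's D, H and F) is individually significant at a calibrated level
#' alpha', found by bisection on a jointly simulated neutral null so that
#' the compound size equals alpha. Component directions are D negative, H
#' negative, F high. Nulls are simulated fixed-theta at the locus's
#' Watterson estimate by default (fixed-S available).
#'
#' @param obs list with observed \code{D}, \code{H_norm}, \code{F}.
#' @param n sample size.
#' @param theta locus-total Watterson theta (fixed_theta conditioning).
#' @param S segregating sites (fixed_S conditioning).
#' @param alpha compound test size (default 0.05).
#' @param reps simulation replicates (default 10000).
#' @param conditioning \code{"fixed_theta"} (default) or \code{"fixed_S"}.
#' @param seed RNG seed.
#' @return list with \code{hew}, \code{dhew} (logical verdicts),
#'   \code{alpha_prime_hew}, \code{alpha_prime_dhew}, component p-values
#'   \code{p_D}, \code{p_H}, \code{p_F}, and \code{reps_used} (replicates
#'   with defined statistics).
#' @export
compound_hew_dhew <- function(obs, n, theta = NULL, S = NULL, alpha = 0.05,
                              reps = 10000,
                              conditioning = c("fixed_theta", "fixed_S"),
                              seed = NULL) {
  conditioning <- match.arg(conditioning)
  null <- with_seed(seed, {
    t(vapply(seq_len(reps), function(r)
      simulate_dhf(n, conditioning, theta = theta, S = S), numeric(3)))
  })
  ok <- stats::complete.cases(null)
  null <- null[ok, , drop = FALSE]
  if (nrow(null) < reps / 10)
    stop("fewer than reps/10 usable simulations (S = 0 draws dominate): ",
         "use fixed-S conditioning")
  B <- nrow(null)
  # component one-sided p of each null replicate within the null sample
  p_lo <- function(v) (rank(v, ties.method = "max")) / B
  p_hi <- function(v) (B + 1 - rank(v, ties.method = "min")) / B
  null_p <- cbind(D = p_lo(null[, "D"]), H = p_lo(null[, "H"]),
                  F = p_hi(null[, "F"]))
  calibrate <- function(cols) {
    size_at <- function(a) mean(apply(null_p[, cols, drop = FALSE] <= a,
                                      1, all))
    lo <- 0; hi <- 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (size_at(mid) > alpha) hi <- mid else lo <- mid
    }
    lo
  }
  ap_hew <- calibrate(c("H", "F"))
  ap_dhew <- calibrate(c("D", "H", "F"))
  p_D <- perm_pvalue(sum(null[, "D"] <= obs$D), B)
  p_H <- perm_pvalue(sum(null[, "H"] <= obs$H_norm), B)
  p_F <- perm_pvalue(sum(null[, "F"] >= obs$F - 1e-12), B)
  list(hew = (p_H <= ap_hew && p_F <= ap_hew),
       dhew = (p_D <= ap_dhew && p_H <= ap_dhew && p_F <= ap_dhew),
       alpha_prime_hew = ap_hew, alpha_prime_dhew = ap_dhew,
       p_D = p_D, p_H = p_H, p_F = p_F, reps_used = B)
}

#' Multilocus HKA test against outgroup divergence
#'
#' Hudson-Kreitman-Aguade framework with one intraspecies sample per locus
#' and a single outgroup sequence, equal-population-size form: E[S_i] =
#' theta_i a_{n_i-1}, Var[S_i] = E[S_i] + theta_i^2 b_{n_i-1}; E[D_i] =
#' theta_i (T + 1), Var[D_i] = E[D_i] + theta_i^2. Parameters minimize the
#' X^2 of observed against expected S and D; X^2 is referred to
#' chi-square(L - 1).
#'
#' @param loci data.frame with columns \code{locus_id}, \code{S} (segregating
#'   sites), \code{D} (divergence count vs the outgroup), \code{n}.
#' @return list with \code{T}, \code{theta} (per-locus vector), \code{X2},
#'   \code{df}, \code{p}, \code{expected} (data.frame of fitted E[S], E[D]),
#'   \code{dropped} (loci with S = 0 and D = 0).
#' @export
hka_test <- function(loci) {
  drop <- loci$S == 0 & loci$D == 0
  if (any(drop))
    warning("dropping ", sum(drop), " locus/loci with S = 0 and D = 0")
  loci <- loci[!drop, , drop = FALSE]
  L <- nrow(loci)
  if (L < 2) stop("HKA needs at least 2 informative loci")
  a <- vapply(loci$n, function(n) harmonic(n - 1), numeric(1))
  b <- vapply(loci$n, function(n) harmonic2(n - 1), numeric(1))
  x2_locus <- function(theta, T, i) {
    ES <- theta * a[i]; VS <- ES + theta^2 * b[i]
    ED <- theta * (T + 1); VD <- ED + theta^2
    (loci$S[i] - ES)^2 / VS + (loci$D[i] - ED)^2 / VD
  }
  # moment-equation starting point
  g <- function(T) sum((loci$S + loci$D) * a / (a + T + 1)) - sum(loci$S)
  T0 <- tryCatch(stats::uniroot(g, c(1e-8, 1e6))$root, error = function(e) 1)
  fit_thetas <- function(T) {
    vapply(seq_len(L), function(i) {
      th0 <- max((loci$S[i] + loci$D[i]) / (a[i] + T + 1), 1e-6)
      stats::optimize(function(th) x2_locus(th, T, i),
                      c(th0 / 20, th0 * 20), tol = 1e-10)$minimum
    }, numeric(1))
  }
  x2_of_T <- function(T) {
    th <- fit_thetas(T)
    sum(vapply(seq_len(L), function(i) x2_locus(th[i], T, i), numeric(1)))
  }
  op <- stats::optimize(x2_of_T, c(max(T0 / 20, 1e-6), T0 * 20 + 1),
                        tol = 1e-9)
  T_hat <- op$minimum
  theta_hat <- fit_thetas(T_hat)
  X2 <- op$objective
  df <- L - 1
  expected <- data.frame(locus_id = loci$locus_id,
                         ES = theta_hat * a, ED = theta_hat * (T_hat + 1))
  list(T = T_hat, theta = theta_hat, X2 = X2, df = df,
       p = stats::pchisq(X2, df, lower.tail = FALSE), expected = expected,
       dropped = sum(drop))
}
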