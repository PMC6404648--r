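# F_ST outlier detection: FDIST-style coalescent envelopes conditional on
# heterozygosity, a Bayesian logistic F_ST decomposition with reversible-jump
# locus effects, and Storey pi0/q-value FDR control.

# Variance-partition F_ST for a binary haploid vector (closed form of the
# two-level AMOVA used elsewhere; see amova_components).
fst_binary <- function(x, pop) {
  N <- length(x)
  pops <- unique(pop)
  P <- length(pops)
  if (P < 2) return(NA_real_)
  N1 <- sum(x)
  ss_t <- N1 * (N - N1) / N
  n_p <- numeric(P); ss_wp <- 0
  for (k in seq_len(P)) {
    idx <- pop == pops[k]
    n_p[k] <- sum(idx)
    n1 <- sum(x[idx])
    ss_wp <- ss_wp + n1 * (n_p[k] - n1) / n_p[k]
  }
  df_ap <- P - 1; df_wp <- N - P
  if (df_wp < 1) return(NA_real_)
  ms_ap <- (ss_t - ss_wp) / df_ap
  ms_wp <- ss_wp / df_wp
  n_prime <- (N - sum(n_p^2) / N) / df_ap
  sigma_c <- ms_wp
  sigma_b <- (ms_ap - ms_wp) / n_prime
  tot <- sigma_b + sigma_c
  if (tot <= 0) 0 else sigma_b / tot
}

# One island-model SNP: genealogy over the sampled demes of a d-deme island
# model, a single mutation placed proportionally to branch length.
island_snp <- function(d, M, samples_per_deme) {
  deme_of_sample <- rep(seq_len(d), rep_len(samples_per_deme, d))
  g <- structured_coalescent(deme_of_sample, n_demes = d, M = M,
                             size_factor = d)
  mut <- mutate_infinite_sites(g, "fixed_S", S = 1, L = 2,
                               return_matrix = FALSE)
  carriers <- mut$carriers[[1]]
  x <- integer(g$n)
  x[carriers] <- 1L
  list(x = x, pop = deme_of_sample)
}

# Mean simulated F_ST (and the (he, fst) cloud) for a migration rate.
island_fst_cloud <- function(d, M, samples_per_deme, reps, maf_min = 0) {
  he <- numeric(reps); fst <- numeric(reps)
  got <- 0L; tries <- 0L
  while (got < reps && tries < reps * 50) {
    tries <- tries + 1L
    snp <- island_snp(d, M, samples_per_deme)
    p <- mean(snp$x)
    if (min(p, 1 - p) <= maf_min) next
    got <- got + 1L
    he[got] <- 2 * p * (1 - p) * length(snp$x) / (length(snp$x) - 1)
    fst[got] <- fst_binary(snp$x, snp$pop)
  }
  if (got < reps) stop("island simulation could not produce enough ",
                       "polymorphic replicates")
  data.frame(he = he, fst = fst)
}

#' Calibrate the island-model migration rate to a target mean F_ST
#'
#' 1-D search on log M so that the mean simulated F_ST across replicate
#' SNPs matches the target.
#'
#' @param target_fst observed multilocus F_ST (> 0).
#' @param d demes.
#' @param samples_per_deme samples per sampled deme (zeros for unsampled).
#' @param reps replicates per evaluation (default 300).
#' @param seed RNG seed.
#' @return calibrated M.
#' @export
calibrate_island_m <- function(target_fst, d, samples_per_deme, reps = 300,
                               seed = NULL) {
  if (target_fst <= 0) stop("degenerate null: observed multilocus F_ST <= 0")
  with_seed(seed, {
    f <- function(logM) {
      mean(island_fst_cloud(d, exp(logM), samples_per_deme, reps)$fst) -
        target_fst
    }
    # within-deme coalescence is accelerated by d, so the migration rate
    # that balances it scales with d too
    lo <- log(0.05 * d); hi <- log(100 * d)
    flo <- f(lo); fhi <- f(hi)
    if (flo < 0) return(exp(lo))    # even minimal migration too weak
    if (fhi > 0) return(exp(hi))
    exp(stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                       tol = 0.05)$root)
  })
}

#' FDIST-style F_ST outlier scan
#'
#' Simulates island-model SNPs with migration calibrated so the mean
#' simulated F_ST matches the observed multilocus F_ST, then forms
#' conditional F_ST envelopes in sliding heterozygosity windows (>= 500
#' simulated loci per window) and flags observed SNPs beyond the 95% and
#' 99% quantiles; the empirical p per SNP is the fraction of window loci
#' with F_ST at least as large.
#'
#' @param obs data.frame with per-SNP \code{fst} and \code{he} (>= 50 SNPs).
#' @param samples_per_deme observed sampling design: haploid samples per
#'   sampled deme.
#' @param demes island-model demes (default 100).
#' @param reps simulated loci (default 20000).
#' @param thresholds envelope quantiles (default c(0.95, 0.99)).
#' @param window minimum simulated loci per heterozygosity window
#'   (default 500).
#' @param target_fst calibration target (default mean of \code{obs$fst}).
#' @param calibration_reps replicates per calibration evaluation.
#' @param seed RNG seed.
#' @return list with \code{table} (per SNP: fst, he, q50/q95/q99, p,
#'   flagged_95, flagged_99), \code{M}, \code{sim} (the simulated cloud),
#'   \code{settings}.
#' @export
fdist_scan <- function(obs, samples_per_deme, demes = 100, reps = 20000,
                       thresholds = c(0.95, 0.99), window = 500,
                       target_fst = NULL, calibration_reps = 300,
                       seed = NULL) {
  if (nrow(obs) < 50)
    warning("fewer than 50 SNPs: envelope will be unstable")
  target_fst <- target_fst %||% mean(obs$fst)
  seeds <- derive_seeds(seed %||% sample.int(2^30, 1), 2)
  spd <- c(samples_per_deme, rep(0, demes - length(samples_per_deme)))
  M <- calibrate_island_m(target_fst, demes, spd, reps = calibration_reps,
                          seed = seeds[1])
  sim <- with_seed(seeds[2], island_fst_cloud(demes, M, spd, reps))
  sim <- sim[order(sim$he), ]
  win <- min(window, nrow(sim))
  if (win < window)
    warning("widening window to all ", win, " simulated loci")
  half <- win %/% 2
  n_sim <- nrow(sim)
  res <- obs
  res$q50 <- res$q95 <- res$q99 <- res$p <- NA_real_
  for (i in seq_len(nrow(obs))) {
    c_idx <- findInterval(obs$he[i], sim$he)
    lo <- max(1, min(c_idx - half, n_sim - win + 1))
    wf <- sim$fst[lo:(lo + win - 1)]
    qs <- stats::quantile(wf, c(0.5, thresholds), names = FALSE)
    res$q50[i] <- qs[1]; res$q95[i] <- qs[2]; res$q99[i] <- qs[3]
    res$p[i] <- perm_pvalue(sum(wf >= obs$fst[i] - 1e-12), win)
  }
  res$flagged_95 <- res$fst > res$q95
  res$flagged_99 <- res$fst > res$q99
  list(table = res, M = M, sim = sim,
       settings = list(demes = demes, reps = reps, window = win,
                       target_fst = target_fst, seed = seed))
}

# Beta-binomial log-likelihood matrix for the logistic F_ST decomposition.
# a, n: SNP x population matrices; p: ancestral frequencies (SNP vector);
# fst: SNP x population matrix of F values in (0,1).
bb_loglik <- function(a, n, p, fst) {
  lam <- 1 / fst - 1
  s1 <- p * lam; s2 <- (1 - p) * lam
  lchoose(n, a) + lbeta(a + s1, n - a + s2) - lbeta(s1, s2)
}

#' Bayesian logistic F_ST decomposition (BayeScan-style outlier scan)
#'
#' logit(F_ST^{ij}) = alpha_i + beta_j with a reversible-jump indicator on
#' each locus effect alpha_i (prior odds for the neutral model
#' \code{prior_odds}); allele counts are beta-binomial given the ancestral
#' frequency p_i and the population-locus F. Pilot runs tune proposal widths;
#' q-values are the local-FDR average of (1 - inclusion probability) down the
#' ranked list.
#'
#' @param a SNP x population matrix of counts of the reference allele.
#' @param n SNP x population matrix of called haploid sample sizes.
#' @param maf_min pooled minor-allele-frequency filter (default 0.05).
#' @param pilot_runs,pilot_length pilot tuning (defaults 20 x 5000... scaled
#'   by \code{pilot_length}).
#' @param burn_in discarded sweeps (default 50000).
#' @param samples retained posterior samples (default 5000).
#' @param thin sweeps between retained samples (default 10).
#' @param prior_odds prior odds for the neutral model (default 10).
#' @param seed RNG seed.
#' @return list with \code{table} (per SNP: pip, alpha, q, selected at
#'   q < 0.05), \code{beta} (posterior means), \code{acceptance},
#'   \code{kept} (row indices of SNPs passing the MAF filter).
#' @export
bayescan_like <- function(a, n, maf_min = 0.05, pilot_runs = 20,
                          pilot_length = 5000, burn_in = 50000,
                          samples = 5000, thin = 10, prior_odds = 10,
                          seed = NULL) {
  stopifnot(all(dim(a) == dim(n)))
  pooled <- rowSums(a) / rowSums(n)
  keep <- pmin(pooled, 1 - pooled) > maf_min
  a <- a[keep, , drop = FALSE]; n <- n[keep, , drop = FALSE]
  I <- nrow(a); J <- ncol(a)
  if (I == 0) stop("no SNPs pass the MAF filter")
  with_seed(seed, {
    p <- pmin(pmax(rowSums(a) / rowSums(n), 0.01), 0.99)
    alpha <- numeric(I)
    delta <- rep(FALSE, I)
    beta <- rep(-1, J)
    sd_p <- rep(0.4, I); sd_a <- rep(0.6, I); sd_b <- rep(0.25, J)
    sd_alpha_prior <- 1; mean_beta_prior <- -1; sd_beta_prior <- 1.8
    p_incl <- 1 / (1 + prior_odds)
    log_odds_incl <- log(p_incl / (1 - p_incl))
    # reversible-jump proposal centred on a per-locus moment estimate of
    # the locus effect (clipped logit of the empirical F against the
    # median locus), which keeps birth moves near the posterior mode
    phat <- a / pmax(n, 1)
    pbar <- rowSums(a) / rowSums(n)
    fhat <- apply(phat, 1, stats::var) / pmax(pbar * (1 - pbar), 1e-6)
    fhat <- pmin(pmax(fhat, 0.005), 0.95)
    mu_rj <- stats::qlogis(fhat) - stats::qlogis(stats::median(fhat))
    mu_rj <- pmin(pmax(mu_rj, -3), 3)
    sd_rj <- 1

    fmat <- function(alpha, beta) {
      f <- stats::plogis(outer(alpha, rep(1, J)) +
                         outer(rep(1, I), beta))
      pmin(pmax(f, 1e-8), 1 - 1e-8)
    }
    ll_rows <- function(p, alpha, beta) {
      rowSums(bb_loglik(a, n, p, fmat(alpha, beta)))
    }
    ll <- ll_rows(p, alpha, beta)

    acc <- c(p = 0, alpha = 0, beta = 0, rj = 0)
    tot <- c(p = 0, alpha = 0, beta = 0, rj = 0)

    sweep_once <- function() {
      # ancestral frequencies (logit random walk, vectorized accept)
      lp <- stats::qlogis(p)
      prop <- stats::plogis(lp + stats::rnorm(I, 0, sd_p))
      ll_prop <- ll_rows(prop, alpha, beta)
      # Jacobian of the logit walk: dp = p(1-p) dlogit
      ratio <- ll_prop - ll +
        log(prop * (1 - prop)) - log(p * (1 - p))
      take <- log(stats::runif(I)) < ratio
      p[take] <<- prop[take]; ll[take] <<- ll_prop[take]
      acc["p"] <<- acc["p"] + sum(take); tot["p"] <<- tot["p"] + I

      # alpha random walk for included loci
      inc <- which(delta)
      if (length(inc) > 0) {
        prop_a <- alpha
        prop_a[inc] <- alpha[inc] + stats::rnorm(length(inc), 0, sd_a[inc])
        ll_prop <- ll_rows(p, prop_a, beta)
        ratio <- (ll_prop - ll) +
          stats::dnorm(prop_a, 0, sd_alpha_prior, log = TRUE) -
          stats::dnorm(alpha, 0, sd_alpha_prior, log = TRUE)
        take <- rep(FALSE, I)
        take[inc] <- log(stats::runif(length(inc))) < ratio[inc]
        alpha[take] <<- prop_a[take]; ll[take] <<- ll_prop[take]
        acc["alpha"] <<- acc["alpha"] + sum(take)
        tot["alpha"] <<- tot["alpha"] + length(inc)
      }

      # reversible jump: toggle each locus effect. Births draw alpha from
      # the moment-centred proposal q = N(mu_rj, sd_rj); the acceptance
      # ratio carries prior(alpha')/q(alpha') (and its inverse for deaths)
      # plus the prior inclusion odds
      prop_a <- alpha
      birth <- !delta
      prop_a[birth] <- stats::rnorm(sum(birth), mu_rj[birth], sd_rj)
      prop_a[!birth] <- 0
      ll_prop <- ll_rows(p, prop_a, beta)
      lp_prior <- stats::dnorm(prop_a, 0, sd_alpha_prior, log = TRUE)
      lp_q <- stats::dnorm(prop_a, mu_rj, sd_rj, log = TRUE)
      lp_prior_cur <- stats::dnorm(alpha, 0, sd_alpha_prior, log = TRUE)
      lp_q_cur <- stats::dnorm(alpha, mu_rj, sd_rj, log = TRUE)
      ratio <- ll_prop - ll +
        ifelse(birth,
               log_odds_incl + lp_prior - lp_q,
               -log_odds_incl - lp_prior_cur + lp_q_cur)
      take <- log(stats::runif(I)) < ratio
      delta[take] <<- !delta[take]
      alpha[take] <<- prop_a[take]; ll[take] <<- ll_prop[take]
      acc["rj"] <<- acc["rj"] + sum(take); tot["rj"] <<- tot["rj"] + I

      # beta random walks (one population at a time)
      for (j in seq_len(J)) {
        prop_b <- beta
        prop_b[j] <- beta[j] + stats::rnorm(1, 0, sd_b[j])
        ll_prop <- ll_rows(p, alpha, prop_b)
        ratio <- sum(ll_prop - ll) +
          stats::dnorm(prop_b[j], mean_beta_prior, sd_beta_prior,
                       log = TRUE) -
          stats::dnorm(beta[j], mean_beta_prior, sd_beta_prior, log = TRUE)
        if (log(stats::runif(1)) < ratio) {
          beta <<- prop_b; ll <<- ll_prop
          acc["beta"] <<- acc["beta"] + 1
        }
        tot["beta"] <<- tot["beta"] + 1
      }
    }

    # pilot runs: tune proposal widths toward ~0.3 acceptance
    for (pr in seq_len(pilot_runs)) {
      acc[] <- 0; tot[] <- 0
      for (it in seq_len(pilot_length)) sweep_once()
      rate <- acc / pmax(tot, 1)
      tune <- function(sd, r) pmin(pmax(sd * exp(r - 0.3), 1e-3), 5)
      sd_p <- tune(sd_p, rate["p"])
      sd_a <- tune(sd_a, rate["alpha"])
      sd_b <- tune(sd_b, rate["beta"])
    }

    acc[] <- 0; tot[] <- 0
    for (it in seq_len(burn_in)) sweep_once()
    rate <- acc / pmax(tot, 1)
    if (any(rate[c("p", "beta")] < 0.1 | rate[c("p", "beta")] > 0.6))
      warning("MCMC acceptance outside [0.1, 0.6] after pilots: ",
              paste(sprintf("%s=%.2f", names(rate), rate), collapse = " "))

    pip <- numeric(I); alpha_sum <- numeric(I); beta_sum <- numeric(J)
    for (s in seq_len(samples)) {
      for (it in seq_len(thin)) sweep_once()
      pip <- pip + delta
      alpha_sum <- alpha_sum + alpha
      beta_sum <- beta_sum + beta
    }
    pip <- pip / samples

    ord <- order(pip, decreasing = TRUE)
    qv <- numeric(I)
    qv[ord] <- cumsum(1 - pip[ord]) / seq_len(I)
    tab <- data.frame(snp = rownames(a) %||% as.character(which(keep)),
                      pip = pip, alpha = alpha_sum / samples, q = qv,
                      selected = qv < 0.05, stringsAsFactors = FALSE)
    list(table = tab, beta = beta_sum / samples,
         acceptance = acc / pmax(tot, 1), kept = which(keep))
  })
}

#' Storey q-values with a fixed lambda
#'
#' pi0 = min(1, #\{p > lambda\} / (m (1 - lambda))); q for the i-th ordered
#' p-value is min over j >= i of pi0 m p_(j) / j.
#'
#' @param p vector of p-values in [0, 1].
#' @param lambda tuning parameter (default 0.15).
#' @return list with \code{pi0}, \code{q} (in the input order),
#'   \code{lambda}.
#' @export
storey_qvalues <- function(p, lambda = 0.15) {
  if (length(p) == 0) stop("empty p-value list")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  list(pi0 = pi0, q = q, lambda = lambda)
}
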