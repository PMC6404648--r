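test_that("Tajima's D vanishes when k-bar equals S/a1 and matches formulas", {
  # toy: S = 2, k-bar = 4/3, a1 = 1.5 -> numerator 0
  vt <- build_variant_table(toy3_alignment())
  expect_equal(tajima_d(vt, reps = 0)$D, 0)
  expect_true(is.na(tajima_d_stat(5, 0, 0)))

  # straight-from-formula check on random SFS draws
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    xi <- sample(seq_len(n - 1), sample(2:15, 1), replace = TRUE)
    S <- length(xi)
    kbar <- sum(2 * xi * (n - xi)) / (n * (n - 1))
    a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    want <- (kbar - S / a1) /
      sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
    got <- pinepop:::tajima_d_from_xi(xi, n)
    if (abs(kbar - S / a1) < 1e-12) want <- 0
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Tajima p-values are calibrated and multilocus D reduces sanely", {
  # calibration: rejection rate at nominal 5% under the null
  set.seed(82)
  n <- 20
  null_cache <- new.env()
  pval <- function(S, D_obs, reps = 400) {
    key <- as.character(S)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- vapply(seq_len(reps), function(r)
        pinepop:::tajima_d_from_xi(
          pinepop:::simulate_sfs(n, "fixed_S", S = S), n), numeric(1))
    }
    null <- null_cache[[key]]
    (sum(null <= D_obs) + 1) / (length(null) + 1)
  }
  hits <- 0; total <- 1200
  for (r in seq_len(total)) {
    xi <- pinepop:::simulate_sfs(n, "fixed_theta", theta = 5)
    if (length(xi) == 0) next
    D <- pinepop:::tajima_d_from_xi(xi, n)
    if (pval(length(xi), D) <= 0.05) hits <- hits + 1
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)

  # multilocus: all-zero observed D against a symmetric null
  loci <- data.frame(n = 20, S = c(8, 12, 5, 9), D = 0)
  ml <- multilocus_tajima(loci, reps = 400, seed = 2)
  expect_gt(ml$p_neg, 0.2)
  expect_lt(ml$p_neg, 0.8)
  expect_error(multilocus_tajima(data.frame(n = 20, S = 0, D = NA)),
               "S = 0")

  # sweep-like genealogies push multilocus D negative
  set.seed(83)
  neg <- 0
  for (r in 1:15) {
    rows <- lapply(1:6, function(l) {
      g <- sweep_genealogy(20, f = 0.95)
      mut <- mutate_infinite_sites(g, "fixed_theta", theta = 5, L = 1e6,
                                   return_matrix = FALSE)
      data.frame(n = 20, S = length(mut$xi),
                 D = pinepop:::tajima_d_from_xi(mut$xi, 20))
    })
    ml <- multilocus_tajima(do.call(rbind, rows), reps = 150)
    if (ml$p_neg < 0.05) neg <- neg + 1
  }
  expect_gte(neg, 12)  # >= 80% of replicates significantly negative
})

test_that("Fay & Wu's H matches hand computation and identities", {
  vt <- polarize_variants(build_variant_table(toy3_alignment()),
                          rep("A", 10))
  fw <- fay_wu_h(vt, reps = 0)
  expect_equal(fw$H, 4 / 3 - 5 / 3, tolerance = 1e-12)

  # n = 2: theta_pi = theta_H at any configuration -> H = 0
  st <- pinepop:::fay_wu_stats(c(1, 1, 1), 2)
  expect_equal(st$H, 0, tolerance = 1e-12)

  # unpolarizable table: undefined flag
  vt_un <- build_variant_table(toy3_alignment())
  expect_true(is.na(fay_wu_h(vt_un, reps = 0)$H))

  # calibration under the neutral null (polarized by construction)
  set.seed(84)
  n <- 20
  cache <- new.env()
  hits <- 0; total <- 1200
  for (r in seq_len(total)) {
    xi <- pinepop:::simulate_sfs(n, "fixed_theta", theta = 5)
    if (length(xi) == 0) next
    Hn <- pinepop:::fay_wu_stats(xi, n)$H_norm
    if (is.na(Hn)) next
    key <- as.character(length(xi))
    if (is.null(cache[[key]])) {
      cache[[key]] <- vapply(1:400, function(j)
        pinepop:::fay_wu_stats(pinepop:::simulate_sfs(
          n, "fixed_S", S = length(xi)), n)$H_norm, numeric(1))
    }
    p <- (sum(cache[[key]] <= Hn, na.rm = TRUE) + 1) / (400 + 1)
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("Ewens-Watterson F and its conditional null behave correctly", {
  mk_hs <- function(counts) {
    n <- sum(counts)
    list(n = n, n_haplotypes = length(counts), freq = counts / n,
         F = sum((counts / n)^2))
  }
  expect_equal(mk_hs(c(3, 1))$F, 0.625)
  r <- ewens_watterson(mk_hs(c(3, 1)), reps = 300, seed = 5)
  expect_equal(r$F, 0.625)
  expect_false(r$degenerate)

  # k = 1: F = 1, degenerate
  r1 <- ewens_watterson(mk_hs(5), reps = 100, seed = 6)
  expect_equal(r1$F, 1)
  expect_true(r1$degenerate)
  expect_equal(r1$p_high, 101 / 101, tolerance = 0.01)

  # all-distinct: F at its minimum, p = 1 under homozygosity excess
  r2 <- ewens_watterson(mk_hs(rep(1, 3)), reps = 100, seed = 7)
  expect_equal(r2$F, 1 / 3, tolerance = 1e-12)
  expect_equal(r2$p_high, 1)

  # theta solved from E[k] is consistent: CRP draws at that theta have
  # mean haplotype count close to k
  theta <- pinepop:::solve_esf_theta(5, 20)
  set.seed(8)
  ks <- replicate(800, length(pinepop:::crp_draw(20, theta)))
  expect_lt(abs(mean(ks) - 5), 3 * sd(ks) / sqrt(800))
})

test_that("compound HEW/DHEW calibrates size and beats D alone on sweeps", {
  # trivial: components at p ~ 1 are never rejected
  obs_null <- list(D = 3, H_norm = 3, F = 0.05)
  r <- compound_hew_dhew(obs_null, n = 12, theta = 4, alpha = 0.05,
                         reps = 600, seed = 9)
  expect_false(r$hew)
  expect_false(r$dhew)
  expect_true(r$alpha_prime_dhew >= 0.05)  # per-component level is relaxed

  # empirical size at nominal 5%: fresh neutral draws against the
  # calibrated thresholds
  set.seed(91)
  n <- 16; theta <- 5
  null <- t(replicate(2500, pinepop:::simulate_dhf(n, "fixed_theta",
                                                   theta = theta)))
  null <- null[complete.cases(null), ]
  B <- nrow(null)
  p_of <- function(v, null_v, low = TRUE) {
    if (low) (rank(c(v))[1] * 0 + sum(null_v <= v) + 1) / (B + 1)
    else (sum(null_v >= v) + 1) / (B + 1)
  }
  # calibrate alpha' on half, evaluate on the other half
  idx <- sample(B); cal <- null[idx[1:(B %/% 2)], ]
  ev <- null[idx[(B %/% 2 + 1):B], ]
  Bc <- nrow(cal)
  pmat <- cbind(D = (rank(cal[, "D"], ties.method = "max")) / Bc,
                H = (rank(cal[, "H"], ties.method = "max")) / Bc,
                F = (Bc + 1 - rank(cal[, "F"], ties.method = "min")) / Bc)
  size_at <- function(a) mean(pmat[, "D"] <= a & pmat[, "H"] <= a &
                                pmat[, "F"] <= a)
  lo <- 0; hi <- 1
  for (i in 1:40) { mid <- (lo + hi) / 2
    if (size_at(mid) > 0.05) hi <- mid else lo <- mid }
  ap <- lo
  rej <- mean(apply(ev, 1, function(row) {
    pD <- (sum(cal[, "D"] <= row["D"]) + 1) / (Bc + 1)
    pH <- (sum(cal[, "H"] <= row["H"]) + 1) / (Bc + 1)
    pF <- (sum(cal[, "F"] >= row["F"]) + 1) / (Bc + 1)
    pD <= ap && pH <= ap && pF <= ap
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.075)

  # sweep-mimicking data: DHEW rejects where it should
  set.seed(92)
  sweep_obs <- function() {
    g <- sweep_genealogy(16, f = 0.9)
    mut <- mutate_infinite_sites(g, "fixed_theta", theta = 5, L = 1e6,
                                 return_matrix = FALSE)
    xi <- mut$xi
    prof <- vapply(1:16, function(i) paste(
      vapply(mut$carriers, function(cs) i %in% cs, logical(1)),
      collapse = ""), character(1))
    cfg <- table(prof)
    list(D = pinepop:::tajima_d_from_xi(xi, 16),
         H_norm = pinepop:::fay_wu_stats(xi, 16)$H_norm,
         F = sum((as.numeric(cfg) / 16)^2), S = length(xi))
  }
  hits <- 0
  for (r in 1:12) {
    ob <- sweep_obs()
    if (is.na(ob$D) || is.na(ob$H_norm)) next
    cc <- compound_hew_dhew(ob, n = 16, theta = 5, reps = 800,
                            seed = 100 + r)
    if (cc$dhew || cc$hew) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("HKA estimation matches a brute-force grid minimization", {
  # perfect symmetry: two identical loci fit exactly
  loci <- data.frame(locus_id = c("a", "b"), S = c(10, 10), D = c(20, 20),
                     n = 10)
  r <- hka_test(loci)
  expect_equal(r$theta[1], r$theta[2], tolerance = 1e-6)
  expect_lt(r$X2, 1e-8)
  expect_equal(r$df, 1)

  # random 5-locus instance vs nested grid search
  set.seed(93)
  loci5 <- data.frame(locus_id = paste0("l", 1:5),
                      S = c(12, 4, 9, 20, 6), D = c(18, 9, 14, 30, 12),
                      n = c(12, 12, 12, 12, 12))
  r5 <- hka_test(loci5)
  a <- sum(1 / 1:11); b <- sum(1 / (1:11)^2)
  x2 <- function(T, th) {
    sum(sapply(1:5, function(i) {
      ES <- th[i] * a; VS <- ES + th[i]^2 * b
      ED <- th[i] * (T + 1); VD <- ED + th[i]^2
      (loci5$S[i] - ES)^2 / VS + (loci5$D[i] - ED)^2 / VD
    }))
  }
  # coarse-to-fine grid on T with a nested per-locus theta grid
  theta_at <- function(T, gr) {
    sapply(1:5, function(i) {
      gr[which.min(sapply(gr, function(t0) {
        ES <- t0 * a; VS <- ES + t0^2 * b
        ED <- t0 * (T + 1); VD <- ED + t0^2
        (loci5$S[i] - ES)^2 / VS + (loci5$D[i] - ED)^2 / VD
      }))]
    })
  }
  search <- function(Ts, gr) {
    best <- Inf; bestT <- NA
    for (T in Ts) {
      v <- x2(T, theta_at(T, gr))
      if (v < best) { best <- v; bestT <- T }
    }
    list(X2 = best, T = bestT)
  }
  coarse <- search(seq(0.2, 6, by = 0.05), seq(0.5, 40, by = 0.1))
  fine <- search(seq(coarse$T - 0.1, coarse$T + 0.1, by = 0.002),
                 seq(0.5, 40, by = 0.005))
  expect_equal(r5$X2, fine$X2, tolerance = 1e-4)
  expect_equal(r5$T, fine$T, tolerance = 0.01)
  expect_true(r5$p >= 0 && r5$p <= 1)

  # S = 0, D = 0 loci are dropped with a warning; < 2 loci errors
  expect_warning(hka_test(data.frame(locus_id = c("a", "b", "c"),
                                     S = c(5, 0, 7), D = c(9, 0, 11),
                                     n = 8)), "dropping")
  expect_error(suppressWarnings(
    hka_test(data.frame(locus_id = c("a", "b"), S = c(5, 0),
                        D = c(9, 0), n = 8))), "at least 2")
})
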