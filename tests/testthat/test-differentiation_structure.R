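test_that("AMOVA components match the sums-of-squares oracle", {
  # hand-checkable 3-level toy: 6 samples, 2 groups, 4 populations
  d <- matrix(0, 6, 6)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 2; d[2, 3] <- d[3, 2] <- 1
  d[4, 5] <- d[5, 4] <- 1; d[4, 6] <- d[6, 4] <- 3; d[5, 6] <- d[6, 5] <- 2
  d[1:3, 4:6] <- 5; d[4:6, 1:3] <- 5
  pop <- c("p1", "p1", "p2", "p3", "p3", "p4")
  grp <- c("g1", "g1", "g1", "g2", "g2", "g2")
  res <- amova(d, pop, grp, perms = 0)
  # hand-worked sums of squares
  ss_tot <- sum(d) / 12
  ss_wp <- (2 * 1) / (2 * 2) + 0 + (2 * 1) / (2 * 2) + 0
  ss_wg <- (2 * (1 + 2 + 1)) / 6 + (2 * (1 + 3 + 2)) / 6
  expect_equal(unname(res$ss["within_pop"]), ss_wp, tolerance = 1e-12)
  expect_equal(unname(res$ss["among_group"]), ss_tot - ss_wg,
               tolerance = 1e-12)
  expect_equal(sum(res$pct), 100, tolerance = 1e-9)

  # two-level vs independent brute-force implementation on random instances
  set.seed(61)
  for (rep in 1:6) {
    n <- 18
    geno <- matrix(sample(c("A", "T"), n * 30, TRUE), n)
    dd <- pairwise_diff_matrix(geno)
    pop <- sample(rep(c("a", "b", "c"), each = 6))
    got <- amova(dd, pop, perms = 0)
    want <- bf_amova2(dd, pop)
    expect_equal(unname(got$sigma), unname(want$sigma), tolerance = 1e-10)
    expect_equal(unname(got$phi["phi_st"]), unname(want$phi_st),
                 tolerance = 1e-10)
  }

  # fixed difference, no within variation: Phi_ST = 1
  d2 <- matrix(3, 8, 8); d2[1:4, 1:4] <- 0; d2[5:8, 5:8] <- 0
  res2 <- amova(d2, rep(c("x", "y"), each = 4), perms = 0)
  expect_equal(unname(res2$phi["phi_st"]), 1)
})

test_that("AMOVA permutation p-values are calibrated under the null", {
  set.seed(62)
  ps <- replicate(60, {
    geno <- matrix(sample(c("A", "T"), 16 * 20, TRUE), 16)
    dd <- pairwise_diff_matrix(geno)
    amova(dd, rep(c("a", "b"), each = 8), perms = 60)$p["phi_st"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("pairwise F_ST detects fixed differences and null identity", {
  geno <- rbind(matrix("A", 5, 10), matrix("T", 5, 10))
  rownames(geno) <- paste0("s", 1:10)
  d <- pairwise_diff_matrix(geno)
  lab <- rep(c("g1", "g2"), each = 5)
  pf <- pairwise_fst(d, lab, perms = 50, seed = 2)
  expect_equal(pf$fst["g1", "g2"], 1)
  expect_lt(pf$p["g1", "g2"], 0.05)

  # identical allele frequencies: F_ST near zero
  set.seed(63)
  geno2 <- matrix(sample(c("A", "T"), 20 * 40, TRUE), 20)
  d2 <- pairwise_diff_matrix(geno2)
  pf2 <- pairwise_fst(d2, rep(c("g1", "g2"), each = 10), perms = 50,
                      seed = 3)
  expect_lt(abs(pf2$fst["g1", "g2"]), 0.1)
  expect_error(pairwise_fst(d2, rep("g1", 20)), "2 distinct")
})

test_that("per-SNP F_ST equals the variance-partition hand computation", {
  # counts deme1: 6A/4a, deme2: 2A/8a
  x <- c(rep("A", 6), rep("T", 4), rep("A", 2), rep("T", 8))
  pops <- rep(c("d1", "d2"), each = 10)
  geno <- matrix(x, ncol = 1, dimnames = list(paste0("s", 1:20), "0"))
  res <- per_site_fst(geno, pops)
  # hand-worked: SS_total = 8*12/20, SS_within = 6*4/10 + 2*8/10
  sst <- 8 * 12 / 20; ssw <- 24 / 10 + 16 / 10
  msa <- (sst - ssw) / 1; msw <- ssw / 18
  sb <- (msa - msw) / 10
  expect_equal(res$fst, sb / (sb + msw), tolerance = 1e-12)
  expect_equal(res$he, 1 - (0.4^2 + 0.6^2), tolerance = 1e-12)

  # agreement with the distance-matrix AMOVA route
  d <- pairwise_diff_matrix(geno)
  expect_equal(res$fst, unname(amova(d, pops, perms = 0)$phi["phi_st"]),
               tolerance = 1e-12)

  # frequencies 1 vs 0 across demes
  g1 <- matrix(c(rep("A", 6), rep("C", 6)), ncol = 1,
               dimnames = list(paste0("s", 1:12), "0"))
  expect_equal(per_site_fst(g1, rep(c("d1", "d2"), each = 6))$fst, 1)

  # equal frequencies in both demes: no positive differentiation signal
  # (the variance-partition estimator is biased to about -1/(n_bar - 1)
  # under identical frequencies)
  g2 <- matrix(rep(c("A", "C"), 10), ncol = 1,
               dimnames = list(paste0("s", 1:20), "0"))
  f_eq <- per_site_fst(g2, rep(c("d1", "d2"), each = 10))$fst
  expect_lte(f_eq, 0)
  expect_gt(f_eq, -0.15)
})

test_that("S_nn matches hand enumeration with tie splitting", {
  # disjoint groups: S_nn = 1
  d <- matrix(5, 10, 10); d[1:5, 1:5] <- 1; d[6:10, 6:10] <- 1; diag(d) <- 0
  lab <- rep(c("a", "b"), each = 5)
  r <- snn(d, lab, perms = 200, seed = 4)
  expect_equal(r$snn, 1)
  expect_lt(r$p, 0.05)

  # 4-sample worked case with a tie: sample 1 ties between 2 (same) and
  # 3 (other); samples 2,3,4 have unique nearest neighbours
  d4 <- matrix(c(0, 1, 1, 4,
                 1, 0, 2, 4,
                 1, 2, 0, 3,
                 4, 4, 3, 0), 4, 4, byrow = TRUE)
  lab4 <- c("a", "a", "b", "b")
  # x1 = 1/2 (tie split), x2 = 1 (nn=1 same), x3 = 1/2? nn of 3 is 1 (d=1)
  # -> different label -> 0; x4: nn is 3 (d=3) same label -> 1
  expect_equal(snn(d4, lab4, perms = 0)$snn, mean(c(0.5, 1, 0, 1)))
  expect_equal(snn(d4, lab4, perms = 0)$snn, bf_snn(d4, lab4))

  # random labels: expectation near group-share baseline
  set.seed(65)
  vals <- replicate(200, {
    dd <- matrix(runif(64), 8, 8); dd <- dd + t(dd); diag(dd) <- 0
    snn(dd, sample(rep(c("a", "b"), each = 4)), perms = 0)$snn
  })
  expect_lt(abs(mean(vals) - 3 / 7), 0.03)

  # invariance under monotone distance transforms
  dd <- matrix(runif(36), 6, 6); dd <- dd + t(dd); diag(dd) <- 0
  lab6 <- rep(c("a", "b"), 3)
  expect_equal(snn(dd, lab6, perms = 0)$snn,
               snn(dd^2, lab6, perms = 0)$snn)
  expect_equal(snn(dd, lab6, perms = 0)$snn,
               snn(log(dd + 1), lab6, perms = 0)$snn)
})

test_that("PCoA reconstructs Euclidean configurations", {
  # collinear points 0, 1, 3
  d <- as.matrix(dist(c(0, 1, 3)))
  p <- pcoa(d)
  expect_equal(unname(sort(abs(diff(sort(p$coords[, 1]))))), c(1, 2),
               tolerance = 1e-8)
  expect_lt(ncol(p$coords), 3)  # axis 2 carries ~ no variance

  # equidistant simplex: equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  p3 <- pcoa(d3)
  pos <- p3$eig[p3$eig > 1e-9]
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-10)

  # 2-D configuration: distances reproduced by the first two axes
  set.seed(66)
  xy <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(xy))
  p2 <- pcoa(d2)
  rec <- as.matrix(dist(p2$coords[, 1:2]))
  expect_equal(rec, d2, tolerance = 1e-8)
  # matches cmdscale as an independent reference
  cs <- stats::cmdscale(d2, k = 2, eig = TRUE)
  expect_equal(abs(p2$coords[, 1]), abs(cs$points[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("the haplotype network keeps exactly the co-minimal MST edges", {
  # chain: unique MST
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = rep(list(c("A", "B", "C")), 2))
  net <- haplotype_mst(d)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "B C"))

  # equal all-pairs distances: all three edges co-minimal
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  expect_equal(nrow(haplotype_mst(d3)$edges), 3)

  # MST weight equals exhaustive spanning-tree minimum (6 haplotypes)
  set.seed(67)
  for (rep in 1:3) {
    dd <- matrix(sample(1:9, 36, TRUE), 6, 6)
    dd <- dd + t(dd); diag(dd) <- 0
    expect_equal(haplotype_mst(dd)$mst_weight, bf_mst_weight(dd))
  }
  # and igraph agrees on a larger instance
  dd <- matrix(sample(1:15, 64, TRUE), 8, 8); dd <- dd + t(dd); diag(dd) <- 0
  g <- igraph::graph_from_adjacency_matrix(dd, mode = "undirected",
                                           weighted = TRUE)
  w_igraph <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(haplotype_mst(dd)$mst_weight, w_igraph)
})
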