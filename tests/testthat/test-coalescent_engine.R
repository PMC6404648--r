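test_that("genealogy expectations match coalescent theory", {
  set.seed(101)
  # E[TMRCA] = 1 - 1/n in 4N units; checked at n = 2 and n = 10
  t2 <- replicate(8000, tmrca(simulate_genealogy(2)))
  expect_lt(abs(mean(t2) - 0.5), 3 * sd(t2) / sqrt(length(t2)))
  t10 <- replicate(4000, tmrca(simulate_genealogy(10)))
  expect_lt(abs(mean(t10) - 0.9), 3 * sd(t10) / sqrt(length(t10)))
  # E[total length] = a_{n-1}
  l10 <- replicate(4000, total_length(simulate_genealogy(10)))
  expect_lt(abs(mean(l10) - sum(1 / 1:9)), 3 * sd(l10) / sqrt(length(l10)))
})

test_that("identical seeds reproduce identical trees and mutations", {
  g1 <- simulate_genealogy(12, seed = 99)
  g2 <- simulate_genealogy(12, seed = 99)
  expect_identical(g1, g2)
  m1 <- mutate_infinite_sites(g1, "fixed_theta", theta = 4, L = 500,
                              seed = 5)
  m2 <- mutate_infinite_sites(g2, "fixed_theta", theta = 4, L = 500,
                              seed = 5)
  expect_identical(m1$matrix, m2$matrix)
  nwk <- genealogy_newick(g1)
  expect_match(nwk, ";$")
  # newick re-parses with the right tip count and ultrametric depths
  tr <- ape::read.tree(text = nwk)
  expect_equal(length(tr$tip.label), 12)
  depths <- ape::node.depth.edgelength(tr)[1:12]
  expect_lt(max(depths) - min(depths), 1e-5)
})

test_that("infinite-sites mutation respects conditioning", {
  set.seed(55)
  # E[S] = theta a_{n-1} at theta=5, n=10
  S <- replicate(6000, length(pinepop:::simulate_sfs(10, "fixed_theta",
                                                     theta = 5)))
  expect_lt(abs(mean(S) - 5 * sum(1 / 1:9)), 3 * sd(S) / sqrt(length(S)))
  # E[pi x L] = theta
  pis <- replicate(4000, {
    xi <- pinepop:::simulate_sfs(10, "fixed_theta", theta = 5)
    sum(2 * xi * (10 - xi)) / (10 * 9)
  })
  expect_lt(abs(mean(pis) - 5), 3 * sd(pis) / sqrt(length(pis)))
  # fixed-S holds S exactly
  g <- simulate_genealogy(8, seed = 3)
  expect_equal(length(mutate_infinite_sites(g, "fixed_S", S = 7,
                                            L = 100)$positions), 7)
  expect_equal(length(mutate_infinite_sites(g, "fixed_S", S = 0,
                                            L = 100)$positions), 0)
  expect_error(mutate_infinite_sites(g, "fixed_S", S = 200, L = 100),
               "infinite-sites")
})

test_that("Tajima's D is centred near zero under the neutral null", {
  set.seed(77)
  D <- replicate(2000, pinepop:::tajima_d_from_xi(
    pinepop:::simulate_sfs(20, "fixed_theta", theta = 5), 20))
  D <- D[!is.na(D)]
  expect_gt(mean(D), -0.1)
  expect_lt(mean(D), 0.1)
})

test_that("island model limits behave correctly", {
  # huge migration ~ panmixia: mean F_ST near 0
  set.seed(202)
  fst <- replicate(200, {
    snp <- pinepop:::island_snp(4, 1000, c(6, 6, 6, 6))
    pinepop:::fst_binary(snp$x, snp$pop)
  })
  expect_lt(mean(fst), 0.01 + 2 * sd(fst) / sqrt(200))

  # single-deme sampling: S distribution ~ panmictic with same theta
  set.seed(203)
  S_island <- replicate(1500, length(simulate_island(
    2, 10, c(8, 0), theta = 4, L = 500)$positions))
  S_pan <- replicate(1500, length(pinepop:::simulate_sfs(
    8, "fixed_theta", theta = 4)))
  expect_gt(suppressWarnings(ks.test(S_island, S_pan)$p.value), 0.01)

  expect_error(simulate_island(3, 0, c(4, 4, 4), theta = 1), "M > 0")
})

test_that("migration calibration reaches a target F_ST", {
  M <- calibrate_island_m(0.1, d = 8, samples_per_deme = rep(6, 8),
                          reps = 250, seed = 11)
  set.seed(12)
  achieved <- mean(pinepop:::island_fst_cloud(8, M, rep(6, 8), 400)$fst)
  expect_lt(abs(achieved - 0.1), 0.02)
})

test_that("split model spans the shared-ancestry to fixed-difference range", {
  set.seed(303)
  splits <- function(T) data.frame(time = T, from = 2, to = 1)
  share_frac <- function(T, theta = 10, L = 4000, reps = 60, ns = 8) {
    counts <- replicate(reps, {
      sim <- simulate_split(splits(T), theta = theta,
                            samples_per_pop = c(ns, ns), L = L)
      if (length(sim$positions) == 0) return(c(0, 0))
      xi1 <- colSums(sim$matrix[sim$pop == 1, sim$positions + 1,
                                drop = FALSE] == "T")
      xi2 <- colSums(sim$matrix[sim$pop == 2, sim$positions + 1,
                                drop = FALSE] == "T")
      poly1 <- xi1 > 0 & xi1 < ns
      poly2 <- xi2 > 0 & xi2 < ns
      c(sum(poly1 & poly2), sum(poly1 | poly2))
    })
    sum(counts[1, ]) / sum(counts[2, ])
  }
  # deep split: essentially no shared polymorphism
  expect_lt(share_frac(100, theta = 2, L = 6000), 0.01)
  # recent split: ancestral polymorphism dominates
  expect_gt(share_frac(0.01, ns = 15), 0.5)

  # single-tip sampling marginalizes to the panmictic S distribution
  set.seed(304)
  S_split <- replicate(1200, length(simulate_split(
    splits(0.5), theta = 4, samples_per_pop = c(8, 0), L = 500)$positions))
  S_pan <- replicate(1200, length(pinepop:::simulate_sfs(
    8, "fixed_theta", theta = 4)))
  expect_gt(suppressWarnings(ks.test(S_split, S_pan)$p.value), 0.01)
})

test_that("the ancestral recombination graph behaves at its limits", {
  # rho = 0: single genealogy, no recombination events
  r0 <- simulate_with_recombination(8, theta = 5, rho = 0, L = 300,
                                    seed = 17)
  expect_equal(r0$n_recomb, 0)
  # reseeded runs identical
  r0b <- simulate_with_recombination(8, theta = 5, rho = 0, L = 300,
                                     seed = 17)
  expect_identical(r0$matrix, r0b$matrix)
  expect_error(simulate_with_recombination(40, 5, 0.01, 100), "guard")
  expect_error(simulate_with_recombination(10, 5, 1, 100), "guard")

  # high rho: r2 decays with distance (near pairs vs far pairs)
  set.seed(404)
  near <- c(); far <- c()
  for (rep in 1:40) {
    sim <- simulate_with_recombination(12, theta = 10, rho = 0.1, L = 400)
    aln <- locus_alignment(paste0("arg", rep), sim$matrix)
    pr <- pairwise_r2(build_variant_table(aln))
    if (nrow(pr) == 0) next
    near <- c(near, pr$r2[pr$dist <= 50])
    far <- c(far, pr$r2[pr$dist >= 200])
  }
  expect_gt(mean(near), mean(far))
})
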