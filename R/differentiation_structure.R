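# Permutation-based differentiation and structure: hierarchical AMOVA with
# Phi-statistics, pairwise and per-SNP F_ST, Hudson's S_nn, PCoA, and the
# haplotype minimum spanning network.

# Sum of squared distances machinery (Excoffier-style AMOVA). `d2` is the
# matrix of squared inter-haplotype distances; with pairwise difference
# counts as input the counts themselves play the role of squared distances
# (the Arlequin convention).
.ss_within <- function(d2, members) {
  if (length(members) < 2) return(0)
  sum(d2[members, members]) / (2 * length(members))
}

amova_components <- function(d2, pop, grp = NULL) {
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- sum(vapply(pops, function(p) .ss_within(d2, which(pop == p)),
                      numeric(1)))
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  if (is.null(grp)) {
    df_ap <- P - 1; df_wp <- N - P
    ss_ap <- ss_total - ss_wp
    ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / max(df_wp, 1)
    n_prime <- (N - sum(n_p^2) / N) / df_ap
    sigma_c <- ms_wp
    sigma_b <- (ms_ap - ms_wp) / n_prime
    tot <- sigma_b + sigma_c
    return(list(sigma = c(among_pop = sigma_b, within_pop = sigma_c),
                phi = c(phi_st = if (tot > 0) sigma_b / tot else 0),
                ss = c(among_pop = ss_ap, within_pop = ss_wp),
                df = c(df_ap, df_wp)))
  }
  grp_of_pop <- vapply(pops, function(p) grp[which(pop == p)[1]],
                       grp[1])
  groups <- unique(grp_of_pop)
  G <- length(groups)
  N_g <- vapply(groups, function(g) sum(grp == g), numeric(1))
  ss_wg <- sum(vapply(groups, function(g) .ss_within(d2, which(grp == g)),
                      numeric(1)))
  ss_ag <- ss_total - ss_wg
  ss_ap_wg <- ss_wg - ss_wp
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ms_ag <- ss_ag / df_ag
  ms_ap <- ss_ap_wg / max(df_ap, 1)
  ms_wp <- ss_wp / max(df_wp, 1)
  sum_np2_over_Ng <- sum(vapply(groups, function(g) {
    idx <- grp_of_pop == g
    sum(n_p[idx]^2) / sum(n_p[idx])
  }, numeric(1)))
  n1 <- (N - sum_np2_over_Ng) / max(df_ap, 1)
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sigma_c <- ms_wp
  sigma_b <- (ms_ap - sigma_c) / n1
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma = c(among_group = sigma_a, among_pop_within_group = sigma_b,
                 within_pop = sigma_c),
       phi = c(phi_st = if (tot > 0) (sigma_a + sigma_b) / tot else 0,
               phi_sc = if (sigma_b + sigma_c > 0)
                 sigma_b / (sigma_b + sigma_c) else 0,
               phi_ct = if (tot > 0) sigma_a / tot else 0),
       ss = c(among_group = ss_ag, among_pop_within_group = ss_ap_wg,
              within_pop = ss_wp),
       df = c(df_ag, df_ap, df_wp))
}

#' Analysis of molecular variance with permutation tests
#'
#' Excoffier-style variance components from squared-distance sums (pairwise
#' difference counts serve directly as squared distances). Permutation
#' schemes follow the standard conventions: Phi_ST permutes haplotypes among
#' populations, Phi_SC permutes haplotypes among populations within groups,
#' Phi_CT permutes whole populations among groups. Permutation p-values use
#' the (b+1)/(B+1) estimator.
#'
#' @param d symmetric matrix of pairwise difference counts (zero diagonal).
#' @param populations population label per sample.
#' @param groups optional higher-level group label per sample (consistent
#'   with populations).
#' @param perms permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{sigma} (variance components), \code{pct}
#'   (percent of total), \code{phi}, \code{p} (permutation p per Phi),
#'   \code{perms}.
#' @export
amova <- function(d, populations, groups = NULL, perms = 1000, seed = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  populations <- as.character(populations)
  if (!is.null(groups)) groups <- as.character(groups)
  obs <- amova_components(d, populations, groups)
  singl <- table(populations)
  if (any(singl == 1))
    warning("population(s) with a single sample: ",
            paste(names(singl)[singl == 1], collapse = ", "))
  p <- rep(NA_real_, length(obs$phi))
  names(p) <- names(obs$phi)
  if (perms > 0) {
    counts <- stats::setNames(rep(0L, length(obs$phi)), names(obs$phi))
    with_seed(seed, {
      for (b in seq_len(perms)) {
        # phi_st: haplotypes among populations (ignores groups)
        perm_all <- sample(populations)
        st <- amova_components(d, perm_all, NULL)$phi["phi_st"]
        if (st >= obs$phi["phi_st"] - 1e-12)
          counts["phi_st"] <- counts["phi_st"] + 1L
        if (!is.null(groups)) {
          # phi_sc: haplotypes among populations within their group
          perm_pop <- populations
          for (g in unique(groups)) {
            idx <- which(groups == g)
            perm_pop[idx] <- sample(populations[idx])
          }
          sc <- amova_components(d, perm_pop, groups)$phi["phi_sc"]
          if (sc >= obs$phi["phi_sc"] - 1e-12)
            counts["phi_sc"] <- counts["phi_sc"] + 1L
          # phi_ct: whole populations among groups
          pops <- unique(populations)
          gp <- vapply(pops, function(pp)
            groups[which(populations == pp)[1]], character(1))
          gp_perm <- stats::setNames(sample(gp), pops)
          ct <- amova_components(d, populations,
                                 unname(gp_perm[populations]))$phi["phi_ct"]
          if (ct >= obs$phi["phi_ct"] - 1e-12)
            counts["phi_ct"] <- counts["phi_ct"] + 1L
        }
      }
    })
    p <- perm_pvalue(counts, perms)
  }
  list(sigma = obs$sigma, pct = 100 * obs$sigma / sum(obs$sigma),
       phi = obs$phi, ss = obs$ss, df = obs$df, p = p, perms = perms)
}

#' Pairwise Phi_ST-type F_ST between groups
#'
#' Each pair of groups gets a two-level AMOVA on the corresponding submatrix
#' with a permutation p-value.
#'
#' @param d symmetric pairwise-difference matrix over all samples.
#' @param labels group label per sample.
#' @param perms permutations per pair (default 1000).
#' @param seed RNG seed.
#' @return list with \code{fst} (symmetric matrix), \code{p} (permutation
#'   p-values), \code{groups}.
#' @export
pairwise_fst <- function(d, labels, perms = 1000, seed = NULL) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 distinct group labels")
  k <- length(groups)
  fst <- matrix(0, k, k, dimnames = list(groups, groups))
  pm <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  seeds <- derive_seeds(seed %||% sample.int(2^30, 1), k * k)
  s <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    s <- s + 1
    idx <- labels %in% c(groups[i], groups[j])
    sub <- d[idx, idx]
    lab <- labels[idx]
    res <- amova(sub, lab, perms = perms, seed = seeds[s])
    fst[i, j] <- fst[j, i] <- unname(res$phi["phi_st"])
    pm[i, j] <- pm[j, i] <- unname(res$p["phi_st"])
  }
  list(fst = fst, p = pm, groups = groups, perms = perms)
}

#' Per-SNP variance-partition F_ST and heterozygosity
#'
#' Each biallelic SNP (multiallelic sites are reduced to major allele vs the
#' rest and flagged) gets the same two-level variance-partition F_ST used by
#' \code{\link{amova}}, computed on 0/1 mismatch distances, plus its pooled
#' expected heterozygosity.
#'
#' @param geno character matrix samples x SNP columns (column names are
#'   positions).
#' @param pops population label per sample (row order).
#' @return data.frame with columns \code{site}, \code{fst}, \code{he},
#'   \code{maf}, \code{n_called}, \code{reduced} (multiallelic flag).
#' @export
per_site_fst <- function(geno, pops) {
  pops <- as.character(pops)
  rows <- lapply(seq_len(ncol(geno)), function(j) {
    col <- geno[, j]
    ok <- col %in% .BASES
    if (sum(ok) < 2) return(NULL)
    x <- col[ok]; pp <- pops[ok]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) < 2) return(NULL)
    reduced <- length(tab) > 2
    bin <- as.integer(x == names(tab)[1])   # major vs rest
    if (length(unique(pp)) < 2) return(NULL)
    d <- outer(bin, bin, FUN = function(a, b) as.numeric(a != b))
    diag(d) <- 0
    comp <- amova_components(d, pp)
    freq <- mean(bin)
    data.frame(site = colnames(geno)[j],
               fst = unname(comp$phi["phi_st"]),
               he = 1 - sum((as.numeric(tab) / sum(tab))^2),
               maf = min(freq, 1 - freq),
               n_called = sum(ok), reduced = reduced,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = character(0), fst = numeric(0),
                      he = numeric(0), maf = numeric(0),
                      n_called = integer(0), reduced = logical(0))
  rownames(out) <- NULL
  out
}

#' Hudson's nearest-neighbour statistic S_nn
#'
#' For each sample, the fraction of its nearest neighbours (minimum
#' distance; ties split equally) sharing its label, averaged over samples.
#' Significance by label permutation, p = Pr(S_nn_perm >= observed).
#'
#' @param d symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, >= 2 samples each).
#' @param perms permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{snn}, \code{p}, \code{perms}.
#' @export
snn <- function(d, labels, perms = 1000, seed = NULL) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 groups")
  n <- nrow(d)
  nn_sets <- lapply(seq_len(n), function(i) {
    di <- d[i, -i]
    idx <- seq_len(n)[-i]
    idx[di <= min(di) + 1e-12]
  })
  stat <- function(lab) {
    mean(vapply(seq_len(n), function(i)
      mean(lab[nn_sets[[i]]] == lab[i]), numeric(1)))
  }
  obs <- stat(labels)
  p <- NA_real_
  if (perms > 0) {
    null <- with_seed(seed, {
      vapply(seq_len(perms), function(b) stat(sample(labels)), numeric(1))
    })
    p <- perm_pvalue(sum(null >= obs - 1e-12), perms)
  }
  list(snn = obs, p = p, perms = perms)
}

#' Principal coordinate analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of the eigenvalue,
#' percent variance is relative to the sum of positive eigenvalues; negative
#' eigenvalues are reported and dropped.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return list with \code{coords} (samples x axes), \code{eig} (all
#'   eigenvalues), \code{pct_variance} (per retained axis),
#'   \code{n_negative}.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("PCoA input must be symmetric")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  list(coords = coords, eig = e$values,
       pct_variance = 100 * e$values[pos] / sum(e$values[pos]),
       n_negative = sum(e$values < -1e-9 * max(abs(e$values))))
}

# union-find for the spanning-network construction
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Haplotype minimum spanning network
#'
#' The minimum spanning tree plus every co-minimal alternative edge: an edge
#' belongs to the network iff its endpoints are not yet connected using only
#' strictly shorter edges (i.e. it lies in at least one minimum spanning
#' tree).
#'
#' @param d symmetric matrix of pairwise differences between distinct
#'   haplotypes.
#' @param freq optional matrix (haplotypes x groups) of frequencies used to
#'   annotate nodes.
#' @return list with \code{edges} (data.frame from, to, weight,
#'   \code{in_mst}), \code{mst_weight}, \code{node_freq}.
#' @export
haplotype_mst <- function(d, freq = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 haplotypes")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  # Kruskal for the MST weight and membership
  parent <- seq_len(n)
  in_mst <- logical(length(w))
  for (e in seq_along(w)) {
    ra <- .uf_find(parent, pairs[e, 1]); rb <- .uf_find(parent, pairs[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      in_mst[e] <- TRUE
    }
  }
  # network edge: endpoints unconnected using strictly shorter edges
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    parent <- seq_len(n)
    shorter <- which(w < w[e] - 1e-12)
    for (f in shorter) {
      ra <- .uf_find(parent, pairs[f, 1]); rb <- .uf_find(parent, pairs[f, 2])
      if (ra != rb) parent[ra] <- rb
    }
    keep[e] <- .uf_find(parent, pairs[e, 1]) != .uf_find(parent, pairs[e, 2])
  }
  nm <- rownames(d) %||% as.character(seq_len(n))
  edges <- data.frame(from = nm[pairs[keep, 1]], to = nm[pairs[keep, 2]],
                      weight = w[keep], in_mst = in_mst[keep],
                      stringsAsFactors = FALSE)
  list(edges = edges, mst_weight = sum(w[in_mst]), node_freq = freq)
}
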