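# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written straight from definitions (exhaustive enumeration,
# direct formulas) and never call the implementation paths they check.

BASES <- c("A", "C", "G", "T")

toy3_alignment <- function() {
  m <- rbind(s1 = strsplit("AAAAAAAAAA", "")[[1]],
             s2 = strsplit("AAAAAAAAAT", "")[[1]],
             s3 = strsplit("AAAAAAAATT", "")[[1]])
  locus_alignment("toy3", m)
}

random_alignment <- function(n, L, seed, miss = 0.02,
                             prob = c(0.7, 0.1, 0.1, 0.1)) {
  set.seed(seed)
  m <- matrix(sample(BASES, n * L, TRUE, prob = prob), n, L)
  if (miss > 0) m[runif(n * L) < miss] <- "N"
  rownames(m) <- paste0("s", seq_len(n))
  locus_alignment(paste0("rand", seed), m)
}

# mean pairwise differences per site, exhaustive pair loop
bf_pi <- function(m, L) {
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% BASES & m[j, ] %in% BASES
    tot <- tot + sum(m[i, ok] != m[j, ok])
  }
  tot / (n * (n - 1) / 2) / L
}

# segregating-site recount straight from columns (SNPs only)
bf_S <- function(m) {
  sum(apply(m, 2, function(col) {
    b <- col[col %in% BASES]
    length(unique(b)) >= 2
  }))
}

bf_singletons <- function(m) {
  sum(apply(m, 2, function(col) {
    b <- col[col %in% BASES]
    tab <- table(b)
    length(tab) >= 2 && min(tab) == 1
  }))
}

bf_hd <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# r2 by direct covariance of 0/1 indicators
bf_r2 <- function(x, y) {
  stats::cov(x, y, use = "complete.obs")^2 * (length(x) - 1)^2 /
    length(x)^2 / (var(x) * (length(x) - 1) / length(x)) /
    (var(y) * (length(y) - 1) / length(y))
}

# mean between-group difference per site, exhaustive
bf_dxy <- function(m, g1, g2, L) {
  tot <- 0; np <- 0
  for (a in g1) for (b in g2) {
    ok <- m[a, ] %in% BASES & m[b, ] %in% BASES
    tot <- tot + sum(m[a, ok] != m[b, ok])
    np <- np + 1
  }
  tot / np / L
}

# two-level AMOVA variance components straight from the sums-of-squares
# definitions (independent of amova_components)
bf_amova2 <- function(d, pop) {
  N <- nrow(d)
  pops <- unique(pop)
  ss_tot <- sum(d) / (2 * N)
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    if (length(idx) > 1) ss_wp <- ss_wp + sum(d[idx, idx]) / (2 * length(idx))
  }
  P <- length(pops)
  msw <- ss_wp / (N - P)
  msa <- (ss_tot - ss_wp) / (P - 1)
  n_p <- sapply(pops, function(p) sum(pop == p))
  nc <- (N - sum(n_p^2) / N) / (P - 1)
  sb <- (msa - msw) / nc
  list(sigma = c(sb, msw), phi_st = sb / (sb + msw))
}

# S_nn by direct enumeration with equal tie splitting
bf_snn <- function(d, lab) {
  n <- nrow(d)
  mean(sapply(seq_len(n), function(i) {
    di <- d[i, -i]
    idx <- (1:n)[-i]
    nn <- idx[abs(di - min(di)) < 1e-12]
    mean(lab[nn] == lab[i])
  }))
}

# Storey q-values by literal formula
bf_storey <- function(p, lambda = 0.15) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i)  # rank of p[i]
    q[i] <- min(pi0 * m * p[ord][j:m] / (j:m))
  }
  pmin(q, 1)
}

# minimum spanning tree weight by exhaustive search over all spanning trees
bf_mst_weight <- function(d) {
  n <- nrow(d)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(edges)
  best <- Inf
  for (comb in utils::combn(ne, n - 1, simplify = FALSE)) {
    # connectivity check by union-find
    parent <- 1:n
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in comb) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(d[edges[comb, , drop = FALSE]]))
  }
  best
}

# write a tiny two-locus study to disk, return config path
write_fixture_study <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lines <- function(path, recs) {
    con <- file(path, "w")
    for (nm in names(recs)) {
      writeLines(paste0(">", nm), con)
      writeLines(recs[[nm]], con)
    }
    close(con)
  }
  write_lines(file.path(dir, "locA.fasta"),
              c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAT", a3 = "ACGAACGTAT",
                a4 = "ACGTACGTAC", OUTGROUP = "ACGTACGTAC"))
  write_lines(file.path(dir, "locB.fasta"),
              c(a1 = "TTTTCCCC", a2 = "TTTTCCCC", a3 = "TTTTCCCG",
                a4 = "TTCTCCCC"))
  writeLines(c("sample_id\ttaxon\tpopulation\tregion",
               "a1\tmugo\tP1\t", "a2\tmugo\tP1\t",
               "a3\tuncinata\tP2\t", "a4\tuncinata\tP2\t"),
             file.path(dir, "samples.tsv"))
  cfg <- list(config_version = 1, samples = "samples.tsv",
              loci = list(list(locus_id = "locA", fasta = "locA.fasta"),
                          list(locus_id = "locB", fasta = "locB.fasta")))
  path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  path
}
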