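# Coalescent engine: panmictic, island and split demographies, infinite-sites
# mutation, and a small ancestral-recombination-graph simulator.
#
# Time is measured in units of 4N generations, so that with k lineages the
# waiting time to the next coalescence is Exponential(rate k(k-1)):
# E[TMRCA] = 1 - 1/n and E[total tree length] = a_{n-1}. Mutations fall as
# Poisson(theta_locus x tree length) with theta_locus = 4N mu per locus;
# this pairing reproduces E[S] = theta a_{n-1} and E[pi x L] = theta.

#' Simulate a neutral panmictic genealogy
#'
#' @param n number of haploid samples (>= 2).
#' @param seed RNG seed (NULL: use current RNG state).
#' @return object of class \code{genealogy}: list with \code{n},
#'   \code{parent} (length 2n-1, root NA), \code{time} (node times, leaves 0),
#'   \code{labels} (leaf names). Nodes 1..n are leaves.
#' @export
simulate_genealogy <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  with_seed(seed, {
    n_nodes <- 2L * n - 1L
    parent <- rep(NA_integer_, n_nodes)
    time <- numeric(n_nodes)
    active <- seq_len(n)
    t <- 0
    nxt <- n + 1L
    while (length(active) > 1) {
      k <- length(active)
      t <- t + stats::rexp(1, rate = k * (k - 1))
      pair <- sample.int(k, 2)
      a <- active[pair[1]]; b <- active[pair[2]]
      parent[a] <- nxt; parent[b] <- nxt
      time[nxt] <- t
      active <- c(active[-pair], nxt)
      nxt <- nxt + 1L
    }
    structure(list(n = n, parent = parent, time = time,
                   labels = paste0("s", seq_len(n))),
              class = "genealogy")
  })
}

#' Simulate a selective-sweep-like genealogy
#'
#' Most lineages coalesce in a near-star burst at a recent time while a few
#' escape lineages join the tree at neutral depths. Mutations dropped on
#' such a tree show the classic sweep signature: an excess of singletons
#' (long external branches of the swept class are absent, but each swept
#' lineage still carries its own short branch), high-frequency derived
#' alleles (mutations on the long internal branch above the swept class)
#' and reduced haplotype diversity. \code{f} controls star-likeness: the
#' burst happens at time (1 - f) x 0.5, so f -> 1 is a maximally recent
#' sweep.
#'
#' @param n samples.
#' @param f sweep-intensity fraction in (0, 1].
#' @param n_escape lineages escaping the sweep (default ~10\% of n, at
#'   least 1).
#' @param seed RNG seed.
#' @return a \code{genealogy}.
#' @export
sweep_genealogy <- function(n, f = 0.9, n_escape = max(1L, round(0.1 * n)),
                            seed = NULL) {
  stopifnot(n >= 3, f > 0, f <= 1, n_escape >= 0, n_escape <= n - 2)
  with_seed(seed, {
    tau <- (1 - f) * 0.5
    n_nodes <- 2L * n - 1L
    parent <- rep(NA_integer_, n_nodes)
    time <- numeric(n_nodes)
    swept <- seq_len(n - n_escape)
    esc <- setdiff(seq_len(n), swept)
    nxt <- n + 1L
    # near-star burst: sequential merges within a vanishing time window
    active <- swept
    j <- 0
    while (length(active) > 1) {
      j <- j + 1
      pair <- sample.int(length(active), 2)
      a <- active[pair[1]]; b <- active[pair[2]]
      parent[a] <- nxt; parent[b] <- nxt
      time[nxt] <- tau * (1 + j * 1e-6)
      active <- c(active[-pair], nxt)
      nxt <- nxt + 1L
    }
    # the swept ancestor and the escapees coalesce neutrally, offset by tau
    deep <- c(active, esc)
    t <- tau * (1 + (j + 1) * 1e-6)
    while (length(deep) > 1) {
      k <- length(deep)
      t <- t + stats::rexp(1, rate = k * (k - 1))
      pair <- sample.int(k, 2)
      a <- deep[pair[1]]; b <- deep[pair[2]]
      parent[a] <- nxt; parent[b] <- nxt
      time[nxt] <- t
      deep <- c(deep[-pair], nxt)
      nxt <- nxt + 1L
    }
    structure(list(n = n, parent = parent, time = time,
                   labels = paste0("s", seq_len(n))),
              class = "genealogy")
  })
}

#' Total branch length of a genealogy (4N units)
#' @param g a \code{genealogy}.
#' @return numeric scalar.
#' @export
total_length <- function(g) {
  has_parent <- !is.na(g$parent)
  sum(g$time[g$parent[has_parent]] - g$time[has_parent])
}

#' Time to the most recent common ancestor (4N units)
#' @param g a \code{genealogy}.
#' @return numeric scalar.
#' @export
tmrca <- function(g) max(g$time)

# Leaf index sets below every node.
branch_leaf_sets <- function(g) {
  n_nodes <- length(g$parent)
  sets <- vector("list", n_nodes)
  for (i in seq_len(g$n)) sets[[i]] <- i
  ord <- order(g$time[(g$n + 1):n_nodes]) + g$n
  kids <- split(seq_len(n_nodes)[!is.na(g$parent)],
                g$parent[!is.na(g$parent)])
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    sets[[v]] <- sort(unlist(sets[ch]))
  }
  sets
}

#' Newick string of a genealogy
#' @param g a \code{genealogy}.
#' @return character scalar (with trailing semicolon).
#' @export
genealogy_newick <- function(g) {
  n_nodes <- length(g$parent)
  kids <- split(seq_len(n_nodes)[!is.na(g$parent)],
                g$parent[!is.na(g$parent)])
  blen <- function(v) {
    p <- g$parent[v]
    if (is.na(p)) 0 else g$time[p] - g$time[v]
  }
  build <- function(v) {
    if (v <= g$n) {
      sprintf("%s:%.8f", g$labels[v], blen(v))
    } else {
      sprintf("(%s):%.8f",
              paste(vapply(kids[[as.character(v)]], build, character(1)),
                    collapse = ","), blen(v))
    }
  }
  root <- which(is.na(g$parent))
  paste0(build(root), ";")
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Mutations are placed on branches proportionally to branch length, each at
#' a distinct uniformly drawn alignment column; under \code{fixed_theta} the
#' count is Poisson(theta x tree length), under \code{fixed_S} it is exactly
#' S.
#'
#' @param g a \code{genealogy}.
#' @param mode \code{"fixed_theta"} or \code{"fixed_S"}.
#' @param theta locus-total 4N mu (fixed_theta mode).
#' @param S segregating-site count (fixed_S mode).
#' @param L locus length in bp.
#' @param seed RNG seed.
#' @param return_matrix build the n x L haplotype matrix (default TRUE;
#'   set FALSE for summary-only use at large L).
#' @return list with \code{matrix} (n x L character haplotypes, ancestral A /
#'   derived T; NULL when \code{return_matrix = FALSE}), \code{positions}
#'   (0-based), \code{xi} (derived counts per mutation), \code{carriers}
#'   (leaf index sets), \code{genealogy}.
#' @export
mutate_infinite_sites <- function(g, mode = c("fixed_theta", "fixed_S"),
                                  theta = NULL, S = NULL, L = 1000,
                                  seed = NULL, return_matrix = TRUE) {
  mode <- match.arg(mode)
  with_seed(seed, {
    has_parent <- which(!is.na(g$parent))
    blen <- g$time[g$parent[has_parent]] - g$time[has_parent]
    tot <- sum(blen)
    n_mut <- if (mode == "fixed_theta") {
      stopifnot(!is.null(theta), theta >= 0)
      stats::rpois(1, theta * tot)
    } else {
      stopifnot(!is.null(S), S >= 0)
      as.integer(S)
    }
    if (n_mut > L)
      stop("requested ", n_mut, " mutations on ", L,
           " sites: infinite-sites violation at this length")
    if (n_mut == 0) {
      m <- if (return_matrix)
        matrix("A", nrow = g$n, ncol = L, dimnames = list(g$labels, NULL))
      else NULL
      return(list(matrix = m, positions = integer(0), xi = integer(0),
                  carriers = list(), genealogy = g))
    }
    branches <- has_parent[sample.int(length(blen), n_mut, replace = TRUE,
                                      prob = blen)]
    positions <- sort(sample.int(L, n_mut)) - 1L
    sets <- branch_leaf_sets(g)
    carriers <- sets[branches]
    m <- NULL
    if (return_matrix) {
      m <- matrix("A", nrow = g$n, ncol = L, dimnames = list(g$labels, NULL))
      for (i in seq_len(n_mut)) m[carriers[[i]], positions[i] + 1L] <- "T"
    }
    list(matrix = m, positions = positions,
         xi = vapply(carriers, length, integer(1)),
         carriers = carriers, genealogy = g)
  })
}

# Fast path for null distributions: derived-allele counts only.
# Returns an integer vector xi (length = mutation count) for one replicate.
simulate_sfs <- function(n, mode = c("fixed_theta", "fixed_S"),
                         theta = NULL, S = NULL) {
  mode <- match.arg(mode)
  sizes <- rep(1L, n)     # leaves below each active lineage
  lens <- numeric(n)      # accumulated branch length of each active lineage
  br_size <- integer(2 * (n - 1))
  br_len <- numeric(2 * (n - 1))
  nb <- 0L
  k <- n
  while (k > 1) {
    dt <- stats::rexp(1, rate = k * (k - 1))
    lens <- lens + dt
    pair <- sample.int(k, 2)
    a <- pair[1]; b <- pair[2]
    br_size[nb + 1L] <- sizes[a]; br_len[nb + 1L] <- lens[a]
    br_size[nb + 2L] <- sizes[b]; br_len[nb + 2L] <- lens[b]
    nb <- nb + 2L
    sizes[a] <- sizes[a] + sizes[b]
    lens[a] <- 0
    sizes <- sizes[-b]; lens <- lens[-b]
    k <- k - 1L
  }
  n_mut <- if (mode == "fixed_theta") stats::rpois(1, theta * sum(br_len))
           else as.integer(S)
  if (n_mut == 0) return(integer(0))
  br_size[sample.int(nb, n_mut, replace = TRUE, prob = br_len[seq_len(nb)])]
}

# General structured coalescent over labelled demes.
#
# deme_of_sample : integer deme index per sample.
# n_demes        : total number of demes (may exceed demes sampled from).
# M              : per-lineage migration rate (4N units); destination uniform
#                  among the other extant demes.
# size_factor    : per-deme coalescence-rate multiplier; a deme holding a
#                  fraction 1/f of the reference population has factor f
#                  (island model with d equal demes: factor d).
# events         : data.frame(time, from, to) of backward-in-time deme merges
#                  (lineages in `from` move to `to`; `from` stops existing).
structured_coalescent <- function(deme_of_sample, n_demes, M = 0,
                                  size_factor = 1, events = NULL,
                                  seed = NULL) {
  n <- length(deme_of_sample)
  stopifnot(n >= 2)
  size_factor <- rep_len(size_factor, n_demes)
  if (!is.null(events)) events <- events[order(events$time), , drop = FALSE]
  with_seed(seed, {
    n_nodes <- 2L * n - 1L
    parent <- rep(NA_integer_, n_nodes)
    time <- numeric(n_nodes)
    active <- seq_len(n)
    deme <- as.integer(deme_of_sample)
    alive_demes <- rep(TRUE, n_demes)
    t <- 0
    nxt <- n + 1L
    ev <- 1L
    while (length(active) > 1) {
      k_by_deme <- tabulate(deme, n_demes)
      coal_rates <- k_by_deme * (k_by_deme - 1) * size_factor
      n_extant <- sum(alive_demes)
      mig_rate <- if (n_extant > 1) M * length(active) else 0
      total <- sum(coal_rates) + mig_rate
      if (total <= 0) {
        if (!is.null(events) && ev <= nrow(events)) {
          t <- events$time[ev]
        } else {
          stop("no possible event: isolated lineages with M = 0 ",
               "cannot find a common ancestor")
        }
      } else {
        dt <- stats::rexp(1, rate = total)
        if (!is.null(events) && ev <= nrow(events) &&
            t + dt >= events$time[ev]) {
          t <- events$time[ev]
        } else {
          t <- t + dt
          if (stats::runif(1) < mig_rate / total) {
            l <- sample.int(length(active), 1)
            dest <- which(alive_demes)
            dest <- dest[dest != deme[l]]
            deme[l] <- if (length(dest) == 1) dest else sample(dest, 1)
          } else {
            d <- sample.int(n_demes, 1, prob = coal_rates)
            members <- which(deme == d)
            pair <- if (length(members) == 2) members
                    else members[sample.int(length(members), 2)]
            a <- active[pair[1]]; b <- active[pair[2]]
            parent[a] <- nxt; parent[b] <- nxt
            time[nxt] <- t
            active <- c(active[-pair], nxt)
            deme <- c(deme[-pair], d)
            nxt <- nxt + 1L
          }
          next
        }
      }
      # apply the scheduled merge event at time t
      if (!alive_demes[events$to[ev]])
        stop("merge event into deme ", events$to[ev],
             " which no longer exists at time ", events$time[ev])
      deme[deme == events$from[ev]] <- events$to[ev]
      alive_demes[events$from[ev]] <- FALSE
      ev <- ev + 1L
    }
    structure(list(n = n, parent = parent, time = time,
                   labels = paste0("s", seq_len(n)),
                   sample_deme = as.integer(deme_of_sample)),
              class = "genealogy")
  })
}

#' Simulate one locus under the finite-island model
#'
#' Symmetric island model with \code{d} demes of equal size; each lineage
#' migrates at rate \code{M = 4Nm} (reference N = total population), and
#' within-deme coalescence is accelerated by the factor \code{d}. A sample
#' drawn from a single deme then has the panmictic mean coalescence time
#' regardless of M.
#'
#' @param d number of demes (>= 2).
#' @param M per-lineage scaled migration rate (> 0).
#' @param samples_per_deme integer vector of haploid sample counts per deme
#'   (length d, zeros allowed).
#' @param theta locus-total 4N mu.
#' @param L locus length in bp.
#' @param seed RNG seed.
#' @return list with \code{matrix} (haplotypes), \code{deme} (deme label per
#'   sample), \code{positions}, \code{xi}, \code{genealogy}.
#' @export
simulate_island <- function(d, M, samples_per_deme, theta, L = 1000,
                            seed = NULL) {
  stopifnot(d >= 2)
  if (M <= 0) stop("island model needs M > 0 for a common ancestor")
  samples_per_deme <- rep_len(samples_per_deme, d)
  deme_of_sample <- rep(seq_len(d), samples_per_deme)
  seeds <- derive_seeds(seed %||% sample.int(2^30, 1), 2)
  g <- structured_coalescent(deme_of_sample, n_demes = d, M = M,
                             size_factor = d, seed = seeds[1])
  mut <- mutate_infinite_sites(g, "fixed_theta", theta = theta, L = L,
                               seed = seeds[2])
  list(matrix = mut$matrix, deme = deme_of_sample,
       positions = mut$positions, xi = mut$xi, genealogy = g)
}

#' Simulate one locus under a population-split model
#'
#' Tip populations are demes of the reference size; backward in time demes
#' merge at the given split times (4N units). Optional symmetric migration
#' among extant demes.
#'
#' @param splits data.frame with columns \code{time}, \code{from}, \code{to}:
#'   at \code{time}, population \code{from} merges into \code{to}.
#' @param theta locus-total 4N mu.
#' @param samples_per_pop named or plain integer vector of samples per tip
#'   population (indices 1..P).
#' @param M symmetric migration rate among extant demes (default 0).
#' @param L locus length.
#' @param seed RNG seed.
#' @return list as for \code{\link{simulate_island}}, with \code{pop} labels.
#' @export
simulate_split <- function(splits, theta, samples_per_pop, M = 0, L = 1000,
                           seed = NULL) {
  P <- length(samples_per_pop)
  if (nrow(splits) > 0 &&
      (any(splits$from > P + nrow(splits)) || any(splits$time <= 0)))
    stop("inconsistent split specification")
  deme_of_sample <- rep(seq_len(P), samples_per_pop)
  seeds <- derive_seeds(seed %||% sample.int(2^30, 1), 2)
  g <- structured_coalescent(deme_of_sample, n_demes = P, M = M,
                             size_factor = 1, events = splits,
                             seed = seeds[1])
  mut <- mutate_infinite_sites(g, "fixed_theta", theta = theta, L = L,
                               seed = seeds[2])
  list(matrix = mut$matrix, pop = deme_of_sample,
       positions = mut$positions, xi = mut$xi, genealogy = g)
}

#' Simulate one locus with intralocus recombination (ancestral graph)
#'
#' Hudson-style ancestral recombination graph over \code{L} discrete sites.
#' Each lineage recombines at rate rho_bp x (bp span of its ancestral
#' material); marginal trees are tracked per site and mutations are dropped
#' per site at rate theta/L on the marginal tree (at most one mutation is
#' applied per site, an infinite-sites approximation at finite L).
#'
#' @param n samples (<= 30).
#' @param theta locus-total 4N mu.
#' @param rho per-bp scaled recombination rate; rho x L <= 50.
#' @param L locus length in bp.
#' @param seed RNG seed.
#' @return list with \code{matrix} (n x L haplotypes), \code{positions}
#'   (0-based polymorphic columns), \code{n_recomb} (recombination events).
#' @export
simulate_with_recombination <- function(n, theta, rho, L, seed = NULL) {
  if (n > 30 || rho * L > 50)
    stop("scenario guard exceeded (n <= 30 and rho x L <= 50): ",
         "request a smaller scenario")
  stopifnot(rho >= 0, n >= 2)
  with_seed(seed, {
    # lineage state: per-site carried node id (NA once a site is resolved
    # or not ancestral to the lineage)
    lineages <- lapply(seq_len(n), function(i) rep.int(i, L))
    node_time <- numeric(n)
    active_count <- rep(n, L)       # ancestral lineages per site
    span_of <- function(x) {
      w <- which(!is.na(x))
      if (length(w) < 2) 0 else max(w) - min(w)
    }
    spans <- rep(L - 1, n)
    edges <- list()
    n_edges <- 0L
    add_edges <- function(child, parent, site) {
      n_edges <<- n_edges + 1L
      edges[[n_edges]] <<- cbind(child, parent, site)
    }
    t <- 0
    nxt <- n + 1L
    nrec <- 0L
    while (any(active_count > 1) && length(lineages) > 1) {
      k <- length(lineages)
      coal_rate <- k * (k - 1)
      rec_rates <- rho * spans
      total <- coal_rate + sum(rec_rates)
      t <- t + stats::rexp(1, rate = total)
      if (stats::runif(1) < coal_rate / total) {
        pair <- sample.int(k, 2)
        a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
        new <- ifelse(is.na(a), b, a)
        both <- which(!is.na(a) & !is.na(b))
        if (length(both) > 0) {
          node_time[nxt] <- t
          add_edges(c(a[both], b[both]), nxt, c(both, both))
          new[both] <- nxt
          active_count[both] <- active_count[both] - 1L
          done <- both[active_count[both] == 1L]
          new[done] <- NA_integer_
          nxt <- nxt + 1L
        }
        lineages[c(pair[1], pair[2])] <- NULL
        spans <- spans[-c(pair[1], pair[2])]
        if (!all(is.na(new))) {
          lineages[[length(lineages) + 1]] <- new
          spans <- c(spans, span_of(new))
        }
      } else {
        l <- sample.int(k, 1, prob = rec_rates)
        x <- lineages[[l]]
        w <- which(!is.na(x))
        bp <- min(w) + stats::runif(1) * (max(w) - min(w))
        left <- x; left[seq_len(L) > bp] <- NA_integer_
        right <- x; right[seq_len(L) <= bp] <- NA_integer_
        lineages[[l]] <- left
        spans[l] <- span_of(left)
        lineages[[length(lineages) + 1]] <- right
        spans <- c(spans, span_of(right))
        nrec <- nrec + 1L
      }
    }
    edge_tab <- do.call(rbind, edges[seq_len(n_edges)])
    edges_child <- edge_tab[, 1]; edges_parent <- edge_tab[, 2]
    edges_site <- edge_tab[, 3]
    # mutations per site on the marginal trees
    m <- matrix("A", nrow = n, ncol = L,
                dimnames = list(paste0("s", seq_len(n)), NULL))
    site_groups <- split(seq_along(edges_site), edges_site)
    for (s_chr in names(site_groups)) {
      s <- as.integer(s_chr)
      idx <- site_groups[[s_chr]]
      child <- edges_child[idx]; par <- edges_parent[idx]
      blen <- node_time[par] - node_time[child]
      len_s <- sum(blen)
      n_mut <- stats::rpois(1, theta / L * len_s)
      if (n_mut >= 1) {
        br <- sample.int(length(idx), 1, prob = blen)
        # leaves below edge child[br] in this marginal tree
        below <- child[br]
        repeat {
          ch <- child[par %in% below & !(child %in% below)]
          if (length(ch) == 0) break
          below <- c(below, ch)
        }
        m[below[below <= n], s] <- "T"
      }
    }
    poly <- which(apply(m, 2, function(col) length(unique(col)) > 1)) - 1L
    list(matrix = m, positions = poly, n_recomb = nrec)
  })
}
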