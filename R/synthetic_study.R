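# Synthetic-study generator: complete studies shaped like the three-taxon
# pine survey (153 haploid samples, 16 populations, 79 nuclear gene
# fragments plus a small non-recombining mtDNA block and an outgroup), with
# known truth for every pipeline stage, plus post-hoc selection-signal
# injection for power and recovery experiments.

#' Default study scenario
#'
#' The defaults emulate the sampling design of the survey the package is
#' built around: taxa "mugo" (79 samples, 8 populations with regional groups
#' CE/CP/B and one ungrouped population), "uliginosa" (24 samples, 3
#' populations) and "uncinata" (50 samples, 5 populations); 79 nuclear loci
#' of 420 bp (about 33 kbp total) with per-locus theta drawn from a
#' log-normal centred near 0.005/site; a shallow split tree
#' ((uliginosa, uncinata), mugo) whose times keep shared polymorphism near
#' 60\% and net divergence below 0.001; an outgroup branch placed so net
#' outgroup divergence is about 0.024; and three mtDNA fragments treated as
#' one non-recombining block.
#'
#' @param n_loci nuclear loci (default 79).
#' @param locus_length bp per locus (default 420).
#' @param theta_site_meanlog,theta_site_sdlog log-normal parameters of
#'   per-site theta across loci (defaults log(0.004), 0.7, giving mean
#'   theta about 0.005/site).
#' @param t_pop population split depth within taxa (4N units, default
#'   0.003).
#' @param t1 uliginosa-uncinata split (default 0.008).
#' @param t2 mugo vs (uliginosa, uncinata) split (default 0.015).
#' @param t_outgroup outgroup divergence time (default 2.4, giving net
#'   divergence ~ 2 x t x theta ~ 0.024).
#' @param mtdna_fragments,mtdna_length,mtdna_theta mtDNA block settings.
#' @param selected_loci integer indices of loci carrying injected selection
#'   (default none); see \code{\link{inject_selection}}.
#' @return a \code{study_scenario} list.
#' @export
study_scenario <- function(n_loci = 79, locus_length = 420,
                           theta_site_meanlog = log(0.004),
                           theta_site_sdlog = 0.7,
                           t_pop = 0.003, t1 = 0.008, t2 = 0.015,
                           t_outgroup = 2.4,
                           mtdna_fragments = 3, mtdna_length = 300,
                           mtdna_theta = 0.7,
                           selected_loci = integer(0)) {
  pops <- data.frame(
    population = c(paste0("PM", 1:8), paste0("PUG", 1:3), paste0("PUN", 1:5)),
    taxon = rep(c("mugo", "uliginosa", "uncinata"), c(8, 3, 5)),
    region = c("CE", "CE", "CE", "CP", "CP", "B", "B", "",
               rep("", 8)),
    n = c(10, 10, 9, 10, 10, 10, 10, 10,   # mugo: 79
          10, 9, 5,                        # uliginosa: 24
          rep(10, 5)),                     # uncinata: 50
    stringsAsFactors = FALSE)
  structure(list(pops = pops, n_loci = n_loci, locus_length = locus_length,
                 theta_site_meanlog = theta_site_meanlog,
                 theta_site_sdlog = theta_site_sdlog,
                 t_pop = t_pop, t1 = t1, t2 = t2, t_outgroup = t_outgroup,
                 mtdna_fragments = mtdna_fragments,
                 mtdna_length = mtdna_length, mtdna_theta = mtdna_theta,
                 selected_loci = selected_loci),
            class = "study_scenario")
}

# Backward-in-time deme merge schedule for the default scenario.
# Demes 1..16 are the populations (taxon blocks 1-8, 9-11, 12-16);
# deme 17 holds the outgroup lineage.
scenario_events <- function(sc) {
  ev <- list()
  add <- function(time, from, to) ev[[length(ev) + 1]] <<-
    data.frame(time = time, from = from, to = to)
  for (f in 2:8) add(sc$t_pop, f, 1)        # mugo populations
  for (f in 10:11) add(sc$t_pop, f, 9)      # uliginosa
  for (f in 13:16) add(sc$t_pop, f, 12)     # uncinata
  add(sc$t1, 9, 12)                         # uliginosa joins uncinata
  add(sc$t2, 12, 1)                         # joint ancestor joins mugo
  add(sc$t_outgroup, 17, 1)                 # outgroup
  do.call(rbind, ev)
}

# Convert a simulated ancestral/derived matrix into a nucleotide alignment:
# random background base per column, derived carriers switched to a random
# different base.
sim_to_alignment <- function(mat) {
  L <- ncol(mat)
  background <- sample(.BASES, L, replace = TRUE)
  out <- matrix(rep(background, each = nrow(mat)), nrow = nrow(mat),
                dimnames = dimnames(mat))
  for (j in which(colSums(mat == "T") > 0)) {
    alt <- sample(setdiff(.BASES, background[j]), 1)
    out[mat[, j] == "T", j] <- alt
  }
  out
}

#' Generate a complete synthetic study
#'
#' Simulates every locus under the scenario's split-plus-substructure
#' demography (population demes merging within taxa, taxa joining at the
#' scenario's split times, one outgroup lineage), converts ancestral/derived
#' states to nucleotides, and returns a \code{study_data} object plus a
#' truth table. With \code{out_dir} the study is also written to disk
#' (FASTA + TSV + JSON config, truth as JSON).
#'
#' @param scenario a \code{study_scenario}.
#' @param seed master seed (all per-locus seeds derive from it).
#' @param out_dir optional output directory.
#' @return list with \code{study} (a \code{study_data}), \code{truth}
#'   (data.frame: locus_id, theta_site, L, mtdna, selected, mechanism).
#' @export
generate_study <- function(scenario = study_scenario(), seed = 1,
                           out_dir = NULL) {
  sc <- scenario
  pops <- sc$pops
  samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(sample_id = sprintf("%s_%02d", pops$population[i],
                                   seq_len(pops$n[i])),
               taxon = pops$taxon[i], population = pops$population[i],
               region = pops$region[i], stringsAsFactors = FALSE)
  }))
  deme_of_sample <- rep(seq_len(nrow(pops)), pops$n)
  deme_of_sample <- c(deme_of_sample, 17L)   # outgroup lineage
  events <- scenario_events(sc)
  n_total <- sc$n_loci + sc$mtdna_fragments
  seeds <- derive_seeds(seed, 2 * n_total + 1)
  thetas <- with_seed(seeds[2 * n_total + 1], {
    stats::rlnorm(sc$n_loci, sc$theta_site_meanlog, sc$theta_site_sdlog)
  })

  make_locus <- function(lid, L, theta_locus, s1, s2) {
    g <- structured_coalescent(deme_of_sample, n_demes = 17, M = 0,
                               size_factor = 1, events = events, seed = s1)
    aln <- with_seed(s2, {
      mut <- mutate_infinite_sites(g, "fixed_theta", theta = theta_locus,
                                   L = L)
      sim_to_alignment(mut$matrix)
    })
    rownames(aln) <- c(samples$sample_id, "OUTGROUP")
    locus_alignment(lid, aln[samples$sample_id, , drop = FALSE],
                    outgroup = aln["OUTGROUP", ])
  }

  alignments <- list()
  for (i in seq_len(sc$n_loci)) {
    lid <- sprintf("locus%02d", i)
    alignments[[lid]] <- make_locus(lid, sc$locus_length,
                                    thetas[i] * sc$locus_length,
                                    seeds[2 * i - 1], seeds[2 * i])
  }
  mt_ids <- character(0)
  for (k in seq_len(sc$mtdna_fragments)) {
    lid <- sprintf("mtdna%d", k)
    mt_ids <- c(mt_ids, lid)
    j <- sc$n_loci + k
    alignments[[lid]] <- make_locus(lid, sc$mtdna_length, sc$mtdna_theta,
                                    seeds[2 * j - 1], seeds[2 * j])
  }

  coverage <- data.frame(locus_id = names(alignments),
                         n_samples = nrow(samples),
                         fraction = 1, flagged = FALSE, row.names = NULL)
  study <- structure(list(alignments = alignments, samples = samples,
                          annotation = list(), mtdna_loci = mt_ids,
                          coverage = coverage, config_path = NA_character_),
                     class = "study_data")
  truth <- data.frame(
    locus_id = names(alignments),
    theta_site = c(thetas, rep(sc$mtdna_theta / sc$mtdna_length,
                               sc$mtdna_fragments)),
    L = c(rep(sc$locus_length, sc$n_loci),
          rep(sc$mtdna_length, sc$mtdna_fragments)),
    mtdna = c(rep(FALSE, sc$n_loci), rep(TRUE, sc$mtdna_fragments)),
    selected = FALSE, mechanism = "", stringsAsFactors = FALSE)
  out <- list(study = study, truth = truth, scenario = sc, seed = seed)
  if (!is.null(out_dir)) {
    write_study(study, out_dir)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Inject a selection signal into a synthetic study
#'
#' Post-hoc modification with exact truth labels. Mechanisms:
#' \describe{
#'   \item{divergent}{in the target taxon, each SNP of the target loci has
#'     its minor... derived-state frequency shifted by \code{delta} (clipped
#'     to [0, 1]) by flipping randomly chosen samples, raising per-SNP F_ST
#'     between that taxon and the rest.}
#'   \item{sweep_like}{the locus is re-simulated on a sweep-like genealogy
#'     (see \code{\link{sweep_genealogy}}): a near-star coalescence burst at
#'     recency controlled by \code{f} with a few escape lineages, skewing
#'     the frequency spectrum toward singletons and high-frequency derived
#'     alleles and reducing haplotype diversity.}
#' }
#'
#' @param study result of \code{\link{generate_study}}.
#' @param loci locus ids (or indices) to modify.
#' @param mechanism \code{"divergent"} or \code{"sweep_like"}.
#' @param delta frequency shift for the divergent mechanism (default 0.5).
#' @param f star-likeness fraction for sweep_like (default 0.9).
#' @param taxon target taxon for the divergent mechanism (default "mugo").
#' @param seed RNG seed.
#' @return the study list with modified alignments and updated truth; for
#'   the divergent mechanism the attribute \code{"injected_snps"} records
#'   each SNP's achieved frequency shift (\code{delta_applied} can fall
#'   short of \code{delta} through clipping at fixation).
#' @export
inject_selection <- function(study, loci,
                             mechanism = c("divergent", "sweep_like"),
                             delta = 0.5, f = 0.9, taxon = "mugo",
                             seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (is.numeric(loci)) loci <- study$truth$locus_id[loci]
  missing <- setdiff(loci, names(study$study$alignments))
  if (length(missing) > 0)
    stop("target loci not in study: ", paste(missing, collapse = ", "))
  samples <- study$study$samples
  seeds <- derive_seeds(seed %||% sample.int(2^30, 1), length(loci))
  injected_snps <- attr(study, "injected_snps") %||%
    data.frame(locus_id = character(0), position = integer(0),
               delta_applied = numeric(0))
  for (k in seq_along(loci)) {
    lid <- loci[k]
    aln <- study$study$alignments[[lid]]
    if (mechanism == "divergent") {
      shifts <- list()
      study$study$alignments[[lid]] <- with_seed(seeds[k], {
        m <- aln$seqs
        target <- samples$sample_id[samples$taxon == taxon]
        vt <- build_variant_table(aln)
        for (pos in vt$sites$position[vt$sites$type == "SNP"]) {
          col <- m[target, pos + 1L]
          tab <- sort(table(col[col %in% .BASES]), decreasing = TRUE)
          allele <- if (length(tab) > 1) {
            names(tab)[length(tab)]   # rarest allele in target taxon
          } else {
            # taxon monomorphic: push in an allele segregating elsewhere
            all_alleles <- strsplit(
              vt$sites$alleles[vt$sites$position == pos][1], ",")[[1]]
            others <- setdiff(all_alleles, names(tab))
            if (length(others) == 0) next
            others[1]
          }
          carriers <- which(col == allele)
          non <- which(col %in% .BASES & col != allele)
          want <- round(min(1, length(carriers) / length(target) + delta) *
                          length(target))
          flip <- min(max(want - length(carriers), 0), length(non))
          if (flip > 0) {
            pick <- if (length(non) == 1) non else sample(non, flip)
            m[target[pick], pos + 1L] <- allele
          }
          shifts[[length(shifts) + 1]] <- data.frame(
            locus_id = lid, position = pos,
            delta_applied = flip / length(target))
        }
        locus_alignment(lid, m, aln$outgroup)
      })
      if (length(shifts))
        injected_snps <- rbind(injected_snps, do.call(rbind, shifts))
    } else {
      tr <- study$truth[study$truth$locus_id == lid, ]
      theta_locus <- tr$theta_site * tr$L
      study$study$alignments[[lid]] <- with_seed(seeds[k], {
        g <- sweep_genealogy(nrow(samples), f = f)
        mut <- mutate_infinite_sites(g, "fixed_theta", theta = theta_locus,
                                     L = tr$L)
        m <- sim_to_alignment(mut$matrix)
        # outgroup: the ancestral base of each column (read off any sample
        # still carrying the ancestral state) plus private divergence
        og <- vapply(seq_len(tr$L), function(j) {
          anc_rows <- which(mut$matrix[, j] == "A")
          if (length(anc_rows) > 0) m[anc_rows[1], j] else m[1, j]
        }, character(1))
        n_div <- stats::rpois(1, theta_locus * study$scenario$t_outgroup)
        if (n_div > 0) {
          at <- sample.int(tr$L, min(n_div, tr$L))
          og[at] <- vapply(at, function(s)
            sample(setdiff(.BASES, og[s]), 1), character(1))
        }
        rownames(m) <- samples$sample_id
        locus_alignment(lid, m, og)
      })
    }
    study$truth$selected[study$truth$locus_id == lid] <- TRUE
    study$truth$mechanism[study$truth$locus_id == lid] <- mechanism
  }
  attr(study, "injected_snps") <- injected_snps
  study
}
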