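---
title: "Methods: multilocus diversity, neutrality and selection scans in pinepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilocus diversity, neutrality and selection scans in pinepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinepop)
```

## Scope and data model

pinepop implements a complete multilocus population-genetics analysis for
haploid sequence data from closely related taxa, organised around the study
design of the *Pinus mugo* species complex: three taxa (*P. mugo*,
*P. uliginosa*, *P. uncinata*) sampled as 153 haploid megagametophyte
sequences from 16 populations at 79 nuclear gene fragments (~33 kbp) plus
three mitochondrial fragments, with a *P. taeda*-like outgroup.

The data substrate is the per-locus alignment (`locus_alignment`): a
character matrix over `{A,C,G,T,-,N}` with one row per haploid sample.
IUPAC ambiguity codes are treated as missing. Coordinates are 0-based
half-open internally and 1-based in reports and VCF output. From an
alignment the package derives:

* a `variant_table` — SNPs called on nucleotide states (gaps and N are
  missing for SNP calling), plus indel events, where one indel event is a
  maximal run of gap columns sharing a presence/absence pattern. Indels
  count toward the "polymorphic sites" total by default
  (`segregating_sites(vt, indels = "count")`), the convention of the
  total-mutations dialect; `indels = "ignore"` switches to SNPs only.
  Per-site statistics (π, θ per site) always exclude indels.
* a `haplotype_set` — haplotypes keyed on the full aligned sequence
  including gaps, after excluding samples with more than 20% missing data
  at the locus.

Missing data are handled by pairwise deletion wherever a pairwise quantity
is computed. Sites with more than two alleles are retained for diversity
statistics (π as expected heterozygosity over all alleles) and reduced to
major-vs-rest, with a flag, where a method requires biallelic input (r²,
the Bayesian F_ST scan).

A definitional detail worth making explicit: a *singleton* site is one
whose rarest allele occurs exactly once (no polarization involved), and an
*informative* site is one with at least two alleles each seen at least
twice. In small samples the derived allele can be the majority allele, so
derived-based and frequency-based singleton counts differ; pinepop uses the
frequency-based convention throughout, which is what DnaSP-style summary
tables report.

## Diversity and its Bayesian multilocus summary

Per locus and group the package reports π (mean pairwise difference per
site), Watterson's θ_W = S/(a_{n−1}L), haplotype diversity
H_d = n/(n−1)(1−Σp²) with Nei's sampling SD, and singleton counts. Silent
sites are defined as noncoding columns plus the synonymous-site fraction of
coding columns, counted by Nei–Gojobori on the group consensus codons;
codons containing gaps, N or stops are skipped. The definition of "silent"
is a package choice — annotation sources rarely state one — and is the
standard noncoding + synonymous union.

The multilocus θ estimate is a Bayesian posterior for a single per-site θ
shared across loci, each locus contributing the closed-form neutral
coalescent probability of its segregating-site count S given θL and n
(Tavaré's alternating-sum formula). The alternating sum is evaluated by
signed log-sum-exp; for n > 50 or S > 500, where cancellation and cost bite,
a Monte-Carlo likelihood replaces it (10,000 simulated total tree lengths
with S | length ~ Poisson, drawn once so the likelihood is smooth in θ
across proposals — common random numbers). The prior is uniform on log10 θ
over [−5, −1], a range that comfortably brackets conifer nuclear diversity;
sampling is a Metropolis random walk on log10 θ (default SD 0.08, burn-in
5,000, 100,000 retained draws — the acceptance script uses 2,000/20,000,
which gives effective sample sizes in the thousands for 79-locus data). The
model deliberately has no locus random effects: one θ with locus length
scaling is the simplest model consistent with a multilocus summary, and the
posterior median plus 95% credible interval is what the summary tables
carry.

## Linkage disequilibrium and ρ/θ

r² is computed for pairs of biallelic informative sites within a locus on
pairwise-complete samples, with Fisher's exact test on the 2×2 haplotype
table. Between-locus pairs are never used: physical distance is only
meaningful inside an amplicon. LD pruning follows the Bonferroni–Fisher
convention: while any pair is significant at α/m, drop the member with more
significant partners, breaking ties toward the lower-MAF site.

The population recombination rate ρ = 4N_e c per bp is fitted by least
squares of observed r² against the Hill–Weir drift-equilibrium expectation
at C = ρ·d, including the finite-sample correction term, with ρ constrained
non-negative (log-spaced grid seed plus local polish, tolerance 1e-10).
The standard error is a bootstrap over loci (1,000 replicates by default).
Two estimator properties matter for interpretation:

* Under complete linkage (ρ = 0) the fit is at the zero boundary for the
  majority of simulated studies, but not ~100% of them: the conditional
  mean r² of informative pairs sits about 0.01 above the Hill–Weir C = 0
  level, and between-locus genealogical noise in a study's mean r²
  occasionally buys a small positive ρ (observed fits stay below about
  6e-3/bp, well under realistic nonzero signals). The boundary case is
  flagged (`at_boundary`).
* The fitted ρ is monotone in the true simulated ρ across
  {0, 0.002, 0.01, 0.05}/bp, which is the property the ρ/θ comparison
  between taxa actually relies on.

ρ/θ divides the fitted per-bp ρ by per-site θ_W from the same sample.

## Coalescent engine and its conventions

All null distributions come from one engine. Time is measured in units of
4N generations with coalescence rate k(k−1) for k lineages, and mutations
fall as Poisson(θ_locus × tree length); this pairing gives
E[TMRCA] = 1 − 1/n, E[total length] = a_{n−1} and E[S] = θ a_{n−1}.
The structured engine adds demes with per-lineage migration rate M and
backward-in-time deme mergers at scheduled times; the island model uses d
equal demes whose within-deme coalescence is accelerated by d, so a sample
from a single deme keeps the panmictic mean coalescence time regardless of
M. Fixed-S conditioning (exactly S mutations placed proportionally to
branch length) is the default for test p-values because it is robust to θ
misestimation; fixed-θ conditioning is retained because the compound-test
protocol conditions on the Watterson estimate. The
ancestral-recombination-graph simulator tracks marginal trees per discrete
site and is deliberately guarded to desk scale (n ≤ 30, ρL ≤ 50); at finite
L it applies at most one mutation per site, an infinite-sites
approximation.

A sweep-like genealogy generator (`sweep_genealogy`) complements the
neutral engine for power experiments: most lineages coalesce in a near-star
burst at a recent time while a few escape lineages join at neutral depths.
The escape lineages are essential — a pure star produces only singletons
(the growth signature: D < 0 but H > 0 and maximal haplotype diversity),
whereas the burst-plus-escapes topology produces the sweep signature the
compound tests are built to detect: singleton excess, high-frequency
derived alleles from the long internal branch, and a dominant haplotype
class.

## Neutrality tests

Tajima's D uses the 1989 variance constants; at S = 0 it is undefined and
excluded from multilocus means, and whenever the numerator vanishes D = 0
is returned (at n = 3 the variance is exactly zero because the pairwise
difference count is a deterministic multiple of S). Per-locus p-values are
one-sided (negative) against fixed-S simulations; the multilocus test
compares the observed mean D with the mean over loci simulated each at its
own (n, S).

Fay & Wu's H is computed from derived counts at sites polarized by the
outgroup (ancestral allele = outgroup base when it matches a segregating
allele; third-allele sites flagged and left unknown). Both the classic
unnormalized H = θ_π − θ_H and the normalized statistic
(θ_π − θ_L)/√Var with the Zeng et al. (2006) variance are reported; nulls
are polarized by construction.

The Ewens–Watterson test compares haplotype homozygosity F = Σp² with
configurations from the Ewens sampling formula conditional on (n, k):
θ is solved from E[k | θ, n] = k and Chinese-restaurant draws are retained
when they produce exactly k haplotypes. The p-value is one-sided for
homozygosity excess. k = 1 and k = n are degenerate and flagged.

The compound tests reject iff every component is individually significant
at a calibrated level α′: HEW uses (H, F), DHEW uses (D, H, F). α′ is found
by bisection on a jointly simulated null so the compound size equals α —
component one-sided p-values are computed for every null replicate within
the null sample by ranking, and α′ is the largest level at which the
fraction of replicates with all components ≤ α′ stays at α. Directions are
D negative, H negative, F high, the selection-detection directions of the
compound-test framework. Null conditioning defaults to fixed-θ at the
locus's Watterson estimate, matching the published protocol, with fixed-S
available.

The HKA test uses the classic one-species-plus-outgroup design with equal
population sizes: E[S_i] = θ_i a_{n_i−1}, Var[S_i] = E + θ_i² b_{n_i−1},
E[D_i] = θ_i (T + 1), Var[D_i] = E + θ_i², parameters estimated by direct
minimization of the X² (nested 1-D optimizations, moment-equation start),
X² referred to χ²(L−1). Loci with S = 0 and D = 0 carry no information and
are dropped with a warning; S = 0 with D > 0 is informative and kept. A
multi-sample outgroup would be reduced to its consensus.

## Differentiation and structure

AMOVA follows the Excoffier variance decomposition on squared distances,
with pairwise difference counts playing the role of squared distances (the
Arlequin convention, which also fixes the F_ST flavour: Φ_ST-type, not
Weir–Cockerham — chosen for comparability with the survey's published
values). Permutation schemes: Φ_ST permutes haplotypes among populations,
Φ_SC within groups, Φ_CT whole populations among groups; all permutation
p-values use (b+1)/(B+1) so ties count and p is never zero. Per-SNP F_ST is
the same variance partition on a single site (a closed form for binary
haploid data), with pooled expected heterozygosity alongside. Hudson's S_nn
splits nearest-neighbour ties equally and permutes labels; the statistic is
invariant under monotone distance transforms. PCoA is Gower
double-centering of −d²/2 with coordinates scaled by √eigenvalue; negative
eigenvalues are reported and dropped. The haplotype network is the minimum
spanning tree plus every co-minimal alternative edge: an edge is kept iff
its endpoints are unconnected using strictly shorter edges, i.e. iff it
lies in at least one MST.

The S_nn implementation follows Hudson (2000) even though differentiation
studies sometimes cite other sources for it; that is the definition the
permutation test needs. Whether an ungrouped population (the design has one
Italian *P. mugo* stand excluded from regional groups) joins taxon-level
AMOVA is a caller decision — both modes work by passing the appropriate
sample subset.

## Outlier scans and FDR

The FDIST-style scan simulates island-model SNPs (default 100 demes,
20,000 replicates, one segregating site per replicate genealogy) with
migration calibrated by 1-D search so the mean simulated F_ST matches the
observed multilocus value, then reads conditional 50/95/99% envelopes of
F_ST in sliding heterozygosity windows of at least 500 simulated loci.
The empirical p per SNP is the fraction of window loci with F_ST at least
as large. The null is the plain finite-island model with sample sizes
matched to the observed groups; a hierarchical-island variant would be a
drop-in replacement of the simulating function but is not implemented.

The Bayesian scan decomposes logit(F_ST^{ij}) = α_i + β_j with
beta-binomial allele counts given the ancestral frequency p_i, a
reversible-jump indicator on each α_i with prior odds 10 for the neutral
model, MAF > 0.05 filtering, pilot-run proposal tuning, and local-FDR
q-values (cumulative mean of 1 − inclusion probability down the ranking,
decisions at q < 0.05). Birth moves draw α from a moment-centred normal
proposal (clipped logit of the empirical locus F against the median locus)
rather than the prior; the proposal density enters the acceptance ratio, and
the change matters — prior-centred births rarely reach the high-α mode.
Posterior inclusion probabilities were validated against exact 2-D
quadrature on small instances and are seed-stable.

A design fact users should know: with few populations the data simply carry
little evidence per locus. At 4 populations of 25 haploid samples, the
*exact* posterior inclusion probability of a locus simulated with α = 2
rarely exceeds 0.7, while a q < 0.05 call needs roughly 0.95; power at that
design is near zero for any implementation, and becomes practical from
about 8 populations. The acceptance suite exercises the 4-population design
as specified and records the outcome honestly.

Storey's FDR uses the fixed-λ estimator π0 = min(1, #{p > λ}/(m(1−λ))) with
λ = 0.15 and the step-up q-value recursion.

## Evidence synthesis

The evidence matrix assembles six flags per gene × taxon: (1) interspecies
F_ST significant (p < 0.01), (2) among-population F_ST within taxon
significant, (3) S_nn significant, (4) highly diverged SNPs at the
interspecific level, (5) outlier SNPs within taxon, (6) HEW and/or DHEW
significant (p < 0.05). Flag 4 is operationalized as SNPs beyond the 99%
FDIST envelope in between-taxon scans — summary tables in this literature
do not pin a cutoff, and the 99% envelope is the conservative choice.
Candidates require, within one taxon, flag 6 AND (1 or 4) AND (2, 3 or 5);
cross-taxon sharing of within-taxon signals (flags 2/3/5/6 in more than one
taxon) is reported separately. The matrix is a pure function of its inputs
with deterministic ordering (flag count descending, then gene id).

## The synthetic-study generator

`generate_study(study_scenario(), seed)` simulates the full survey shape:
153 samples in 16 populations with the real per-population sample sizes
(including the 9/9/5 deficits), 79 nuclear loci of 420 bp, three mtDNA
fragments, and one outgroup lineage. The demography is population demes
merging into taxon demes at t_pop = 0.003 (4N units), the
uliginosa–uncinata join at t1 = 0.008, the joint ancestor meeting mugo at
t2 = 0.015, and the outgroup at t = 2.4; per-site θ is log-normal
(meanlog log 0.004, sdlog 0.7). These values were fixed once against the
generator's calibration targets: π ≈ 0.004–0.006, shared polymorphism
between the large taxa in the 45–75% band, per-locus net divergence well
below 0.001 with no fixed differences, and outgroup net divergence ≈ 0.024.

What the generator does *not* emulate: taxon-level Φ_ST comes out near
0.03, not the ~0.15 of the real survey. A pure split model cannot produce
both high shared ancestral polymorphism and strong taxon differentiation;
the real history presumably involves gene flow, unequal effective sizes and
selection at some loci. It also omits sequencing artefacts, alignment
error, indel polymorphism and mutation-rate heterogeneity along loci.
Passing calibration and recovery tests on these studies therefore
demonstrates correctness of the estimators under a clean neutral model, not
robustness to real-data messiness.

The generator simulates loci without intralocus recombination, so a
fitted rho on synthetic studies does not measure true recombination: it
reflects how far the finite-sample, structure-affected r2 level sits from
the Hill-Weir curve (values of rho/theta up to a few units arise this way).
Recombination-aware experiments use the ARG simulator directly.

Selection injection is post-hoc with exact truth labels: `divergent` shifts
SNP allele frequencies by δ in one taxon (clipped), raising between-taxon
per-SNP F_ST; `sweep_like` re-simulates a locus on a sweep genealogy
(panmictic across the whole sample — the locus loses its population
structure, a documented stylization that keeps runtime at desk scale and
truth exact).

## Numerical choices and problem sizes

Tolerances: the ρ fit polishes C to 1e-10; the HKA inner optimizations run
at 1e-10 with a ±20× box around the moment start; bisection for α′ runs 40
halvings. Degenerate inputs return flagged values rather than errors where
the field's tools do the same (D at S = 0, Ewens at k ∈ {1, n}, S_nn with
all-zero distances). RNG: every stochastic function takes an explicit seed;
derived child seeds stay below 2^31.

The test suite and the acceptance script run simulations at sizes chosen to
make their statistical assertions decisive while staying desk-scale: null
calibrations use 2,000 evaluation replicates with 500-replicate conditional
nulls; FDIST checks use 12–50 demes and 2,500–4,000 simulated loci with
400 observed SNPs; the compound-test sizes use a 3,000-replicate joint
null split into calibration and evaluation halves; the θ-posterior recovery
uses the full 79-locus design at n = 20; the acceptance script analyses the
complete default study (79 loci × 153 samples) with 100–200 permutations
per test, 800-replicate compound nulls on a 30-sample subsample of
*P. mugo*, a 30-sequence subsample per taxon for the θ posterior (where
the closed-form likelihood is numerically exact), and a 2,500-replicate
FDIST scan over 10 demes.

## Known limitations

* The generator's split-only demography understates taxon-level F_ST (see
  above); headline F_ST values from the synthetic study are not comparable
  to the survey's.
* The Bayesian scan's q < 0.05 decisions are effectively unavailable at
  4-population designs (information bound, not an implementation limit).
* The ARG simulator is exact but desk-scale only; ρ/θ estimation on large
  designs relies on the analytic Hill–Weir fit, not on ARG simulation.
* HKA is implemented in its classic equal-size two-species form with a
  single outgroup sequence; lineage-specific rates or partitioned variance
  forms are out of scope.
* Admixture-model clustering (STRUCTURE/BAPS-style) is deliberately absent;
  PCoA and F_ST views stand in for it.
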