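Package: pinepop
Title: Multilocus Population Genetics of Closely Related Pine Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete multilocus population-genetics pipeline for haploid
    sequence data from closely related taxa, built around the study design of
    the Pinus mugo species complex (P. mugo, P. uliginosa, P. uncinata):
    per-locus and multilocus diversity (pi, Watterson's theta with a Bayesian
    multilocus posterior, haplotype diversity), linkage-disequilibrium decay
    and the rho/theta ratio, divergence and polymorphism sharing between taxa,
    a seeded coalescent engine (panmictic, island, population-split, and
    ancestral-recombination-graph demographies) providing null distributions,
    site-frequency-spectrum and haplotype neutrality tests (Tajima's D,
    Fay and Wu's normalized H, Ewens-Watterson, compound HEW/DHEW, multilocus
    HKA), permutation-based differentiation (AMOVA Phi-statistics, pairwise
    and per-SNP F_ST, Hudson's S_nn, PCoA, haplotype networks), F_ST outlier
    scans (FDIST-style coalescent envelopes and a Bayesian logistic F_ST
    decomposition), Storey q-value FDR control, and an evidence-matrix
    synthesis identifying candidate genes under selection. A synthetic-study
    generator reproduces the sampling design of the original survey with known
    truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
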