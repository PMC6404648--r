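test_that("study loading round-trips fixture files and validates metadata", {
  dir <- withr::local_tempdir()
  cfg <- write_fixture_study(dir)
  study <- load_study(cfg)
  expect_length(study$alignments, 2)
  expect_equal(nrow(study$samples), 4)
  expect_equal(study$alignments$locA$length, 10)
  # outgroup record is split off, not counted as a sample
  expect_equal(nrow(study$alignments$locA$seqs), 4)
  expect_equal(study$alignments$locA$outgroup,
               strsplit("ACGTACGTAC", "")[[1]])
  expect_false(any(study$coverage$flagged))

  # write -> re-load is the identity on alignments and metadata
  dir2 <- withr::local_tempdir()
  cfg2 <- write_study(study, dir2)
  study2 <- load_study(cfg2)
  expect_equal(study2$alignments$locA$seqs, study$alignments$locA$seqs)
  expect_equal(study2$alignments$locB$seqs, study$alignments$locB$seqs)
  expect_equal(study2$alignments$locA$outgroup, study$alignments$locA$outgroup)
  expect_equal(study2$samples, study$samples)
})

test_that("a FASTA sample missing from metadata is a fatal, named error", {
  dir <- withr::local_tempdir()
  cfg <- write_fixture_study(dir)
  tsv <- file.path(dir, "samples.tsv")
  tab <- read.delim(tsv, colClasses = "character")
  write.table(tab[tab$sample_id != "a3", ], tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_study(cfg), "a3")
  expect_error(load_study(file.path(dir, "nope.json")), "not found")
})

test_that("variant tables recount S, singletons and MAF correctly", {
  aln <- toy3_alignment()
  vt <- build_variant_table(aln)
  expect_equal(vt$n_snps, 2)
  expect_equal(segregating_sites(vt), 2)
  # both toy variants have a once-occurring minor allele
  expect_equal(singleton_summary(vt), 2)
  expect_true(all(vt$sites$maf <= 0.5))
  expect_equal(vt$sites$position, c(8L, 9L))

  # monomorphic alignment
  m <- matrix("A", 3, 8, dimnames = list(paste0("s", 1:3), NULL))
  vt0 <- build_variant_table(locus_alignment("mono", m))
  expect_equal(nrow(vt0$sites), 0)
  expect_equal(vt0$n_snps, 0)

  # brute-force recount on random alignments incl. missing data
  for (seed in 1:5) {
    aln <- random_alignment(8, 300, seed)
    vt <- build_variant_table(aln)
    expect_equal(vt$n_snps, bf_S(aln$seqs))
    expect_equal(singleton_summary(vt, indels = "ignore"),
                 bf_singletons(aln$seqs))
    # column sums of allele counts equal the non-missing sample count
    for (r in which(vt$sites$type == "SNP")) {
      cnt <- as.integer(strsplit(vt$sites$counts[r], ",")[[1]])
      col <- aln$seqs[, vt$sites$position[r] + 1]
      expect_equal(sum(cnt), sum(col %in% BASES))
    }
  }
})

test_that("contiguous gap runs collapse to single indel events", {
  m <- rbind(s1 = strsplit("AC--GTACGT", "")[[1]],
             s2 = strsplit("ACTTGTACGT", "")[[1]],
             s3 = strsplit("ACTTGTACGT", "")[[1]])
  vt <- build_variant_table(locus_alignment("indel", m))
  expect_equal(vt$n_indels, 1)
  expect_equal(segregating_sites(vt), 1)
  expect_equal(segregating_sites(vt, indels = "ignore"), 0)

  # two runs with different carriers stay distinct events
  m2 <- rbind(s1 = strsplit("A--TG--TAC", "")[[1]],
              s2 = strsplit("ACCTGGGTAC", "")[[1]],
              s3 = strsplit("ACCTG--TAC", "")[[1]])
  vt2 <- build_variant_table(locus_alignment("indel2", m2))
  expect_equal(vt2$n_indels, 2)
  # adjacent gap columns with different presence patterns split too
  m3 <- rbind(s1 = strsplit("A---GT", "")[[1]],
              s2 = strsplit("AC--GT", "")[[1]],
              s3 = strsplit("ACCTGT", "")[[1]])
  vt3 <- build_variant_table(locus_alignment("indel3", m3))
  expect_equal(vt3$n_indels, 2)
})

test_that("polarization reads ancestral states off the outgroup", {
  aln <- toy3_alignment()
  vt <- polarize_variants(build_variant_table(aln), rep("A", 10))
  expect_equal(vt$sites$ancestral, c("A", "A"))
  expect_equal(vt$sites$derived_count, c(1L, 2L))
  expect_equal(attr(vt, "fraction_polarized"), 1)

  # outgroup N -> unknown; third allele -> unknown and flagged
  og <- rep("A", 10); og[9] <- "N"; og[10] <- "G"
  vt2 <- polarize_variants(build_variant_table(aln), og)
  expect_true(is.na(vt2$sites$ancestral[1]))
  expect_true(is.na(vt2$sites$ancestral[2]))
  expect_equal(vt2$sites$ancestral_flag[2], "third_allele")

  # ancestral allele always among the segregating alleles
  for (seed in 6:9) {
    aln <- random_alignment(6, 150, seed)
    og <- sample(c(BASES, "N"), 150, TRUE)
    vt <- polarize_variants(build_variant_table(aln), og)
    known <- !is.na(vt$sites$ancestral)
    ok <- mapply(function(anc, all) anc %in% strsplit(all, ",")[[1]],
                 vt$sites$ancestral[known], vt$sites$alleles[known])
    expect_true(all(ok))
  }
})

test_that("haplotype extraction counts distinct full-locus sequences", {
  m <- rbind(s1 = strsplit("AAAA", "")[[1]], s2 = strsplit("AAAA", "")[[1]],
             s3 = strsplit("AAAT", "")[[1]], s4 = strsplit("AAAT", "")[[1]])
  hs <- extract_haplotypes(locus_alignment("h", m))
  expect_equal(hs$n_haplotypes, 2)
  expect_equal(hs$freq, c(0.5, 0.5))
  expect_equal(hs$F, 0.5)

  hs3 <- extract_haplotypes(toy3_alignment())
  expect_equal(hs3$n_haplotypes, 3)
  expect_equal(hs3$F, 1 / 3, tolerance = 1e-12)

  m[1, ] <- "A"
  m[] <- "A"
  hs1 <- extract_haplotypes(locus_alignment("same", m))
  expect_equal(hs1$n_haplotypes, 1)
  expect_equal(hs1$F, 1)

  # heavy-missing sample is excluded
  m2 <- rbind(s1 = rep("A", 10), s2 = rep("A", 10),
              s3 = c(rep("N", 5), rep("A", 5)))
  hs2 <- extract_haplotypes(locus_alignment("miss", m2))
  expect_equal(hs2$excluded, "s3")
  expect_equal(hs2$n, 2)
})

test_that("exports are deterministic and VCF preserves record counts", {
  aln <- random_alignment(6, 200, 11)
  vt <- build_variant_table(aln)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  tabs <- list(sites = vt$sites)
  export_results(tabs, d1, summary = list(seed = 11))
  export_results(tabs, d2, summary = list(seed = 11))
  expect_identical(readLines(file.path(d1, "sites.tsv")),
                   readLines(file.path(d2, "sites.tsv")))

  vcf <- file.path(d1, "out.vcf")
  write_variant_vcf(vt, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), vt$n_snps)
  # haploid GT, 1-based positions
  first <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(first[2]), vt$sites$position[1] + 1L)
  expect_true(all(strsplit(first[10], ",")[[1]] %in% c(".", "0", "1", "2")))
})

test_that("synthetic study write/read round-trip is exact", {
  st <- generate_study(study_scenario(n_loci = 2, mtdna_fragments = 1),
                       seed = 21)
  dir <- withr::local_tempdir()
  write_study(st$study, dir)
  re <- load_study(file.path(dir, "config.json"))
  for (lid in names(st$study$alignments)) {
    expect_equal(re$alignments[[lid]]$seqs, st$study$alignments[[lid]]$seqs)
    expect_equal(re$alignments[[lid]]$outgroup,
                 st$study$alignments[[lid]]$outgroup)
  }
  expect_equal(re$samples, st$study$samples)
  expect_equal(re$mtdna_loci, st$study$mtdna_loci)
})
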