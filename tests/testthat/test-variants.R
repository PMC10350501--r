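test_that("substitutions classify by purine/pyrimidine class", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "T"), "transversion")
  expect_equal(classify_substitution(c("G", "T"), c("A", "C")),
               c("transition", "transition"))
  expect_error(classify_substitution("N", "A"), "single bases")
  expect_error(classify_substitution("AC", "A"), "single bases")
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("a uniformly random substitution process has Ti/Tv near 0.5", {
  set.seed(19)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 20000, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  cls <- classify_substitution(ref, alt)
  # 4 of 12 ordered pairs are transitions
  expect_lt(abs(sum(cls == "transition") / sum(cls == "transversion") - 0.5),
            0.03)
})

test_that("per-sample summaries count zygosity and Ti/Tv correctly", {
  sites <- dplyr::bind_rows(
    make_sites("chr1", 100, "A", "G",
               list(S1 = list(gt = "0/1", ad_ref = 5, ad_alt = 5),
                    S2 = list(gt = "0/0", ad_ref = 10, ad_alt = 0))),
    make_sites("chr1", 200, "C", "T",
               list(S1 = list(gt = "1/1", ad_ref = 0, ad_alt = 9),
                    S2 = list(gt = "0/1", ad_ref = 4, ad_alt = 6))),
    make_sites("chr1", 300, "A", "T",
               list(S1 = list(gt = "1/1", ad_ref = 0, ad_alt = 8),
                    S2 = list(gt = "./.", ad_ref = 0, ad_alt = 0))),
    make_sites("chr1", 400, "A", "AT",
               list(S1 = list(gt = "0/1", ad_ref = 3, ad_alt = 4),
                    S2 = list(gt = "0/0", ad_ref = 11, ad_alt = 0))),
    make_sites("chr1", 500, "ACGT", "A",
               list(S1 = list(gt = "0/0", ad_ref = 12, ad_alt = 0),
                    S2 = list(gt = "1/1", ad_ref = 0, ad_alt = 7)))
  )
  s1 <- sample_summary(sites, "S1")
  expect_equal(s1$n_snp, 3)
  expect_equal(s1$n_ins, 1)
  expect_equal(s1$n_del, 0)
  expect_equal(s1$transition, 2)
  expect_equal(s1$transversion, 1)
  expect_equal(s1$het + s1$hom, s1$n_variants)
  expect_equal(s1$het, 2)
  expect_equal(s1$hom, 2)

  s2 <- sample_summary(sites, "S2")
  expect_equal(s2$n_variants, 2) # 0/0 and ./. sites are not carried
  expect_equal(s2$het + s2$hom, s2$n_variants)

  # record order is irrelevant
  perm <- sites[sample(nrow(sites)), ]
  expect_equal(sample_summary(perm, "S1"), s1)
  expect_error(sample_summary(sites, "nope"), "unknown sample")
})

test_that("Ti/Tv ratios round half-up to two decimals", {
  expect_equal(titv_ratio(1509021, 699275), 2.16)
  expect_equal(titv_ratio(11647053, 5266567), 2.21)
  expect_equal(titv_ratio(215, 100), 2.15) # exact boundary stays put
  expect_equal(titv_ratio(2155, 1000), 2.16) # .155 rounds up, not to even
  expect_true(is.na(titv_ratio(5, 0)))
})

test_that("indel spectrum keys signed lengths and recovers planted spectra", {
  sites <- dplyr::bind_rows(
    make_sites("chr1", 10, "A", "ATT",
               list(S = list(gt = "0/1", ad_ref = 5, ad_alt = 5))),
    make_sites("chr1", 20, "ACGT", "A",
               list(S = list(gt = "1/1", ad_ref = 0, ad_alt = 9))),
    make_sites("chr1", 30, "G", "GAA",
               list(S = list(gt = "0/1", ad_ref = 4, ad_alt = 4))),
    make_sites("chr1", 40, "C", "A",
               list(S = list(gt = "1/1", ad_ref = 0, ad_alt = 9)))
  )
  sp <- indel_length_spectrum(sites, "S")
  expect_equal(sp$length, c(-3L, 2L))
  expect_equal(sp$n, c(1L, 2L))
  expect_equal(attr(sp, "totals"),
               c(insertions = 2L, deletions = 1L))

  # planted genome-level spectrum is recovered exactly for the donor parent
  gm <- genome_model(n_chrom = 1, chrom_length = 1e6, markers_per_chrom = 200,
                     indel_fraction = 0.3, indel_lengths = c(-2, 1, 3),
                     seed = 31)
  dos <- matrix(2L, 4, 200,
                dimnames = list(sprintf("L%04d", 1:4),
                                paste0("chr1:", gm$markers$pos)))
  pop <- make_pop(dos, gm)
  sites2 <- simulate_bulk_depths(pop, "L0001", "L0002", depth_model(), seed = 32)
  sp2 <- indel_length_spectrum(sites2, "P2") # donor carries every marker
  truth <- table(nchar(gm$markers$alt) - nchar(gm$markers$ref))
  truth <- truth[names(truth) != "0"]
  expect_equal(setNames(sp2$n, sp2$length), setNames(as.integer(truth), names(truth)))
})

test_that("impact tallies recover planted classes and reject unknown labels", {
  gm <- genome_model(n_chrom = 1, chrom_length = 1e6, markers_per_chrom = 50,
                     impact_probs = c(HIGH = 0.2, MODERATE = 0.3,
                                      LOW = 0.2, MODIFIER = 0.3),
                     seed = 41)
  dos <- matrix(2L, 4, 50,
                dimnames = list(sprintf("L%04d", 1:4),
                                paste0("chr1:", gm$markers$pos)))
  pop <- make_pop(dos, gm)
  sites <- simulate_bulk_depths(pop, "L0001", "L0002", depth_model(), seed = 42)
  f <- tempfile(fileext = ".vcf.gz")
  write_variant_vcf(sites, f)
  back <- read_variant_vcf(f)
  tal <- impact_tally(back, "P2")
  want <- table(factor(gm$markers$impact,
                       c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  expect_equal(as.integer(tal), as.integer(want))

  bad <- sites
  bad$impact <- "SEVERE"
  expect_error(impact_tally(bad, "P2"), "SEVERE")

  none <- sites[0, ]
  expect_equal(as.integer(impact_tally(none, "P2")), rep(0L, 4))
})

test_that("multiallelic VCF records decompose into biallelic ones", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:AD\t0/1:4,5,0\t1/2:1,6,7",
    "chr1\t200\t.\tC\tT\t.\tPASS\tIMPACT=HIGH;CSQ=stop_gained\tGT:AD\t1/1:0,9\t0/0:8,0"
  ), f)
  sites <- read_variant_vcf(f)
  expect_equal(nrow(sites), 6) # (2 alts + 1) x 2 samples
  a1 <- sites[sites$pos == 100 & sites$alt == "G", ]
  expect_equal(a1$gt[a1$sample == "S1"], "0/1")
  expect_equal(a1$ad_alt[a1$sample == "S1"], 5L)
  # S2 carries G and T: within the G-record its 1/2 genotype is unresolvable
  expect_equal(a1$gt[a1$sample == "S2"], "./.")
  a2 <- sites[sites$pos == 200, ]
  expect_equal(unique(a2$impact), "HIGH")
  expect_equal(unique(a2$consequence), "stop_gained")
  summ <- variant_summary_table(sites)
  expect_equal(summ$het + summ$hom, summ$n_variants)
})
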