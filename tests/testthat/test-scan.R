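test_that("SNP-index and delta obey their analytic corner cases", {
  expect_equal(snp_index(7, 0), 1)
  expect_equal(snp_index(5, 5), 0.5)
  expect_equal(snp_index(0, 9), 0)
  expect_true(is.na(snp_index(0, 0))) # undefined marker, skipped
  expect_equal(snp_index(c(1, 3), c(3, 1)), c(0.25, 0.75))
  expect_error(snp_index(-1, 3), "non-negative")

  expect_equal(delta_snp_index(1, 0), 1)
  expect_equal(delta_snp_index(0.5, 0.5), 0)
  expect_equal(delta_snp_index(0, 1), -1)
  expect_error(delta_snp_index(1.2, 0), "0, 1")
})

test_that("only opposite-homozygote parent sites with enough depth survive", {
  mk <- function(pos, gt_p1, gt_p2, dres, dsus, ad_res = NULL, ad_sus = NULL) {
    ad_res <- ad_res %||% c(dres - 2, 2)
    ad_sus <- ad_sus %||% c(dsus, 0)
    make_sites("chr1", pos, "A", "G",
               list(P1 = list(gt = gt_p1, ad_ref = 20, ad_alt = 0),
                    P2 = list(gt = gt_p2, ad_ref = 0, ad_alt = 20),
                    bulk_res = list(gt = "0/1", ad_ref = ad_res[1], ad_alt = ad_res[2]),
                    bulk_sus = list(gt = "0/0", ad_ref = ad_sus[1], ad_alt = ad_sus[2])))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  sites <- dplyr::bind_rows(
    mk(100, "0/0", "1/1", 40, 40), # informative
    mk(200, "0/0", "1/1", 9, 30), # shallow resistant bulk
    mk(300, "0/0", "0/0", 40, 40), # parents agree
    mk(400, "./.", "1/1", 40, 40), # missing parent
    mk(500, "1/1", "0/0", 30, 30, c(6, 24), c(24, 6)) # donor is REF here
  )
  rec <- filter_informative_sites(sites, min_depth = 10)
  expect_equal(rec$pos, c(100, 500))
  drops <- attr(rec, "dropped")
  expect_equal(drops$n[drops$reason == "depth"], 1)
  expect_equal(drops$n[drops$reason == "non_informative"], 1)
  expect_equal(drops$n[drops$reason == "missing_parent"], 1)

  # orientation: at pos 500 the donor allele is REF, so DepM = ad_ref
  r5 <- rec[rec$pos == 500, ]
  expect_equal(r5$dep_m_res, 6)
  expect_equal(r5$index_res, 0.2)
  expect_equal(r5$index_sus, 0.8)
  expect_equal(r5$delta, -0.6)

  # a synthetic table with k informative sites keeps exactly k records
  gm <- genome_model(n_chrom = 1, chrom_length = 1e6, markers_per_chrom = 120,
                     seed = 51)
  dos <- matrix(rbinom(120 * 40, 2, 0.2), 40, 120,
                dimnames = list(sprintf("L%04d", 1:40),
                                paste0("chr1:", gm$markers$pos)))
  pop <- make_pop(dos, gm)
  full <- simulate_bulk_depths(pop, sprintf("L%04d", 1:20),
                               sprintf("L%04d", 21:40),
                               depth_model(mean_depth = 60), seed = 52)
  rec2 <- filter_informative_sites(full, min_depth = 10)
  deep <- full |>
    dplyr::filter(sample %in% c("bulk_res", "bulk_sus")) |>
    dplyr::group_by(pos) |>
    dplyr::summarise(ok = min(dp) >= 10)
  expect_equal(nrow(rec2), sum(deep$ok))
})

test_that("index and delta bounds hold on fuzzed depth tables", {
  set.seed(61)
  for (i in 1:20) {
    dm <- rpois(200, 5)
    dw <- rpois(200, 5)
    idx <- snp_index(dm, dw)
    ok <- !is.na(idx)
    expect_true(all(idx[ok] >= 0 & idx[ok] <= 1))
    d <- delta_snp_index(idx[ok], rev(idx[ok]))
    expect_true(all(d >= -1 & d <= 1))
  }
})

test_that("sliding windows average contained sites and mask sparse ones", {
  rec1 <- tibble::tibble(chrom = "chr1", pos = 500000L, index_res = 0.9,
                         index_sus = 0.5, delta = 0.4, dp_res = 40, dp_sus = 40)
  win <- sliding_windows(rec1, c(chr1 = 1e6), window = 1e6, step = 5000,
                         min_sites = 1)
  covering <- win[!is.na(win$delta), ]
  expect_true(all(covering$delta == 0.4))
  expect_true(all(covering$start <= 500000 & covering$end > 500000))
  expect_true(all(win$masked == (win$n_sites < 1)))

  expect_error(sliding_windows(rec1, window = 100, step = 5000), "window")

  # all-zero deltas average to zero everywhere
  rec0 <- tibble::tibble(chrom = "chr1", pos = seq(1000L, 999000L, 1000L),
                         index_res = 0.125, index_sus = 0.125, delta = 0,
                         dp_res = 40, dp_sus = 40)
  win0 <- sliding_windows(rec0, c(chr1 = 1e6))
  expect_true(all(win0$delta[!win0$masked] == 0))
})

test_that("window means match a brute-force recomputation on random sites", {
  set.seed(71)
  rec <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample.int(2e6, 1000),
    index_res = runif(1000), index_sus = runif(1000),
    dp_res = rpois(1000, 40), dp_sus = rpois(1000, 40)
  )
  rec$delta <- rec$index_res - rec$index_sus
  lens <- c(chr1 = 2e6, chr2 = 2e6)
  got <- sliding_windows(rec, lens, window = 1e6, step = 50000, min_sites = 5)
  want <- oracle_windows(rec, lens, window = 1e6, step = 50000)
  got <- got[order(got$chrom, got$start), ]
  want <- want[order(want$chrom, want$start), ]
  expect_equal(got$n_sites, want$n_sites)
  expect_equal(got$delta, want$delta)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("null thresholds match exact enumeration and shrink with depth", {
  nm <- null_model(n_bulk = 30, reps = 10000)
  thr <- null_thresholds(nm, data.frame(dp_res = c(10, 40, 100),
                                        dp_sus = c(10, 40, 100)), seed = 5)
  exact <- oracle_null_quantile(30, 10, c(0.95, 0.99))
  expect_lt(abs(thr$thr_95[thr$dp_res == 10] - exact[1]), 0.01)
  expect_lt(abs(thr$thr_99[thr$dp_res == 10] - exact[2]), 0.01)
  # monotone non-increasing in depth at every level
  expect_true(all(diff(thr$thr_95) <= 0))
  expect_true(all(diff(thr$thr_99) <= 0))
  expect_lt(thr$thr_95[thr$dp_res == 100], thr$thr_95[thr$dp_res == 10])
  # zero-depth windows get no threshold
  thr0 <- null_thresholds(nm, data.frame(dp_res = 0, dp_sus = 10), seed = 5)
  expect_true(is.na(thr0$thr_95))
  expect_error(null_model(reps = 10), "reps")
})

test_that("candidate regions reproduce the printed geometry", {
  # a run of significant windows spanning 60,120,000-61,980,000 -> 1.86 Mb
  starts <- seq(60120000L, 60980000L, by = 5000L)
  w <- make_windows("chr18", starts, starts + 1e6, delta = 0.8)
  reg <- call_candidate_regions(w, level = 0.999, step = 5000)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 60120000L)
  expect_equal(reg$end, 61980000L)
  expect_equal(reg$length_mb, 1.86)
  expect_equal(reg$level_attained, 0.999)

  # 57,795,000-58,850,000 -> 1.06 Mb (the .x5 boundary rounds up)
  starts2 <- seq(57795000L, 57850000L, by = 5000L)
  w2 <- make_windows("chr25", starts2, starts2 + 1e6, delta = -0.7)
  reg2 <- call_candidate_regions(w2, level = 0.99, step = 5000)
  expect_equal(reg2$length_mb, 1.06)
  expect_equal(reg2$peak_delta, -0.7)

  # length always equals the half-up Mb rounding of the printed coordinates
  printed <- data.frame(start = c(60120000, 57795000, 58890000, 95745000),
                        end = c(61980000, 58850000, 60825000, 97150000),
                        mb = c(1.86, 1.06, 1.94, 1.41))
  expect_equal(region_length_mb(printed$start, printed$end), printed$mb)
})

test_that("regions merge within one step and split beyond it", {
  s <- c(1L, 5001L, 10001L, 100001L)
  w <- make_windows("chr1", s, s + 1e6, delta = c(0.9, 0.9, 0.9, 0.9))
  reg <- call_candidate_regions(w, level = 0.99, step = 5000)
  expect_equal(nrow(reg), 1) # heavy window overlap: everything merges
  # far-apart significant windows stay separate when windows are narrow
  s2 <- c(1L, 2001L, 50001L)
  w2 <- make_windows("chr1", s2, s2 + 1000L, delta = 0.9)
  reg2 <- call_candidate_regions(w2, level = 0.99, step = 2000)
  expect_equal(nrow(reg2), 2)
  expect_equal(reg2$n_windows, c(2L, 1L))

  # masked windows and sub-threshold deltas never seed a region
  w3 <- make_windows("chr1", 1L, 1e6, delta = 0.9, masked = TRUE)
  expect_equal(nrow(call_candidate_regions(w3, level = 0.99)), 0)
  w4 <- make_windows("chr1", 1L, 1e6, delta = 0.2)
  expect_equal(nrow(call_candidate_regions(w4, level = 0.99)), 0)

  # effective variants: HIGH/MODERATE sites inside the region bounds
  sites <- tibble::tibble(chrom = "chr1", pos = c(5e5, 7e5, 15e5 + 1e5),
                          impact = c("HIGH", "LOW", "MODERATE"),
                          consequence = c("stop_gained", "synonymous_variant",
                                          "missense_variant"))
  reg5 <- call_candidate_regions(
    make_windows("chr1", 1L, 1e6, delta = 0.9), level = 0.99, sites = sites
  )
  expect_equal(reg5$n_effective, 1L)
  expect_equal(reg5$effective[[1]]$consequence, "stop_gained")
})

test_that("the scan plot builds from windows and regions", {
  w <- make_windows("chr1", seq(1L, 50001L, 5000L),
                    seq(1L, 50001L, 5000L) + 1e6, delta = 0.1)
  reg <- call_candidate_regions(make_windows("chr1", 1L, 1e6, delta = 0.9))
  p <- plot_scan(w, reg)
  expect_s3_class(p, "ggplot")
})
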