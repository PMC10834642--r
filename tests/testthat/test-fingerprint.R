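# Peak detection, common-peak matching, reference fingerprint, similarity.

test_that("a single rendered Gaussian is detected with its area within 1%", {
  cfg0 <- fix_cfg0()
  pt <- tibble::tibble(sample_id = "X", condition_id = "ref", channel = "210",
                       peak_id = "saikosaponin_a", rt_min = 13.838,
                       area = 191429, height = NA_real_)
  chrom <- simulate_chromatogram(cfg0, pt, seed = 1)
  pk <- detect_peaks(chrom)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, 191429, tolerance = 0.01)
  expect_equal(pk$rt_min, 13.838, tolerance = 0.02)
})

test_that("two well-separated Gaussians give exactly two peaks, noise alone none", {
  cfg0 <- fix_cfg0()
  pt <- tibble::tibble(sample_id = "X", condition_id = "ref",
                       channel = "210", peak_id = c("p1", "p2"),
                       rt_min = c(10, 10.5), area = c(5e4, 8e4),
                       height = NA_real_)
  chrom <- simulate_chromatogram(cfg0, pt, seed = 1)
  pk <- detect_peaks(chrom)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$area, c(5e4, 8e4), tolerance = 0.01)
  # pure noise trace at the default noise level: no detections
  cfgN <- fix_cfg(baseline_noise_sd = 4000, seed = 2)
  noise_only <- simulate_chromatogram(cfgN, pt[0, ], seed = 21)
  expect_equal(nrow(detect_peaks(noise_only)), 0)
  # flat trace: empty result, not an error
  flat <- noise_only
  flat$intensity <- rep(0, length(flat$intensity))
  expect_equal(nrow(detect_peaks(flat)), 0)
})

test_that("detection on a full rendered sample recovers the peak-table areas", {
  cfg0 <- fix_cfg0()
  pt <- simulate_peak_table(cfg0, 1, replicate_seed = 3)
  chrom <- simulate_chromatogram(cfg0, pt, channel = "210", seed = 1)
  pk <- detect_peaks(chrom)
  truth <- pt[pt$channel == "210", ]
  expect_equal(nrow(pk), nrow(truth))
  truth <- truth[order(truth$rt_min), ]
  expect_equal(pk$area, truth$area, tolerance = 0.01)
})

test_that("common-peak matching applies the all-samples rule", {
  base <- tibble::tibble(sample_id = "A", condition_id = "ref",
                         channel = "210", peak_id = paste0("p", 1:3),
                         rt_min = c(5, 10, 15), area = c(1, 2, 3) * 1e4,
                         height = 1)
  b <- base; b$sample_id <- "B"; b$rt_min <- b$rt_min + 0.03
  c_ <- base; c_$sample_id <- "C"; c_$rt_min <- c_$rt_min - 0.02
  # identical layouts: every peak common
  all3 <- match_common_peaks(list(base, b, c_))
  expect_equal(nrow(all3$peaks), 3)
  expect_true(all(diff(all3$peaks$consensus_rt_min) > 0))
  # one sample missing one peak: that peak is no longer common
  c_drop <- c_[c_$peak_id != "p2", ]
  two <- match_common_peaks(list(base, b, c_drop))
  expect_equal(nrow(two$peaks), 2)
  expect_equal(two$peaks$consensus_rt_min, c(5, 15), tolerance = 0.05)
  # permutation invariance of sample order
  perm <- match_common_peaks(list(c_, base, b))
  expect_equal(perm$peaks$consensus_rt_min, all3$peaks$consensus_rt_min)
  expect_equal(perm$areas[rownames(all3$areas), ], all3$areas)
})

test_that("default 20-batch study yields 17 common peaks", {
  cfg <- fix_cfg()
  pts <- simulate_study(cfg, seed = 5)
  common <- match_common_peaks(pts, rt_tolerance = 0.1)
  expect_equal(nrow(common$peaks), 17)
  expect_equal(common$n_samples, 20)
})

test_that("reference fingerprint takes per-peak median or mean", {
  areas <- matrix(c(1, 2, 9, 4, 4, 4), nrow = 3,
                  dimnames = list(c("A", "B", "C"), c("P01", "P02")))
  common <- structure(list(
    peaks = tibble::tibble(common_peak_id = c("P01", "P02"),
                           consensus_rt_min = c(5, 10)),
    areas = areas, rts = areas, samples = c("A", "B", "C"), n_samples = 3L
  ), class = "common_peak_set")
  expect_equal(unname(reference_fingerprint(common, "median")), c(2, 4))
  expect_equal(unname(reference_fingerprint(common, "mean")), c(4, 4))
})

test_that("congruence similarity is bounded, scale-invariant and correct", {
  r <- c(3, 1, 4, 1, 5)
  expect_equal(similarity(r, r), 1)
  expect_equal(similarity(5 * r, r), 1)            # dilution invariance
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)    # orthogonal
  set.seed(8)
  for (i in 1:25) {
    x <- runif(6)
    s <- similarity(x, r[c(1:5, 3)])
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  # adding a peak with matched relative area never decreases similarity
  x <- c(2, 1, 3)
  ref <- c(4, 1, 2)
  s0 <- similarity(x, ref)
  s1 <- similarity(c(x, 5 * sum(x)), c(ref, 5 * sum(ref)))
  expect_gte(s1 + 1e-12, s0)
  expect_warning(s_zero <- similarity(c(0, 0), c(1, 1)), "all-zero")
  expect_equal(s_zero, 0)
  expect_error(similarity(c(1, 2), c(0, 0)), "all zero")
  # correlation option agrees with stats::cor
  expect_equal(similarity(x, ref, method = "correlation"), cor(x, ref))
})

test_that("similarity report scores every batch against the median reference", {
  cfg <- fix_cfg()
  pts <- simulate_study(cfg, seed = 5)
  common <- match_common_peaks(pts)
  rep <- similarity_report(common)
  expect_equal(nrow(rep), 20)
  expect_true(all(rep$similarity > 0 & rep$similarity <= 1))
  # batch-to-batch composition differences keep similarities below 1
  expect_true(any(rep$similarity < 0.9999))
})
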