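# Synthetic-data generator: exact arithmetic, condition scaling,
# determinism, chromatogram rendering.

test_that("noiseless peak areas follow the response lines exactly", {
  cfg0 <- fix_cfg0()
  a <- cfg0$analytes
  # pin one batch concentration to 100 ug/mL for saikosaponin a
  cfg0$concentrations[1, "saikosaponin_a"] <- 100
  pt <- simulate_peak_table(cfg0, 1, replicate_seed = 5)
  area_a <- pt$area[pt$peak_id == "saikosaponin_a"]
  expect_identical(area_a, 2015.2 * 100 - 10091)  # = 191429
  # every target matches slope * C + intercept exactly
  for (nm in a$name) {
    C <- cfg0$concentrations[1, nm]
    row <- a[a$name == nm, ]
    expect_identical(pt$area[pt$peak_id == nm],
                     unname(row$slope * C + row$intercept))
  }
})

test_that("condition scaling is exactly proportional in volume and inverse in flow", {
  cfg0 <- fix_cfg0()
  base <- default_condition()
  pt2 <- simulate_peak_table(cfg0, 3, base, replicate_seed = 9)
  v4 <- new_condition("BEH_C18", 35, 0.30, 4)
  pt4 <- simulate_peak_table(cfg0, 3, v4, replicate_seed = 9)
  expect_equal(pt4$area, 2 * pt2$area)
  f36 <- new_condition("BEH_C18", 35, 0.36, 2)
  ptf <- simulate_peak_table(cfg0, 3, f36, replicate_seed = 9)
  expect_equal(ptf$area, pt2$area * 0.30 / 0.36)
})

test_that("condition perturbation grids enumerate the stated levels", {
  temps <- perturb_condition(family = "temperature")
  expect_equal(vapply(temps, function(c) c$temperature, numeric(1)),
               c(28, 32, 35, 38))
  flows <- perturb_condition(family = "flow_rate")
  expect_equal(vapply(flows, function(c) c$flow_rate, numeric(1)),
               c(0.30, 0.32, 0.34, 0.36))
  cols <- perturb_condition(family = "column")
  expect_equal(vapply(cols, function(c) c$column_id, character(1)),
               c("BEH_C18", "HSS_T3"))
  vols <- perturb_condition(family = "injection_volume")
  expect_equal(vapply(vols, function(c) c$injection_volume, numeric(1)),
               1:4)
  # every family grid contains the base condition; unknown family errors
  base_id <- condition_id(default_condition())
  for (fam in c("column", "temperature", "flow_rate", "injection_volume")) {
    ids <- vapply(perturb_condition(family = fam), condition_id, character(1))
    expect_true(base_id %in% ids)
  }
  expect_error(perturb_condition(family = "gradient"), "unknown")
  expect_length(condition_grid(), 11)
})

test_that("generators are deterministic in their seeds", {
  cfg <- fix_cfg()
  expect_identical(simulate_peak_table(cfg, 2, replicate_seed = 7),
                   simulate_peak_table(cfg, 2, replicate_seed = 7))
  expect_false(isTRUE(all.equal(
    simulate_peak_table(cfg, 2, replicate_seed = 7)$area,
    simulate_peak_table(cfg, 2, replicate_seed = 8)$area)))
  s1 <- simulate_calibration_series(cfg, "saikosaponin_e", noise_cv = 0.02,
                                    seed = 3)
  s2 <- simulate_calibration_series(cfg, "saikosaponin_e", noise_cv = 0.02,
                                    seed = 3)
  expect_identical(s1, s2)
  g1 <- simulate_condition_grid(cfg, seed = 4)
  g2 <- simulate_condition_grid(cfg, seed = 4)
  expect_identical(g1, g2)
  ch1 <- simulate_chromatogram(cfg, simulate_peak_table(cfg, 1, replicate_seed = 7),
                               seed = 11)
  ch2 <- simulate_chromatogram(cfg, simulate_peak_table(cfg, 1, replicate_seed = 7),
                               seed = 11)
  expect_identical(ch1$intensity, ch2$intensity)
})

test_that("noiseless calibration series sits exactly on the generating line", {
  cfg0 <- fix_cfg0()
  ser <- simulate_calibration_series(cfg0, "saikosaponin_d", n_levels = 5,
                                     noise_cv = 0)
  expect_equal(ser$area, 2132.2 * ser$concentration - 5982.5)
  fit <- lm(area ~ concentration, ser)
  expect_equal(unname(coef(fit)), c(-5982.5, 2132.2), tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("out-of-range concentrations are refused", {
  cfg0 <- fix_cfg0()
  cfg0$concentrations[1, "saikosaponin_b2"] <- 20  # range 0.6-14.4
  expect_error(simulate_peak_table(cfg0, 1, replicate_seed = 1),
               "outside linear range")
  expect_error(simulate_calibration_series(cfg0, "saikosaponin_a",
                                           n_levels = 2),
               "n_levels")
})

test_that("rendered chromatogram integrals match peak-table areas at zero noise", {
  cfg0 <- fix_cfg0()
  pt <- simulate_peak_table(cfg0, 1, replicate_seed = 2)
  for (ch in c("210", "254")) {
    chrom <- simulate_chromatogram(cfg0, pt, channel = ch, seed = 1)
    tot <- sum(diff(chrom$time) *
               (chrom$intensity[-1] + chrom$intensity[-length(chrom$intensity)]) / 2)
    expect_equal(tot, sum(pt$area[pt$channel == ch]), tolerance = 1e-3)
  }
  # empty peak table, zero noise: all-zero trace
  empty <- pt[0, ]
  chrom0 <- simulate_chromatogram(cfg0, empty, seed = 1)
  expect_true(all(chrom0$intensity == 0))
  expect_error(simulate_chromatogram(cfg0, pt, sampling_step = 0.2),
               "sampling_step")
})

test_that("true concentrations respect linear ranges and group structure", {
  cfg <- fix_cfg()
  a <- cfg$analytes
  m <- cfg$concentrations
  expect_true(all(m >= rep(a$range_low, each = nrow(m))))
  expect_true(all(m <= rep(a$range_high, each = nrow(m))))
  # configured group effects are recoverable as content-level ordering
  g <- default_batches()$group
  overall <- rowMeans(scale(m))
  means <- tapply(overall, g, mean)
  expect_gt(means[["south"]], means[["mid"]])
  expect_gt(means[["mid"]], means[["north"]])
})
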