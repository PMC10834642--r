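# Relative calibration factors, internal-reference selection,
# single-marker quantification, content, QAMS-vs-ESM comparison.

test_that("the factor of the reference against itself is exactly 1", {
  s <- data.frame(concentration = c(50, 100, 200), area = c(1e5, 2e5, 4e5))
  expect_identical(compute_rcf(s, s), 1)
})

test_that("single-level factor matches the hand-derived response ratio", {
  # independent arithmetic: areas of a and d at 100 ug/mL from their
  # response lines, factor = A_a / A_d at equal concentrations
  a_area <- 2015.2 * 100 - 10091     # 191429
  d_area <- 2132.2 * 100 - 5982.5    # 207237.5
  f <- compute_rcf(data.frame(concentration = 100, area = d_area),
                   data.frame(concentration = 100, area = a_area))
  expect_equal(f, a_area / d_area, tolerance = 1e-15)
  expect_equal(round(f, 4), 0.9237)
})

test_that("the factor is linear in areas and invariant to global rescaling", {
  s <- data.frame(concentration = c(50, 100), area = c(90000, 185000))
  i <- data.frame(concentration = c(40, 80), area = c(61000, 118000))
  f <- compute_rcf(s, i)
  i2 <- i; i2$area <- 2 * i2$area
  expect_equal(compute_rcf(s, i2), 2 * f, tolerance = 1e-12)
  # common detector rescaling cancels
  s3 <- s; s3$area <- 7 * s3$area
  i3 <- i; i3$area <- 7 * i3$area
  expect_equal(compute_rcf(s3, i3), f, tolerance = 1e-12)
  expect_error(compute_rcf(s, i[1, , drop = FALSE]), "level-matched")
  bad <- i; bad$area[1] <- -5
  expect_error(compute_rcf(s, bad), "positive")
})

test_that("factor reciprocity holds per level at matched concentrations", {
  cfg0 <- fix_cfg0()
  sa <- simulate_calibration_series(cfg0, "saikosaponin_a", noise_cv = 0)
  sd_ <- simulate_calibration_series(cfg0, "saikosaponin_d", noise_cv = 0)
  f_ad <- saikoqams:::rcf_per_level(sd_, sa)
  f_da <- saikoqams:::rcf_per_level(sa, sd_)
  expect_equal(f_ad * f_da, rep(1, length(f_ad)), tolerance = 1e-12)
})

test_that("stability table: identical series give zero RSD, reference row is exact", {
  cfg0 <- fix_cfg0()
  conds <- perturb_condition(family = "temperature")
  # zero wobble: conditions differ only by deterministic scaling, which
  # cancels in the factor -> all RSDs identically 0
  grid <- simulate_condition_grid(cfg0, conds, wobble_sd = 0, seed = 1)
  tb <- rcf_stability(grid, "saikosaponin_d")
  expect_true(all(tb$summary$rsd_percent < 1e-10))
  ir_row <- tb$summary[tb$summary$analyte == "saikosaponin_d", ]
  expect_identical(ir_row$mean_rcf, 1)
  expect_identical(ir_row$rsd_percent, 0)
  expect_true(all(tb$per_condition["saikosaponin_d", ] == 1))
  expect_error(rcf_stability(grid[grid$analyte != "saikosaponin_c" |
                                  grid$condition_id != grid$condition_id[1], ],
                             "saikosaponin_d"),
               "missing analyte saikosaponin_c")
})

test_that("reference selection screens on RSD and breaks ties by availability", {
  mk_table <- function(ir, rsds) {
    analytes <- names(rsds)
    structure(list(
      ir = ir, conditions = c("c1", "c2"),
      per_condition = matrix(1, length(analytes), 2,
                             dimnames = list(analytes, c("c1", "c2"))),
      summary = tibble::tibble(analyte = analytes, mean_rcf = 1,
                               rsd_percent = unname(rsds))
    ), class = "rcf_table")
  }
  rank <- c(x = 2L, y = 1L, z = 3L)
  zero <- c(x = 0, y = 0, z = 0)
  # one candidate with all-zero RSDs wins outright
  one <- list(x = mk_table("x", zero))
  expect_equal(select_ir(one, rank)$ir, "x")
  # identical summary RSDs: better availability rank wins (both orderings)
  two <- list(x = mk_table("x", c(x = 0, y = 1, z = 1)),
              y = mk_table("y", c(x = 1, y = 0, z = 1)))
  expect_equal(select_ir(two, rank)$ir, "y")
  expect_equal(select_ir(two, rank, order_by = "rsd")$ir, "y")
  # strict rsd ordering prefers the lower summary RSD over availability
  three <- list(x = mk_table("x", c(x = 0, y = 0.5, z = 0.5)),
                y = mk_table("y", c(x = 2, y = 0, z = 2)))
  expect_equal(select_ir(three, rank, order_by = "rsd")$ir, "x")
  # failing the 5% screen reports every summary RSD
  bad <- list(x = mk_table("x", c(x = 0, y = 9, z = 9)),
              y = mk_table("y", c(x = 8, y = 0, z = 8)))
  expect_error(select_ir(bad, rank), "no candidate passes")
})

test_that("zero-noise zero-intercept pipeline: QAMS = ESM = truth exactly", {
  cfgz <- fix_cfg_zero_intercept()
  curves <- lapply(cfgz$analytes$name, function(nm)
    fit_calibration(simulate_calibration_series(cfgz, nm, noise_cv = 0), nm))
  names(curves) <- cfgz$analytes$name
  grid <- simulate_condition_grid(cfgz, wobble_sd = 0, seed = 1)
  tb <- rcf_stability(grid, "saikosaponin_d")
  pt <- simulate_peak_table(cfgz, 4, replicate_seed = 3)
  q <- quantify_qams(pt, curves$saikosaponin_d, tb)
  e <- quantify_esm(pt, curves)
  truth <- cfgz$concentrations[4, q$analyte]
  expect_equal(q$concentration, unname(truth), tolerance = 1e-9)
  expect_equal(e$concentration, unname(cfgz$concentrations[4, e$analyte]),
               tolerance = 1e-9)
  cmp <- compare_qams_esm(q, e)
  expect_lt(max(cmp$pairs$re_percent), 1e-8)
})

test_that("quantification of the reference analyte is self-consistent", {
  cfg <- fix_cfg()
  curves <- lapply(cfg$analytes$name, function(nm)
    fit_calibration(simulate_calibration_series(cfg, nm, noise_cv = 0), nm))
  names(curves) <- cfg$analytes$name
  grid <- simulate_condition_grid(cfg, seed = 5)
  tb <- rcf_stability(grid, "saikosaponin_d")
  pt <- simulate_peak_table(cfg, 1, replicate_seed = 11)
  q <- quantify_qams(pt, curves$saikosaponin_d, tb)
  e <- quantify_esm(pt, curves)
  d_q <- q$concentration[q$analyte == "saikosaponin_d"]
  d_e <- e$concentration[e$analyte == "saikosaponin_d"]
  expect_equal(d_q, d_e, tolerance = 1e-12)  # F = 1, same curve
  # halving the factor doubles the concentration
  tb2 <- tb
  tb2$summary$mean_rcf <- tb$summary$mean_rcf / 2
  q2 <- quantify_qams(pt, curves$saikosaponin_d, tb2)
  expect_equal(q2$concentration, 2 * q$concentration, tolerance = 1e-12)
  # missing reference peak errors
  pt_no_ir <- pt[pt$peak_id != "saikosaponin_d", ]
  expect_error(quantify_qams(pt_no_ir, curves$saikosaponin_d, tb),
               "missing")
})

test_that("content converts concentration to mg/g with the workup defaults", {
  expect_equal(content(2000), 50)  # 25 mL, 1.0 g
  expect_equal(content(0), 0)
  expect_equal(content(2000, extract_volume = 50), 100)  # linear in V
  expect_equal(content(2000, sample_mass = 2), 25)
  expect_error(content(2000, extract_volume = 0), "extract_volume")
  expect_error(content(-1), "concentration")
})

test_that("method comparison computes relative deviations and catches mismatches", {
  q <- tibble::tibble(sample_id = "S1", analyte = c("a", "b"),
                      method = "QAMS", concentration = c(105, 100))
  e <- tibble::tibble(sample_id = "S1", analyte = c("a", "b"),
                      method = "ESM", concentration = c(100, 100))
  cmp <- compare_qams_esm(q, e)
  expect_equal(cmp$pairs$re_percent, c(5, 0))
  expect_equal(cmp$by_analyte$max_re_percent[cmp$by_analyte$analyte == "a"], 5)
  e_missing <- e[e$analyte != "b", ]
  expect_error(compare_qams_esm(q, e_missing), "unmatched")
})
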