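# Synthetic data generators: peak tables, calibration series, condition
# grids, and rendered chromatograms.

# Deterministic condition -> area scaling. Detector load grows linearly with
# injected volume and inversely with flow rate (band dilution); the nominal
# state (2 uL, 0.30 mL/min) has factor 1.
condition_area_factor <- function(cond) {
  (cond$injection_volume / 2) * (0.30 / cond$flow_rate)
}

# Deterministic condition -> retention-time shift (minutes). Temperature
# moves retention by -0.02 min/degC away from 35 degC; the HSS T3 column
# retains everything 0.15 min longer. Flow and volume leave Rt unchanged.
condition_rt_shift <- function(cond) {
  -0.02 * (cond$temperature - 35) + if (cond$column_id == "HSS_T3") 0.15 else 0
}

# Noiseless expected peak area for one analyte row at concentration conc
# under condition cond: (slope * C + intercept) scaled by the condition
# factor. Refuses concentrations outside the declared linear range.
expected_area <- function(analyte_row, conc, cond = default_condition()) {
  out <- conc < analyte_row$range_low | conc > analyte_row$range_high
  if (any(out)) {
    stop(sprintf(
      "concentration %.4g ug/mL outside linear range [%g, %g] for %s",
      conc[which(out)[1]], analyte_row$range_low, analyte_row$range_high,
      analyte_row$name), call. = FALSE)
  }
  (analyte_row$slope * conc + analyte_row$intercept) * condition_area_factor(cond)
}

#' Simulate one sample's peak table
#'
#' Generates the detected-peak table for one batch measured under one
#' instrument condition: one peak per target analyte with expected area
#' `slope * C + intercept` scaled by the condition (area proportional to
#' injection volume, inverse to flow rate) under multiplicative lognormal
#' noise of CV `config$area_noise_cv`, plus the configured non-target common
#' peaks. Retention times carry the deterministic condition drift plus
#' Gaussian jitter. Peak heights assume Gaussian peaks of the configured
#' sigma. Identical `(config, batch, condition, replicate_seed)` inputs give
#' bit-identical tables.
#'
#' @param config A [sim_config()].
#' @param batch Batch index (1-based) or `sample_id` string.
#' @param condition An `instrument_condition` (default the reference
#'   condition).
#' @param replicate_seed Integer seed for this injection's noise draw.
#' @return A peak-table tibble: `sample_id`, `condition_id`, `channel`,
#'   `peak_id`, `rt_min`, `area`, `height`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' simulate_peak_table(cfg, 1, replicate_seed = 42)
simulate_peak_table <- function(config, batch,
                                condition = default_condition(),
                                replicate_seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_condition(condition)
  if (is.character(batch)) batch <- match(batch, config$batches$sample_id)
  if (is.na(batch) || batch < 1 || batch > nrow(config$batches))
    stop("batch out of range", call. = FALSE)

  a <- config$analytes
  conc <- config$concentrations[batch, a$name]
  nominal <- vapply(seq_len(nrow(a)), function(i)
    expected_area(a[i, ], conc[[i]], condition), numeric(1))

  # Per-batch extra-peak composition: fixed per batch across replicates.
  ep <- config$extra_peaks
  ep_factor <- with_seed(derive_seed(config$seed, 1000L + batch),
                         noise_multiplier(nrow(ep), config$extra_peak_cv))
  ep_nominal <- ep$area * ep_factor * condition_area_factor(condition)

  rt_shift <- condition_rt_shift(condition)
  with_seed(replicate_seed, {
    n_all <- nrow(a) + nrow(ep)
    noise <- noise_multiplier(n_all, config$area_noise_cv)
    jitter <- if (config$rt_jitter_sd > 0)
      stats::rnorm(n_all, 0, config$rt_jitter_sd) else rep(0, n_all)
    area <- c(nominal, ep_nominal) * noise
    sigma <- c(a$peak_width_sigma, ep$peak_width_sigma)
    tbl <- tibble::tibble(
      sample_id = config$batches$sample_id[batch],
      condition_id = condition_id(condition),
      channel = c(a$channel, ep$channel),
      peak_id = c(a$name, ep$peak_id),
      rt_min = c(a$rt_min, ep$rt_min) + rt_shift + jitter,
      area = area,
      height = area * gauss_gain(sigma)
    )
    tbl[order(tbl$rt_min), ]
  })
}

#' Simulate a calibration dilution series for one analyte
#'
#' Concentration levels are linearly spaced over the analyte's linear range
#' (optionally a sub-span of it) and areas follow the analyte's response
#' line under multiplicative lognormal noise, at the reference condition.
#'
#' @param config A [sim_config()].
#' @param analyte Analyte name (a row of `config$analytes`).
#' @param n_levels Number of levels (>= 3; default 6).
#' @param noise_cv Multiplicative area-noise CV (0 for an exact line).
#' @param seed Integer seed for the noise draw.
#' @param span Two fractions of the linear range delimiting the series,
#'   default `c(0, 1)` (the full range).
#' @return A tibble `concentration`, `area`, `height`, ordered by
#'   concentration, with the analyte name in column `analyte`.
#' @export
simulate_calibration_series <- function(config, analyte, n_levels = 6,
                                        noise_cv = 0, seed = 1,
                                        span = c(0, 1)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_levels < 3) stop("n_levels must be >= 3", call. = FALSE)
  row <- config$analytes[config$analytes$name == analyte, ]
  if (nrow(row) != 1L) stop("unknown analyte: ", analyte, call. = FALSE)
  if (length(span) != 2L || span[1] < 0 || span[2] > 1 || span[1] >= span[2])
    stop("span must be increasing fractions within [0, 1]", call. = FALSE)
  width <- row$range_high - row$range_low
  conc <- seq(row$range_low + span[1] * width,
              row$range_low + span[2] * width, length.out = n_levels)
  nominal <- expected_area(row, conc)
  with_seed(seed, {
    area <- nominal * noise_multiplier(n_levels, noise_cv)
    tibble::tibble(analyte = row$name, concentration = conc, area = area,
                   height = area * gauss_gain(row$peak_width_sigma))
  })
}

#' Simulate standard-mixture responses across an instrument-condition grid
#'
#' Emulates the robustness experiment behind internal-reference selection:
#' the standard mixture is measured, as an `n_levels`-point dilution
#' gradient, under every condition of the four perturbation families. Each
#' (condition, analyte) pair receives one multiplicative response wobble of
#' sd `wobble_sd` (run-to-run detector fluctuation; this is what makes the
#' relative-calibration-factor RSDs nonzero), and each area additionally
#' carries lognormal noise of CV `noise_cv`.
#'
#' @param config A [sim_config()].
#' @param conditions List of `instrument_condition`s (default the full
#'   [condition_grid()], 11 unique conditions).
#' @param n_levels Gradient levels per condition (default 6).
#' @param wobble_sd Per-(condition, analyte) lognormal response wobble sd
#'   (default 0.005, i.e. 0.5%).
#' @param noise_cv Additional per-area lognormal noise CV (default 0).
#' @param seed Integer seed.
#' @param span Fractional span of each linear range for the gradient;
#'   default `c(0.2, 1)` — factor determination uses working
#'   concentrations, where the response is effectively proportional.
#' @return A long tibble: `condition_id`, `analyte`, `level`,
#'   `concentration`, `area`.
#' @export
simulate_condition_grid <- function(config,
                                    conditions = condition_grid(),
                                    n_levels = 6, wobble_sd = 0.005,
                                    noise_cv = 0, seed = 1,
                                    span = c(0.2, 1)) {
  stopifnot(inherits(config, "sim_config"))
  a <- config$analytes
  with_seed(seed, {
    out <- lapply(seq_along(conditions), function(j) {
      cond <- conditions[[j]]
      validate_condition(cond)
      wobble <- if (wobble_sd > 0)
        exp(stats::rnorm(nrow(a), 0, wobble_sd)) else rep(1, nrow(a))
      per_analyte <- lapply(seq_len(nrow(a)), function(i) {
        row <- a[i, ]
        width <- row$range_high - row$range_low
        conc <- seq(row$range_low + span[1] * width,
                    row$range_low + span[2] * width, length.out = n_levels)
        area <- expected_area(row, conc, cond) * wobble[i] *
          noise_multiplier(n_levels, noise_cv)
        tibble::tibble(condition_id = condition_id(cond), analyte = row$name,
                       level = seq_len(n_levels), concentration = conc,
                       area = area)
      })
      dplyr::bind_rows(per_analyte)
    })
    dplyr::bind_rows(out)
  })
}

#' Render a chromatogram from a peak table
#'
#' Sum of Gaussian peaks (area and retention time from the peak table,
#' sigma from the analyte/extra-peak specs) on an even time grid over
#' `[0, run_length]`, plus white baseline noise, for one detection channel.
#'
#' @param config A [sim_config()].
#' @param peak_table A peak-table tibble (one sample).
#' @param channel Detection channel to render (`"210"` or `"254"`).
#' @param sampling_step Grid step in minutes; must be at most one third of
#'   the narrowest peak sigma (default 0.01).
#' @param seed Integer seed for the baseline noise.
#' @return A list of class `chromatogram`: `sample_id`, `channel`,
#'   `time` (minutes), `intensity`.
#' @export
simulate_chromatogram <- function(config, peak_table, channel = "210",
                                  sampling_step = 0.01, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  sigmas <- c(stats::setNames(config$analytes$peak_width_sigma,
                              config$analytes$name),
              stats::setNames(config$extra_peaks$peak_width_sigma,
                              config$extra_peaks$peak_id))
  min_sigma <- if (length(sigmas)) min(sigmas) else 0.05
  if (sampling_step <= 0 || sampling_step > min_sigma / 3)
    stop("sampling_step must be positive and <= min peak sigma / 3",
         call. = FALSE)
  pk <- peak_table[peak_table$channel == channel, ]
  time <- seq(0, config$run_length, by = sampling_step)
  intensity <- numeric(length(time))
  for (i in seq_len(nrow(pk))) {
    sig <- unname(sigmas[pk$peak_id[i]])
    if (length(sig) != 1L || is.na(sig)) sig <- 0.05
    intensity <- intensity + pk$area[i] * gauss_gain(sig) *
      exp(-((time - pk$rt_min[i])^2) / (2 * sig^2))
  }
  with_seed(seed, {
    if (config$baseline_noise_sd > 0)
      intensity <- intensity +
        stats::rnorm(length(time), 0, config$baseline_noise_sd)
    structure(list(
      sample_id = if (nrow(pk)) pk$sample_id[1] else NA_character_,
      channel = channel, time = time, intensity = intensity
    ), class = "chromatogram")
  })
}

#' Simulate the full default study: all batches at the reference condition
#'
#' Convenience wrapper producing one peak table per batch (replicate seeds
#' derived from `seed`), bound into one long tibble.
#'
#' @param config A [sim_config()].
#' @param condition Measurement condition (default reference).
#' @param seed Integer seed from which per-batch replicate seeds derive.
#' @return A long peak-table tibble covering every batch.
#' @export
simulate_study <- function(config, condition = default_condition(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  dplyr::bind_rows(lapply(seq_len(nrow(config$batches)), function(b)
    simulate_peak_table(config, b, condition, derive_seed(seed, b))))
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram>", x$sample_id, "@", x$channel, "nm;",
      length(x$time), "points over", max(x$time), "min\n")
  invisible(x)
}
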