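#' Simulation configuration for the synthetic study
#'
#' Assembles the full specification of the synthetic chromatography study:
#' the analyte panel with its detector response lines, the batch metadata
#' with latitude-linked groups, the true per-batch concentration matrix,
#' and the noise / layout parameters used by the generators.
#'
#' The true concentration matrix is drawn once, deterministically from
#' `seed`: each analyte's baseline concentration sits at 45% of its linear
#' range, scaled by a multiplicative group effect (`group_effects`) and a
#' per-batch lognormal heterogeneity with coefficient of variation
#' `batch_cv`. The defaults (group effects 1.25 / 1.00 / 0.75 for the
#' south / mid / north latitude bands, batch CV 0.08) give a between-group
#' separation of roughly three within-group standard deviations, the regime
#' the chemometrics stage is expected to resolve. Concentrations are clamped
#' to stay strictly inside each analyte's linear range.
#'
#' @param analytes Analyte panel tibble (see [default_analytes()]).
#' @param batches Batch metadata tibble with `sample_id` and `group`
#'   columns (see [default_batches()]).
#' @param area_noise_cv Multiplicative (lognormal) coefficient of variation
#'   of peak areas per injection; default 0.02, matching replicate-injection
#'   RSDs of 1-3%.
#' @param rt_jitter_sd Gaussian retention-time jitter per peak, minutes.
#' @param baseline_noise_sd White baseline noise sd for rendered
#'   chromatograms, detector units.
#' @param n_extra_peaks Number of non-target peaks common to every batch
#'   (default 10, giving 17 common peaks with the 7 targets).
#' @param extra_peak_cv Lognormal CV of per-batch heterogeneity of the
#'   extra-peak areas (composition differences between batches).
#' @param extract_volume Extraction volume V, mL (default 25).
#' @param sample_mass Weighed sample mass M, g (default 1.0).
#' @param group_effects Named multiplicative content effects per group.
#' @param batch_cv Within-group lognormal CV of true concentrations.
#' @param run_length Chromatographic run length, minutes.
#' @param seed Integer seed fixing the drawn concentration matrix and the
#'   batch-level extra-peak factors.
#' @return A list of class `sim_config`; element `concentrations` is the
#'   batches x analytes matrix of true concentrations (ug/mL).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' dim(cfg$concentrations)
sim_config <- function(analytes = default_analytes(),
                       batches = default_batches(),
                       area_noise_cv = 0.02,
                       rt_jitter_sd = 0.02,
                       baseline_noise_sd = 4000,
                       n_extra_peaks = 10,
                       extra_peak_cv = 0.25,
                       extract_volume = 25,
                       sample_mass = 1.0,
                       group_effects = c(south = 1.25, mid = 1.00, north = 0.75),
                       batch_cv = 0.08,
                       run_length = 31,
                       seed = 101) {
  stopifnot(is.data.frame(analytes), is.data.frame(batches))
  if (area_noise_cv < 0) stop("area_noise_cv must be >= 0", call. = FALSE)
  if (!all(analytes$range_low < analytes$range_high))
    stop("each analyte needs range_low < range_high", call. = FALSE)
  if (!all(analytes$slope > 0)) stop("response slopes must be > 0", call. = FALSE)
  if (!all(batches$group %in% names(group_effects)))
    stop("every batch group needs an entry in group_effects", call. = FALSE)
  stopifnot_scalar_pos(extract_volume, "extract_volume")
  stopifnot_scalar_pos(sample_mass, "sample_mass")

  cfg <- list(
    analytes = analytes, batches = batches,
    area_noise_cv = area_noise_cv, rt_jitter_sd = rt_jitter_sd,
    baseline_noise_sd = baseline_noise_sd,
    n_extra_peaks = as.integer(n_extra_peaks),
    extra_peak_cv = extra_peak_cv,
    extract_volume = extract_volume, sample_mass = sample_mass,
    group_effects = group_effects, batch_cv = batch_cv,
    run_length = run_length, seed = as.integer(seed)
  )
  cfg$extra_peaks <- make_extra_peaks(cfg)
  cfg$concentrations <- make_concentration_matrix(cfg)
  structure(cfg, class = "sim_config")
}

# Non-target common peaks: fixed retention times away from every target Rt,
# slowly decaying nominal areas, all on the 210 nm channel.
make_extra_peaks <- function(cfg) {
  n <- cfg$n_extra_peaks
  if (n == 0L) {
    return(tibble::tibble(peak_id = character(), rt_min = numeric(),
                          area = numeric(), channel = character(),
                          peak_width_sigma = numeric()))
  }
  slots <- c(2.0, 3.5, 5.2, 6.6, 10.4, 12.1, 15.6, 20.5, 23.8, 26.9,
             4.4, 21.9, 25.3, 28.4, 29.6)
  if (n > length(slots))
    stop("at most ", length(slots), " extra peaks are supported", call. = FALSE)
  tibble::tibble(
    peak_id = sprintf("U%02d", seq_len(n)),
    rt_min = slots[seq_len(n)],
    area = 1e4 * seq(9, by = -0.65, length.out = n),
    channel = "210",
    peak_width_sigma = 0.05
  )
}

make_concentration_matrix <- function(cfg) {
  a <- cfg$analytes
  b <- cfg$batches
  base <- a$range_low + 0.45 * (a$range_high - a$range_low)
  eff <- unname(cfg$group_effects[b$group])
  with_seed(derive_seed(cfg$seed, 1L), {
    sdlog <- sqrt(log(1 + cfg$batch_cv^2))
    het <- matrix(exp(stats::rnorm(nrow(b) * nrow(a), -sdlog^2 / 2, sdlog)),
                  nrow = nrow(b))
    m <- outer(eff, base) * het
    # keep true values strictly inside the declared linear ranges
    lo <- a$range_low + 0.01 * (a$range_high - a$range_low)
    hi <- a$range_high - 0.01 * (a$range_high - a$range_low)
    m <- pmin(pmax(m, rep(lo, each = nrow(b))), rep(hi, each = nrow(b)))
    dimnames(m) <- list(b$sample_id, a$name)
    m
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", nrow(x$batches), "batches x", nrow(x$analytes),
      "analytes;", x$n_extra_peaks, "extra peaks; area CV",
      x$area_noise_cv, "; seed", x$seed, "\n")
  invisible(x)
}
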