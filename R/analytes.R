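#' Default saikosaponin analyte panel
#'
#' The seven saikosaponins quantified by the UPLC-PDA method, with their
#' detector response lines (peak area = slope * concentration + intercept,
#' concentration in ug/mL), retention times on the 31-minute gradient,
#' linear ranges, and detection channel. Saikosaponin b2 is read at 254 nm,
#' the other six at 210 nm. `peak_width_sigma` is the Gaussian peak sigma
#' (minutes) used when rendering chromatograms; `availability_rank` orders
#' the standards by how cheap/abundant they are (saikosaponin d first: it is
#' the most abundant saikosaponin in the root and the cheapest standard,
#' about a quarter of the price of saikosaponin e).
#'
#' @return A tibble with one row per analyte: `name`, `rt_min`, `slope`,
#'   `intercept`, `range_low`, `range_high` (ug/mL), `channel` ("210"/"254"),
#'   `peak_width_sigma` (min), `availability_rank`.
#' @export
#' @examples
#' default_analytes()
default_analytes <- function() {
  tibble::tibble(
    name = c("saikosaponin_a", "saikosaponin_b1", "saikosaponin_b2",
             "saikosaponin_c", "saikosaponin_d", "saikosaponin_e",
             "saikosaponin_f"),
    rt_min = c(13.838, 17.176, 14.407, 8.553, 18.937, 17.803, 8.871),
    slope = c(2015.2, 2679.1, 9033.5, 1255.6, 2132.2, 1994.3, 1357.7),
    intercept = c(-10091, -2189, -823.95, -1936.3, -5982.5, -991.36, -865.23),
    range_low = c(7.60, 3.10, 0.60, 16.0, 31.7, 4.00, 4.80),
    range_high = c(400, 100, 14.4, 243, 475, 83.0, 150),
    channel = c("210", "210", "254", "210", "210", "210", "210"),
    peak_width_sigma = 0.05,
    availability_rank = c(2L, 3L, 4L, 5L, 1L, 6L, 7L)
  )
}

#' Default 20-batch sample metadata
#'
#' The twenty root batches with their production regions and coordinates.
#' Batches are grouped by latitude band (`south` < 35 deg N, `mid` 35-38,
#' `north` > 38): saikosaponin accumulation is latitude-sensitive, and the
#' synthetic concentration generator gives the southern band the highest
#' contents and the northern band the lowest.
#'
#' @return A tibble: `sample_id`, `region`, `longitude`, `latitude`,
#'   `source`, `group`.
#' @export
default_batches <- function() {
  b <- tibble::tibble(
    sample_id = paste0("S", 1:20),
    region = c("Baoji, Shaanxi", "Baoji, Shaanxi", "Chengde, Hebei",
               "Luoyang, Henan", "Jiangxian, Shanxi", "Jishan, Shanxi",
               "Shiyan, Hubei", "Haidian, Beijing", "Baokang, Hubei",
               "Qingyang, Gansu", "Wanrong, Shanxi", "Wenxi, Shanxi",
               "Chifeng, Inner Mongolia", "Liangcheng, Inner Mongolia",
               "Chengcheng, Shaanxi", "Qingyang, Gansu", "Dingxi, Gansu",
               "Chifeng, Inner Mongolia", "Pingshun, Shanxi",
               "Fangshan, Beijing"),
    longitude = c(107.735, 107.735, 117.340, 112.092, 111.575, 110.989,
                  111.734, 116.305, 111.234, 107.649, 110.845, 111.231,
                  118.896, 112.511, 109.938, 107.649, 104.632, 118.896,
                  113.443, 116.149),
    latitude = c(34.356, 34.356, 40.948, 34.141, 35.497, 35.610, 32.047,
                 39.965, 31.749, 35.715, 35.421, 35.363, 42.262, 40.537,
                 35.197, 35.715, 35.587, 42.262, 36.206, 39.754),
    source = c("Planting Base", "Market", "Planting Base", "Planting Base",
               "Planting Base", "Planting Base", "Planting Base",
               "Planting Base", "Market", "Market", "Market", "Market",
               "Market", "Market", "Market", "Planting Base",
               "Planting Base", "Planting Base", "Planting Base",
               "Planting Base")
  )
  b$group <- ifelse(b$latitude < 35, "south",
                    ifelse(b$latitude < 38, "mid", "north"))
  b
}

#' Reference instrument condition
#'
#' The nominal chromatographic condition: BEH C18 column, 35 degC column
#' temperature, 0.30 mL/min flow, 2 uL injection.
#'
#' @return A list of class `instrument_condition`.
#' @export
default_condition <- function() {
  new_condition("BEH_C18", 35, 0.30, 2)
}

#' Construct an instrument condition
#'
#' All fields must lie on the enumerated perturbation grids: column in
#' `{BEH_C18, HSS_T3}`, temperature in `{28, 32, 35, 38}` degC, flow rate
#' in `{0.30, 0.32, 0.34, 0.36}` mL/min, injection volume in `{1, 2, 3, 4}`
#' uL.
#'
#' @param column_id Column label.
#' @param temperature Column temperature, degC.
#' @param flow_rate Mobile-phase flow, mL/min.
#' @param injection_volume Injection volume, uL.
#' @return An `instrument_condition`.
#' @export
new_condition <- function(column_id, temperature, flow_rate, injection_volume) {
  cond <- list(column_id = column_id, temperature = temperature,
               flow_rate = flow_rate, injection_volume = injection_volume)
  validate_condition(cond)
  structure(cond, class = "instrument_condition")
}

condition_families <- function() {
  list(
    column = c("BEH_C18", "HSS_T3"),
    temperature = c(28, 32, 35, 38),
    flow_rate = c(0.30, 0.32, 0.34, 0.36),
    injection_volume = c(1, 2, 3, 4)
  )
}

validate_condition <- function(cond) {
  fam <- condition_families()
  if (!cond$column_id %in% fam$column)
    stop("unknown column_id: ", cond$column_id, call. = FALSE)
  if (!cond$temperature %in% fam$temperature)
    stop("temperature must be one of ", paste(fam$temperature, collapse = ", "),
         call. = FALSE)
  if (!isTRUE(any(abs(cond$flow_rate - fam$flow_rate) < 1e-9)))
    stop("flow_rate must be one of ", paste(fam$flow_rate, collapse = ", "),
         call. = FALSE)
  if (!cond$injection_volume %in% fam$injection_volume)
    stop("injection_volume must be one of ",
         paste(fam$injection_volume, collapse = ", "), call. = FALSE)
  invisible(cond)
}

#' Short identifier string for an instrument condition
#' @param cond An `instrument_condition`.
#' @return A single string, e.g. `"BEH_C18_T35_F0.30_V2"`.
#' @export
condition_id <- function(cond) {
  sprintf("%s_T%g_F%.2f_V%g", cond$column_id, cond$temperature,
          cond$flow_rate, cond$injection_volume)
}

#' @export
print.instrument_condition <- function(x, ...) {
  cat("<instrument_condition>", condition_id(x), "\n")
  invisible(x)
}

#' Enumerate one family of instrument-condition perturbations
#'
#' Robustness of the relative calibration factors is probed along four
#' condition families: two column chemistries, four column temperatures,
#' four flow rates and four injection volumes. For the requested family the
#' full enumerated grid is returned with every other field held at `base`;
#' the base condition itself is always a member of the returned list.
#'
#' @param base An `instrument_condition` (default [default_condition()]).
#' @param family One of `"column"`, `"temperature"`, `"flow_rate"`,
#'   `"injection_volume"`.
#' @return A list of `instrument_condition` objects.
#' @export
#' @examples
#' perturb_condition(family = "temperature")
perturb_condition <- function(base = default_condition(), family) {
  fam <- condition_families()
  if (length(family) != 1L || !family %in% names(fam))
    stop("unknown condition family: ", paste(family, collapse = ", "),
         "; must be one of ", paste(names(fam), collapse = ", "),
         call. = FALSE)
  validate_condition(base)
  lapply(fam[[family]], function(v) {
    cond <- unclass(base)
    cond[[if (family == "column") "column_id" else family]] <- v
    do.call(new_condition, cond)
  })
}

#' Full instrument-condition grid over all four families
#'
#' Union of the four family grids around `base`, with duplicates (the base
#' condition appears in every family) removed. With the default grids this
#' yields 11 unique conditions.
#'
#' @inheritParams perturb_condition
#' @return A list of unique `instrument_condition` objects.
#' @export
condition_grid <- function(base = default_condition()) {
  conds <- unlist(lapply(names(condition_families()), function(f)
    perturb_condition(base, f)), recursive = FALSE)
  ids <- vapply(conds, condition_id, character(1))
  conds[!duplicated(ids)]
}
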