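# Single-marker quantification (QAMS): relative calibration factors, their
# stability across instrument conditions, internal-reference selection,
# quantification, content, and the QAMS-vs-ESM comparison.

#' Relative calibration factor from a matched standard gradient
#'
#' For a level-matched dilution series of the internal reference s and an
#' analyte i, the per-level relative calibration factor is
#' `F_si = (A_i * C_s) / (A_s * C_i)` — the ratio of the reference's
#' response factor `C_s / A_s` to the analyte's `C_i / A_i`. The returned
#' factor is the arithmetic mean over the gradient levels. With nonzero
#' response intercepts the per-level factor varies slightly with
#' concentration; the gradient mean is the adopted convention.
#'
#' @param ir_points Data frame (`concentration`, `area`) for the internal
#'   reference, one row per gradient level.
#' @param analyte_points Data frame of the same shape and length for the
#'   analyte, level-matched to `ir_points`.
#' @return The mean relative calibration factor (unitless scalar).
#' @export
#' @examples
#' # identical series: F = 1 exactly
#' s <- data.frame(concentration = c(50, 100, 200), area = c(1e5, 2e5, 4e5))
#' compute_rcf(s, s)
compute_rcf <- function(ir_points, analyte_points) {
  mean(rcf_per_level(ir_points, analyte_points))
}

# Per-level factors; shared by compute_rcf and the stability machinery.
rcf_per_level <- function(ir_points, analyte_points) {
  for (p in list(ir_points, analyte_points)) {
    if (!is.data.frame(p) || !all(c("concentration", "area") %in% names(p)))
      stop("points need columns 'concentration' and 'area'", call. = FALSE)
  }
  if (nrow(ir_points) != nrow(analyte_points))
    stop("reference and analyte series must be level-matched ",
         "(equal length)", call. = FALSE)
  vals <- c(ir_points$concentration, ir_points$area,
            analyte_points$concentration, analyte_points$area)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all concentrations and areas must be positive", call. = FALSE)
  (analyte_points$area * ir_points$concentration) /
    (ir_points$area * analyte_points$concentration)
}

#' Relative-calibration-factor stability across instrument conditions
#'
#' Computes the per-condition RCF of every analyte against a chosen
#' internal reference from condition-wise standard gradients, then
#' summarises each analyte's factor by its mean and relative standard
#' deviation across conditions. A stable factor (low RSD) is the evidence
#' that single-marker quantification transfers across columns,
#' temperatures, flow rates and injection volumes.
#'
#' @param grid Long tibble as returned by [simulate_condition_grid()]:
#'   columns `condition_id`, `analyte`, `level`, `concentration`, `area`;
#'   every condition must carry every analyte.
#' @param ir Internal-reference analyte name (must appear in `grid`).
#' @return An object of class `rcf_table`: `ir`, `conditions`,
#'   `per_condition` (analytes x conditions matrix of factors), and
#'   `summary` (tibble `analyte`, `mean_rcf`, `rsd_percent`).
#' @export
rcf_stability <- function(grid, ir) {
  req <- c("condition_id", "analyte", "level", "concentration", "area")
  if (!all(req %in% names(grid)))
    stop("grid needs columns ", paste(req, collapse = ", "), call. = FALSE)
  conds <- unique(grid$condition_id)
  analytes <- unique(grid$analyte)
  if (length(conds) < 2)
    stop("RCF stability needs at least 2 conditions", call. = FALSE)
  if (!ir %in% analytes)
    stop("internal reference '", ir, "' not present in grid", call. = FALSE)

  per_condition <- matrix(NA_real_, nrow = length(analytes),
                          ncol = length(conds),
                          dimnames = list(analytes, conds))
  for (cid in conds) {
    sub <- grid[grid$condition_id == cid, ]
    ir_pts <- sub[sub$analyte == ir, ]
    ir_pts <- ir_pts[order(ir_pts$level), ]
    if (nrow(ir_pts) == 0)
      stop("condition ", cid, " is missing the internal reference ", ir,
           call. = FALSE)
    for (an in analytes) {
      pts <- sub[sub$analyte == an, ]
      pts <- pts[order(pts$level), ]
      if (nrow(pts) == 0)
        stop("condition ", cid, " is missing analyte ", an, call. = FALSE)
      per_condition[an, cid] <- compute_rcf(ir_pts, pts)
    }
  }
  summary <- tibble::tibble(
    analyte = analytes,
    mean_rcf = unname(rowMeans(per_condition)),
    rsd_percent = unname(apply(per_condition, 1, function(v)
      100 * stats::sd(v) / mean(v)))
  )
  structure(list(ir = ir, conditions = conds,
                 per_condition = per_condition, summary = summary),
            class = "rcf_table")
}

#' Relative calibration factors from a single standard gradient
#'
#' Builds an `rcf_table` from one dilution-gradient measurement (one
#' condition): each analyte's factor is the gradient mean of the per-level
#' factors against the chosen reference. Use [rcf_stability()] when
#' multiple conditions are available; this constructor serves routine
#' quantification, where the factors come from one standard-mixture run.
#'
#' @param gradient Long tibble with columns `analyte`, `level`,
#'   `concentration`, `area` (e.g. one condition of
#'   [simulate_condition_grid()], or stacked [simulate_calibration_series()]
#'   outputs).
#' @param ir Internal-reference analyte name.
#' @return An `rcf_table` with a single condition and `rsd_percent = NA`.
#' @export
rcf_from_gradient <- function(gradient, ir) {
  req <- c("analyte", "level", "concentration", "area")
  if (!all(req %in% names(gradient)))
    stop("gradient needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  analytes <- unique(gradient$analyte)
  if (!ir %in% analytes)
    stop("internal reference '", ir, "' not present in gradient",
         call. = FALSE)
  ir_pts <- gradient[gradient$analyte == ir, ]
  ir_pts <- ir_pts[order(ir_pts$level), ]
  fct <- vapply(analytes, function(an) {
    pts <- gradient[gradient$analyte == an, ]
    compute_rcf(ir_pts, pts[order(pts$level), ])
  }, numeric(1))
  per_condition <- matrix(unname(fct), ncol = 1,
                          dimnames = list(analytes, "gradient"))
  structure(list(
    ir = ir, conditions = "gradient", per_condition = per_condition,
    summary = tibble::tibble(analyte = analytes, mean_rcf = unname(fct),
                             rsd_percent = NA_real_)
  ), class = "rcf_table")
}

#' @export
print.rcf_table <- function(x, ...) {
  cat("<rcf_table> IR =", x$ir, "over", length(x$conditions), "conditions\n")
  print(x$summary)
  invisible(x)
}

#' Select the internal reference from candidate RCF tables
#'
#' A candidate passes the screen when every analyte's RCF RSD across
#' conditions is below `rsd_limit` (default 5%). Among passing candidates
#' the winner minimises, lexicographically: the summary RSD (the maximum
#' per-analyte RSD over the non-reference analytes — a conservative
#' summary), then the availability rank (cheap, abundant standards first),
#' then the name. This mirrors the two-sided selection rule: the factor
#' must be stable, and the standard must be economical and easy to obtain.
#'
#' @param tables Named list of `rcf_table`s, one per candidate reference;
#'   names must equal each table's `ir`.
#' @param availability_rank Named integer vector, analyte -> ordinal (1 =
#'   most available). Defaults to the panel's ranks.
#' @param rsd_limit Screening threshold in percent (default 5).
#' @param order_by `"availability"` (default): all candidates passing the
#'   stability screen are considered equivalently robust, so availability
#'   decides, with summary RSD then name breaking ties — the published
#'   selection logic. `"rsd"`: strict lexicographic (summary RSD,
#'   availability, name).
#' @return A list: `ir` (the winner) and `ranking` (tibble with
#'   `ir_candidate`, `summary_rsd_percent`, `availability_rank`, `passes`,
#'   ordered as ranked).
#' @export
select_ir <- function(tables,
                      availability_rank = stats::setNames(
                        default_analytes()$availability_rank,
                        default_analytes()$name),
                      rsd_limit = 5,
                      order_by = c("availability", "rsd")) {
  order_by <- match.arg(order_by)
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$ir, character(1))
  all_analytes <- unique(unlist(lapply(tables, function(t) t$summary$analyte)))
  ranking <- dplyr::bind_rows(lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    if (!all(all_analytes %in% tb$summary$analyte))
      stop("candidate ", nm, " does not cover all analytes", call. = FALSE)
    non_ir <- tb$summary[tb$summary$analyte != tb$ir, ]
    tibble::tibble(
      ir_candidate = tb$ir,
      summary_rsd_percent = max(non_ir$rsd_percent),
      availability_rank = unname(availability_rank[tb$ir])
    )
  }))
  ranking$passes <- ranking$summary_rsd_percent < rsd_limit
  ord <- if (order_by == "availability") {
    order(!ranking$passes, ranking$availability_rank,
          ranking$summary_rsd_percent, ranking$ir_candidate)
  } else {
    order(!ranking$passes, ranking$summary_rsd_percent,
          ranking$availability_rank, ranking$ir_candidate)
  }
  ranking <- ranking[ord, ]
  if (!any(ranking$passes))
    stop("no candidate passes the ", rsd_limit, "% RSD screen; summary RSDs: ",
         paste(sprintf("%s=%.2f%%", ranking$ir_candidate,
                       ranking$summary_rsd_percent), collapse = ", "),
         call. = FALSE)
  list(ir = ranking$ir_candidate[1], ranking = ranking)
}

#' Quantify a sample by the single-marker method
#'
#' Only the internal reference's own calibration curve is consulted: its
#' concentration `C_s` comes from curve inversion of its peak area `A_s`,
#' and every other analyte's concentration follows from its mean relative
#' calibration factor, `C_i = (A_i * C_s) / (A_s * F_si)`.
#'
#' @param peak_table Peak-table tibble for one or more samples (columns
#'   `sample_id`, `peak_id`, `area`).
#' @param ir_curve `calibration_curve` of the internal reference; its
#'   `analyte` must equal `rcf_table$ir`.
#' @param rcf_table An `rcf_table` supplying mean factors.
#' @param curves Optional named list of per-analyte `calibration_curve`s;
#'   when given, each result below its analyte's LOQ is flagged (and still
#'   reported).
#' @return Tibble of quantification results: `sample_id`, `analyte`,
#'   `method` ("QAMS"), `concentration` (ug/mL), `below_loq` flag.
#' @export
quantify_qams <- function(peak_table, ir_curve, rcf_table, curves = NULL) {
  stopifnot(inherits(ir_curve, "calibration_curve"),
            inherits(rcf_table, "rcf_table"))
  if (ir_curve$analyte != rcf_table$ir)
    stop("rcf_table IR (", rcf_table$ir, ") does not match the curve (",
         ir_curve$analyte, ")", call. = FALSE)
  fct <- stats::setNames(rcf_table$summary$mean_rcf,
                         rcf_table$summary$analyte)
  out <- lapply(split(peak_table, peak_table$sample_id), function(pt) {
    ir_row <- pt[pt$peak_id == rcf_table$ir, ]
    if (nrow(ir_row) != 1L)
      stop("internal-reference peak '", rcf_table$ir,
           "' missing (or duplicated) in sample ", pt$sample_id[1],
           call. = FALSE)
    c_s <- predict_concentration(ir_curve, ir_row$area,
                                 warn_out_of_range = FALSE)
    targets <- pt[pt$peak_id %in% names(fct), ]
    skipped <- setdiff(intersect(pt$peak_id, default_analytes()$name),
                       names(fct))
    if (length(skipped))
      warning("no RCF for detected target(s) ",
              paste(skipped, collapse = ", "), " in sample ",
              pt$sample_id[1], "; skipped", call. = FALSE)
    conc <- (targets$area * c_s) / (ir_row$area * fct[targets$peak_id])
    tibble::tibble(sample_id = targets$sample_id, analyte = targets$peak_id,
                   method = "QAMS", concentration = unname(conc))
  })
  res <- dplyr::bind_rows(out)
  loq_of <- function(an) {
    cv <- if (!is.null(curves)) curves[[an]] else NULL
    if (is.null(cv)) NA_real_ else cv$loq
  }
  loqs <- vapply(res$analyte, loq_of, numeric(1))
  res$below_loq <- !is.na(loqs) & res$concentration < loqs
  res[order(res$sample_id, res$analyte), ]
}

#' Quantify a sample by the external standard method
#'
#' Each analyte's concentration is obtained by inverting its own
#' calibration curve.
#'
#' @param peak_table Peak-table tibble (columns `sample_id`, `peak_id`,
#'   `area`).
#' @param curves Named list of `calibration_curve`s (names = analyte).
#' @return Tibble: `sample_id`, `analyte`, `method` ("ESM"),
#'   `concentration` (ug/mL), `below_loq`.
#' @export
quantify_esm <- function(peak_table, curves) {
  if (is.null(names(curves)))
    names(curves) <- vapply(curves, function(cv) cv$analyte, character(1))
  targets <- peak_table[peak_table$peak_id %in% names(curves), ]
  res <- dplyr::bind_rows(lapply(seq_len(nrow(targets)), function(i) {
    cv <- curves[[targets$peak_id[i]]]
    conc <- predict_concentration(cv, targets$area[i],
                                  warn_out_of_range = FALSE)
    tibble::tibble(sample_id = targets$sample_id[i],
                   analyte = targets$peak_id[i], method = "ESM",
                   concentration = conc,
                   below_loq = !is.na(cv$loq) & conc < cv$loq)
  }))
  res[order(res$sample_id, res$analyte), ]
}

#' Content of an analyte in the dried material
#'
#' `W = C * V / M`, converted from ug/g to mg/g: concentration in the
#' extract (ug/mL) times extract volume (mL) over weighed sample mass (g),
#' divided by 1000.
#'
#' @param concentration Concentration(s) in the extract, ug/mL (>= 0).
#' @param extract_volume Extract volume V, mL (> 0); default 25.
#' @param sample_mass Sample mass M, g (> 0); default 1.0.
#' @return Content in mg per g of material.
#' @export
#' @examples
#' content(2000)  # 50 mg/g with the default 25 mL / 1.0 g workup
content <- function(concentration, extract_volume = 25, sample_mass = 1.0) {
  stopifnot_scalar_pos(extract_volume, "extract_volume")
  stopifnot_scalar_pos(sample_mass, "sample_mass")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  concentration * extract_volume / sample_mass / 1000
}

#' Compare single-marker and external-standard quantification
#'
#' Joins QAMS and ESM results on (sample, analyte) and reports the relative
#' deviation `RE = 100 * |C_QAMS - C_ESM| / C_ESM` per pair, with
#' per-analyte maxima and means. Agreement below 5% is the usual evidence
#' that the single-marker method can replace per-analyte standards.
#'
#' @param qams_results,esm_results Tibbles from [quantify_qams()] /
#'   [quantify_esm()].
#' @return A list: `pairs` (tibble `sample_id`, `analyte`, `c_qams`,
#'   `c_esm`, `re_percent`) and `by_analyte` (tibble `analyte`,
#'   `max_re_percent`, `mean_re_percent`).
#' @export
compare_qams_esm <- function(qams_results, esm_results) {
  q <- qams_results[, c("sample_id", "analyte", "concentration")]
  e <- esm_results[, c("sample_id", "analyte", "concentration")]
  names(q)[3] <- "c_qams"
  names(e)[3] <- "c_esm"
  pairs <- dplyr::full_join(q, e, by = c("sample_id", "analyte"))
  bad <- pairs[is.na(pairs$c_qams) | is.na(pairs$c_esm), ]
  if (nrow(bad))
    stop("unmatched (sample, analyte) pairs: ",
         paste(sprintf("%s/%s", bad$sample_id, bad$analyte), collapse = ", "),
         call. = FALSE)
  if (any(pairs$c_esm <= 0))
    stop("ESM concentrations must be positive for relative deviation",
         call. = FALSE)
  pairs$re_percent <- 100 * abs(pairs$c_qams - pairs$c_esm) / pairs$c_esm
  an <- unique(pairs$analyte)
  re_by <- split(pairs$re_percent, pairs$analyte)
  by_analyte <- tibble::tibble(
    analyte = an,
    max_re_percent = unname(vapply(re_by, max, numeric(1))[an]),
    mean_re_percent = unname(vapply(re_by, mean, numeric(1))[an])
  )
  list(pairs = pairs, by_analyte = by_analyte)
}
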