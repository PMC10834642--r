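# CSV interchange and pipeline orchestration.

peak_table_columns <- c("sample_id", "condition_id", "channel", "peak_id",
                        "rt_min", "area", "height")

#' Read a peak-table CSV
#'
#' Expects the columns written by [write_peak_table_csv()] (`sample_id`,
#' `condition_id`, `channel`, `peak_id`, `rt_min`, `area`, `height`);
#' unknown extra columns are kept untouched. Rows whose `area` or `rt_min`
#' cannot be parsed as numbers are rejected with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A long peak-table tibble.
#' @export
read_peak_table_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(peak_table_columns, names(raw))
  if (length(missing))
    stop("peak-table CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0)
    stop("peak-table CSV has a header but no rows: ", path, call. = FALSE)
  for (col in c("rt_min", "area", "height")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    raw[[col]] <- vals
  }
  tibble::as_tibble(raw)
}

# Fixed decimal formatting so reruns are byte-stable.
format_csv_value <- function(x) {
  if (is.double(x)) sprintf("%.6f", x) else as.character(x)
}

write_csv_fixed <- function(df, path) {
  out <- as.data.frame(lapply(df, format_csv_value),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a peak table to CSV
#'
#' Numeric columns use a fixed 6-decimal format so repeated runs produce
#' byte-identical files.
#'
#' @param peak_table A peak-table tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peak_table_csv <- function(peak_table, path) {
  missing <- setdiff(peak_table_columns, names(peak_table))
  if (length(missing))
    stop("peak table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  write_csv_fixed(peak_table, path)
}

pipeline_stages <- c("simulate", "calibrate", "rcf", "select_ir",
                     "quantify", "compare", "fingerprint", "cluster")

stage_deps <- list(
  simulate = character(),
  calibrate = character(),
  rcf = character(),
  select_ir = "rcf",
  quantify = c("simulate", "calibrate", "rcf"),
  compare = "quantify",
  fingerprint = "simulate",
  cluster = "quantify"
)

#' Run the full quality-evaluation pipeline
#'
#' Executes the enabled stages in dependency order over a synthetic study:
#' simulate batch peak tables, fit calibration curves (with LOD/LOQ),
#' compute relative-calibration-factor stability over the instrument
#' condition grid for every candidate reference, select the internal
#' reference, quantify every batch by both the single-marker and the
#' external-standard method, compare them, run the fingerprint stage
#' (common peaks + similarity), and cluster the content matrix. Per-stage
#' CSVs and a run log (seeds and parameter echo) are written under
#' `outdir`; reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param stages Character vector of stages to run, a subset of
#'   `"simulate"`, `"calibrate"`, `"rcf"`, `"select_ir"`, `"quantify"`,
#'   `"compare"`, `"fingerprint"`, `"cluster"`. Dependencies must be
#'   included; a stage whose dependency is disabled raises an error before
#'   any work is done.
#' @param seed Integer seed governing every stochastic stage.
#' @param n_levels Calibration levels (default 6).
#' @param rcf_span Fractional linear-range span of the factor-determination
#'   gradient (default `c(0.2, 1)`, working concentrations).
#' @param wobble_sd Per-(condition, analyte) response wobble for the grid
#'   experiment (default 0.005).
#' @param rt_tolerance Common-peak matching window, minutes (default 0.1).
#' @param k_groups Groups for the content-matrix clustering (default 3,
#'   the generator's latitude-band structure).
#' @param similarity_method `"cosine"` (default) or `"correlation"`.
#' @return A named list with each executed stage's results, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         stages = pipeline_stages, seed = config$seed,
                         n_levels = 6, rcf_span = c(0.2, 1),
                         wobble_sd = 0.005, rt_tolerance = 0.1,
                         k_groups = 3, similarity_method = "cosine") {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (st in stages) {
    unmet <- setdiff(stage_deps[[st]], stages)
    if (length(unmet))
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(unmet, collapse = ", "), call. = FALSE)
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(outdir)) write_csv_fixed(df, file.path(outdir, name))
  }
  res <- list()
  log_lines <- c(
    "quality-evaluation pipeline run",
    sprintf("seed: %d", seed),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    sprintf("area_noise_cv: %g; rt_jitter_sd: %g; batches: %d; extras: %d",
            config$area_noise_cv, config$rt_jitter_sd,
            nrow(config$batches), config$n_extra_peaks),
    sprintf("n_levels: %d; rcf_span: [%g, %g]; wobble_sd: %g", n_levels,
            rcf_span[1], rcf_span[2], wobble_sd),
    sprintf("rt_tolerance: %g min; k_groups: %d; similarity: %s (median reference)",
            rt_tolerance, k_groups, similarity_method),
    sprintf("extract_volume: %g mL; sample_mass: %g g",
            config$extract_volume, config$sample_mass)
  )

  if ("simulate" %in% stages) {
    res$peak_tables <- simulate_study(config, seed = derive_seed(seed, 11L))
    emit(res$peak_tables, "peak_tables.csv")
  }
  if ("calibrate" %in% stages) {
    gain <- gauss_gain(config$analytes$peak_width_sigma)
    res$curves <- lapply(seq_len(nrow(config$analytes)), function(i) {
      an <- config$analytes$name[i]
      ser <- simulate_calibration_series(config, an, n_levels = n_levels,
                                         noise_cv = 0.005,
                                         seed = derive_seed(seed, 20L + i))
      cv <- fit_calibration(ser, an)
      estimate_lod_loq(cv, height_slope = cv$slope * gain[i],
                       baseline_noise_sd = config$baseline_noise_sd)
    })
    names(res$curves) <- config$analytes$name
    emit(curve_summary(res$curves), "calibration_curves.csv")
  }
  if ("rcf" %in% stages) {
    res$grid <- simulate_condition_grid(config, n_levels = n_levels,
                                        wobble_sd = wobble_sd,
                                        seed = derive_seed(seed, 31L),
                                        span = rcf_span)
    res$rcf_tables <- lapply(config$analytes$name, function(ir)
      rcf_stability(res$grid, ir))
    names(res$rcf_tables) <- config$analytes$name
    long <- dplyr::bind_rows(lapply(res$rcf_tables, function(tb) {
      df <- as.data.frame.table(tb$per_condition,
                                stringsAsFactors = FALSE)
      names(df) <- c("analyte", "condition_id", "rcf")
      df$ir <- tb$ir
      tibble::as_tibble(df[, c("ir", "analyte", "condition_id", "rcf")])
    }))
    res$rcf_long <- long
    emit(long, "rcf_long.csv")
    emit(dplyr::bind_rows(lapply(res$rcf_tables, function(tb) {
      s <- tb$summary
      s$ir <- tb$ir
      s[, c("ir", "analyte", "mean_rcf", "rsd_percent")]
    })), "rcf_summary.csv")
  }
  if ("select_ir" %in% stages) {
    res$ir_selection <- select_ir(res$rcf_tables)
    emit(res$ir_selection$ranking, "ir_ranking.csv")
    log_lines <- c(log_lines,
                   sprintf("selected internal reference: %s",
                           res$ir_selection$ir))
  }
  if ("quantify" %in% stages) {
    ir <- if (!is.null(res$ir_selection)) res$ir_selection$ir
          else "saikosaponin_d"
    res$ir <- ir
    q <- quantify_qams(res$peak_tables, res$curves[[ir]],
                       res$rcf_tables[[ir]], curves = res$curves)
    e <- quantify_esm(res$peak_tables, res$curves)
    q$content_mg_g <- content(q$concentration, config$extract_volume,
                              config$sample_mass)
    e$content_mg_g <- content(e$concentration, config$extract_volume,
                              config$sample_mass)
    res$quant <- dplyr::bind_rows(q, e)
    emit(res$quant, "quantification.csv")
  }
  if ("compare" %in% stages) {
    res$comparison <- compare_qams_esm(
      res$quant[res$quant$method == "QAMS", ],
      res$quant[res$quant$method == "ESM", ])
    emit(res$comparison$pairs, "comparison_pairs.csv")
    emit(res$comparison$by_analyte, "comparison_by_analyte.csv")
  }
  if ("fingerprint" %in% stages) {
    res$common_peaks <- match_common_peaks(res$peak_tables, rt_tolerance)
    res$similarity <- similarity_report(res$common_peaks,
                                        method = similarity_method)
    emit(res$similarity, "similarity.csv")
    emit(res$common_peaks$peaks, "common_peaks.csv")
  }
  if ("cluster" %in% stages) {
    esm <- res$quant[res$quant$method == "ESM", ]
    cm <- content_matrix(esm, config$extract_volume, config$sample_mass)
    res$content <- cm
    res$pca <- pca_contents(cm)
    res$hca <- hca_contents(cm, k_groups = k_groups)
    assign_df <- tibble::tibble(
      sample_id = names(res$hca$assignments),
      hca_group = unname(res$hca$assignments),
      pc1 = res$pca$scores[, 1], pc2 = res$pca$scores[, 2]
    )
    emit(assign_df, "cluster_assignments.csv")
    res$assignments <- assign_df
  }
  if (!is.null(outdir))
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  res$log <- log_lines
  invisible(res)
}
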