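# Fingerprint stage: peak detection in rendered chromatograms, common-peak
# matching across batches, reference fingerprint, congruence similarity.

#' Detect peaks in a chromatogram
#'
#' Local maxima of a moving-average-smoothed trace, kept when the smoothed
#' height clears both `min_snr` times the estimated baseline noise and
#' `min_height_frac` of the global maximum. Peak areas come from
#' trapezoidal integration between the flanking minima of the smoothed
#' trace; reported heights are read from the raw trace at the apex.
#' Baseline noise is estimated as `mad(diff(intensity)) / sqrt(2)`, which
#' is insensitive to the peaks themselves. A flat trace yields an empty
#' table.
#'
#' @param chromatogram A `chromatogram` (list with `time`, `intensity`).
#' @param min_snr Minimum apex signal-to-noise (default 3).
#' @param min_height_frac Minimum apex height as a fraction of the global
#'   smoothed maximum (default 0.005).
#' @param smooth_window Moving-average window length in points (odd;
#'   default 5).
#' @return Tibble of detected peaks: `rt_min`, `area`, `height`, sorted by
#'   retention time.
#' @export
detect_peaks <- function(chromatogram, min_snr = 3, min_height_frac = 0.005,
                         smooth_window = 5) {
  t <- chromatogram$time
  y <- chromatogram$intensity
  if (length(t) < 5) stop("trace needs at least 5 points", call. = FALSE)
  if (min_snr <= 0) stop("min_snr must be positive", call. = FALSE)
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1

  ys <- stats::filter(y, rep(1 / smooth_window, smooth_window), sides = 2)
  ys <- as.numeric(ys)
  half <- (smooth_window - 1) / 2
  ys[seq_len(half)] <- ys[half + 1]
  n <- length(ys)
  ys[(n - half + 1):n] <- ys[n - half]

  noise_sd <- stats::mad(diff(y)) / sqrt(2)
  ymax <- max(ys)
  if (ymax <= 0 || all(ys == ys[1])) {
    return(tibble::tibble(rt_min = numeric(), area = numeric(),
                          height = numeric()))
  }
  threshold <- max(min_snr * noise_sd, min_height_frac * ymax)

  mid <- 2:(n - 1)
  is_max <- mid[ys[mid] > ys[mid - 1] & ys[mid] >= ys[mid + 1]]
  apex <- is_max[ys[is_max] >= threshold]
  if (!length(apex)) {
    return(tibble::tibble(rt_min = numeric(), area = numeric(),
                          height = numeric()))
  }

  # integration bounds: the minimum of the smoothed trace between
  # neighbouring kept apexes (trace ends at the flanks)
  bounds <- integer(length(apex) + 1)
  bounds[1] <- 1L
  bounds[length(apex) + 1] <- n
  if (length(apex) > 1) {
    for (k in seq_len(length(apex) - 1)) {
      seg <- apex[k]:apex[k + 1]
      bounds[k + 1] <- seg[which.min(ys[seg])]
    }
  }
  tibble::tibble(
    rt_min = t[apex],
    area = vapply(seq_along(apex), function(k) {
      idx <- bounds[k]:bounds[k + 1]
      trapz(t[idx], y[idx])
    }, numeric(1)),
    height = y[apex]
  )
}

#' Match common peaks across samples by retention time
#'
#' Peaks from all samples are grouped by single-linkage clustering of their
#' retention times cut at `rt_tolerance`; within a group each sample
#' contributes at most one peak (the one nearest the group's median Rt).
#' Groups represented in every sample become common peaks, ordered by
#' consensus retention time (the median of member Rts).
#'
#' @param peak_tables Either a named list of peak-table tibbles (one per
#'   sample) or a single long tibble with a `sample_id` column.
#' @param rt_tolerance Retention-time matching window in minutes
#'   (default 0.1).
#' @return An object of class `common_peak_set`: `peaks` (tibble
#'   `common_peak_id`, `consensus_rt_min`), `areas` and `rts` (samples x
#'   common-peaks matrices), `samples`, `n_samples`.
#' @export
match_common_peaks <- function(peak_tables, rt_tolerance = 0.1) {
  if (rt_tolerance <= 0) stop("rt_tolerance must be positive", call. = FALSE)
  if (is.data.frame(peak_tables)) {
    long <- peak_tables
  } else {
    long <- dplyr::bind_rows(peak_tables)
  }
  if (!all(c("sample_id", "rt_min", "area") %in% names(long)))
    stop("peak tables need sample_id, rt_min, area columns", call. = FALSE)
  samples <- unique(long$sample_id)
  if (length(samples) < 2)
    stop("common-peak matching needs at least 2 samples", call. = FALSE)

  if (nrow(long) >= 2) {
    hc <- stats::hclust(stats::dist(long$rt_min), method = "single")
    long$grp <- stats::cutree(hc, h = rt_tolerance)
  } else {
    long$grp <- seq_len(nrow(long))
  }

  groups <- split(long, long$grp)
  keep <- lapply(groups, function(g) {
    med <- stats::median(g$rt_min)
    # one peak per sample: nearest to the group median
    g <- g[order(abs(g$rt_min - med)), ]
    g <- g[!duplicated(g$sample_id), ]
    if (length(unique(g$sample_id)) == length(samples)) g else NULL
  })
  keep <- keep[!vapply(keep, is.null, logical(1))]
  if (!length(keep)) {
    return(structure(list(
      peaks = tibble::tibble(common_peak_id = character(),
                             consensus_rt_min = numeric()),
      areas = matrix(numeric(), nrow = length(samples), ncol = 0,
                     dimnames = list(samples, NULL)),
      rts = matrix(numeric(), nrow = length(samples), ncol = 0,
                   dimnames = list(samples, NULL)),
      samples = samples, n_samples = length(samples)
    ), class = "common_peak_set"))
  }
  cons <- unname(vapply(keep, function(g) stats::median(g$rt_min), numeric(1)))
  ord <- order(cons)
  keep <- keep[ord]
  cons <- cons[ord]
  ids <- sprintf("P%02d", seq_along(keep))
  areas <- vapply(keep, function(g)
    g$area[match(samples, g$sample_id)], numeric(length(samples)))
  rts <- vapply(keep, function(g)
    g$rt_min[match(samples, g$sample_id)], numeric(length(samples)))
  dimnames(areas) <- dimnames(rts) <- list(samples, ids)
  structure(list(
    peaks = tibble::tibble(common_peak_id = ids, consensus_rt_min = cons),
    areas = areas, rts = rts, samples = samples,
    n_samples = length(samples)
  ), class = "common_peak_set")
}

#' @export
print.common_peak_set <- function(x, ...) {
  cat("<common_peak_set>", nrow(x$peaks), "common peaks across",
      x$n_samples, "samples\n")
  invisible(x)
}

#' Reference fingerprint from a common-peak set
#'
#' Per-common-peak median (default) or mean area across all samples, in
#' consensus retention-time order.
#'
#' @param common A `common_peak_set` with at least one common peak.
#' @param kind `"median"` (default) or `"mean"`.
#' @return Named numeric vector of reference areas, one per common peak.
#' @export
reference_fingerprint <- function(common, kind = c("median", "mean")) {
  kind <- match.arg(kind)
  stopifnot(inherits(common, "common_peak_set"))
  if (ncol(common$areas) == 0)
    stop("empty common-peak set: no reference can be built", call. = FALSE)
  f <- if (kind == "median") stats::median else mean
  apply(common$areas, 2, f)
}

#' Congruence (cosine) similarity between fingerprint vectors
#'
#' The normalized inner product
#' `sum(x * r) / sqrt(sum(x^2) * sum(r^2))`, which lies in `[0, 1]` for
#' non-negative vectors and is invariant to overall dilution. With
#' `method = "correlation"` the Pearson correlation of the two vectors is
#' returned instead (the alternative convention of fingerprint software).
#'
#' @param sample_vector Non-negative areas over the common peaks.
#' @param reference_vector Reference areas, same order and length; must
#'   not be all zero.
#' @param method `"cosine"` (default) or `"correlation"`.
#' @return Similarity scalar; an all-zero sample yields 0 with a warning.
#' @export
#' @examples
#' similarity(c(1, 2, 3), c(2, 4, 6))  # 1: dilution-invariant
similarity <- function(sample_vector, reference_vector,
                       method = c("cosine", "correlation")) {
  method <- match.arg(method)
  x <- as.numeric(sample_vector)
  r <- as.numeric(reference_vector)
  if (length(x) != length(r) || length(x) < 1)
    stop("vectors must have equal positive length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(r)))
    stop("vectors must be finite", call. = FALSE)
  if (all(r == 0)) stop("reference vector is all zero", call. = FALSE)
  if (all(x == 0)) {
    warning("all-zero sample vector; similarity defined as 0", call. = FALSE)
    return(0)
  }
  if (method == "cosine") {
    sum(x * r) / sqrt(sum(x^2) * sum(r^2))
  } else {
    stats::cor(x, r)
  }
}

#' Per-sample similarity report against a consensus reference
#'
#' Convenience wrapper: builds the reference fingerprint and scores every
#' sample's common-peak area vector against it.
#'
#' @param common A `common_peak_set`.
#' @param kind Reference kind, `"median"` (default) or `"mean"`.
#' @param method Similarity metric, see [similarity()].
#' @return Tibble `sample_id`, `similarity`; the reference vector is
#'   attached as attribute `"reference"`.
#' @export
similarity_report <- function(common, kind = "median", method = "cosine") {
  ref <- reference_fingerprint(common, kind)
  out <- tibble::tibble(
    sample_id = common$samples,
    similarity = vapply(common$samples, function(s)
      similarity(common$areas[s, ], ref, method), numeric(1))
  )
  attr(out, "reference") <- ref
  attr(out, "reference_kind") <- kind
  out
}
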