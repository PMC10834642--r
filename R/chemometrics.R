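# Validation statistics and content-matrix structure analysis.

#' Relative standard deviation
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation — the universal precision/stability/repeatability statistic of
#' analytical method validation.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(98, 100, 102))  # 2
rsd <- function(values) {
  if (length(values) < 2) stop("rsd needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("rsd undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Spike recovery
#'
#' `100 * (spiked_measured - base_measured) / added`: the fraction of a
#' known added amount recovered by the assay.
#'
#' @param spiked_measured Measured amount in the spiked sample.
#' @param base_measured Measured amount in the unspiked sample.
#' @param added Amount added (> 0), same units.
#' @return Recovery in percent.
#' @export
#' @examples
#' recovery(198.5, 100, 100)  # 98.5
recovery <- function(spiked_measured, base_measured, added) {
  if (any(added <= 0)) stop("added amount must be positive", call. = FALSE)
  100 * (spiked_measured - base_measured) / added
}

as_content_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("content matrix must be numeric", call. = FALSE)
  if (any(!is.finite(m))) stop("content matrix has missing cells", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("B", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("A", seq_len(ncol(m)))
  m
}

#' Principal component analysis of a content matrix
#'
#' Columns (analytes) are centred and scaled to unit variance before the
#' eigendecomposition — saikosaponin contents span an order of magnitude,
#' so autoscaling is required for every analyte to contribute. Component
#' signs follow a fixed convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param matrix Batches x analytes numeric matrix (mg/g), >= 3 batches and
#'   >= 2 analytes; rows batches, columns analytes.
#' @return A list of class `cluster_result`: `method` ("PCA"), `scores`
#'   (batches x components), `loadings`, `explained_variance` (percent per
#'   component, non-increasing, summing to 100).
#' @export
pca_contents <- function(matrix) {
  m <- as_content_matrix(matrix)
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("PCA needs >= 3 batches and >= 2 analytes", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant analyte column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading per component positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(method = "PCA", scores = p$x, loadings = p$rotation,
                 sdev = p$sdev, explained_variance = ev),
            class = "cluster_result")
}

#' Hierarchical clustering of a content matrix
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances, the
#' typical statistical-software default) of autoscaled contents, cut at
#' `k_groups`. Group labels are renumbered deterministically in order of
#' first appearance along the batch index.
#'
#' @param matrix Batches x analytes numeric matrix (mg/g).
#' @param k_groups Number of groups to cut the tree at (default 4).
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @param dist_method Distance for [stats::dist()] (default
#'   `"euclidean"`).
#' @return A list of class `cluster_result`: `method` ("HCA"), `tree`
#'   (the `hclust` object, n - 1 merges), `assignments` (named integer
#'   vector batch -> group), `k_groups`.
#' @export
hca_contents <- function(matrix, k_groups = 4, linkage = "ward.D2",
                         dist_method = "euclidean") {
  m <- as_content_matrix(matrix)
  if (k_groups > nrow(m))
    stop("k_groups cannot exceed the number of batches", call. = FALSE)
  sc <- scale(m)
  tree <- stats::hclust(stats::dist(sc, method = dist_method),
                        method = linkage)
  raw <- stats::cutree(tree, k = k_groups)
  relabel <- match(raw, unique(raw))
  names(relabel) <- rownames(m)
  structure(list(method = "HCA", tree = tree, assignments = relabel,
                 k_groups = k_groups),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  if (x$method == "PCA") {
    cat("<cluster_result> PCA:", ncol(x$scores), "components; PC1-2 explain",
        sprintf("%.1f%%", sum(x$explained_variance[1:2])), "\n")
  } else {
    cat("<cluster_result> HCA:", x$k_groups, "groups over",
        length(x$assignments), "batches\n")
  }
  invisible(x)
}

#' Content matrix of a quantification result
#'
#' Reshapes long quantification output into the batches x analytes content
#' matrix (mg/g) consumed by [pca_contents()] and [hca_contents()].
#'
#' @param quant Tibble with `sample_id`, `analyte`, `concentration`
#'   (ug/mL).
#' @param extract_volume,sample_mass Workup parameters for [content()].
#' @return Numeric matrix, rows = samples, columns = analytes, mg/g.
#' @export
content_matrix <- function(quant, extract_volume = 25, sample_mass = 1.0) {
  w <- content(quant$concentration, extract_volume, sample_mass)
  samples <- unique(quant$sample_id)
  analytes <- unique(quant$analyte)
  m <- matrix(NA_real_, length(samples), length(analytes),
              dimnames = list(samples, analytes))
  m[cbind(match(quant$sample_id, samples), match(quant$analyte, analytes))] <- w
  if (any(is.na(m))) stop("content matrix has missing cells", call. = FALSE)
  m
}
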