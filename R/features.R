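#' Per-point features for stem/leaf classification
#'
#' Builds the per-point feature matrix used by the semantic classifier: the 3D
#' coordinates concatenated with a 33-bin fast point feature histogram (FPFH)
#' describing the local surface geometry within `radius`. The FPFH bins the
#' three Darboux-frame angles between a point's normal and the normals of its
#' radius neighbors (11 bins each), then blends each point's histogram with a
#' distance-weighted mean over its neighbors' histograms. Coordinates are
#' centered on the stem-base point (the lowest point of the cloud) so the
#' features transfer across scans of a growing plant.
#'
#' Points with fewer than `k_min` neighbors inside `radius` get a zero-filled
#' histogram and are flagged in the `flagged` attribute.
#'
#' @param cloud a [point_cloud()].
#' @param radius neighborhood radius in meters; `NA` (default) uses 5x the
#'   median nearest-neighbor spacing of the cloud.
#' @param k_min minimum neighbor count for a valid histogram.
#' @param center center coordinates on the lowest point of the cloud.
#' @return a numeric matrix with `n` rows and 36 columns (`x`, `y`, `z`,
#'   `fpfh1..fpfh33`), with attributes `radius` and `flagged` (logical vector).
#' @export
compute_features <- function(cloud, radius = NA_real_, k_min = 5L, center = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.na(radius) && radius <= 0) stop("`radius` must be positive")
  P <- cloud$points
  if (is.na(radius)) radius <- 5 * median_nn_spacing(cloud)
  nbrs <- cpp_radius_neighbors(P, radius)
  normals <- cpp_normals(P, nbrs)
  fp <- cpp_fpfh(P, normals, nbrs, as.integer(k_min))
  base <- P[which.min(P[, 3]), ]
  xyz <- if (center) sweep(P, 2, base) else P
  X <- cbind(xyz, fp$fpfh)
  colnames(X) <- c("x", "y", "z", paste0("fpfh", 1:33))
  attr(X, "radius") <- radius
  attr(X, "flagged") <- fp$flagged
  X
}

#' Estimate per-point surface normals
#'
#' Smallest-eigenvector normal of the local covariance within `radius`, with a
#' deterministic canonical sign (positive z, then y, then x component).
#'
#' @inheritParams compute_features
#' @return an `n` x 3 matrix of unit normals.
#' @export
compute_normals <- function(cloud, radius = NA_real_) {
  P <- cloud$points
  if (is.na(radius)) radius <- 5 * median_nn_spacing(cloud)
  cpp_normals(P, cpp_radius_neighbors(P, radius))
}
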