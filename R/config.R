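#' Default configuration for the registration pipeline
#'
#' Returns the nested list of tunable parameters used across the pipeline, all
#' overridable by the caller. Distances are in meters. Several spacings default
#' to `NA`, meaning "derive from the cloud" as a multiple of the median
#' nearest-neighbor spacing (`feature_radius`: 5x, `dbscan eps`: 4x).
#'
#' @param ... named overrides, e.g. `default_config(skeleton = list(min_spacing = 0.005))`.
#'   Overrides are merged recursively into the defaults.
#' @return a nested list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    features = list(
      radius = NA_real_,   # descriptor radius; NA = 5 x median nn spacing
      k_min = 5L           # below this many neighbors: zero histogram + flag
    ),
    svm = list(cost = 1, gamma = NULL, seed = 1L),  # gamma NULL = 1/ncol heuristic
    segmentation = list(
      eps = NA_real_,           # DBSCAN radius; NA = 4 x median nn spacing
      min_samples = 10L,        # DBSCAN core-point threshold
      min_cluster_size = 50L,   # clusters smaller than this are dissolved
      k_reassign = 5L           # kNN majority vote for dissolved points
    ),
    skeleton = list(
      min_spacing = 0.010,      # keypoint spacing target (m)
      som_epochs = 200L,
      som_eta = c(0.5, 0.01),   # learning-rate schedule (start, end)
      som_tol = 1e-4            # convergence: max keypoint motion per epoch (m)
    ),
    matching = list(
      w_d = 1, w_e = 10, w_sem = 1,  # emission weights
      c_nm = 10 * 0.05               # not-matched emission cost (w_e x 5 cm)
    ),
    deformation = list(
      w_corresp = 100, w_rot = 10, w_reg = 1,
      cauchy_scale = 0.002,     # robust kernel scale (m)
      max_iter = 200L,
      step_tol = 1e-8
    ),
    pipeline = list(
      max_outer_iter = 10L,
      use_labels = TRUE         # use per-point labels when the cloud has them
    ),
    icp = list(max_iter = 50L, tol = 1e-8, subsample = 2000L)
  )
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Median nearest-neighbor spacing of a cloud
#'
#' Used to derive resolution-dependent defaults (descriptor radius, DBSCAN
#' eps). Computed on a subsample for large clouds.
#'
#' @param cloud a [point_cloud()].
#' @param max_n subsample size.
#' @return median distance (m) from a point to its nearest neighbor.
#' @export
median_nn_spacing <- function(cloud, max_n = 2000L) {
  P <- cloud$points
  n <- nrow(P)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  nn <- cpp_knn(P[idx, , drop = FALSE], P, 2L)
  stats::median(nn$dist[, 2])
}
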