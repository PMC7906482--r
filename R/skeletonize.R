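#' Number of skeleton keypoints for an organ
#'
#' The chain length is proportional to the organ's size: the extent of the
#' point set along its first principal axis divided by the minimum keypoint
#' spacing, floored, and at least 1.
#'
#' @param organ_points numeric matrix (n x 3) of the organ's points.
#' @param min_spacing minimum distance between keypoints (m); default 1 cm.
#' @return integer chain length.
#' @export
chain_length <- function(organ_points, min_spacing = 0.010) {
  organ_points <- as.matrix(organ_points)
  if (nrow(organ_points) == 0) stop("organ has no points")
  if (nrow(organ_points) == 1) return(1L)
  ctr <- colMeans(organ_points)
  X <- sweep(organ_points, 2, ctr)
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  s <- X %*% v
  extent <- max(s) - min(s)
  max(1L, as.integer(floor(extent / min_spacing)))
}

#' Fit a 1-D self-organizing-map chain to an organ's points
#'
#' Trains an `n x 1` chain of 3D units on the organ's points by competitive
#' learning: each randomly drawn point selects its best matching unit (the
#' nearest chain unit) and every unit moves toward the point, weighted by a
#' Gaussian over chain-index distance to the best matching unit. The
#' neighborhood width and the learning rate decay linearly over epochs;
#' training stops early once the maximum keypoint motion in an epoch falls
#' below `tol`. The chain is initialized on `n` evenly spaced positions along
#' the organ's first principal axis, which makes convergence fast and the
#' chain ordering monotone along the organ.
#'
#' @param organ_points numeric matrix (m x 3).
#' @param n chain length; reduced (with a warning) if the organ has fewer
#'   points.
#' @param epochs epoch cap.
#' @param eta learning-rate schedule `c(start, end)`, decayed linearly.
#' @param tol convergence threshold on per-epoch keypoint motion (m).
#' @param seed optional RNG seed; the fit is deterministic given the seed.
#' @return an `n x 3` matrix of ordered chain keypoints.
#' @export
fit_som_chain <- function(organ_points, n, epochs = 200L, eta = c(0.5, 0.01),
                          tol = 1e-4, seed = NULL) {
  P <- as.matrix(organ_points)
  storage.mode(P) <- "double"
  if (!is.null(seed)) set.seed(seed)
  if (n > nrow(P)) {
    warning("chain length ", n, " exceeds point count ", nrow(P), "; reducing")
    n <- nrow(P)
  }
  if (n < 1) stop("chain length must be at least 1")
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  if (n == 1 || nrow(P) == 1) return(matrix(ctr, 1, 3))
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  s <- as.numeric(X %*% v)
  init <- outer(seq(min(s), max(s), length.out = n), v) +
    matrix(ctr, n, 3, byrow = TRUE)
  cpp_som_chain(P, init, as.integer(epochs), eta[1], eta[2], tol)
}

#' Build the semantic curve skeleton of a segmented plant
#'
#' Fits one SOM chain per organ instance (stem first) and connects them into
#' an acyclic graph: each leaf chain is oriented so its proximal end is the
#' endpoint nearest the stem chain, and a single edge joins that proximal node
#' to its nearest stem node. The root is the stem node with the smallest z.
#'
#' @param segmentation an `organ_segmentation` from [cluster_instances()].
#' @param cloud the segmented [point_cloud()].
#' @param min_spacing keypoint spacing (m), see [chain_length()].
#' @param epochs,eta,tol SOM schedule, see [fit_som_chain()].
#' @param seed optional RNG seed for the SOM fits.
#' @return a [skeleton()] whose node organ ids match the segmentation's
#'   instance ids.
#' @export
build_skeleton <- function(segmentation, cloud, min_spacing = 0.010,
                           epochs = 200L, eta = c(0.5, 0.01), tol = 1e-4,
                           seed = NULL) {
  stopifnot(inherits(segmentation, "organ_segmentation"),
            inherits(cloud, "point_cloud"))
  if (!is.null(seed)) set.seed(seed)
  tab <- segmentation$instance_table
  stem_ids <- tab$id[tab$class == "stem"]
  if (length(stem_ids) != 1) stop("segmentation must contain exactly one stem instance")
  P <- cloud$points

  fit_organ <- function(oid) {
    pts <- P[segmentation$instances == oid, , drop = FALSE]
    n <- chain_length(pts, min_spacing)
    fit_som_chain(pts, n, epochs = epochs, eta = eta, tol = tol)
  }

  stem_kp <- fit_organ(stem_ids)
  # order the stem chain bottom-up so node 1 is the stem base
  if (nrow(stem_kp) > 1 && stem_kp[1, 3] > stem_kp[nrow(stem_kp), 3])
    stem_kp <- stem_kp[rev(seq_len(nrow(stem_kp))), , drop = FALSE]
  nodes <- data.frame(id = seq_len(nrow(stem_kp)),
                      x = stem_kp[, 1], y = stem_kp[, 2], z = stem_kp[, 3],
                      label = "stem", organ = stem_ids)
  edges <- if (nrow(stem_kp) > 1) cbind(1:(nrow(stem_kp) - 1), 2:nrow(stem_kp))
           else matrix(integer(0), 0, 2)

  leaf_ids <- tab$id[tab$class == "leaf"]
  for (oid in sort(leaf_ids)) {
    kp <- fit_organ(oid)
    # proximal end = chain endpoint nearest any stem node
    d_first <- min(sqrt(rowSums(sweep(stem_kp, 2, kp[1, ])^2)))
    d_last <- min(sqrt(rowSums(sweep(stem_kp, 2, kp[nrow(kp), ])^2)))
    if (d_last < d_first) kp <- kp[rev(seq_len(nrow(kp))), , drop = FALSE]
    base_id <- nrow(nodes)
    ids <- base_id + seq_len(nrow(kp))
    nodes <- rbind(nodes, data.frame(id = ids, x = kp[, 1], y = kp[, 2],
                                     z = kp[, 3], label = "leaf", organ = oid))
    if (nrow(kp) > 1) edges <- rbind(edges, cbind(ids[-length(ids)], ids[-1]))
    attach_stem <- which.min(sqrt(rowSums(sweep(stem_kp, 2, kp[1, ])^2)))
    edges <- rbind(edges, c(ids[1], attach_stem))
  }
  skeleton(nodes, edges)
}
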