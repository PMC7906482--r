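#' Specification of a synthetic potted seedling
#'
#' Describes a single plant as a curved stem (tube around a control curve)
#' with planar, drooped elliptical leaves attached at given heights. Two
#' presets mirror the two morphologies the registration problem is hardest
#' and easiest on: `"tomato"` (many small leaflets on a short stem) and
#' `"maize"` (few long leaves on a taller stem).
#'
#' @param preset `"tomato"` or `"maize"`, or `NULL` to specify everything.
#' @param height plant height (m).
#' @param stem_radius stem tube radius (m).
#' @param bend lateral offset of the stem tip (m); the stem bows smoothly.
#' @param leaves data frame with one row per leaf: `height_frac` (attachment
#'   height as a fraction of stem length, in (0, 1]), `azimuth` (rad),
#'   `length`, `width` (m), `droop` (rad below horizontal).
#' @param stem_points,leaf_points surface sample counts per organ.
#' @param noise_sigma per-point Gaussian sensor noise (m); default 0.5 mm.
#' @param petiole_gap gap between the stem surface and the leaf blade (m);
#'   keeps a realistic stem-leaf clearance.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(preset = c("tomato", "maize"), height = NULL,
                       stem_radius = NULL, bend = NULL, leaves = NULL,
                       stem_points = NULL, leaf_points = NULL,
                       noise_sigma = 5e-4, petiole_gap = 5e-3, seed = 1L) {
  preset <- if (is.null(preset)) "custom" else match.arg(preset)
  if (preset == "tomato") {
    if (is.null(height)) height <- 0.12
    if (is.null(stem_radius)) stem_radius <- 0.0025
    if (is.null(bend)) bend <- 0.008
    if (is.null(leaves))
      leaves <- data.frame(
        height_frac = c(0.30, 0.45, 0.60, 0.72, 0.85),
        azimuth = c(0.3, 2.4, 4.4, 1.3, 3.4),
        length = c(0.035, 0.035, 0.030, 0.028, 0.025),
        width = c(0.020, 0.020, 0.018, 0.016, 0.014),
        droop = c(0.45, 0.40, 0.35, 0.30, 0.30))
    if (is.null(stem_points)) stem_points <- 3000L
    if (is.null(leaf_points)) leaf_points <- 900L
  } else if (preset == "maize") {
    if (is.null(height)) height <- 0.22
    if (is.null(stem_radius)) stem_radius <- 0.004
    if (is.null(bend)) bend <- 0.012
    if (is.null(leaves))
      leaves <- data.frame(
        height_frac = c(0.35, 0.55, 0.78),
        azimuth = c(0.5, 3.6, 1.8),
        length = c(0.085, 0.075, 0.060),
        width = c(0.022, 0.020, 0.016),
        droop = c(0.55, 0.45, 0.40))
    if (is.null(stem_points)) stem_points <- 4500L
    if (is.null(leaf_points)) leaf_points <- 1400L
  }
  stopifnot(height > 0, stem_radius > 0, noise_sigma > 0,
            all(leaves$height_frac > 0), all(leaves$height_frac <= 1),
            all(leaves$length > 0), all(leaves$width > 0))
  structure(list(height = height, stem_radius = stem_radius, bend = bend,
                 leaves = leaves, stem_points = as.integer(stem_points),
                 leaf_points = as.integer(leaf_points),
                 noise_sigma = noise_sigma, petiole_gap = petiole_gap,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

# smoothly bowed stem center line and its unit tangent, t in [0, 1]
.stem_curve <- function(spec) {
  h <- spec$height; b <- spec$bend
  list(pos = function(t) cbind(b * t^2, 0.4 * b * t^2, h * t),
       tan = function(t) {
         d <- cbind(2 * b * t, 0.8 * b * t, h)
         d / sqrt(rowSums(d^2))
       })
}

.leaf_frame <- function(az, droop) {
  dir <- c(cos(az) * cos(droop), sin(az) * cos(droop), -sin(droop))
  lat <- c(-sin(az), cos(az), 0)
  list(dir = dir, lat = lat)
}

# clean (noise-free) surface samples + axis keypoints for one leaf
.sample_leaf <- function(attach, az, droop, len, wid, gap, npts, min_spacing) {
  fr <- .leaf_frame(az, droop)
  start <- attach + gap * fr$dir
  center <- start + (len / 2) * fr$dir
  r <- sqrt(stats::runif(npts))
  phi <- stats::runif(npts, 0, 2 * pi)
  pts <- matrix(center, npts, 3, byrow = TRUE) +
    outer(r * cos(phi) * len / 2, fr$dir) + outer(r * sin(phi) * wid / 2, fr$lat)
  n_kp <- max(2L, as.integer(ceiling((gap + len) / min_spacing)) + 1L)
  s <- seq(0, gap + len, length.out = n_kp)
  kp <- matrix(attach, n_kp, 3, byrow = TRUE) + outer(s, fr$dir)
  list(points = pts, keypoints = kp)
}

#' Generate a labeled synthetic plant point cloud with its true skeleton
#'
#' Samples the stem on a tube around the bowed center line and each leaf on a
#' drooped planar ellipse, adds Gaussian sensor noise, and builds the
#' ground-truth skeleton with nodes spaced at most `min_spacing` along the
#' generating curves. Instance ids: stem = 1, leaves = 2, 3, ... in the order
#' of the spec's leaf table.
#'
#' @param spec a [plant_spec()].
#' @param min_spacing truth-skeleton node spacing (m).
#' @return a list with `cloud` (labeled [point_cloud()]), `skeleton` (truth
#'   [skeleton()]), and `clean` (the noise-free point matrix, useful for
#'   constructing known deformations).
#' @export
generate_plant <- function(spec, min_spacing = 0.010) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  cv <- .stem_curve(spec)

  t_s <- stats::runif(spec$stem_points)
  theta <- stats::runif(spec$stem_points, 0, 2 * pi)
  cpos <- cv$pos(t_s)
  tang <- cv$tan(t_s)
  ref <- c(1, 0, 0)
  u <- cbind(tang[, 2] * ref[3] - tang[, 3] * ref[2],
             tang[, 3] * ref[1] - tang[, 1] * ref[3],
             tang[, 1] * ref[2] - tang[, 2] * ref[1])
  u <- u / sqrt(rowSums(u^2))
  w <- cbind(tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
             tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
             tang[, 1] * u[, 2] - tang[, 2] * u[, 1])
  stem_clean <- cpos + spec$stem_radius * (cos(theta) * u + sin(theta) * w)

  # stem keypoints at <= min_spacing along the center line
  arc <- spec$height * 1.01  # curve is nearly vertical; slight bow margin
  n_kp <- max(2L, as.integer(ceiling(arc / min_spacing)) + 1L)
  kp_stem <- cv$pos(seq(0, 1, length.out = n_kp))

  clean <- stem_clean
  labels <- rep("stem", nrow(stem_clean))
  instances <- rep(1L, nrow(stem_clean))
  nodes <- data.frame(id = seq_len(n_kp), x = kp_stem[, 1], y = kp_stem[, 2],
                      z = kp_stem[, 3], label = "stem", organ = 1L)
  edges <- cbind(1:(n_kp - 1), 2:n_kp)

  for (l in seq_len(nrow(spec$leaves))) {
    lf <- spec$leaves[l, ]
    attach <- as.numeric(cv$pos(lf$height_frac))
    sm <- .sample_leaf(attach, lf$azimuth, lf$droop, lf$length, lf$width,
                       spec$petiole_gap, spec$leaf_points, min_spacing)
    clean <- rbind(clean, sm$points)
    labels <- c(labels, rep("leaf", nrow(sm$points)))
    instances <- c(instances, rep(l + 1L, nrow(sm$points)))
    base_id <- nrow(nodes)
    ids <- base_id + seq_len(nrow(sm$keypoints))
    nodes <- rbind(nodes, data.frame(id = ids, x = sm$keypoints[, 1],
                                     y = sm$keypoints[, 2], z = sm$keypoints[, 3],
                                     label = "leaf", organ = l + 1L))
    edges <- rbind(edges, cbind(ids[-length(ids)], ids[-1]))
    # attach the leaf chain to the nearest stem keypoint
    d <- sqrt(rowSums(sweep(kp_stem, 2, sm$keypoints[1, ])^2))
    edges <- rbind(edges, c(ids[1], which.min(d)))
  }

  noisy <- clean + matrix(stats::rnorm(length(clean), 0, spec$noise_sigma),
                          nrow(clean), 3)
  structure(list(cloud = point_cloud(noisy, labels, instances),
                 skeleton = skeleton(nodes, edges),
                 clean = clean),
            spec = spec)
}

#' Specification of growth between two scans
#'
#' Growth is modeled as a global uniform scaling about the stem base composed
#' with per-leaf anisotropic changes: elongation along the leaf axis about
#' its attachment point and an increase of the droop angle (leaves sag as
#' they grow). New leaves may emerge near the top of the stem. All applied
#' transforms are returned exactly, enabling parameter-recovery tests.
#'
#' @param scale global scale factor about the stem base.
#' @param leaf_elongation per-leaf elongation factor(s) along the leaf axis
#'   (recycled over leaves).
#' @param droop_delta per-leaf droop increase in radians (recycled).
#' @param new_leaves number of leaves emerging in the child scan.
#' @param noise_sigma sensor noise of the child scan (m).
#' @param seed RNG seed for the child scan's sampling noise.
#' @return a `growth_spec` list.
#' @export
growth_spec <- function(scale = 1.15, leaf_elongation = 1.2,
                        droop_delta = 10 * pi / 180, new_leaves = 1L,
                        noise_sigma = 5e-4, seed = 2L) {
  stopifnot(scale > 0, all(leaf_elongation > 0))
  structure(list(scale = scale, leaf_elongation = leaf_elongation,
                 droop_delta = droop_delta, new_leaves = as.integer(new_leaves),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "growth_spec")
}

# affine helpers
.affine <- function(A, t) { M <- diag(4); M[1:3, 1:3] <- A; M[1:3, 4] <- t; M }
.scale_about <- function(s, c) .affine(diag(3) * s, (1 - s) * c)
.elongate_about <- function(f, dir, c) {
  A <- diag(3) + (f - 1) * outer(dir, dir)
  .affine(A, c - A %*% c)
}
.rotate_about <- function(axis, angle, c) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  .affine(R, c - R %*% c)
}

#' Grow a synthetic plant into a child scan with known deformations
#'
#' Applies the growth model at fraction `stage` (1 = the full inter-scan
#' growth, 0.5 = the midpoint) to the parent plant: every parent skeleton
#' node receives a known affine transform (global scaling composed with its
#' leaf's elongation and droop rotation about the attachment point), the
#' parent's noise-free points are deformed by blending these node transforms
#' along the skeleton, fresh sensor noise is added, and — at `stage = 1` —
#' new leaves are inserted near the top of the stem. The exact per-node
#' transforms and the node correspondence (identity on parent node ids) are
#' returned for validation.
#'
#' @param plant output of [generate_plant()].
#' @param growth a [growth_spec()].
#' @param stage growth fraction in (0, 1].
#' @param min_spacing truth-skeleton node spacing for inserted leaves (m).
#' @return list with `cloud` (child [point_cloud()]), `skeleton` (child truth
#'   [skeleton()]), `transforms` (truth [node_transforms] for parent nodes),
#'   `correspondences` (truth `correspondence_set`), and `clean`.
#' @export
grow_plant <- function(plant, growth, stage = 1, min_spacing = 0.010) {
  stopifnot(inherits(growth, "growth_spec"), stage > 0, stage <= 1)
  set.seed(growth$seed)
  S <- plant$skeleton
  n <- nrow(S$nodes)
  s_t <- 1 + (growth$scale - 1) * stage
  base <- as.numeric(S$nodes[match(S$root, S$nodes$id), c("x", "y", "z")])
  G <- .scale_about(s_t, base)

  organs <- sort(unique(S$nodes$organ))
  leaf_organs <- organs[organs != 1L]
  elong <- rep_len(growth$leaf_elongation, length(leaf_organs))
  ddroop <- rep_len(growth$droop_delta, length(leaf_organs))

  transforms <- vector("list", n)
  names(transforms) <- S$nodes$id
  for (i in seq_len(n)) {
    if (S$nodes$label[i] == "stem") {
      transforms[[i]] <- G
    } else {
      l <- match(S$nodes$organ[i], leaf_organs)
      chain <- S$nodes[S$nodes$organ == S$nodes$organ[i], ]
      attach <- as.numeric(chain[1, c("x", "y", "z")])
      tipv <- as.numeric(chain[nrow(chain), c("x", "y", "z")]) - attach
      dir <- tipv / sqrt(sum(tipv^2))
      lat <- c(-dir[2], dir[1], 0)
      lat <- lat / sqrt(sum(lat^2))
      f_t <- 1 + (elong[l] - 1) * stage
      E <- .elongate_about(f_t, dir, attach)
      # positive rotation about the lateral axis lowers the tip
      ang <- ddroop[l] * stage
      Rz <- .droop_rotation(dir, lat, ang, attach)
      transforms[[i]] <- G %*% Rz %*% E
    }
  }
  class(transforms) <- "node_transforms"

  # child skeleton: transformed parent nodes
  child_nodes <- S$nodes
  for (i in seq_len(n)) {
    p <- transforms[[i]] %*% c(S$nodes$x[i], S$nodes$y[i], S$nodes$z[i], 1)
    child_nodes$x[i] <- p[1]; child_nodes$y[i] <- p[2]; child_nodes$z[i] <- p[3]
  }
  child_edges <- S$edges

  # child cloud: blend the known node transforms over the parent's clean points
  parent_clean <- point_cloud(plant$clean, plant$cloud$labels,
                              plant$cloud$instances)
  warped <- deform_cloud(parent_clean, S, transforms)
  clean <- warped$points
  labels <- warped$labels
  instances <- warped$instances

  # new leaves emerge near the top of the (scaled) stem
  if (stage >= 1 && growth$new_leaves > 0) {
    stem_nodes <- child_nodes[child_nodes$label == "stem", ]
    spec0 <- attr(plant, "spec")
    npts_new <- if (!is.null(spec0)) max(150L, as.integer(round(spec0$leaf_points * 0.3)))
                else 250L
    for (k in seq_len(growth$new_leaves)) {
      hf <- 0.93 - 0.06 * (k - 1)
      zs <- stem_nodes$z
      target_z <- min(zs) + hf * (max(zs) - min(zs))
      irow <- which.min(abs(zs - target_z))
      attach <- as.numeric(stem_nodes[irow, c("x", "y", "z")])
      az <- 5.5 + 1.7 * (k - 1)
      sm <- .sample_leaf(attach, az, 0.35, 0.018, 0.010, 0.004,
                         npts_new, min_spacing)
      oid <- max(child_nodes$organ) + 1L
      clean <- rbind(clean, sm$points)
      labels <- c(labels, rep("leaf", nrow(sm$points)))
      instances <- c(instances, rep(oid, nrow(sm$points)))
      base_id <- max(child_nodes$id)
      ids <- base_id + seq_len(nrow(sm$keypoints))
      child_nodes <- rbind(child_nodes,
                           data.frame(id = ids, x = sm$keypoints[, 1],
                                      y = sm$keypoints[, 2], z = sm$keypoints[, 3],
                                      label = "leaf", organ = oid))
      child_edges <- rbind(child_edges, cbind(ids[-length(ids)], ids[-1]),
                           c(ids[1], stem_nodes$id[irow]))
    }
  }

  noisy <- clean + matrix(stats::rnorm(length(clean), 0, growth$noise_sigma),
                          nrow(clean), 3)
  C <- data.frame(source = S$nodes$id, target = S$nodes$id)
  class(C) <- c("correspondence_set", "data.frame")
  list(cloud = point_cloud(noisy, labels, instances),
       skeleton = skeleton(child_nodes, child_edges),
       transforms = transforms,
       correspondences = C,
       clean = clean)
}

# rotation that increases the droop: rotate the leaf direction about the
# lateral axis so that the tip moves downward
.droop_rotation <- function(dir, lat, angle, center) {
  R1 <- .rotate_about(lat, angle, center)
  d1 <- (R1[1:3, 1:3] %*% dir)[3]
  R2 <- .rotate_about(lat, -angle, center)
  d2 <- (R2[1:3, 1:3] %*% dir)[3]
  if (d1 <= d2) R1 else R2
}
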