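#' Mean nearest-neighbor registration error
#'
#' For every point of the deformed source cloud, the distance to its nearest
#' neighbor in the target cloud; the mean is the registration error, with the
#' standard deviation and maximum reported alongside.
#'
#' @param deformed deformed source [point_cloud()].
#' @param target target [point_cloud()].
#' @return list with `mean`, `sd`, `max` (m) and the per-point `distances`.
#' @export
registration_error <- function(deformed, target) {
  if (n_points(deformed) == 0 || n_points(target) == 0) stop("empty point cloud")
  d <- cpp_nn1(deformed$points, target$points)$dist
  list(mean = mean(d), sd = stats::sd(d), max = max(d), distances = d)
}

#' Organ-level correspondence accuracy
#'
#' Fraction of matched node pairs whose two nodes carry the same persistent
#' organ identifier. Not-matched source nodes are ignored.
#'
#' @param C12 correspondence data frame (`source`, `target`).
#' @param organ_truth_1,organ_truth_2 named vectors mapping node id (as
#'   character names) to persistent organ id, for the source and target
#'   skeletons.
#' @return fraction in `[0, 1]` (`NaN` if nothing is matched).
#' @export
correspondence_accuracy <- function(C12, organ_truth_1, organ_truth_2) {
  m <- !is.na(C12$target)
  if (!any(m)) return(NaN)
  o1 <- organ_truth_1[as.character(C12$source[m])]
  o2 <- organ_truth_2[as.character(C12$target[m])]
  mean(o1 == o2)
}

#' Map extracted skeleton nodes to persistent organ ids
#'
#' An extracted skeleton's organ ids are segmentation instance ids, which are
#' arbitrary across scans. When the cloud carries ground-truth instance ids,
#' each segmentation instance is mapped to the truth instance holding the
#' majority of its points, giving every skeleton node a persistent organ id
#' comparable across scans.
#'
#' @param S an extracted [skeleton()].
#' @param segmentation the `organ_segmentation` the skeleton was built from.
#' @param cloud the [point_cloud()] with ground-truth `instances`.
#' @return named vector: node id (character) -> persistent organ id.
#' @export
persistent_organ_map <- function(S, segmentation, cloud) {
  if (is.null(cloud$instances)) stop("cloud has no ground-truth instance ids")
  inst_map <- vapply(unique(segmentation$instances), function(i) {
    truth <- cloud$instances[segmentation$instances == i]
    as.integer(names(sort(table(truth), decreasing = TRUE))[1])
  }, integer(1))
  names(inst_map) <- unique(segmentation$instances)
  out <- inst_map[as.character(S$nodes$organ)]
  names(out) <- S$nodes$id
  out
}

#' Instance transfer accuracy of a deformation
#'
#' Fraction of deformed source points whose nearest neighbor in the target
#' cloud belongs to the corresponding organ instance. Guards against the
#' degenerate "all points collapse onto one target point" failure mode that a
#' small nearest-neighbor error alone would not detect.
#'
#' @param deformed deformed source cloud carrying `instances`.
#' @param target target cloud carrying ground-truth `instances`.
#' @param mapping optional named vector mapping source instance id ->
#'   target instance id; by default ids correspond directly.
#' @return fraction in `[0, 1]`.
#' @export
instance_transfer_accuracy <- function(deformed, target, mapping = NULL) {
  if (is.null(deformed$instances) || is.null(target$instances))
    stop("both clouds must carry instance ids")
  sel <- deformed$instances > 0
  nn <- cpp_nn1(deformed$points[sel, , drop = FALSE], target$points)
  src <- deformed$instances[sel]
  if (!is.null(mapping)) src <- mapping[as.character(src)]
  mean(target$instances[nn$idx] == src)
}

# segment one cloud: ground-truth labels when available and allowed,
# otherwise the trained classifier
.segment_cloud <- function(cloud, config, classifier) {
  if (isTRUE(config$pipeline$use_labels) && !is.null(cloud$labels)) {
    classes <- cloud$labels
  } else {
    if (is.null(classifier))
      stop("no classifier given and cloud has no labels", call. = FALSE)
    feats <- compute_features(cloud, radius = config$features$radius,
                              k_min = config$features$k_min)
    classes <- classify_points(classifier, feats)
  }
  cluster_instances(cloud, classes,
                    eps = config$segmentation$eps,
                    min_samples = config$segmentation$min_samples,
                    min_cluster_size = config$segmentation$min_cluster_size,
                    k_reassign = config$segmentation$k_reassign)
}

#' Register a pair of temporally separated plant scans
#'
#' The full skeleton-driven non-rigid registration: both clouds are segmented
#' into organs and skeletonized, then the pipeline alternates between HMM
#' correspondence estimation (with the source skeleton nodes moved by the
#' current deformation, so distant matches can be captured) and per-node
#' affine deformation estimation, until the correspondence set stops changing
#' or `max_outer_iter` is reached. Finally the whole source cloud is warped
#' by blending the node transforms.
#'
#' @param P1,P2 source and target [point_cloud()]s. If they carry labels and
#'   `config$pipeline$use_labels` is `TRUE` (default), those labels drive
#'   segmentation; otherwise `classifier` is required.
#' @param config parameter list from [default_config()].
#' @param classifier optional `point_classifier` for label-free clouds.
#' @param seed RNG seed; the whole run is deterministic given the seed.
#' @return an object of class `registration_result`: list with `S1`, `S2`
#'   (skeletons), `seg1`, `seg2`, `correspondences`, `transforms`, `deformed`
#'   (warped P1), `e_reg`, `iterations`, `match_history` (matched-pair counts
#'   per outer iteration), and `stable` (whether the correspondence set
#'   converged before the cap).
#' @export
register_pair <- function(P1, P2, config = default_config(), classifier = NULL,
                          seed = 1L) {
  stopifnot(inherits(P1, "point_cloud"), inherits(P2, "point_cloud"))
  if (n_points(P1) == 0 || n_points(P2) == 0) stop("empty input cloud")
  set.seed(seed)
  seg1 <- tryCatch(.segment_cloud(P1, config, classifier),
                   error = function(e) stop("segmentation of P1 failed: ",
                                            conditionMessage(e), call. = FALSE))
  seg2 <- tryCatch(.segment_cloud(P2, config, classifier),
                   error = function(e) stop("segmentation of P2 failed: ",
                                            conditionMessage(e), call. = FALSE))
  mk_skel <- function(seg, cloud, which) {
    # both skeletons use the same SOM seed so identical clouds give
    # identical skeletons
    tryCatch(build_skeleton(seg, cloud,
                            min_spacing = config$skeleton$min_spacing,
                            epochs = config$skeleton$som_epochs,
                            eta = config$skeleton$som_eta,
                            tol = config$skeleton$som_tol,
                            seed = seed),
             error = function(e) stop("skeletonization of ", which, " failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  S1 <- mk_skel(seg1, P1, "P1")
  S2 <- mk_skel(seg2, P2, "P2")

  mw <- list(w_d = config$matching$w_d, w_e = config$matching$w_e,
             w_sem = config$matching$w_sem)
  dw <- list(w_corresp = config$deformation$w_corresp,
             w_rot = config$deformation$w_rot,
             w_reg = config$deformation$w_reg)
  transforms <- NULL
  C_prev <- NULL
  history <- integer(0)
  stable <- FALSE
  iterations <- 0L
  for (it in seq_len(config$pipeline$max_outer_iter)) {
    S1_cur <- if (is.null(transforms)) S1 else apply_node_transforms(S1, transforms)
    C <- viterbi_match(S1_cur, S2, weights = mw, c_nm = config$matching$c_nm,
                       S1_structure = if (is.null(transforms)) NULL else S1)
    history <- c(history, sum(!is.na(C$target)))
    if (!is.null(C_prev) && identical(C$target, C_prev$target)) {
      stable <- TRUE
      break
    }
    iterations <- it
    transforms <- optimize_deformation(
      S1, S2, C, weights = dw,
      cauchy_scale = config$deformation$cauchy_scale,
      max_iter = config$deformation$max_iter,
      step_tol = config$deformation$step_tol,
      init = transforms)
    C_prev <- C
  }
  deformed <- deform_cloud(P1, S1, transforms)
  structure(list(S1 = S1, S2 = S2, seg1 = seg1, seg2 = seg2,
                 correspondences = C_prev, transforms = transforms,
                 deformed = deformed,
                 e_reg = registration_error(deformed, P2),
                 iterations = iterations, match_history = history,
                 stable = stable),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("registration_result: %d -> %d skeleton nodes, ",
                     "%d matched, e_reg %.2f mm (sd %.2f, max %.2f), ",
                     "%d outer iteration(s)%s\n"),
              nrow(x$S1$nodes), nrow(x$S2$nodes),
              sum(!is.na(x$correspondences$target)),
              1000 * x$e_reg$mean, 1000 * x$e_reg$sd, 1000 * x$e_reg$max,
              x$iterations, if (x$stable) "" else " (cap reached)"))
  invisible(x)
}

#' Rigid ICP baseline
#'
#' Standard point-to-point iterative-closest-point registration with a single
#' rigid transform, for comparison against the non-rigid pipeline. Pairs
#' whose nearest-neighbor distance exceeds 2.5x the median are rejected in
#' each iteration.
#'
#' @param P1,P2 source and target [point_cloud()]s.
#' @param max_iter iteration cap.
#' @param tol stop when the motion of the estimate falls below this.
#' @param subsample source subsample size used to fit the transform.
#' @return list with the 4x4 `transform`, `e_reg` (from
#'   [registration_error()] on the fully transformed `P1`), and `diverged`
#'   (`TRUE` when the final error exceeds the initial one).
#' @export
icp_baseline <- function(P1, P2, max_iter = 50L, tol = 1e-8, subsample = 2000L) {
  if (n_points(P1) == 0 || n_points(P2) == 0) stop("empty point cloud")
  P <- P1$points
  if (nrow(P) > subsample)
    P <- P[round(seq(1, nrow(P), length.out = subsample)), , drop = FALSE]
  Q <- P2$points
  R <- diag(3); tr <- c(0, 0, 0)
  e_prev <- Inf
  for (it in seq_len(max_iter)) {
    Pt <- t(R %*% t(P)) + matrix(tr, nrow(P), 3, byrow = TRUE)
    nn <- cpp_nn1(Pt, Q)
    keep <- nn$dist <= 2.5 * stats::median(nn$dist)
    A <- Pt[keep, , drop = FALSE]
    B <- Q[nn$idx[keep], , drop = FALSE]
    ca <- colMeans(A); cb <- colMeans(B)
    H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    Rstep <- sv$v %*% D %*% t(sv$u)
    tstep <- cb - Rstep %*% ca
    R <- Rstep %*% R
    tr <- as.numeric(Rstep %*% tr + tstep)
    e <- mean(nn$dist[keep])
    if (abs(e_prev - e) < tol) break
    e_prev <- e
  }
  M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- tr
  full <- point_cloud(t(R %*% t(P1$points)) +
                        matrix(tr, n_points(P1), 3, byrow = TRUE),
                      P1$labels, P1$instances)
  err <- registration_error(full, P2)
  err0 <- registration_error(P1, P2)
  list(transform = M, e_reg = err, diverged = err$mean > err0$mean)
}
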