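#' Warp a point cloud with per-node skeleton transforms
#'
#' Each point is deformed by a convex blend of the affine transforms attached
#' to the two endpoint nodes of the skeleton edge nearest to it:
#' `p_hat = alpha_a T_a p + alpha_b T_b p`, where the weights come from the
#' normalized projection parameter of `p` onto that edge, clamped to `[0, 1]`
#' (points beyond an endpoint — e.g. leaf tips — take that endpoint's
#' transform fully). Labels and instance ids are carried through unchanged.
#'
#' @param cloud the source [point_cloud()].
#' @param S the source [skeleton()].
#' @param transforms a [node_transforms] list covering every node of `S`.
#' @return the deformed `point_cloud`.
#' @export
deform_cloud <- function(cloud, S, transforms) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(S, "skeleton"))
  if (nrow(S$nodes) == 0) stop("empty skeleton")
  P <- cloud$points
  n <- nrow(P)
  ids <- S$nodes$id
  miss <- setdiff(as.character(ids), names(transforms))
  if (length(miss) > 0) stop("missing transforms for node(s) ", paste(miss, collapse = ", "))
  if (nrow(S$edges) == 0) {
    Ti <- transforms[[as.character(ids[1])]]
    Q <- t(Ti[1:3, 1:3] %*% t(P)) + matrix(Ti[1:3, 4], n, 3, byrow = TRUE)
    return(point_cloud(Q, cloud$labels, cloud$instances))
  }
  ne <- nrow(S$edges)
  X <- as.matrix(S$nodes[c("x", "y", "z")])
  best_d2 <- rep(Inf, n)
  best_e <- integer(n)
  best_s <- numeric(n)
  for (e in seq_len(ne)) {
    a <- X[match(S$edges[e, 1], ids), ]
    b <- X[match(S$edges[e, 2], ids), ]
    ab <- b - a
    len2 <- sum(ab^2)
    dp <- sweep(P, 2, a)
    s <- if (len2 > 0) pmin(1, pmax(0, as.numeric(dp %*% ab) / len2)) else rep(0, n)
    foot <- outer(s, ab) + matrix(a, n, 3, byrow = TRUE)
    d2 <- rowSums((P - foot)^2)
    upd <- d2 < best_d2  # strict: ties keep the lower edge index
    best_d2[upd] <- d2[upd]
    best_e[upd] <- e
    best_s[upd] <- s[upd]
  }
  # precompute T p for the needed nodes
  Tp <- list()
  node_pts <- function(id) {
    key <- as.character(id)
    if (is.null(Tp[[key]])) {
      Ti <- transforms[[key]]
      Tp[[key]] <<- t(Ti[1:3, 1:3] %*% t(P)) + matrix(Ti[1:3, 4], n, 3, byrow = TRUE)
    }
    Tp[[key]]
  }
  Q <- matrix(0, n, 3)
  for (e in unique(best_e)) {
    sel <- best_e == e
    ida <- S$edges[e, 1]; idb <- S$edges[e, 2]
    s <- best_s[sel]
    A <- node_pts(ida)[sel, , drop = FALSE]
    B <- node_pts(idb)[sel, , drop = FALSE]
    Q[sel, ] <- A + s * (B - A)  # exact when both transforms agree
  }
  point_cloud(Q, cloud$labels, cloud$instances)
}

#' Polar decomposition of an affine transform
#'
#' Factors a 4x4 affine `T` as `T = T_s T_R T_t`: a symmetric
#' positive-definite scale/shear `T_s`, a pure rotation `T_R` (determinant
#' +1), and a pure translation `T_t`. Computed from the SVD of the linear
#' part; reflections (negative determinant) are rejected.
#'
#' @param T_affine a 4x4 affine with nonsingular, positive-determinant linear
#'   part.
#' @return list with 4x4 matrices `Ts`, `TR`, `Tt`; their product reproduces
#'   `T_affine` to machine precision.
#' @export
decompose_affine <- function(T_affine) {
  A <- T_affine[1:3, 1:3]
  dA <- det(A)
  if (abs(dA) < 1e-300) stop("singular linear part")
  if (dA < 0) stop("reflection (negative determinant) unsupported")
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  S <- A %*% t(R)  # symmetric positive definite
  tt <- solve(A, T_affine[1:3, 4])
  mk <- function(lin, tr) { M <- diag(4); M[1:3, 1:3] <- lin; M[1:3, 4] <- tr; M }
  list(Ts = mk(S, c(0, 0, 0)), TR = mk(R, c(0, 0, 0)), Tt = mk(diag(3), tt))
}

# rotation matrix <-> unit quaternion (w, x, y, z)
.rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# spherical linear interpolation from the identity rotation
.slerp_from_identity <- function(R, t) {
  q <- .rot_to_quat(R)
  if (q[1] < 0) q <- -q  # shorter arc
  w <- min(1, max(-1, q[1]))
  theta <- acos(w)
  if (theta < 1e-12) return(diag(3))
  axis <- q[2:4] / sin(theta)
  th_t <- t * theta
  .quat_to_rot(c(cos(th_t), sin(th_t) * axis))
}

#' Interpolate an affine transform toward the identity
#'
#' Produces the transform at fraction `t` of the way from the identity to
#' `T`: the scale/shear and translation factors of the polar decomposition
#' are interpolated linearly and the rotation by spherical linear
#' interpolation (constant angular velocity), then recomposed as
#' `T(t) = lerp(I, T_s; t) slerp(I, T_R; t) lerp(I, T_t; t)`.
#'
#' @param T_affine a 4x4 affine (see [decompose_affine()]).
#' @param t interpolation fraction in `[0, 1]`; `T(0)` is the identity and
#'   `T(1)` reproduces `T_affine`.
#' @return a 4x4 affine.
#' @export
interpolate_transform <- function(T_affine, t) {
  if (!is.finite(t) || t < 0 || t > 1) stop("`t` must be in [0, 1]")
  d <- decompose_affine(T_affine)
  St <- (1 - t) * diag(3) + t * d$Ts[1:3, 1:3]
  Rt <- .slerp_from_identity(d$TR[1:3, 1:3], t)
  ttr <- t * d$Tt[1:3, 4]
  M <- diag(4)
  M[1:3, 1:3] <- St %*% Rt
  M[1:3, 4] <- St %*% Rt %*% ttr
  M
}

#' Interpolate a deformed point cloud at an intermediate time
#'
#' Applies [deform_cloud()] with every node transform replaced by
#' [interpolate_transform()] at fraction `t`, giving an estimate of the plant
#' in between the two acquisition times. `t = 0` returns the source cloud and
#' `t = 1` the fully deformed cloud.
#'
#' @inheritParams deform_cloud
#' @param t interpolation fraction in `[0, 1]`.
#' @return a `point_cloud`.
#' @export
interpolate_cloud <- function(cloud, S, transforms, t) {
  Ti <- lapply(transforms, interpolate_transform, t = t)
  names(Ti) <- names(transforms)
  class(Ti) <- "node_transforms"
  deform_cloud(cloud, S, Ti)
}
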