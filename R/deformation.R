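#' Energy terms of the skeletal deformation objective
#'
#' `energy_corresp` sums, over matched correspondences, the distance between
#' the transformed source node and its target node, `||T_i x_i - y_j||`,
#' optionally passed through the Cauchy robust loss
#' `rho(r) = s^2/2 log(1 + (r/s)^2)`. Not-matched pairs contribute nothing.
#'
#' @param transforms a [node_transforms] list keyed by `S1` node id.
#' @param C12 correspondence data frame (`source`, `target`, `NA` = unmatched).
#' @param S1,S2 source and target [skeleton()]s.
#' @param cauchy_scale Cauchy kernel scale in meters, or `NULL` for the plain
#'   (unrobustified) norm.
#' @return non-negative scalar.
#' @export
energy_corresp <- function(transforms, C12, S1, S2, cauchy_scale = NULL) {
  total <- 0
  for (r in seq_len(nrow(C12))) {
    j <- C12$target[r]
    if (is.na(j)) next
    Ti <- transforms[[as.character(C12$source[r])]]
    if (is.null(Ti)) stop("missing transform for node ", C12$source[r])
    x <- c(.node_pos(S1, C12$source[r]), 1)
    y <- .node_pos(S2, j)
    d <- sqrt(sum(((Ti %*% x)[1:3] - y)^2))
    total <- total + if (is.null(cauchy_scale)) d else
      cauchy_scale^2 / 2 * log(1 + (d / cauchy_scale)^2)
  }
  total
}

#' @rdname energy_corresp
#' @details `energy_rot` measures how far the linear part of a single affine
#' transform is from a pure rotation: the squared dot products of the three
#' column pairs (orthogonality) plus the squared deviations of the three
#' column norms from 1. It is zero exactly when the linear part is
#' orthonormal, and is invariant under column-wise sign flips.
#' @param T_affine a single 4x4 affine transform.
#' @export
energy_rot <- function(T_affine) {
  A <- T_affine[1:3, 1:3]
  c1 <- A[, 1]; c2 <- A[, 2]; c3 <- A[, 3]
  sum(c(sum(c1 * c2), sum(c2 * c3), sum(c3 * c1))^2) +
    sum((c(sum(c1 * c1), sum(c2 * c2), sum(c3 * c3)) - 1)^2)
}

#' @rdname energy_corresp
#' @details `energy_reg` couples skeleton-adjacent transforms: for every
#' skeleton edge (taken once, with the lower node id first) it adds the
#' Frobenius norm of `T_i^-1 T_j - I` after dividing each matrix by its (4,4)
#' entry (homogeneous normalization). Zero when all transforms are equal.
#' @export
energy_reg <- function(transforms, S1) {
  total <- 0
  for (e in seq_len(nrow(S1$edges))) {
    ij <- sort(S1$edges[e, ])
    Ti <- transforms[[as.character(ij[1])]]
    Tj <- transforms[[as.character(ij[2])]]
    if (abs(det(Ti)) < 1e-300)
      stop("singular transform at node ", ij[1])
    M <- solve(Ti) %*% Tj
    M <- M / M[4, 4]
    total <- total + sqrt(sum((M - diag(4))^2))
  }
  total
}

#' Combined (reported) deformation energy
#'
#' `w_corresp * E_corresp + w_rot * E_rot + w_reg * E_reg` using the reported
#' (norm-based) energy terms. Defaults `w_corresp = 100`, `w_rot = 10`,
#' `w_reg = 1`.
#'
#' @inheritParams energy_corresp
#' @param weights list with `w_corresp`, `w_rot`, `w_reg`.
#' @return scalar total energy.
#' @export
energy_total <- function(transforms, C12, S1, S2,
                         weights = list(w_corresp = 100, w_rot = 10, w_reg = 1)) {
  weights$w_corresp * energy_corresp(transforms, C12, S1, S2) +
    weights$w_rot * sum(vapply(transforms, energy_rot, numeric(1))) +
    weights$w_reg * energy_reg(transforms, S1)
}

# --- Gauss-Newton machinery --------------------------------------------------
# Parameter vector: 12 entries per S1 node (node-table order): the 3x3 linear
# part row-major, then the translation.

.theta_to_transforms <- function(theta, ids) {
  n <- length(ids)
  Ts <- vector("list", n)
  for (i in seq_len(n)) {
    p <- theta[(12 * (i - 1) + 1):(12 * i)]
    Ti <- diag(4)
    Ti[1:3, 1:3] <- matrix(p[1:9], 3, 3, byrow = TRUE)
    Ti[1:3, 4] <- p[10:12]
    Ts[[i]] <- Ti
  }
  names(Ts) <- ids
  structure(Ts, class = "node_transforms")
}

.transforms_to_theta <- function(transforms) {
  unlist(lapply(transforms, function(Ti) c(t(Ti[1:3, 1:3]), Ti[1:3, 4])),
         use.names = FALSE)
}

# residuals and Jacobian of the least-squares system at theta.
# prob: list(n, X (node positions), pairs (node index, target pos rows),
#            edges (index pairs), weights, s_c)
# Returns r, J, and the robust objective value F.
.deform_residuals <- function(theta, prob, with_jacobian = TRUE) {
  n <- prob$n
  A <- vector("list", n); tr <- vector("list", n)
  for (i in seq_len(n)) {
    p <- theta[(12 * (i - 1) + 1):(12 * i)]
    A[[i]] <- matrix(p[1:9], 3, 3, byrow = TRUE)
    tr[[i]] <- p[10:12]
  }
  w_c <- prob$weights$w_corresp
  w_r <- prob$weights$w_rot
  w_g <- prob$weights$w_reg
  s_c <- prob$s_c
  npair <- length(prob$pairs$node)
  nres <- 3 * npair + 6 * n + 12 * nrow(prob$edges)
  r <- numeric(nres)
  J <- if (with_jacobian) matrix(0, nres, 12 * n) else NULL
  Fobj <- 0
  row0 <- 0L
  # index of parameter a_{rc} of node i (row-major), and of t_c
  pa <- function(i, rr, cc) 12 * (i - 1) + 3 * (rr - 1) + cc
  pt <- function(i, cc) 12 * (i - 1) + 9 + cc

  for (k in seq_len(npair)) {
    i <- prob$pairs$node[k]
    x <- prob$pairs$x[k, ]
    y <- prob$pairs$y[k, ]
    res <- A[[i]] %*% x + tr[[i]] - y
    d <- sqrt(sum(res^2))
    kap <- 1 / (1 + (d / s_c)^2)          # IRLS weight of the Cauchy loss
    Fobj <- Fobj + w_c * s_c^2 / 2 * log(1 + (d / s_c)^2)
    sc <- sqrt(w_c * kap)
    r[row0 + 1:3] <- sc * res
    if (with_jacobian) {
      for (rr in 1:3) {
        J[row0 + rr, pa(i, rr, 1:3)] <- sc * x
        J[row0 + rr, pt(i, rr)] <- sc
      }
    }
    row0 <- row0 + 3L
  }

  sr <- sqrt(w_r)
  combos <- rbind(c(1, 2), c(2, 3), c(3, 1))
  for (i in seq_len(n)) {
    Ai <- A[[i]]
    for (q in 1:3) {
      a <- combos[q, 1]; b <- combos[q, 2]
      val <- sum(Ai[, a] * Ai[, b])
      r[row0 + q] <- sr * val
      if (with_jacobian) {
        J[row0 + q, pa(i, 1:3, a)] <- sr * Ai[, b]
        J[row0 + q, pa(i, 1:3, b)] <- J[row0 + q, pa(i, 1:3, b)] + sr * Ai[, a]
      }
    }
    for (q in 1:3) {
      val <- sum(Ai[, q]^2) - 1
      r[row0 + 3 + q] <- sr * val
      if (with_jacobian) J[row0 + 3 + q, pa(i, 1:3, q)] <- sr * 2 * Ai[, q]
    }
    Fobj <- Fobj + sum(r[row0 + 1:6]^2)
    row0 <- row0 + 6L
  }

  sg <- sqrt(w_g)
  for (e in seq_len(nrow(prob$edges))) {
    i <- prob$edges[e, 1]; j <- prob$edges[e, 2]
    Ainv <- tryCatch(solve(A[[i]]), error = function(err)
      stop("singular transform at node index ", i))
    dt <- tr[[j]] - tr[[i]]
    Mlin <- Ainv %*% A[[j]]
    Mt <- Ainv %*% dt
    res <- cbind(Mlin - diag(3), Mt)  # 3 x 4
    r[row0 + 1:12] <- sg * as.numeric(t(res))  # row-major
    Fobj <- Fobj + w_g * sum(res^2)
    if (with_jacobian) {
      # rows of the residual block: row-major over the 3x4 matrix
      ridx <- function(rr, cc) row0 + 4 * (rr - 1) + cc
      for (rr in 1:3) for (cc in 1:3) {
        # d/d A_j[rr, cc]: Mlin gains Ainv[, rr] in column cc
        J[ridx(1:3, cc), pa(j, rr, cc)] <- sg * Ainv[, rr]
      }
      for (cc in 1:3) {
        # d/d t_j and t_i on the translation column
        J[ridx(1:3, 4), pt(j, cc)] <- sg * Ainv[, cc]
        J[ridx(1:3, 4), pt(i, cc)] <- -sg * Ainv[, cc]
      }
      for (rr in 1:3) for (cc in 1:3) {
        dAinv <- -Ainv[, rr, drop = FALSE] %*% Ainv[cc, , drop = FALSE]
        dMlin <- dAinv %*% A[[j]]
        dMt <- dAinv %*% dt
        dres <- cbind(dMlin, dMt)
        J[row0 + 1:12, pa(i, rr, cc)] <- sg * as.numeric(t(dres))
      }
    }
    row0 <- row0 + 12L
  }
  list(r = r, J = J, F = Fobj)
}

.robust_objective <- function(theta, prob) {
  .deform_residuals(theta, prob, with_jacobian = FALSE)$F
}

.build_deform_problem <- function(S1, S2, C12, weights, cauchy_scale) {
  ids <- S1$nodes$id
  X <- as.matrix(S1$nodes[c("x", "y", "z")])
  matched <- which(!is.na(C12$target))
  if (length(matched) == 0) stop("at least one matched correspondence required")
  node <- match(C12$source[matched], ids)
  Y <- t(vapply(C12$target[matched], function(j) .node_pos(S2, j), numeric(3)))
  if (nrow(S1$edges) > 0) {
    eo <- t(apply(S1$edges, 1, sort))
    edges <- cbind(match(eo[, 1], ids), match(eo[, 2], ids))
  } else edges <- matrix(integer(0), 0, 2)
  list(n = length(ids), ids = ids,
       pairs = list(node = node, x = X[node, , drop = FALSE], y = Y),
       edges = edges, weights = weights, s_c = cauchy_scale)
}

#' Estimate per-node affine deformations between two skeletons
#'
#' Minimizes the combined energy `w_corresp E_corresp + w_rot E_rot +
#' w_reg E_reg` over one 4x4 affine transform (12 free parameters) per source
#' node, by Gauss-Newton with Levenberg-style damping, starting from the
#' identity (or `init`). Correspondence residuals pass through the Cauchy
#' robust kernel, which bounds the influence of wrong correspondences;
#' orthonormality of the linear parts is soft-constrained by `E_rot`, and
#' `E_reg` propagates constraints to nodes without correspondences.
#'
#' @param S1,S2 source and target [skeleton()]s.
#' @param C12 correspondences from [viterbi_match()] (at least one match).
#' @param weights list with `w_corresp`, `w_rot`, `w_reg` (defaults 100, 10, 1).
#' @param cauchy_scale robust kernel scale (m); default 2 mm, the expected
#'   inlier residual level of extracted skeletons.
#' @param max_iter Gauss-Newton iteration cap.
#' @param step_tol stop when the max absolute parameter update falls below this.
#' @param init optional [node_transforms] initialization.
#' @return a [node_transforms] list for every `S1` node, with attributes
#'   `converged` (logical), `energy_trace` (robust objective per accepted
#'   iterate, non-increasing), and `e_total` (reported [energy_total()] at the
#'   solution).
#' @export
optimize_deformation <- function(S1, S2, C12,
                                 weights = list(w_corresp = 100, w_rot = 10,
                                                w_reg = 1),
                                 cauchy_scale = 0.002, max_iter = 200L,
                                 step_tol = 1e-8, init = NULL) {
  stopifnot(all(unlist(weights) > 0))
  prob <- .build_deform_problem(S1, S2, C12, weights, cauchy_scale)
  theta <- if (is.null(init)) .transforms_to_theta(identity_transforms(S1)) else
    .transforms_to_theta(init)
  lambda <- 1e-4
  trace <- .robust_objective(theta, prob)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rj <- .deform_residuals(theta, prob)
    H <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$r)
    accepted <- FALSE
    for (try in 1:10) {
      Hd <- H + lambda * diag(diag(H)) + 1e-12 * diag(nrow(H))
      delta <- tryCatch(-solve(Hd, g), error = function(e) NULL)
      if (!is.null(delta)) {
        Fnew <- .robust_objective(theta + delta, prob)
        if (is.finite(Fnew) && Fnew <= rj$F) {
          theta <- theta + as.numeric(delta)
          trace <- c(trace, Fnew)
          lambda <- max(lambda / 3, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    if (max(abs(delta)) < step_tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 0) {
    # ran out of iterations (or damping failed): return the best iterate
    if (length(trace) <= 1) warning("deformation optimization made no progress")
  }
  out <- .theta_to_transforms(theta, prob$ids)
  attr(out, "converged") <- converged
  attr(out, "energy_trace") <- trace
  attr(out, "e_total") <- energy_total(out, C12, S1, S2, weights)
  out
}
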