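#' Emission cost of a node correspondence
#'
#' Cost for matching node `i` of skeleton `S1` to node `j` of skeleton `S2`:
#' the weighted sum of the absolute degree difference, the Euclidean distance
#' between the node positions (m), and a semantic mismatch indicator that is 1
#' when the labels differ. Defaults `w_d = 1`, `w_e = 10`, `w_sem = 1`.
#'
#' @param c_ij length-2 vector `c(source_id, target_id)`; an `NA` target means
#'   the not-matched state, costing `c_nm`.
#' @param S1,S2 the two [skeleton()]s.
#' @param weights list with `w_d`, `w_e`, `w_sem`.
#' @param c_nm emission cost of the not-matched state.
#' @return non-negative cost (dimensionless).
#' @export
emission_cost <- function(c_ij, S1, S2,
                          weights = list(w_d = 1, w_e = 10, w_sem = 1),
                          c_nm = weights$w_e * 0.05) {
  j <- c_ij[2]
  if (is.na(j)) return(c_nm)
  ii <- match(c_ij[1], S1$nodes$id)
  jj <- match(j, S2$nodes$id)
  if (is.na(ii) || is.na(jj)) stop("unknown node id in correspondence")
  xi <- as.numeric(S1$nodes[ii, c("x", "y", "z")])
  xj <- as.numeric(S2$nodes[jj, c("x", "y", "z")])
  weights$w_d * abs(node_degrees(S1)[ii] - node_degrees(S2)[jj]) +
    weights$w_e * sqrt(sum((xi - xj)^2)) +
    weights$w_sem * as.numeric(S1$nodes$label[ii] != S2$nodes$label[jj])
}

#' Transition cost between two correspondences
#'
#' Cost of accepting `c_kh` as a match given that `c_ij` is one: the absolute
#' difference of the geodesic distances along the two skeletons, plus the
#' weighted difference of branch counts along the two paths, plus a direction
#' penalty applied when the displacement vectors `x_i - x_j` and `x_k - x_h`
#' point in opposite directions (angle greater than pi/2; zero-length
#' displacements count as aligned). The branch weight and the direction
#' penalty both equal the maximum geodesic distance between any two nodes of
#' `S1`. For not-matched states the missing target position is substituted by
#' the source node's position and the target-side geodesic/branch terms by the
#' source-side ones, so all terms stay defined.
#'
#' @param c_ij,c_kh length-2 vectors `c(source_id, target_id)` (`NA` target =
#'   not matched).
#' @param S1,S2 the two [skeleton()]s.
#' @return non-negative cost.
#' @export
transition_cost <- function(c_ij, c_kh, S1, S2) {
  pen <- .max_geodesic(S1)
  i <- c_ij[1]; j <- c_ij[2]; k <- c_kh[1]; h <- c_kh[2]
  xi <- .node_pos(S1, i); xk <- .node_pos(S1, k)
  xj <- if (is.na(j)) xi else .node_pos(S2, j)
  xh <- if (is.na(h)) xk else .node_pos(S2, h)
  dg1 <- geodesic_distance(S1, i, k)
  nb1 <- branch_count(S1, i, k)
  if (is.na(j) || is.na(h)) {
    dg2 <- dg1; nb2 <- nb1
  } else {
    dg2 <- geodesic_distance(S2, j, h)
    nb2 <- branch_count(S2, j, h)
  }
  d1 <- xi - xj; d2 <- xk - xh
  # displacements below 0.1 mm carry no usable direction (sensor-noise scale)
  rho <- if (sum(d1^2) < 1e-8 || sum(d2^2) < 1e-8) 0 else
    if (sum(d1 * d2) < 0) pen else 0
  abs(dg1 - dg2) + pen * abs(nb1 - nb2) + rho
}

.node_pos <- function(S, id) {
  i <- match(id, S$nodes$id)
  if (is.na(i)) stop("unknown node id ", id)
  as.numeric(S$nodes[i, c("x", "y", "z")])
}

.max_geodesic <- function(S) {
  if (nrow(S$nodes) < 2) return(0)
  max(igraph::distances(.skel_graph(S), weights = .edge_lengths(S)))
}

# emission and transition tables for the Viterbi DP, indexed by position in
# the DFS observation sequence and by S2 node-table index (state m+1 = NM).
# S1_structure optionally supplies the source-side geodesic/branch tables
# (used when S1's positions have been moved by a deformation estimate but its
# intrinsic topology-derived terms should stay those of the original skeleton)
.hmm_tables <- function(S1, S2, weights, c_nm, S1_structure = NULL) {
  obs <- dfs_order(S1)
  oi <- match(obs, S1$nodes$id)
  n <- length(obs)
  m <- nrow(S2$nodes)
  X1 <- as.matrix(S1$nodes[c("x", "y", "z")])
  X2 <- as.matrix(S2$nodes[c("x", "y", "z")])
  deg1 <- node_degrees(S1); deg2 <- node_degrees(S2)
  lab1 <- S1$nodes$label; lab2 <- S2$nodes$label
  g1 <- .geodesic_tables(if (is.null(S1_structure)) S1 else S1_structure)
  g2 <- .geodesic_tables(S2)
  pen <- if (n > 1) max(g1$dist) else 0

  E <- matrix(c_nm, n, m + 1)
  for (t in seq_len(n)) {
    i <- oi[t]
    d <- sqrt(colSums((t(X2) - X1[i, ])^2))
    E[t, seq_len(m)] <- weights$w_d * abs(deg1[i] - deg2) +
      weights$w_e * d + weights$w_sem * as.numeric(lab1[i] != lab2)
  }

  # transition cost array for consecutive observations: G[[t]][p, s] is the
  # cost of moving from state p at obs t-1 to state s at obs t
  G <- vector("list", n)
  for (t in 2:max(2, n)) {
    if (t > n) break
    a <- oi[t - 1]; k <- oi[t]
    dg1 <- g1$dist[a, k]; nb1 <- g1$nbr[a, k]
    M <- matrix(0, m + 1, m + 1)
    # real -> real
    if (m > 0) {
      dg2 <- g2$dist; nb2 <- g2$nbr
      D1a <- -sweep(X2, 2, X1[a, ]) # x_a - x_j, row per j
      D2k <- -sweep(X2, 2, X1[k, ]) # x_k - x_h, row per h
      dot <- D1a %*% t(D2k)
      # sub-0.1 mm displacements carry no usable direction
      z1 <- rowSums(D1a^2) < 1e-8
      z2 <- rowSums(D2k^2) < 1e-8
      rho <- (dot < 0) * pen
      rho[z1, ] <- 0; rho[, z2] <- 0
      M[seq_len(m), seq_len(m)] <- abs(dg1 - dg2) + pen * abs(nb1 - nb2) + rho
    }
    # transitions involving NM: substituted terms cancel -> cost 0
    G[[t]] <- M
  }
  list(obs = obs, oi = oi, E = E, G = G, n = n, m = m, X1 = X1, X2 = X2)
}

#' Skeleton node correspondences via an HMM solved by Viterbi
#'
#' The nodes of `S1` in depth-first order from the stem base form the
#' observation sequence; the hidden state of each observation is either a node
#' of `S2` or an explicit not-matched state. The Viterbi algorithm (min-sum
#' over [emission_cost()] plus [transition_cost()], the monotone equivalent of
#' max-product on negative log probabilities) returns the minimum-cost state
#' sequence. If several source nodes land on the same target node, only the
#' pair with the smallest Euclidean distance is kept and the others are marked
#' not matched, making the matching one-to-one. Ties are broken toward the
#' lower S2 node id.
#'
#' @param S1,S2 the two [skeleton()]s (source and target).
#' @param weights emission weights, see [emission_cost()].
#' @param c_nm not-matched emission cost; default `w_e * 0.05`, the cost of a
#'   5 cm residual.
#' @param S1_structure optional skeleton supplying the source-side geodesic
#'   and branch-count tables. Used by the iterative registration loop, which
#'   re-matches with `S1` node positions moved by the current deformation
#'   while keeping the topology-derived terms of the original skeleton.
#' @return a `correspondence_set` data frame with integer columns `source` and
#'   `target` (`NA` = not matched), one row per `S1` node in DFS order, with
#'   the total path cost in attribute `path_cost`.
#' @export
viterbi_match <- function(S1, S2,
                          weights = list(w_d = 1, w_e = 10, w_sem = 1),
                          c_nm = weights$w_e * 0.05, S1_structure = NULL) {
  if (nrow(S1$nodes) == 0 || nrow(S2$nodes) == 0) stop("empty skeleton")
  tb <- .hmm_tables(S1, S2, weights, c_nm, S1_structure)
  n <- tb$n; m <- tb$m
  ns <- m + 1
  cost <- matrix(Inf, n, ns)
  back <- matrix(0L, n, ns)
  cost[1, ] <- tb$E[1, ]  # uniform initial distribution
  if (n > 1) {
    for (t in 2:n) {
      Gt <- tb$G[[t]]
      for (s in seq_len(ns)) {
        tot <- cost[t - 1, ] + Gt[, s]
        p <- which.min(tot)  # first minimum = lowest S2 id (NM last)
        cost[t, s] <- tot[p] + tb$E[t, s]
        back[t, s] <- p
      }
    }
  }
  path <- integer(n)
  path[n] <- which.min(cost[n, ])
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  target <- ifelse(path <= m, S2$nodes$id[pmin(path, m)], NA_integer_)

  C <- data.frame(source = tb$obs, target = as.integer(target))
  # resolve duplicate targets: keep the closest pair (ties: lower source id)
  dup_t <- unique(C$target[duplicated(C$target) & !is.na(C$target)])
  for (tg in dup_t) {
    rows <- which(!is.na(C$target) & C$target == tg)
    d <- vapply(rows, function(r) {
      sqrt(sum((tb$X1[match(C$source[r], S1$nodes$id), ] -
                tb$X2[match(tg, S2$nodes$id), ])^2))
    }, numeric(1))
    keep <- rows[order(d, C$source[rows])][1]
    C$target[setdiff(rows, keep)] <- NA_integer_
  }
  attr(C, "path_cost") <- min(cost[n, ])
  attr(C, "weights") <- weights
  attr(C, "c_nm") <- c_nm
  class(C) <- c("correspondence_set", "data.frame")
  C
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("correspondence_set: %d source nodes, %d matched, %d not matched\n",
              nrow(x), sum(!is.na(x$target)), sum(is.na(x$target))))
  invisible(x)
}
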