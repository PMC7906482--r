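#' Length of an organ along the skeleton
#'
#' Sum of the lengths of the skeleton edges internal to the organ's chain
#' (both endpoints in the organ). A single-node organ has length 0.
#'
#' @param S a [skeleton()].
#' @param organ_id organ id present in the skeleton.
#' @return length in meters.
#' @export
organ_length <- function(S, organ_id) {
  ids <- S$nodes$id[S$nodes$organ == organ_id]
  if (length(ids) == 0) stop("unknown organ id ", organ_id)
  if (nrow(S$edges) == 0) return(0)
  internal <- S$edges[, 1] %in% ids & S$edges[, 2] %in% ids
  if (!any(internal)) return(0)
  sum(.edge_lengths(S)[internal])
}

#' Stem diameter from the point cloud and skeleton
#'
#' Every stem-class point is assigned to its nearest stem node; for each node
#' the local main axis is estimated by SVD of the assigned neighborhood (the
#' node's points pooled with its chain neighbors' points, which keeps the
#' axis estimate well-conditioned when a node's own slice is short), and the
#' mean distance of the node's points to that axis is computed. The stem
#' diameter is twice the average of these per-node means, with all nodes
#' weighted equally. Nodes with fewer than 3 assigned points are skipped with
#' a warning.
#'
#' @param cloud a [point_cloud()]; stem points are taken from its labels
#'   (all points are used if labels are absent).
#' @param S the plant's [skeleton()].
#' @return diameter in meters.
#' @export
stem_diameter <- function(cloud, S) {
  stem_idx <- which(S$nodes$label == "stem")
  if (length(stem_idx) == 0) stop("skeleton has no stem nodes")
  pts <- cloud$points
  if (!is.null(cloud$labels)) pts <- pts[cloud$labels == "stem", , drop = FALSE]
  if (nrow(pts) == 0) stop("no stem points in the cloud")
  nodes <- as.matrix(S$nodes[stem_idx, c("x", "y", "z")])
  assign <- cpp_nn1(pts, nodes)$idx
  # chain neighbors among stem nodes (for axis estimation)
  ids <- S$nodes$id[stem_idx]
  adj <- lapply(seq_along(stem_idx), function(k) {
    id <- ids[k]
    nb <- c(S$edges[S$edges[, 1] == id, 2], S$edges[S$edges[, 2] == id, 1])
    match(intersect(nb, ids), ids)
  })
  per_node <- rep(NA_real_, length(stem_idx))
  skipped <- 0L
  for (k in seq_along(stem_idx)) {
    own <- which(assign == k)
    if (length(own) < 3) { skipped <- skipped + 1L; next }
    pool <- which(assign %in% c(k, adj[[k]]))
    X <- pts[pool, , drop = FALSE]
    ctr <- colMeans(X)
    ax <- svd(sweep(X, 2, ctr), nu = 0, nv = 1)$v[, 1]
    dp <- sweep(pts[own, , drop = FALSE], 2, ctr)
    proj <- as.numeric(dp %*% ax)
    per_node[k] <- mean(sqrt(pmax(0, rowSums(dp^2) - proj^2)))
  }
  if (skipped > 0)
    warning(skipped, " stem node(s) with fewer than 3 points skipped")
  if (all(is.na(per_node))) stop("no stem node has enough points")
  2 * mean(per_node, na.rm = TRUE)
}

#' Leaf area from per-node convex hulls
#'
#' The organ's points are assigned to their nearest node of that organ; per
#' node, the points are projected onto the node's main plane (the two
#' dominant SVD directions) and the area of the 2D convex hull is taken. The
#' leaf area is the sum over the organ's nodes. Nodes with fewer than 3
#' points, or with collinear points, contribute 0 (with a warning). Because
#' per-node hulls may overlap near node boundaries, the sum can slightly
#' overestimate the blade area.
#'
#' @param cloud a [point_cloud()] whose `instances` identify the organ's
#'   points (falls back to leaf-labeled points when instances are absent).
#' @param S the plant's [skeleton()].
#' @param organ_id the leaf organ id.
#' @return area in square meters.
#' @export
leaf_area <- function(cloud, S, organ_id) {
  node_idx <- which(S$nodes$organ == organ_id)
  if (length(node_idx) == 0) stop("unknown organ id ", organ_id)
  pts <- cloud$points
  if (!is.null(cloud$instances)) {
    pts <- pts[cloud$instances == organ_id, , drop = FALSE]
  } else if (!is.null(cloud$labels)) {
    pts <- pts[cloud$labels == "leaf", , drop = FALSE]
  }
  if (nrow(pts) == 0) return(0)
  nodes <- as.matrix(S$nodes[node_idx, c("x", "y", "z")])
  assign <- cpp_nn1(pts, nodes)$idx
  total <- 0
  degenerate <- 0L
  for (k in seq_along(node_idx)) {
    X <- pts[assign == k, , drop = FALSE]
    if (nrow(X) < 3) next
    ctr <- colMeans(X)
    V <- svd(sweep(X, 2, ctr), nu = 0, nv = 3)$v
    uv <- sweep(X, 2, ctr) %*% V[, 1:2]
    h <- grDevices::chull(uv)
    if (length(h) < 3) { degenerate <- degenerate + 1L; next }
    total <- total + .polygon_area(uv[h, , drop = FALSE])
  }
  if (degenerate > 0)
    warning(degenerate, " node(s) with collinear points contribute no area")
  total
}

# shoelace formula; vertices in hull order
.polygon_area <- function(V) {
  x <- V[, 1]; y <- V[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Track organ-level traits through a scan sequence
#'
#' Propagates persistent organ identities through the chain of node
#' correspondences — an organ at time `t + 1` inherits the persistent id of
#' the time-`t` organ holding the strict majority of its matched nodes, and
#' organs with no (majority) predecessor are emergence events — then computes
#' per-scan traits for each persistent organ: leaf length and area, stem
#' length and diameter. Persistent ids are never reused.
#'
#' @param scans list of scans, each a list with elements `cloud` (a
#'   [point_cloud()] whose instance ids match the skeleton's organ ids) and
#'   `skeleton`.
#' @param registrations list of correspondence sets between consecutive
#'   scans (`registrations[[t]]` maps skeleton `t` to `t + 1`); length must
#'   be `length(scans) - 1`.
#' @param times optional numeric scan times (default `1:n`), strictly
#'   increasing.
#' @return an object of class `trait_series`: list with `traits` (data frame
#'   `time`, `organ`, `class`, `trait`, `value`) and `events` (data frame
#'   `organ`, `time` of first appearance after the first scan).
#' @export
track_traits <- function(scans, registrations, times = NULL) {
  nscan <- length(scans)
  if (length(registrations) != nscan - 1)
    stop("need exactly ", nscan - 1, " registrations for ", nscan,
         " scans; missing registration for gap ",
         which(seq_len(nscan - 1) > length(registrations))[1])
  if (is.null(times)) times <- seq_len(nscan)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")

  # persistent id assignment per scan: list of named vectors organ -> pid
  pid <- vector("list", nscan)
  S1 <- scans[[1]]$skeleton
  organs1 <- sort(unique(S1$nodes$organ))
  pid[[1]] <- stats::setNames(seq_along(organs1), organs1)
  next_id <- length(organs1) + 1L
  events <- list()
  for (t in seq_len(nscan - 1)) {
    St <- scans[[t]]$skeleton
    Sn <- scans[[t + 1]]$skeleton
    C <- registrations[[t]]
    organs_n <- sort(unique(Sn$nodes$organ))
    assigned <- stats::setNames(rep(NA_integer_, length(organs_n)),
                                organs_n)
    votes <- list()
    for (o in organs_n) {
      tgt_nodes <- Sn$nodes$id[Sn$nodes$organ == o]
      rows <- which(C$target %in% tgt_nodes)
      if (length(rows) == 0) next
      src_org <- St$nodes$organ[match(C$source[rows], St$nodes$id)]
      src_pid <- pid[[t]][as.character(src_org)]
      tb <- sort(table(src_pid), decreasing = TRUE)
      if (tb[1] > 0.5 * length(rows))
        votes[[as.character(o)]] <- c(as.integer(names(tb)[1]), tb[1])
    }
    # resolve conflicts: the organ with more supporting nodes keeps the id
    if (length(votes) > 0) {
      vo <- data.frame(organ = as.integer(names(votes)),
                       pid = vapply(votes, `[`, integer(1), 1),
                       n = vapply(votes, `[`, integer(1), 2))
      vo <- vo[order(-vo$n), ]
      taken <- integer(0)
      for (r in seq_len(nrow(vo))) {
        if (!vo$pid[r] %in% taken) {
          assigned[as.character(vo$organ[r])] <- vo$pid[r]
          taken <- c(taken, vo$pid[r])
        }
      }
    }
    for (o in organs_n) {
      if (is.na(assigned[as.character(o)])) {
        assigned[as.character(o)] <- next_id
        events[[length(events) + 1]] <- data.frame(organ = next_id,
                                                   time = times[t + 1])
        next_id <- next_id + 1L
      }
    }
    pid[[t + 1]] <- assigned
  }

  rows <- list()
  for (t in seq_len(nscan)) {
    S <- scans[[t]]$skeleton
    cloud <- scans[[t]]$cloud
    for (o in sort(unique(S$nodes$organ))) {
      p <- pid[[t]][as.character(o)]
      cls <- S$nodes$label[match(o, S$nodes$organ)]
      add <- function(trait, value) {
        rows[[length(rows) + 1]] <<- data.frame(
          time = times[t], organ = as.integer(p), class = cls,
          trait = trait, value = value)
      }
      add("length", organ_length(S, o))
      if (cls == "leaf") {
        add("area", leaf_area(cloud, S, o))
      } else {
        add("diameter", suppressWarnings(stem_diameter(cloud, S)))
      }
    }
  }
  traits <- do.call(rbind, rows)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(organ = integer(0), time = numeric(0))
  structure(list(traits = traits, events = events, persistent_ids = pid),
            class = "trait_series")
}

#' @export
print.trait_series <- function(x, ...) {
  cat(sprintf("trait_series: %d organ(s), %d time point(s), %d emergence event(s)\n",
              length(unique(x$traits$organ)), length(unique(x$traits$time)),
              nrow(x$events)))
  invisible(x)
}
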