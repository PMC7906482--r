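#' Construct a plant skeleton
#'
#' A skeleton is an undirected acyclic connected graph summarizing the plant's
#' topology. Each node carries a 3D position (m), a semantic label
#' (`"stem"`/`"leaf"`) and an organ instance id; per-node affine transforms are
#' stored separately as [node_transforms].
#'
#' @param nodes data frame with columns `id` (unique integers), `x`, `y`, `z`
#'   (m), `label` (`"stem"`/`"leaf"`), `organ` (integer organ id).
#' @param edges two-column integer matrix of node ids (undirected edges).
#' @param root id of the root node (stem base); defaults to the stem node with
#'   the smallest z coordinate.
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(nodes, edges, root = NULL) {
  nodes <- as.data.frame(nodes)
  need <- c("id", "x", "y", "z", "label", "organ")
  if (!all(need %in% names(nodes))) {
    stop("`nodes` must have columns ", paste(need, collapse = ", "))
  }
  nodes <- nodes[need]
  nodes$id <- as.integer(nodes$id)
  nodes$organ <- as.integer(nodes$organ)
  nodes$label <- as.character(nodes$label)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    stop("node positions must be finite")
  if (!all(nodes$label %in% c("stem", "leaf")))
    stop("node labels must be 'stem' or 'leaf'")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0 && !all(edges %in% nodes$id))
    stop("edge references a missing node id")
  if (nrow(nodes) > 1) {
    g <- igraph::graph_from_edgelist(
      matrix(match(edges, nodes$id), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
    if (!igraph::is_connected(g)) stop("skeleton must be connected")
    if (igraph::ecount(g) != nrow(nodes) - 1)  # connected + |E| = |V|-1 <=> tree
      stop("skeleton must be acyclic")
  }
  if (is.null(root)) {
    stem <- nodes[nodes$label == "stem", ]
    if (nrow(stem) == 0) stop("skeleton has no stem node to root at")
    root <- stem$id[which.min(stem$z)]
  }
  if (!root %in% nodes$id) stop("root id not present in nodes")
  structure(list(nodes = nodes, edges = edges, root = as.integer(root)),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d nodes, %d edges, %d organ(s), root id %d\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$organ)), x$root))
  invisible(x)
}

#' Number of skeleton nodes
#' @param S a `skeleton`.
#' @return integer node count.
#' @export
n_nodes <- function(S) nrow(S$nodes)

# igraph view of the skeleton, vertices in nodes-table order
.skel_graph <- function(S) {
  g <- igraph::make_empty_graph(n = nrow(S$nodes), directed = FALSE)
  if (nrow(S$edges) > 0) {
    ij <- matrix(match(S$edges, S$nodes$id), ncol = 2)
    g <- igraph::add_edges(g, t(ij))
  }
  g
}

.edge_lengths <- function(S) {
  if (nrow(S$edges) == 0) return(numeric(0))
  a <- match(S$edges[, 1], S$nodes$id)
  b <- match(S$edges[, 2], S$nodes$id)
  P <- as.matrix(S$nodes[c("x", "y", "z")])
  sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2))
}

#' Per-node degree
#' @param S a `skeleton`.
#' @return integer vector of degrees, in node-table order.
#' @export
node_degrees <- function(S) {
  deg <- integer(nrow(S$nodes))
  if (nrow(S$edges) > 0) {
    t1 <- table(factor(match(S$edges, S$nodes$id), levels = seq_len(nrow(S$nodes))))
    deg <- as.integer(t1)
  }
  deg
}

#' Geodesic distance along the skeleton
#'
#' Summed edge length (m) of the unique tree path between two nodes.
#'
#' @param S a `skeleton`.
#' @param a,b node ids.
#' @return length in meters.
#' @export
geodesic_distance <- function(S, a, b) {
  ia <- match(a, S$nodes$id); ib <- match(b, S$nodes$id)
  if (is.na(ia) || is.na(ib)) stop("unknown node id")
  if (ia == ib) return(0)
  g <- .skel_graph(S)
  if (!igraph::is_connected(g)) stop("skeleton is disconnected")
  as.numeric(igraph::distances(g, v = ia, to = ib, weights = .edge_lengths(S)))
}

#' Branch count between two nodes
#'
#' Number of branching nodes (degree greater than 2) strictly between `a` and
#' `b` on the unique tree path.
#'
#' @inheritParams geodesic_distance
#' @return integer count.
#' @export
branch_count <- function(S, a, b) {
  ia <- match(a, S$nodes$id); ib <- match(b, S$nodes$id)
  if (is.na(ia) || is.na(ib)) stop("unknown node id")
  if (ia == ib) return(0L)
  g <- .skel_graph(S)
  if (!igraph::is_connected(g)) stop("skeleton is disconnected")
  p <- igraph::shortest_paths(g, from = ia, to = ib,
                              weights = .edge_lengths(S))$vpath[[1]]
  inner <- as.integer(p)[-c(1, length(p))]
  if (length(inner) == 0) return(0L)
  sum(node_degrees(S)[inner] > 2L)
}

# all-pairs geodesic matrix + branch-count matrix, in node-table order
.geodesic_tables <- function(S) {
  n <- nrow(S$nodes)
  g <- .skel_graph(S)
  wl <- .edge_lengths(S)
  D <- igraph::distances(g, weights = wl)
  deg <- node_degrees(S)
  B <- matrix(0L, n, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      paths <- igraph::shortest_paths(g, from = i, weights = wl)$vpath
      for (j in seq_len(n)) {
        p <- as.integer(paths[[j]])
        if (length(p) > 2) B[i, j] <- sum(deg[p[-c(1, length(p))]] > 2L)
      }
    }
  }
  list(dist = D, nbr = B)
}

#' Depth-first node order from the root
#'
#' Nodes of the skeleton in depth-first order starting from the stem-base root,
#' visiting children in ascending node-id order. This is the observation
#' sequence used by the correspondence HMM.
#'
#' @param S a `skeleton`.
#' @return integer vector of node ids.
#' @export
dfs_order <- function(S) {
  n <- nrow(S$nodes)
  adj <- vector("list", n)
  if (nrow(S$edges) > 0) {
    ij <- matrix(match(S$edges, S$nodes$id), ncol = 2)
    for (k in seq_len(nrow(ij))) {
      adj[[ij[k, 1]]] <- c(adj[[ij[k, 1]]], ij[k, 2])
      adj[[ij[k, 2]]] <- c(adj[[ij[k, 2]]], ij[k, 1])
    }
  }
  ids <- S$nodes$id
  start <- match(S$root, ids)
  visited <- logical(n)
  out <- integer(0)
  stack <- start
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    out <- c(out, v)
    nb <- adj[[v]]
    nb <- nb[!visited[nb]]
    if (length(nb) > 0) stack <- c(stack, nb[order(ids[nb], decreasing = TRUE)])
  }
  ids[out]
}

# --- on-disk formats ---------------------------------------------------------

#' Read and write skeleton files
#'
#' Plain-text format, one record per line: node lines
#' `"N id x y z class organ"` followed by edge lines `"E id1 id2"`. The class
#' field is `stem` or `leaf`. Files violating the skeleton invariants (unique
#' ids, edges referencing existing ids, acyclic connected graph) are rejected.
#'
#' @param path file to read or write.
#' @return `read_skeleton` returns a [skeleton()].
#' @export
read_skeleton <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nd <- list(); ed <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] == "N") {
      if (length(tok) != 7) stop("parse error in ", path, " at line ", i)
      nd[[length(nd) + 1]] <- data.frame(
        id = as.integer(tok[2]), x = as.numeric(tok[3]), y = as.numeric(tok[4]),
        z = as.numeric(tok[5]), label = tok[6], organ = as.integer(tok[7]))
    } else if (tok[1] == "E") {
      if (length(tok) != 3) stop("parse error in ", path, " at line ", i)
      ed[[length(ed) + 1]] <- as.integer(tok[2:3])
    } else stop("parse error in ", path, " at line ", i, ": unknown record '", tok[1], "'")
  }
  if (length(nd) == 0) stop("no nodes in ", path)
  nodes <- do.call(rbind, nd)
  edges <- if (length(ed)) do.call(rbind, ed) else matrix(integer(0), 0, 2)
  skeleton(nodes, edges)
}

#' @rdname read_skeleton
#' @param S a [skeleton()] to write.
#' @export
write_skeleton <- function(S, path) {
  stopifnot(inherits(S, "skeleton"))
  nl <- sprintf("N %d %.17g %.17g %.17g %s %d",
                S$nodes$id, S$nodes$x, S$nodes$y, S$nodes$z,
                S$nodes$label, S$nodes$organ)
  el <- if (nrow(S$edges)) sprintf("E %d %d", S$edges[, 1], S$edges[, 2]) else character(0)
  writeLines(c(nl, el), path)
  invisible(path)
}

#' Read and write correspondence files
#'
#' One `"id1 id2"` pair per line; `-1` in the second column marks a source node
#' with no match.
#'
#' @param path file to read or write.
#' @return `read_correspondences` returns a data frame with integer columns
#'   `source` and `target` (`NA` target = not matched).
#' @export
read_correspondences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.table(path, col.names = c("source", "target"))
  m$source <- as.integer(m$source)
  m$target <- as.integer(m$target)
  m$target[m$target == -1L] <- NA_integer_
  class(m) <- c("correspondence_set", "data.frame")
  m
}

#' @rdname read_correspondences
#' @param C correspondence data frame (columns `source`, `target`).
#' @export
write_correspondences <- function(C, path) {
  tgt <- C$target
  tgt[is.na(tgt)] <- -1L
  writeLines(sprintf("%d %d", C$source, tgt), path)
  invisible(path)
}

#' Read and write per-node transform files
#'
#' One line per node: the node id followed by the 12 free entries of its 4x4
#' affine transform in row-major 3x4 order (the constant last row is omitted).
#'
#' @param path file to read or write.
#' @return `read_transforms` returns a [node_transforms] list keyed by node id.
#' @export
read_transforms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 13) stop("parse error in ", path, ": expected 13 columns per line")
  Ts <- lapply(seq_len(nrow(m)), function(i) {
    rbind(matrix(m[i, 2:13], nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  })
  names(Ts) <- as.integer(m[, 1])
  structure(Ts, class = "node_transforms")
}

#' @rdname read_transforms
#' @param transforms a [node_transforms] list (names are node ids).
#' @export
write_transforms <- function(transforms, path) {
  lines <- vapply(seq_along(transforms), function(i) {
    paste(c(names(transforms)[i], sprintf("%.17g", t(transforms[[i]][1:3, ]))), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Identity transforms for every node of a skeleton
#'
#' @param S a [skeleton()].
#' @return a `node_transforms` list of 4x4 identity matrices keyed by node id.
#' @export
identity_transforms <- function(S) {
  Ts <- lapply(seq_len(nrow(S$nodes)), function(i) diag(4))
  names(Ts) <- S$nodes$id
  structure(Ts, class = "node_transforms")
}

#' Apply per-node transforms to the skeleton node positions
#'
#' Returns a copy of `S` whose node `i` has been moved to `T_i x_i`. Used by
#' the iterative registration loop to re-match with deformed node positions.
#'
#' @param S a [skeleton()].
#' @param transforms a [node_transforms] list keyed by node id.
#' @return a `skeleton`.
#' @export
apply_node_transforms <- function(S, transforms) {
  S2 <- S
  for (i in seq_len(nrow(S$nodes))) {
    Ti <- transforms[[as.character(S$nodes$id[i])]]
    p <- Ti %*% c(S$nodes$x[i], S$nodes$y[i], S$nodes$z[i], 1)
    S2$nodes$x[i] <- p[1]; S2$nodes$y[i] <- p[2]; S2$nodes$z[i] <- p[3]
  }
  S2
}
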