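# Shared fixtures and independent oracles used across the test files.

# small, fast synthetic plant for unit tests (acceptance tests use the
# full-size presets)
small_plant_spec <- function(seed = 1L, preset = "tomato") {
  plant_spec(preset, seed = seed, stem_points = 900L, leaf_points = 280L)
}

# straight-line path skeleton along z with given node spacing (m)
path_skeleton <- function(n, spacing = 0.01, label = "stem") {
  nodes <- data.frame(id = seq_len(n), x = 0, y = 0,
                      z = spacing * (seq_len(n) - 1),
                      label = label, organ = 1L)
  if (label != "stem") nodes$label[1] <- "stem"  # need a stem root
  edges <- if (n > 1) cbind(1:(n - 1), 2:n) else matrix(integer(0), 0, 2)
  skeleton(nodes, edges)
}

# random tree skeleton: node i > 1 attaches to a random earlier node
rand_skeleton <- function(n, seed, scale = 0.05) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n),
                      x = stats::runif(n, 0, scale),
                      y = stats::runif(n, 0, scale),
                      z = stats::runif(n, 0, scale),
                      label = sample(c("stem", "leaf"), n, replace = TRUE),
                      organ = sample(1:3, n, replace = TRUE))
  nodes$label[1] <- "stem"
  edges <- if (n > 1) cbind(sapply(2:n, function(i) sample(i - 1, 1)), 2:n)
           else matrix(integer(0), 0, 2)
  skeleton(nodes, edges)
}

# apply a rigid transform to all skeleton node positions
transform_skeleton <- function(S, R = diag(3), tt = c(0, 0, 0)) {
  X <- as.matrix(S$nodes[c("x", "y", "z")])
  Y <- t(R %*% t(X)) + matrix(tt, nrow(X), 3, byrow = TRUE)
  S$nodes$x <- Y[, 1]; S$nodes$y <- Y[, 2]; S$nodes$z <- Y[, 3]
  S
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# --- independent oracles -----------------------------------------------------

# O(N^2) mean nearest-neighbor distance
bf_nn_distances <- function(A, B) {
  apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2))))
}

# tree-path geodesic + branch count by explicit path search (DFS), written
# independently of the package's igraph-based implementation
bf_tree_path <- function(S, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  ids <- S$nodes$id
  adj <- lapply(ids, function(id)
    c(S$edges[S$edges[, 1] == id, 2], S$edges[S$edges[, 2] == id, 1]))
  names(adj) <- ids
  found <- NULL
  walk <- function(v, prev, path) {
    path <- c(path, v)
    if (v == b) { found <<- path; return(TRUE) }
    for (w in adj[[as.character(v)]]) {
      if (!identical(w, prev) && walk(w, v, path)) return(TRUE)
    }
    FALSE
  }
  walk(a, NA_integer_, integer(0))
  P <- as.matrix(S$nodes[match(found, ids), c("x", "y", "z")])
  dg <- if (length(found) > 1)
    sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
  else 0
  deg <- sapply(found, function(id) sum(S$edges == id))
  nbr <- if (length(found) > 2) sum(deg[-c(1, length(deg))] > 2) else 0L
  list(dist = dg, nbr = nbr)
}

# cost tables for the HMM written directly from the cost definitions
# (emission Eq-style formula; transitions with the documented not-matched
# substitution), independent of the package's table construction
bf_hmm_tables <- function(S1, S2, weights, c_nm) {
  obs <- dfs_order(S1)
  n <- length(obs)
  m <- nrow(S2$nodes)
  X1 <- as.matrix(S1$nodes[match(obs, S1$nodes$id), c("x", "y", "z")])
  X2 <- as.matrix(S2$nodes[c("x", "y", "z")])
  deg1 <- node_degrees(S1)[match(obs, S1$nodes$id)]
  deg2 <- node_degrees(S2)
  lab1 <- S1$nodes$label[match(obs, S1$nodes$id)]
  lab2 <- S2$nodes$label
  # all-pairs via the brute-force path oracle
  d1 <- function(i, k) bf_tree_path(S1, obs[i], obs[k])
  d2 <- function(j, h) bf_tree_path(S2, S2$nodes$id[j], S2$nodes$id[h])
  pen <- 0
  for (i in seq_len(nrow(S1$nodes)))
    for (k in seq_len(nrow(S1$nodes)))
      pen <- max(pen, bf_tree_path(S1, S1$nodes$id[i], S1$nodes$id[k])$dist)
  E <- matrix(c_nm, n, m + 1)
  for (t in seq_len(n)) for (j in seq_len(m)) {
    E[t, j] <- weights$w_d * abs(deg1[t] - deg2[j]) +
      weights$w_e * sqrt(sum((X1[t, ] - X2[j, ])^2)) +
      weights$w_sem * (lab1[t] != lab2[j])
  }
  G <- vector("list", n)
  if (n > 1) for (t in 2:n) {
    M <- matrix(0, m + 1, m + 1)
    p1 <- d1(t - 1, t)
    for (p in seq_len(m + 1)) for (s in seq_len(m + 1)) {
      if (p > m || s > m) { M[p, s] <- 0; next }  # substitution cancels terms
      p2 <- d2(p, s)
      disp1 <- X1[t - 1, ] - X2[p, ]
      disp2 <- X1[t, ] - X2[s, ]
      rho <- if (sum(disp1^2) < 1e-8 || sum(disp2^2) < 1e-8) 0 else
        if (sum(disp1 * disp2) < 0) pen else 0
      M[p, s] <- abs(p1$dist - p2$dist) + pen * abs(p1$nbr - p2$nbr) + rho
    }
    G[[t]] <- M
  }
  list(E = E, G = G, n = n, m = m)
}

# exhaustive enumeration over all state sequences; returns the minimum cost
bf_min_path_cost <- function(S1, S2, weights, c_nm) {
  tb <- bf_hmm_tables(S1, S2, weights, c_nm)
  ns <- tb$m + 1
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(ns)), tb$n)))
  cost <- tb$E[cbind(1, grid[, 1])]
  if (tb$n > 1) for (t in 2:tb$n) {
    cost <- cost + tb$G[[t]][cbind(grid[, t - 1], grid[, t])] +
      tb$E[cbind(t, grid[, t])]
  }
  min(cost)
}
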