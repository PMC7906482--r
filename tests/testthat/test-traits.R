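test_that("organ length sums the chain's internal edges", {
  S <- path_skeleton(5, spacing = 0.01)
  expect_equal(organ_length(S, 1L), 0.04)
  # single-node organ -> 0
  nodes <- data.frame(id = 1:2, x = c(0, 0.01), y = 0, z = c(0, 0.02),
                      label = c("stem", "leaf"), organ = 1:2)
  S1 <- skeleton(nodes, matrix(c(1, 2), 1, 2))
  expect_equal(organ_length(S1, 2L), 0)
  expect_error(organ_length(S1, 9L), "unknown organ")
  # curved chain equals the brute-force sum of segment lengths
  set.seed(2)
  th <- seq(0, pi / 2, length.out = 8)
  P <- cbind(0.05 * cos(th), 0.05 * sin(th), seq(0, 0.02, length.out = 8))
  Sc <- skeleton(data.frame(id = 1:8, x = P[, 1], y = P[, 2], z = P[, 3],
                            label = "stem", organ = 1L),
                 cbind(1:7, 2:8))
  expect_equal(organ_length(Sc, 1L),
               sum(sqrt(rowSums((P[-1, ] - P[-8, ])^2))))
})

test_that("stem diameter recovers the radius of a sampled cylinder", {
  set.seed(3)
  n <- 6000
  th <- runif(n, 0, 2 * pi); z <- runif(n, 0, 0.06)
  mk_cyl <- function(r) point_cloud(cbind(r * cos(th), r * sin(th), z),
                                    labels = rep("stem", n))
  S <- skeleton(data.frame(id = 1:7, x = 0, y = 0, z = seq(0, 0.06, by = 0.01),
                           label = "stem", organ = 1L),
                cbind(1:6, 2:7))
  d5 <- stem_diameter(mk_cyl(0.005), S)
  expect_equal(d5, 0.010, tolerance = 0.02)
  # homogeneity: scaling the scene doubles the diameter estimate exactly
  big <- mk_cyl(0.005)
  big$points <- 2 * big$points
  S2x <- S
  S2x$nodes$z <- 2 * S2x$nodes$z
  expect_equal(stem_diameter(big, S2x), 2 * d5, tolerance = 1e-9)
  # all points exactly on the axis -> 0
  axis_cloud <- point_cloud(cbind(0, 0, z), labels = rep("stem", n))
  expect_equal(stem_diameter(axis_cloud, S), 0, tolerance = 1e-9)
})

test_that("leaf area equals known planar areas and is rigid-invariant", {
  # 3 non-collinear points -> exact triangle area
  tri <- point_cloud(rbind(c(0, 0, 0.02), c(0.01, 0, 0.02), c(0, 0.01, 0.02)),
                     labels = rep("leaf", 3), instances = rep(2L, 3))
  S <- skeleton(data.frame(id = 1:2, x = 0, y = 0, z = c(0, 0.02),
                           label = c("stem", "leaf"), organ = 1:2),
                matrix(c(1, 2), 1, 2))
  expect_equal(leaf_area(tri, S, 2L), 0.5 * 0.01 * 0.01)
  # dense unit square scaled to 10 mm: ~100 mm^2
  set.seed(4)
  m <- 5000
  sq <- point_cloud(cbind(runif(m, 0, 0.01), runif(m, 0, 0.01), 0.02),
                    labels = rep("leaf", m), instances = rep(2L, m))
  a <- leaf_area(sq, S, 2L)
  expect_equal(a, 1e-4, tolerance = 0.02)
  # rigid motion leaves the area unchanged
  R <- rot_z(33) %*% matrix(c(1, 0, 0, 0, cos(0.7), -sin(0.7),
                              0, sin(0.7), cos(0.7)), 3, 3, byrow = TRUE)
  sq_rot <- point_cloud(t(R %*% t(sq$points)) + 0.01,
                        labels = sq$labels, instances = sq$instances)
  S_rot <- S
  Xr <- t(R %*% t(as.matrix(S$nodes[c("x", "y", "z")]))) + 0.01
  S_rot$nodes$x <- Xr[, 1]; S_rot$nodes$y <- Xr[, 2]; S_rot$nodes$z <- Xr[, 3]
  expect_equal(leaf_area(sq_rot, S_rot, 2L), a, tolerance = 1e-9)
})

test_that("traits scale with the coordinate scale (homogeneity)", {
  p <- generate_plant(small_plant_spec(seed = 6))
  s <- 2.5
  scaled_cloud <- point_cloud(s * p$cloud$points, p$cloud$labels,
                              p$cloud$instances)
  Ss <- p$skeleton
  Ss$nodes$x <- s * Ss$nodes$x; Ss$nodes$y <- s * Ss$nodes$y
  Ss$nodes$z <- s * Ss$nodes$z
  leaf_organ <- max(p$skeleton$nodes$organ)
  expect_equal(organ_length(Ss, leaf_organ),
               s * organ_length(p$skeleton, leaf_organ), tolerance = 1e-9)
  expect_equal(leaf_area(scaled_cloud, Ss, leaf_organ),
               s^2 * leaf_area(p$cloud, p$skeleton, leaf_organ),
               tolerance = 1e-9)
  expect_equal(suppressWarnings(stem_diameter(scaled_cloud, Ss)),
               s * suppressWarnings(stem_diameter(p$cloud, p$skeleton)),
               tolerance = 1e-9)
})

test_that("trait tracking propagates organ identity and flags emergence", {
  p <- generate_plant(small_plant_spec(seed = 31))
  g1 <- grow_plant(p, growth_spec(seed = 32, new_leaves = 1L))
  # grow the child again, without further insertions
  g2 <- grow_plant(g1, growth_spec(seed = 33, new_leaves = 0L, scale = 1.1))
  scans <- list(list(cloud = p$cloud, skeleton = p$skeleton),
                list(cloud = g1$cloud, skeleton = g1$skeleton),
                list(cloud = g2$cloud, skeleton = g2$skeleton))
  regs <- list(g1$correspondences, g2$correspondences)
  ts <- suppressWarnings(track_traits(scans, regs))

  # exactly one emergence event, at scan 2
  expect_equal(nrow(ts$events), 1)
  expect_equal(ts$events$time, 2)
  # every persistent organ has exactly one id per scan
  for (t in 1:3) expect_equal(anyDuplicated(ts$persistent_ids[[t]]), 0)
  # leaf length series are non-decreasing under monotone growth
  leaves <- unique(ts$traits$organ[ts$traits$class == "leaf"])
  for (o in leaves) {
    v <- ts$traits$value[ts$traits$organ == o & ts$traits$trait == "length"]
    expect_true(all(diff(v) > -1e-9))
  }
  # stem length and diameter grow too
  sl <- ts$traits$value[ts$traits$class == "stem" & ts$traits$trait == "length"]
  expect_true(all(diff(sl) > 0))
  expect_error(suppressWarnings(track_traits(scans, regs[1])), "registration")
})
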