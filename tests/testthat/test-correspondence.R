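test_that("emission cost combines degree, distance and semantics", {
  S <- path_skeleton(3)
  # identical node -> 0
  expect_equal(emission_cost(c(2, 2), S, S), 0)
  # same degree and label, 0.05 m apart, default weights -> 10 * 0.05
  Sb <- S
  Sb$nodes$x <- Sb$nodes$x + 0.05
  expect_equal(emission_cost(c(2, 2), S, Sb), 0.5)
  # degree difference 1, same position, different labels -> 1 + 0 + 1
  Sc <- skeleton(data.frame(id = 1:4, x = c(0, 0, 0, 0.01),
                            y = c(0, 0, 0, 0), z = c(0, 0.01, 0.02, 0.01),
                            label = c("stem", "leaf", "stem", "stem"),
                            organ = 1L),
                 rbind(c(1, 2), c(2, 3), c(2, 4)))
  # node 2 of Sc: degree 3, label leaf, position (0,0,0.01) = node 2 of S
  expect_equal(emission_cost(c(2, 2), S, Sc), 1 + 0 + 1)
  # not-matched state costs c_nm
  expect_equal(emission_cost(c(2, NA), S, S, c_nm = 0.7), 0.7)
})

test_that("transition cost compares path structure along both skeletons", {
  S <- path_skeleton(5, spacing = 0.01)
  # identical skeletons, identity pairs -> 0 (zero displacements are aligned)
  expect_equal(transition_cost(c(1, 1), c(2, 2), S, S), 0)
  # geodesic lengths differing by 3 mm, aligned directions -> 0.003
  Sb <- path_skeleton(5, spacing = 0.01)
  Sb$nodes$z <- Sb$nodes$z * 1.075  # edge 0.01 -> 0.01075; path 1->5: +3 mm
  Sb$nodes$x <- Sb$nodes$x + 0.02   # uniform displacement: directions aligned
  expect_equal(transition_cost(c(1, 1), c(5, 5), S, Sb), 0.003)
  # anti-parallel displacements add exactly the max-geodesic penalty
  Sc <- path_skeleton(5, spacing = 0.01)
  Sc$nodes$x[1] <- 0.02   # node 1 displaced +x
  Sc$nodes$x[2] <- -0.02  # node 2 displaced -x
  pen <- 0.04  # max geodesic of S: 4 edges x 0.01
  base <- transition_cost(c(1, 1), c(2, 2), S, S)
  got <- transition_cost(c(1, 1), c(2, 2), S, Sc)
  expect_equal(got - abs(geodesic_distance(S, 1, 2) -
                           geodesic_distance(Sc, 1, 2)), pen)
})

test_that("geodesic distances and branch counts match a path-walking oracle", {
  S <- path_skeleton(5, spacing = 0.01)
  expect_equal(geodesic_distance(S, 1, 2), 0.01)
  expect_equal(branch_count(S, 1, 2), 0L)
  expect_equal(geodesic_distance(S, 3, 3), 0)
  expect_equal(geodesic_distance(S, 1, 5), 0.04)
  for (seed in 1:5) {
    Sr <- rand_skeleton(10, seed = seed)
    for (pair in list(c(1, 10), c(3, 7), c(2, 2), c(5, 9))) {
      oracle <- bf_tree_path(Sr, pair[1], pair[2])
      expect_equal(geodesic_distance(Sr, pair[1], pair[2]), oracle$dist)
      expect_equal(branch_count(Sr, pair[1], pair[2]), oracle$nbr,
                   ignore_attr = TRUE)
    }
  }
})

test_that("Viterbi matching recovers the identity on identical skeletons", {
  for (seed in c(2, 5, 9)) {
    S <- rand_skeleton(12, seed = seed)
    C <- viterbi_match(S, S)
    expect_equal(C$target, C$source)
    expect_equal(attr(C, "path_cost"), 0)
  }
})

test_that("Viterbi path cost equals exhaustive enumeration on small pairs", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    S1 <- rand_skeleton(sample(2:5, 1), seed = seed)
    S2 <- rand_skeleton(sample(2:4, 1), seed = seed + 50)
    w <- list(w_d = 1, w_e = 10, w_sem = 1)
    C <- viterbi_match(S1, S2, weights = w, c_nm = 0.5)
    expect_equal(attr(C, "path_cost"),
                 bf_min_path_cost(S1, S2, w, 0.5), tolerance = 1e-12)
  }
})

test_that("lone nodes fall into the not-matched state when it is cheaper", {
  mk1 <- function(x) skeleton(data.frame(id = 1L, x = x, y = 0, z = 0,
                                         label = "stem", organ = 1L),
                              matrix(integer(0), 0, 2))
  S1 <- mk1(0); S2 <- mk1(1)  # 1 m apart: emission 10 > c_nm
  C <- viterbi_match(S1, S2, c_nm = 0.5)
  expect_true(is.na(C$target))
  # and matched when closer than the not-matched cost
  C2 <- viterbi_match(S1, mk1(0.01), c_nm = 0.5)
  expect_equal(C2$target, 1L)
})

test_that("matching is one-to-one after resolution", {
  for (seed in 1:8) {
    S1 <- rand_skeleton(10, seed = seed)
    S2 <- rand_skeleton(6, seed = seed + 30)
    C <- viterbi_match(S1, S2)
    tg <- C$target[!is.na(C$target)]
    expect_equal(anyDuplicated(tg), 0)
  }
})

test_that("matching is stable under small rigid perturbations", {
  p <- generate_plant(small_plant_spec(seed = 6))
  seg <- cluster_instances(p$cloud, p$cloud$labels)
  S1 <- build_skeleton(seg, p$cloud, seed = 1)
  S2 <- transform_skeleton(S1, rot_z(2), c(0.002, -0.001, 0.001))
  C <- viterbi_match(S1, S2)
  expect_equal(C$target, C$source)
})
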