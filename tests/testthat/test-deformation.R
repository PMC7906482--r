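test_that("energy terms match their closed forms and a direct-sum oracle", {
  S <- path_skeleton(4)
  trs <- identity_transforms(S)
  C <- data.frame(source = S$nodes$id, target = S$nodes$id)
  # identity transforms, coincident pairs -> 0
  expect_equal(energy_corresp(trs, C, S, S), 0)
  # single pair offset 1 m, no robustifier -> 1
  Sb <- S; Sb$nodes$x[2] <- 1
  C1 <- data.frame(source = 2L, target = 2L)
  expect_equal(energy_corresp(trs, C1, S, Sb), 1)
  # not-matched pairs contribute nothing
  Cnm <- data.frame(source = S$nodes$id, target = c(1L, NA, NA, 4L))
  expect_equal(energy_corresp(trs, Cnm, S, Sb),
               energy_corresp(trs, data.frame(source = c(1L, 4L),
                                              target = c(1L, 4L)), S, Sb))

  # E_rot: zero exactly on rotations, 27 on 2I, sign-flip invariant
  expect_equal(energy_rot(diag(4)), 0)
  Trot <- diag(4); Trot[1:3, 1:3] <- rot_z(37)
  expect_equal(energy_rot(Trot), 0, tolerance = 1e-14)
  expect_equal(energy_rot(diag(c(2, 2, 2, 1))), 27)
  Tf <- diag(c(2, -2, 2, 1))
  expect_equal(energy_rot(Tf), energy_rot(diag(c(2, 2, 2, 1))))

  # E_reg: equal transforms -> 0; translation-only neighbor -> ||t||
  expect_equal(energy_reg(trs, S), 0)
  S2n <- path_skeleton(2)
  tr2 <- identity_transforms(S2n)
  tr2[["2"]][1:3, 4] <- c(0.03, 0, 0.04)
  expect_equal(energy_reg(tr2, S2n), 0.05)

  # random fixtures: energies equal brute-force sums computed directly
  set.seed(8)
  Sr <- rand_skeleton(7, seed = 3)
  trr <- identity_transforms(Sr)
  for (k in names(trr)) {
    M <- diag(4)
    M[1:3, 1:3] <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    M[1:3, 4] <- rnorm(3, 0, 0.02)
    trr[[k]] <- M
  }
  Sr2 <- rand_skeleton(7, seed = 23)
  Cr <- data.frame(source = Sr$nodes$id, target = Sr2$nodes$id)
  ec <- 0
  for (r in seq_len(nrow(Cr))) {
    Ti <- trr[[as.character(Cr$source[r])]]
    x <- as.numeric(Sr$nodes[r, c("x", "y", "z")])
    y <- as.numeric(Sr2$nodes[r, c("x", "y", "z")])
    ec <- ec + sqrt(sum((Ti[1:3, 1:3] %*% x + Ti[1:3, 4] - y)^2))
  }
  expect_equal(energy_corresp(trr, Cr, Sr, Sr2), ec)
  er <- 0
  for (e in seq_len(nrow(Sr$edges))) {
    ij <- sort(Sr$edges[e, ])
    M <- solve(trr[[as.character(ij[1])]]) %*% trr[[as.character(ij[2])]]
    er <- er + sqrt(sum((M / M[4, 4] - diag(4))^2))
  }
  expect_equal(energy_reg(trr, Sr), er)
})

test_that("residual Jacobians match central finite differences", {
  Sr <- rand_skeleton(5, seed = 13)
  Sr2 <- rand_skeleton(5, seed = 17)
  C <- data.frame(source = Sr$nodes$id, target = Sr2$nodes$id)
  w <- list(w_corresp = 100, w_rot = 10, w_reg = 1)
  # a huge robust scale makes the correspondence block effectively
  # unweighted, so the analytic Jacobian is comparable everywhere
  prob <- plantreg4d:::.build_deform_problem(Sr, Sr2, C, w, 1e6)
  set.seed(3)
  for (rep in 1:3) {
    theta <- plantreg4d:::.transforms_to_theta(identity_transforms(Sr)) +
      rnorm(12 * nrow(Sr$nodes), 0, 0.05)
    rj <- plantreg4d:::.deform_residuals(theta, prob)
    h <- 1e-6
    idx <- sample(length(theta), 20)
    for (k in idx) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      fd <- (plantreg4d:::.deform_residuals(tp, prob, FALSE)$r -
               plantreg4d:::.deform_residuals(tm, prob, FALSE)$r) / (2 * h)
      expect_lt(max(abs(fd - rj$J[, k])), 1e-5)
    }
  }
})

test_that("deformation optimization recovers exact and rigid solutions", {
  p <- generate_plant(small_plant_spec(seed = 3))
  S1 <- p$skeleton
  C <- data.frame(source = S1$nodes$id, target = S1$nodes$id)
  # S2 == S1: global optimum at identity
  trs <- optimize_deformation(S1, S1, C)
  expect_lt(attr(trs, "e_total"), 1e-8)
  for (Ti in trs) expect_lt(max(abs(Ti - diag(4))), 1e-4)

  # rigid motion: every node transform converges to [R | t]
  R <- rot_z(10); tt <- c(0.02, 0, 0)
  S2 <- transform_skeleton(S1, R, tt)
  tr2 <- optimize_deformation(S1, S2, C)
  expect_lt(attr(tr2, "e_total"), 1e-6)
  for (Ti in tr2) {
    expect_lt(sqrt(sum((Ti[1:3, 1:3] - R)^2)), 1e-3)
    expect_lt(sqrt(sum((Ti[1:3, 4] - tt)^2)), 1e-3)
  }
  # accepted iterates never increase the robust objective
  expect_true(all(diff(attr(tr2, "energy_trace")) <= 1e-12))
})

test_that("the Cauchy kernel suppresses correspondence outliers", {
  p <- generate_plant(small_plant_spec(seed = 5))
  S1 <- p$skeleton
  R <- rot_z(5); tt <- c(0.005, 0.002, 0.01)
  S2 <- transform_skeleton(S1, R, tt)
  C <- data.frame(source = S1$nodes$id, target = S1$nodes$id)
  base <- optimize_deformation(S1, S2, C)
  S2o <- S2
  S2o$nodes$x[4] <- S2o$nodes$x[4] + 0.3  # one wildly wrong target
  out <- optimize_deformation(S1, S2o, C)
  pos <- function(trs) t(vapply(seq_len(nrow(S1$nodes)), function(i) {
    as.numeric((trs[[i]] %*% c(S1$nodes$x[i], S1$nodes$y[i], S1$nodes$z[i], 1))[1:3])
  }, numeric(3)))
  expect_lt(max(sqrt(rowSums((pos(base) - pos(out))^2))), 0.002)
})

test_that("unmatched nodes are carried by the regularizer", {
  p <- generate_plant(small_plant_spec(seed = 7))
  S1 <- p$skeleton
  R <- rot_z(8); tt <- c(0.01, 0, 0.005)
  S2 <- transform_skeleton(S1, R, tt)
  C <- data.frame(source = S1$nodes$id, target = S1$nodes$id)
  C$target[c(3, 9)] <- NA  # drop some correspondences
  trs <- optimize_deformation(S1, S2, C)
  # the unmatched nodes still end up near the rigid motion
  for (i in c(3, 9)) {
    Ti <- trs[[i]]
    x <- as.numeric(S1$nodes[i, c("x", "y", "z")])
    moved <- Ti[1:3, 1:3] %*% x + Ti[1:3, 4]
    expect_lt(sqrt(sum((moved - (R %*% x + tt))^2)), 1e-3)
  }
  expect_error(optimize_deformation(S1, S2,
                                    data.frame(source = S1$nodes$id,
                                               target = NA_integer_)),
               "matched")
})
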