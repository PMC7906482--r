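test_that("cloud warping blends the two nearest node transforms", {
  p <- generate_plant(small_plant_spec(seed = 2))
  S <- p$skeleton
  # identity transforms: exact no-op
  out <- deform_cloud(p$cloud, S, identity_transforms(S))
  expect_identical(out$points, p$cloud$points)
  expect_identical(out$labels, p$cloud$labels)

  # one common rigid transform: convexity gives the rigid result exactly
  R <- rot_z(25); tt <- c(0.01, -0.02, 0.03)
  trs <- identity_transforms(S)
  for (k in names(trs)) { trs[[k]][1:3, 1:3] <- R; trs[[k]][1:3, 4] <- tt }
  out2 <- deform_cloud(p$cloud, S, trs)
  expected <- t(R %*% t(p$cloud$points)) +
    matrix(tt, n_points(p$cloud), 3, byrow = TRUE)
  expect_lt(max(abs(out2$points - expected)), 1e-9)

  # a point projecting onto an edge midpoint: hand-computed 50/50 blend
  S2 <- path_skeleton(2, spacing = 0.02)
  ta <- diag(4); tb <- diag(4)
  tb[1:3, 4] <- c(0.004, 0, 0)
  trs2 <- structure(list(`1` = ta, `2` = tb), class = "node_transforms")
  pmid <- point_cloud(matrix(c(0.003, 0, 0.01), 1, 3))
  got <- deform_cloud(pmid, S2, trs2)$points
  expect_equal(as.numeric(got),
               as.numeric(0.5 * c(0.003, 0, 0.01) +
                            0.5 * c(0.003 + 0.004, 0, 0.01)),
               tolerance = 1e-12)

  # beyond the terminal node the terminal transform applies fully
  ptip <- point_cloud(matrix(c(0, 0, 0.05), 1, 3))
  gott <- deform_cloud(ptip, S2, trs2)$points
  expect_equal(as.numeric(gott), c(0.004, 0, 0.05), tolerance = 1e-12)

  expect_error(deform_cloud(p$cloud, S, identity_transforms(S)[-1]), "missing")
})

test_that("warping is equivariant under a global rotation", {
  p <- generate_plant(small_plant_spec(seed = 4))
  S <- p$skeleton
  set.seed(5)
  trs <- identity_transforms(S)
  for (k in names(trs)) {
    trs[[k]][1:3, 1:3] <- rot_z(runif(1, -10, 10)) %*% diag(1 + rnorm(3, 0, 0.03))
    trs[[k]][1:3, 4] <- rnorm(3, 0, 0.004)
  }
  out <- deform_cloud(p$cloud, S, trs)
  G <- rot_z(33)
  rot_cloud <- point_cloud(t(G %*% t(p$cloud$points)))
  Srot <- transform_skeleton(S, G)
  trs_rot <- trs
  Gh <- diag(4); Gh[1:3, 1:3] <- G
  for (k in names(trs)) trs_rot[[k]] <- Gh %*% trs[[k]] %*% solve(Gh)
  out_rot <- deform_cloud(rot_cloud, Srot, trs_rot)
  expect_lt(max(abs(out_rot$points - t(G %*% t(out$points)))), 1e-9)
})

test_that("polar decomposition splits scale, rotation and translation", {
  # pure rotation -> T_s = I, T_t = I
  Trot <- diag(4); Trot[1:3, 1:3] <- rot_z(40)
  d <- decompose_affine(Trot)
  expect_equal(d$Ts, diag(4), tolerance = 1e-12)
  expect_equal(d$Tt, diag(4), tolerance = 1e-12)
  # 2I linear part -> T_s = 2I, T_R = I
  d2 <- decompose_affine(diag(c(2, 2, 2, 1)))
  expect_equal(d2$Ts[1:3, 1:3], 2 * diag(3), tolerance = 1e-12)
  expect_equal(d2$TR, diag(4), tolerance = 1e-12)
  # random well-conditioned affines: T_s T_R T_t reproduces T; T_R is a
  # proper rotation and T_s symmetric
  set.seed(9)
  for (rep in 1:50) {
    M <- diag(4)
    M[1:3, 1:3] <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)
    if (det(M[1:3, 1:3]) <= 0.05) next
    M[1:3, 4] <- rnorm(3, 0, 0.05)
    d3 <- decompose_affine(M)
    expect_lt(max(abs(d3$Ts %*% d3$TR %*% d3$Tt - M)), 1e-9)
    R <- d3$TR[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_gt(det(R), 0)
    expect_lt(max(abs(d3$Ts - t(d3$Ts))), 1e-9)
  }
  refl <- diag(c(-1, 1, 1, 1))
  expect_error(decompose_affine(refl), "determinant")
})

test_that("transform interpolation hits its endpoints and midpoints", {
  M <- diag(4)
  M[1:3, 1:3] <- 1.3 * rot_z(90)
  M[1:3, 4] <- c(0.05, -0.01, 0.02)
  expect_lt(max(abs(interpolate_transform(M, 0) - diag(4))), 1e-12)
  expect_lt(max(abs(interpolate_transform(M, 1) - M)), 1e-9)
  # 90 degree rotation at t = 0.5 -> 45 degrees
  Tr <- diag(4); Tr[1:3, 1:3] <- rot_z(90)
  expect_equal(interpolate_transform(Tr, 0.5)[1:3, 1:3], rot_z(45),
               tolerance = 1e-12)
  # scale 2 at t = 0.5 -> scale 1.5
  expect_equal(interpolate_transform(diag(c(2, 2, 2, 1)), 0.5),
               diag(c(1.5, 1.5, 1.5, 1)), tolerance = 1e-12)
  expect_error(interpolate_transform(M, 1.5), "\\[0, 1\\]")
})

test_that("cloud interpolation is anchored, monotone and continuous", {
  p <- generate_plant(small_plant_spec(seed = 6))
  S <- p$skeleton
  trs <- identity_transforms(S)
  R <- rot_z(12); tt <- c(0.015, 0.005, 0.01)
  for (k in names(trs)) { trs[[k]][1:3, 1:3] <- R; trs[[k]][1:3, 4] <- tt }
  i0 <- interpolate_cloud(p$cloud, S, trs, 0)
  expect_lt(max(abs(i0$points - p$cloud$points)), 1e-9)
  i1 <- interpolate_cloud(p$cloud, S, trs, 1)
  full <- deform_cloud(p$cloud, S, trs)
  expect_lt(max(abs(i1$points - full$points)), 1e-9)
  # mean displacement grows with t under a rigid motion
  disp <- vapply(c(0.25, 0.5, 0.75), function(t) {
    mean(sqrt(rowSums((interpolate_cloud(p$cloud, S, trs, t)$points -
                         p$cloud$points)^2)))
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
  # small steps in t move points by small amounts
  delta <- 1e-4
  d <- max(abs(interpolate_cloud(p$cloud, S, trs, 0.5 + delta)$points -
                 interpolate_cloud(p$cloud, S, trs, 0.5)$points))
  expect_lt(d, 1e-4)
})

test_that("interpolating a registered pair approximates the true mid-stage", {
  p <- generate_plant(small_plant_spec(seed = 3))
  g1 <- grow_plant(p, growth_spec(seed = 4))
  gmid <- grow_plant(p, growth_spec(seed = 5), stage = 0.5)
  # use the generator's exact transforms: interpolation halfway must land
  # near the generator's own mid-stage cloud
  clean <- point_cloud(p$clean, p$cloud$labels, p$cloud$instances)
  mid <- interpolate_cloud(clean, p$skeleton, g1$transforms, 0.5)
  err <- registration_error(mid, gmid$cloud)
  expect_lt(err$mean, 2 * 5e-4)
})
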