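test_that("FPFH descriptors reflect local geometry, not point order", {
  gx <- seq(0, 0.04, by = 0.001)
  plane <- as.matrix(expand.grid(x = gx, y = gx, z = 0))
  cl <- point_cloud(plane)
  f <- compute_features(cl, radius = 0.004, center = FALSE)
  # two interior points with congruent neighborhoods: identical histograms
  i1 <- which(plane[, 1] == 0.020 & plane[, 2] == 0.020)
  i2 <- which(plane[, 1] == 0.019 & plane[, 2] == 0.021)
  expect_lt(max(abs(f[i1, 4:36] - f[i2, 4:36])), 1e-6)

  # plane vs 5 mm cylinder: clearly different histograms
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  zz <- seq(0, 0.04, by = 0.001)
  g <- as.matrix(expand.grid(th = th, z = zz))
  cyl <- cbind(0.005 * cos(g[, 1]), 0.005 * sin(g[, 1]), g[, 2])
  fc <- compute_features(point_cloud(cyl), radius = 0.004, center = FALSE)
  ic <- which.min(rowSums(sweep(cyl, 2, c(0.005, 0, 0.02))^2))
  expect_gt(sum(abs(f[i1, 4:36] - fc[ic, 4:36])), 0.1)

  # order invariance: permuting the input permutes the features
  set.seed(1)
  perm <- sample(nrow(plane))
  fp <- compute_features(point_cloud(plane[perm, ]), radius = 0.004,
                         center = FALSE)
  expect_equal(fp[order(perm), ], f, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(compute_features(cl, radius = -1), "positive")
})

test_that("sparse neighborhoods yield zero-filled, flagged histograms", {
  pts <- rbind(matrix(runif(300, 0, 0.01), ncol = 3), c(5, 5, 5))
  f <- compute_features(point_cloud(pts), radius = 0.005, center = FALSE)
  flagged <- attr(f, "flagged")
  expect_true(flagged[nrow(pts)])
  expect_equal(unname(f[nrow(pts), 4:36]), rep(0, 33))
})

test_that("SVM classifier separates stem from leaf and is deterministic", {
  set.seed(3)
  X <- rbind(matrix(rnorm(200, 0), ncol = 2), matrix(rnorm(200, 5), ncol = 2))
  y <- rep(c("stem", "leaf"), each = 100)
  fit <- train_classifier(X, y, seed = 1)
  expect_equal(fit$train_accuracy, 1)
  expect_identical(classify_points(fit, X), y)
  # determinism: retraining reproduces the predictions exactly
  fit2 <- train_classifier(X, y, seed = 1)
  expect_identical(classify_points(fit2, X), classify_points(fit, X))
  expect_error(train_classifier(X, rep("stem", 200)), "both classes")
  expect_error(classify_points(fit, X[, 1, drop = FALSE]), "width")
})

test_that("classifier trained on one scan transfers to a later scan", {
  p1 <- generate_plant(small_plant_spec(seed = 11))
  p2 <- grow_plant(p1, growth_spec(seed = 12))
  fit <- train_classifier(compute_features(p1$cloud), p1$cloud$labels)
  pred <- classify_points(fit, compute_features(p2$cloud))
  for (cls in c("stem", "leaf")) {
    tp <- sum(pred == cls & p2$cloud$labels == cls)
    fn <- sum(pred != cls & p2$cloud$labels == cls)
    expect_gt(tp / (tp + fn), 0.9)  # per-class recall
  }
})

test_that("density clustering finds organ instances and absorbs satellites", {
  set.seed(7)
  blob <- function(center, n, sd = 0.001)
    matrix(rnorm(n * 3, sd = sd), n, 3) + matrix(center, n, 3, byrow = TRUE)
  eps <- 0.003
  # two leaf blobs separated by 10x eps -> exactly 2 leaf instances
  P <- rbind(blob(c(0, 0, 0.05), 300), blob(c(10 * eps + 0.03, 0, 0.05), 300),
             blob(c(0.015, 0, 0), 200))
  cl <- point_cloud(P)
  classes <- c(rep("leaf", 600), rep("stem", 200))
  seg <- cluster_instances(cl, classes, eps = eps, min_samples = 10,
                           min_cluster_size = 50, k_reassign = 5)
  tab <- seg$instance_table
  expect_equal(sum(tab$class == "leaf"), 2)
  expect_equal(sum(tab$class == "stem"), 1)
  # partition: every point in exactly one instance
  expect_true(all(seg$instances > 0))
  expect_equal(sum(tab$n), n_points(cl))

  # satellite blob below min_cluster_size dissolves into the big instance
  P2 <- rbind(blob(c(0, 0, 0.05), 500), blob(c(0.05, 0, 0.05), 49),
              blob(c(0.02, 0, 0), 200))
  seg2 <- cluster_instances(point_cloud(P2),
                            c(rep("leaf", 549), rep("stem", 200)),
                            eps = eps, min_samples = 10,
                            min_cluster_size = 50, k_reassign = 5)
  expect_equal(sum(seg2$instance_table$class == "leaf"), 1)
  expect_equal(seg2$instance_table$n[seg2$instance_table$class == "leaf"], 549)

  # a connected chain within eps forms a single instance
  chain <- cbind(seq(0, 0.1, by = 5e-4), 0, 0.05)
  seg3 <- cluster_instances(point_cloud(rbind(chain, blob(c(0.05, 0.03, 0), 100))),
                            c(rep("leaf", nrow(chain)), rep("stem", 100)),
                            eps = eps, min_samples = 3,
                            min_cluster_size = 50, k_reassign = 5)
  expect_equal(sum(seg3$instance_table$class == "leaf"), 1)

  # no leaf points -> stem-only segmentation
  seg4 <- cluster_instances(point_cloud(blob(c(0, 0, 0), 100)),
                            rep("stem", 100), eps = eps)
  expect_equal(seg4$instance_table$class, "stem")
})

test_that("segmentation metrics match their defining formulas", {
  # tp = 90, fp = 10 -> precision 0.90 (constructed directly)
  pred <- list(classes = c(rep("stem", 100), rep("leaf", 100)),
               instances = rep(1:2, each = 100))
  truth <- list(classes = c(rep("stem", 90), rep("leaf", 110)),
                instances = c(rep(1L, 90), rep(2L, 110)))
  class(pred) <- class(truth) <- "organ_segmentation"
  m <- evaluate_segmentation(pred, truth)
  expect_equal(m$per_class$precision[m$per_class$class == "stem"], 0.90)

  # tp = 50, fp = 25, fn = 25 -> IoU 0.50
  pred2 <- list(classes = c(rep("stem", 75), rep("leaf", 25)),
                instances = rep(1L, 100))
  truth2 <- list(classes = c(rep("stem", 50), rep("leaf", 25), rep("stem", 25)),
                 instances = rep(1L, 100))
  class(pred2) <- class(truth2) <- "organ_segmentation"
  m2 <- evaluate_segmentation(pred2, truth2)
  expect_equal(m2$per_class$iou[m2$per_class$class == "stem"], 0.50)

  # perfect prediction -> all metrics 1
  m3 <- evaluate_segmentation(truth, truth)
  expect_true(all(unlist(m3$per_class[c("precision", "recall", "iou")]) == 1))
  expect_equal(m3$instance$precision, 1)

  # IoU <= min(precision, recall), on a noisy random case
  set.seed(5)
  predr <- list(classes = sample(c("stem", "leaf"), 500, replace = TRUE),
                instances = sample(1:3, 500, replace = TRUE))
  truthr <- list(classes = sample(c("stem", "leaf"), 500, replace = TRUE),
                 instances = sample(1:3, 500, replace = TRUE))
  class(predr) <- class(truthr) <- "organ_segmentation"
  mr <- evaluate_segmentation(predr, truthr)$per_class
  expect_true(all(mr$iou <= pmin(mr$precision, mr$recall) + 1e-12))

  expect_error(evaluate_segmentation(pred, list(classes = "stem")), "size")
})
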