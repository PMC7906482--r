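#' Cluster classified points into organ instances
#'
#' Leaf-class points are grouped by density-based spatial clustering (DBSCAN)
#' on their xyz coordinates; all stem-class points form a single stem
#' instance. Clusters smaller than `min_cluster_size` are dissolved and their
#' points reassigned by a majority vote of the `k_reassign` nearest points
#' that belong to a retained cluster. The result partitions the cloud: every
#' point belongs to exactly one instance.
#'
#' @param cloud a [point_cloud()].
#' @param classes character vector of per-point classes (`"stem"`/`"leaf"`).
#' @param eps DBSCAN neighborhood radius (m); `NA` = 4x median nn spacing.
#' @param min_samples DBSCAN core-point neighbor threshold.
#' @param min_cluster_size smallest cluster kept after refinement.
#' @param k_reassign neighbors consulted when reassigning dissolved points.
#' @return an object of class `organ_segmentation`: list with per-point
#'   `classes`, per-point `instances` (stem instance id is 1), and an
#'   `instance_table` data frame (`id`, `class`, `n`).
#' @export
cluster_instances <- function(cloud, classes, eps = NA_real_, min_samples = 10L,
                              min_cluster_size = 50L, k_reassign = 5L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  classes <- as.character(classes)
  if (length(classes) != n) stop("`classes` must have one entry per point")
  if (is.na(eps)) eps <- 4 * median_nn_spacing(cloud)
  inst <- integer(n)
  is_leaf <- classes == "leaf"
  inst[!is_leaf] <- 1L  # the stem is always a single organ
  if (any(is_leaf)) {
    L <- cloud$points[is_leaf, , drop = FALSE]
    cl <- .dbscan(L, eps, min_samples)
    cl <- .refine_clusters(L, cl, min_cluster_size, k_reassign)
    inst[is_leaf] <- cl + 1L  # leaf instances start at 2
  }
  tab <- as.data.frame(table(inst))
  tab <- data.frame(id = as.integer(as.character(tab$inst)),
                    class = ifelse(as.integer(as.character(tab$inst)) == 1L,
                                   "stem", "leaf"),
                    n = as.integer(tab$Freq))
  tab <- tab[tab$n > 0, ]
  structure(list(classes = classes, instances = inst, instance_table = tab),
            class = "organ_segmentation")
}

#' @export
print.organ_segmentation <- function(x, ...) {
  cat(sprintf("organ_segmentation: %d points, %d instance(s)\n",
              length(x$classes), nrow(x$instance_table)))
  print(x$instance_table, row.names = FALSE)
  invisible(x)
}

# classic DBSCAN; returns cluster id per point (0 = noise)
.dbscan <- function(P, eps, min_samples) {
  n <- nrow(P)
  nbrs <- cpp_radius_neighbors(P, eps)
  core <- vapply(nbrs, length, integer(1)) + 1L >= min_samples  # incl. self
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    cl[i] <- cur
    queue <- nbrs[[i]]
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (cl[j] == 0L) {
        cl[j] <- cur
        if (core[j]) queue <- c(queue, nbrs[[j]][cl[nbrs[[j]]] == 0L])
      }
    }
  }
  cl
}

# dissolve small clusters and noise; reassign their points by kNN majority
# among points of retained clusters
.refine_clusters <- function(P, cl, min_cluster_size, k_reassign) {
  sizes <- table(cl[cl > 0])
  keep <- as.integer(names(sizes)[sizes >= min_cluster_size])
  if (length(keep) == 0) {
    # nothing survives the size threshold: keep the largest group instead
    if (length(sizes) == 0) return(rep(1L, nrow(P)))
    keep <- as.integer(names(sizes)[which.max(sizes)])
  }
  bad <- which(!(cl %in% keep))
  good <- which(cl %in% keep)
  if (length(bad) > 0) {
    k <- min(k_reassign, length(good))
    nn <- cpp_knn(P[bad, , drop = FALSE], P[good, , drop = FALSE], k)
    for (t in seq_along(bad)) {
      votes <- cl[good[nn$idx[t, ]]]
      tabv <- sort(table(votes), decreasing = TRUE)
      cl[bad[t]] <- as.integer(names(tabv)[1])
    }
  }
  # renumber retained clusters 1..K deterministically (by first member index)
  first <- vapply(keep, function(k) which(cl == k)[1], integer(1))
  relab <- keep[order(first)]
  match(cl, relab)
}

#' Segmentation accuracy metrics
#'
#' Class-wise precision, recall and intersection-over-union for the stem and
#' leaf classes, plus instance-level precision/recall after a maximum-overlap
#' one-to-one matching between predicted and true instances.
#'
#' @param predicted,truth `organ_segmentation` objects over the same points.
#' @return a list with `per_class` (data frame: class, precision, recall, iou)
#'   and `instance` (list: precision, recall, matching data frame).
#' @export
evaluate_segmentation <- function(predicted, truth) {
  if (length(predicted$classes) != length(truth$classes))
    stop("predicted and truth segmentations differ in size")
  per_class <- do.call(rbind, lapply(c("stem", "leaf"), function(cls) {
    tp <- sum(predicted$classes == cls & truth$classes == cls)
    fp <- sum(predicted$classes == cls & truth$classes != cls)
    fn <- sum(predicted$classes != cls & truth$classes == cls)
    data.frame(class = cls,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_)
  }))
  m <- .match_instances(predicted$instances, truth$instances)
  tp <- sum(vapply(seq_len(nrow(m)), function(k) {
    sum(predicted$instances == m$predicted[k] & truth$instances == m$truth[k])
  }, numeric(1)))
  inst <- list(precision = tp / length(predicted$instances),
               recall = tp / length(truth$instances),
               matching = m)
  list(per_class = per_class, instance = inst)
}

# maximum-overlap one-to-one assignment between predicted and truth instance
# ids; exact search for small instance counts, greedy above that
.match_instances <- function(pred, truth) {
  pid <- sort(unique(pred)); tid <- sort(unique(truth))
  ov <- outer(pid, tid, Vectorize(function(p, t) sum(pred == p & truth == t)))
  if (length(pid) <= 8 && length(tid) <= 8) {
    # exact: enumerate injective assignments from the smaller side
    if (length(pid) <= length(tid)) {
      perms <- .permutations(seq_along(tid), length(pid))
      vals <- apply(perms, 1, function(p) sum(ov[cbind(seq_along(pid), p)]))
      best <- perms[which.max(vals), ]
      data.frame(predicted = pid, truth = tid[best])
    } else {
      perms <- .permutations(seq_along(pid), length(tid))
      vals <- apply(perms, 1, function(p) sum(ov[cbind(p, seq_along(tid))]))
      best <- perms[which.max(vals), ]
      data.frame(predicted = pid[best], truth = tid)
    }
  } else {
    used_p <- logical(length(pid)); used_t <- logical(length(tid))
    res <- list()
    ord <- order(ov, decreasing = TRUE)
    for (k in ord) {
      i <- (k - 1) %% length(pid) + 1
      j <- (k - 1) %/% length(pid) + 1
      if (!used_p[i] && !used_t[j] && ov[i, j] > 0) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        res[[length(res) + 1]] <- data.frame(predicted = pid[i], truth = tid[j])
      }
    }
    do.call(rbind, res)
  }
}

# all k-permutations of v (small inputs only)
.permutations <- function(v, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), v)
  do.call(rbind, out)
}
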