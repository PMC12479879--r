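# Two-cluster agglomerative cut and cluster-quality indices (average
# silhouette, CDbw) computed on the 2-D embedding.

#' Two-cluster average-linkage cut
#'
#' Agglomerative clustering with unweighted average linkage on Euclidean
#' distances, tree cut at exactly two clusters. Labels are nominal and made
#' deterministic by size: 0 is the larger cluster (ties: the cluster holding
#' the lowest point index). Above `max_n` points a seeded uniform subsample is
#' clustered and the remaining points take the label of their nearest
#' clustered neighbour (linkage memory is O(n^2)).
#'
#' @param embedding n x 2 coordinate matrix (n >= 2).
#' @param max_n subsample threshold.
#' @param seed seed for the subsample draw.
#' @return integer vector of labels in {0, 1}.
#' @export
hcluster2 <- function(embedding, max_n = 30000L, seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 2) stop("need at least 2 points to cut two clusters")
  if (n > max_n) {
    sub <- with_seed(seed, sort(sample.int(n, max_n)))
    lab_sub <- hcluster2(embedding[sub, , drop = FALSE], max_n = n)
    labels <- integer(n)
    labels[sub] <- lab_sub
    rest <- setdiff(seq_len(n), sub)
    for (i in rest) {
      d2 <- (embedding[sub, 1] - embedding[i, 1])^2 +
        (embedding[sub, 2] - embedding[i, 2])^2
      labels[i] <- lab_sub[which.min(d2)]
    }
    return(labels)
  }
  cl <- cutree(hclust(dist(embedding), method = "average"), k = 2)
  sizes <- tabulate(cl, 2)
  if (sizes[1] > sizes[2] || (sizes[1] == sizes[2] && cl[1] == 1)) {
    labels <- ifelse(cl == 1, 0L, 1L)
  } else {
    labels <- ifelse(cl == 2, 0L, 1L)
  }
  labels
}

#' Average silhouette score
#'
#' Per point, `(b - a) / max(a, b)` with `a` the mean distance to its own
#' cluster's other members and `b` the smallest mean distance to another
#' cluster; members of singleton clusters contribute 0. The average lies in
#' \[-1, 1\].
#'
#' @param embedding n x m coordinate matrix.
#' @param labels cluster labels (any nominal coding, >= 2 distinct values).
#' @return mean silhouette width.
#' @export
silhouette_score <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2)
    stop("silhouette is undefined for a single cluster")
  D <- as.matrix(dist(embedding))
  n <- nrow(D)
  sizes <- tabulate(labels, max(ks))
  # mean distance from every point to every cluster, in one product
  member <- outer(labels, ks, "==") + 0
  sums <- D %*% member
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1) { s[i] <- 0; next }
    a <- sums[i, li] / (sizes[li] - 1)
    b <- min(sums[i, ks != li] / sizes[ks != li])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Farthest-point traversal: r boundary representatives of one cluster,
# starting from the point farthest from the centroid.
fps_representatives <- function(pts, r) {
  centroid <- colMeans(pts)
  d2c <- rowSums(sweep(pts, 2, centroid)^2)
  chosen <- which.max(d2c)
  mind <- rowSums(sweep(pts, 2, pts[chosen[1], ])^2)
  while (length(chosen) < r) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, rowSums(sweep(pts, 2, pts[nxt, ])^2))
  }
  pts[chosen, , drop = FALSE]
}

#' CDbw cluster-validity index
#'
#' Composed density between and within clusters (after Halkidi &
#' Vazirgiannis 2008), suited to non-spherical cluster geometries. Per
#' cluster, `n_reps` boundary representatives are picked by farthest-point
#' traversal from the centroid. Cohesion derives from the within-cluster
#' density around the representatives shrunk toward the centroid over shrink
#' factors `s` in {0.1, ..., 0.8} (compactness penalized by the density
#' change across shrink levels); separation contrasts the distance between
#' mutually-closest representative pairs of different clusters with the
#' density at their midpoints. The index is cohesion x separation x
#' compactness; higher is better. Densities use a Gaussian kernel at the
#' cluster's RMS radius, so the index is strictly positive and its ranking of
#' candidate labelings is invariant to a global rescaling of the coordinates.
#'
#' @param embedding n x m coordinate matrix.
#' @param labels cluster labels (each cluster needs >= `n_reps` points).
#' @param n_reps representatives per cluster.
#' @param shrink shrink-factor grid.
#' @return positive scalar; higher means denser, better-separated clusters.
#' @export
cdbw <- function(embedding, labels, n_reps = 10L,
                 shrink = seq(0.1, 0.8, by = 0.1)) {
  embedding <- as.matrix(embedding)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("CDbw needs >= 2 clusters")
  clusters <- lapply(ks, function(k) embedding[labels == k, , drop = FALSE])
  if (any(vapply(clusters, nrow, 1L) < n_reps))
    stop("every cluster needs at least n_reps = ", n_reps, " points")
  sigma <- vapply(clusters, function(p)
    sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2))), 1)
  sigma[sigma == 0] <- .Machine$double.eps
  reps <- lapply(clusters, fps_representatives, r = n_reps)
  centroids <- lapply(clusters, colMeans)

  gauss_density <- function(points, at, s) {
    d2 <- rowSums(sweep(points, 2, at)^2)
    mean(exp(-d2 / (2 * s^2)))
  }
  # within-cluster density at each shrink level
  intra <- vapply(shrink, function(s) {
    mean(vapply(seq_along(clusters), function(i) {
      v <- reps[[i]] + s * (matrix(centroids[[i]], n_reps, ncol(embedding),
                                   byrow = TRUE) - reps[[i]])
      mean(vapply(seq_len(n_reps), function(j)
        gauss_density(clusters[[i]], v[j, ], sigma[i]), 1))
    }, 1))
  }, 1)
  compactness <- mean(intra)
  intra_change <- if (length(intra) > 1) mean(abs(diff(intra))) else 0
  cohesion <- compactness / (1 + intra_change)

  # separation over cluster pairs: mutually-closest representative pairs
  sep_pairs <- c()
  for (i in seq_along(clusters)[-length(clusters)]) {
    for (j in (i + 1):length(clusters)) {
      cross <- as.matrix(dist(rbind(reps[[i]], reps[[j]])))[
        seq_len(n_reps), n_reps + seq_len(n_reps), drop = FALSE]
      nearest_j <- apply(cross, 1, which.min)
      nearest_i <- apply(cross, 2, which.min)
      mutual <- which(nearest_i[nearest_j] == seq_len(n_reps))
      if (!length(mutual)) mutual <- which.min(apply(cross, 1, min))
      both <- rbind(clusters[[i]], clusters[[j]])
      s_ij <- (sigma[i] + sigma[j]) / 2
      dists <- dens <- numeric(length(mutual))
      for (m in seq_along(mutual)) {
        u <- reps[[i]][mutual[m], ]
        v <- reps[[j]][nearest_j[mutual[m]], ]
        dists[m] <- sqrt(sum((u - v)^2))
        dens[m] <- gauss_density(both, (u + v) / 2, s_ij)
      }
      sep_pairs <- c(sep_pairs, mean(dists) / (1 + mean(dens)))
    }
  }
  sep <- min(sep_pairs)
  cohesion * sep * compactness
}
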