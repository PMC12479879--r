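# t-SNE embedding of EOD feature vectors.
#
# The heavy lifting (perplexity calibration, exact gradient) is compiled code;
# this wrapper adds PCA preprocessing, the deterministic PCA initialization
# and argument checking.

#' Separation (embedding + clustering) configuration
#'
#' @param perplexity t-SNE neighbourhood scale; the study default is 50,
#'   selected on dyadic combinations of 24 individuals over a 30-120 grid.
#' @param seed RNG seed (initialization jitter; the embedding is deterministic
#'   given the seed).
#' @param n_iter gradient-descent iterations (750 with early exaggeration 12
#'   for the first 250).
#' @param pca_dims input is reduced to this many principal components before
#'   the pairwise-affinity computation (standard t-SNE preprocessing; 0
#'   disables).
#' @param k number of clusters cut from the average-linkage tree (a dyad has
#'   two fish; fixed at 2).
#' @param n_reps CDbw boundary representatives per cluster.
#' @param max_cluster_n above this many events the linkage tree is built on a
#'   uniform subsample and remaining points inherit the label of their nearest
#'   clustered neighbour (O(n^2) linkage memory).
#' @return `separation_config` list. Linkage is unweighted average, the metric
#'   Euclidean, in both the clustering and the quality indices.
#' @export
separation_config <- function(perplexity = 50, seed = 1L, n_iter = 750,
                              pca_dims = 50, k = 2L, n_reps = 10L,
                              max_cluster_n = 30000L) {
  if (perplexity < 5) stop("perplexity must be >= 5")
  if (k != 2L) stop("the dyad separation cuts the tree at exactly k = 2")
  structure(list(perplexity = perplexity, seed = as.integer(seed),
                 n_iter = n_iter, pca_dims = pca_dims, k = 2L,
                 n_reps = as.integer(n_reps),
                 max_cluster_n = as.integer(max_cluster_n),
                 linkage = "average", metric = "euclidean", init = "pca"),
            class = "separation_config")
}

#' Embed feature vectors in 2-D with t-SNE
#'
#' Exact t-SNE: input affinities are Gaussian kernels calibrated per point to
#' the configured perplexity, output affinities are Student-t, and the KL
#' divergence between the two is minimized by gradient descent (750
#' iterations, early exaggeration 12 for 250 iterations, momentum 0.5 then
#' 0.8, adaptive gains). Initialization is the first two principal components
#' scaled to SD 1e-4 plus a seeded jitter, so the embedding is deterministic
#' given the seed (not across seeds).
#'
#' @param features n x d numeric matrix (n >= 3 * perplexity).
#' @param config a [separation_config()].
#' @return n x 2 embedding matrix.
#' @export
tsne_embed <- function(features, config = separation_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (!all(is.finite(features))) stop("features must be finite")
  if (n < 3 * config$perplexity)
    stop("perplexity ", config$perplexity, " too large for n = ", n,
         " (need n >= 3 * perplexity); lower the perplexity")
  X <- features
  if (config$pca_dims > 0 && ncol(X) > config$pca_dims) {
    X <- prcomp(X, center = TRUE, scale. = FALSE,
                rank. = config$pca_dims)$x
  }
  p2 <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)$x
  if (ncol(p2) < 2) p2 <- cbind(p2, 0)[, 1:2]
  s <- stats::sd(p2[, 1])
  Y0 <- p2 / (if (s > 0) s else 1) * 1e-4
  Y0 <- Y0 + with_seed(config$seed, matrix(rnorm(2 * n, sd = 1e-6), ncol = 2))
  .tsne_cpp(X, Y0, config$perplexity, as.integer(config$n_iter), 250L, 12,
            max(50, n / 12))
}
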