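# Independent brute-force oracles the implementation is checked against.

# Average-linkage agglomerative clustering by direct recomputation of all
# inter-cluster mean pairwise distances at every merge; ties broken by
# smallest (i, j) in lexicographic order. Returns the k-cluster membership.
brute_average_linkage <- function(points, k = 2) {
  D <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(points)))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1] - 1e-12) best <- c(d, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  membership <- integer(nrow(points))
  for (c in seq_along(clusters)) membership[clusters[[c]]] <- c
  membership
}

# Silhouette by the definition, all pairwise distances recomputed per point.
brute_silhouette <- function(points, labels) {
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(points) - points[i, ])^2))
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(di[labels == l]), 1))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Direct O(N^2) DFT magnitudes.
brute_dft_mag <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    Mod(sum(x * exp(-2i * pi * k * (0:(N - 1)) / N))), 1)
}

# Identical partition up to label renaming.
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Instantaneous phase of a real tone via the analytic signal (FFT Hilbert).
analytic_phase <- function(x) {
  N <- length(x)
  X <- fft(x)
  h <- numeric(N); h[1] <- 1
  if (N %% 2 == 0) { h[N / 2 + 1] <- 1; h[2:(N / 2)] <- 2 }
  else h[2:((N + 1) / 2)] <- 2
  Arg(fft(X * h, inverse = TRUE) / N)
}
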