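two_fish_features <- function(n_per_fish, divergence = 0.9, seed = 1,
                              noise_sd = 0.03) {
  wa <- fish_waveforms(make_fish(seed * 2 + 1, divergence), n_per_fish,
                       noise_sd = noise_sd, seed = seed * 10 + 1)
  wb <- fish_waveforms(make_fish(seed * 2 + 2, divergence), n_per_fish,
                       noise_sd = noise_sd, seed = seed * 10 + 2)
  list(features = feature_matrix(rbind(wa, wb), "timefreq", fs = 50000),
       truth = rep(c("A", "B"), each = n_per_fish))
}

test_that("t-SNE embeds distinct fish into locally pure neighbourhoods", {
  fs <- two_fish_features(250, divergence = 0.9, seed = 1)
  emb <- tsne_embed(fs$features, separation_config(perplexity = 30, seed = 1))
  expect_equal(dim(emb), c(500, 2))
  D <- as.matrix(dist(emb)); diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  purity <- mean(fs$truth[nn] == fs$truth)
  expect_gte(purity, 0.99)
})

test_that("t-SNE is deterministic given the seed and keeps duplicates together", {
  fs <- two_fish_features(60, seed = 2)
  cfg <- separation_config(perplexity = 30, seed = 7)
  e1 <- tsne_embed(fs$features, cfg)
  e2 <- tsne_embed(fs$features, cfg)
  expect_identical(e1, e2)

  dup <- rbind(fs$features, fs$features)
  emb <- tsne_embed(dup, separation_config(perplexity = 30, seed = 3))
  n <- nrow(fs$features)
  gap <- sqrt(rowSums((emb[1:n, ] - emb[n + 1:n, ])^2))
  spread <- mean(sqrt(rowSums(sweep(emb, 2, colMeans(emb))^2)))
  expect_lt(max(gap) / spread, 0.05)

  expect_error(tsne_embed(fs$features[1:50, ],
                          separation_config(perplexity = 50)),
               "perplexity")
})

test_that("hcluster2 matches a brute-force average-linkage oracle", {
  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(rnorm(2 * sample(5:10, 1)), ncol = 2)
    expect_true(same_partition(hcluster2(pts),
                               brute_average_linkage(pts, k = 2)))
  }
  # well-separated pairs on a line
  pts <- cbind(c(0, 0.1, 10, 10.1), 0)
  lab <- hcluster2(pts)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_true(lab[1] != lab[3])
  # exact ties: reproducible output
  tied <- cbind(c(0, 1, 10, 11), 0)
  expect_identical(hcluster2(tied), hcluster2(tied))
  expect_error(hcluster2(pts[1, , drop = FALSE]), "2 points")
})

test_that("labels 0/1 are ordered by cluster size", {
  pts <- rbind(matrix(rnorm(20, mean = 0, sd = 0.1), ncol = 2),
               matrix(rnorm(8, mean = 5, sd = 0.1), ncol = 2))
  lab <- hcluster2(pts)
  expect_equal(sum(lab == 0L), 10)
  expect_equal(sum(lab == 1L), 4)
})

test_that("subsampled clustering labels every point consistently", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(120, 0, 0.3), ncol = 2),
               matrix(rnorm(120, 6, 0.3), ncol = 2))
  lab_full <- hcluster2(pts)
  lab_sub <- hcluster2(pts, max_n = 50, seed = 1)
  expect_true(same_partition(lab_full, lab_sub))
})

test_that("silhouette matches its brute-force definition and bounds", {
  for (s in 1:5) {
    set.seed(s)
    pts <- matrix(rnorm(40), ncol = 2)
    labs <- sample(0:1, 20, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1] <- 1 - labs[1]
    ss <- silhouette_score(pts, labs)
    expect_equal(ss, brute_silhouette(pts, labs), tolerance = 1e-12)
    expect_gte(ss, -1); expect_lte(ss, 1)
  }
  blobs <- rbind(matrix(rnorm(20, 0, 0.05), ncol = 2),
                 matrix(rnorm(20, 10, 0.05), ncol = 2))
  expect_gt(silhouette_score(blobs, rep(0:1, each = 10)), 0.9)
  # random split of a single blob hovers near zero
  scores <- vapply(1:10, function(s) {
    set.seed(s)
    one <- matrix(rnorm(80), ncol = 2)
    silhouette_score(one, sample(0:1, 40, replace = TRUE))
  }, 1)
  expect_lt(max(abs(scores)), 0.2)
  expect_error(silhouette_score(blobs, rep(0, 20)), "single cluster")
})

test_that("CDbw prefers true labelings, stays positive, ranks scale-free", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    pts <- rbind(matrix(rnorm(120, 0, 0.5), ncol = 2),
                 matrix(rnorm(120, 8, 0.5), ncol = 2))
    true_lab <- rep(0:1, each = 60)
    rand_lab <- sample(true_lab)
    cd_true <- cdbw(pts, true_lab)
    cd_rand <- cdbw(pts, rand_lab)
    expect_gt(cd_true, 0)
    expect_gt(cd_rand, 0)
    if (cd_true > cd_rand) wins <- wins + 1
    if (s == 1) {
      # doubling all coordinates must not change the ranking
      expect_equal(cdbw(pts * 2, true_lab) > cdbw(pts * 2, rand_lab),
                   cd_true > cd_rand)
    }
  }
  expect_gte(wins, 9)
  expect_error(cdbw(matrix(rnorm(20), ncol = 2), rep(0:1, 5), n_reps = 10),
               "n_reps")
})

test_that("perplexity selection returns the grid's best-scoring value", {
  expect_error(select_perplexity(list(), c(50)), "feature sets")
  expect_error(select_perplexity(list(two_fish_features(50)), c(10, 50)),
               "\\[30, 120\\]")
  sets <- list(two_fish_features(90, seed = 1))
  single <- select_perplexity(sets, grid = 50,
                              config = separation_config(seed = 1))
  expect_equal(single$perplexity, 50)

  sets3 <- lapply(1:2, function(s) two_fish_features(150, seed = s))
  sel <- select_perplexity(sets3, grid = c(30, 50, 100),
                           config = separation_config(seed = 1))
  best_row <- which(sel$scores$perplexity == sel$perplexity)
  expect_equal(sel$scores$median_mcc[best_row], max(sel$scores$median_mcc))
  expect_equal(nrow(sel$scores), 3)
})

test_that("cluster identities follow channel dominance and polarity", {
  ev <- eod_events(t_s = (1:40) / 100,
                   channel = rep(c(0L, 1L), 20),
                   peak_amp_V = rep(c(0.02, -0.015), 20))
  labels <- rep(c(0L, 1L), 20)
  id <- assign_cluster_identity(ev, labels)
  expect_equal(unname(id$map["0"]), "A")   # channel-0-positive cluster
  expect_equal(unname(id$map["1"]), "B")
  expect_false(id$ambiguous)
  # relabeling clusters leaves the per-event assignment unchanged
  id_sw <- assign_cluster_identity(ev, 1L - labels)
  expect_equal(unname(id_sw$map["1"]), "A")
  expect_equal(unname(id$map[as.character(labels)]),
               unname(id_sw$map[as.character(1L - labels)]))
  # identical signatures: flagged ambiguous
  ev2 <- eod_events(t_s = (1:4) / 100, channel = 0L, peak_amp_V = 0.02)
  id2 <- assign_cluster_identity(ev2, c(0L, 1L, 0L, 1L))
  expect_true(id2$ambiguous)
})

test_that("the end-to-end pipeline separates an easy dyad near-perfectly", {
  fa <- make_fish(21, 0.9); fb <- make_fish(22, 0.9)
  sim <- simulate_dyad(fa, fb, dyad_sim_config(duration_s = 25, seed = 21))
  cfg <- separation_config(perplexity = 30, seed = 21)
  res <- separate(sim$recording, config = cfg)
  expect_s3_class(res, "eod_separation")
  ev <- suppressMessages(evaluate_run(res$events, sim$truth,
                                      tol_s = 1 / sim$recording$fs))
  expect_gte(ev$acc, 0.99)
  expect_equal(sort(unique(res$labels)), c(0L, 1L))
  expect_true(all(res$events$label %in% c("A", "B")))
  # determinism
  res2 <- separate(sim$recording, config = cfg)
  expect_identical(res$labels, res2$labels)
  expect_identical(res$events$label, res2$events$label)
})

test_that("a solo recording still yields two clusters but is flagged", {
  fa <- make_fish(31, 0.8)
  sim <- simulate_dyad(fa, NULL, dyad_sim_config(duration_s = 30, seed = 31))
  res <- separate(sim$recording,
                  config = separation_config(perplexity = 30, seed = 31))
  expect_equal(length(unique(res$labels)), 2)
  expect_true(res$weak_separation)
})

test_that("too few events for the perplexity raises an informative error", {
  rec <- plant_recording(c(0.1, 0.2, 0.3), 0.02, 0L, duration_s = 0.5)
  expect_error(separate(rec, config = separation_config(perplexity = 50)),
               "lower the perplexity")
})
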