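# The unsupervised separation pipeline: detect -> extract -> scalogram
# features -> t-SNE -> average-linkage two-cluster cut -> quality indices ->
# cluster-to-fish identity assignment.

#' Map clusters to fish identities from amplitude/polarity signatures
#'
#' A fish's position relative to the two opposite-corner electrodes leaves a
#' stable signature in which channel carries its larger amplitude and with
#' which polarity. Per cluster, the mean signed peak amplitude on each
#' channel is computed; clusters are ordered by (dominant channel, mean
#' polarity) and mapped to fish "A" (channel 0 / positive first) and "B".
#' Identical signatures are flagged ambiguous, not an error.
#'
#' @param events event table carrying `channel` and `peak_amp_V`.
#' @param labels cluster labels from [hcluster2()], one per event.
#' @return list: `map` (cluster id -> "A"/"B"), `ambiguous`, `signatures`
#'   (per-cluster mean signed amplitude per channel).
#' @export
assign_cluster_identity <- function(events, labels) {
  stopifnot(nrow(events) == length(labels))
  ids <- sort(unique(labels))
  sig <- t(vapply(ids, function(cl) {
    e <- events[labels == cl, , drop = FALSE]
    vapply(0:1, function(ch) {
      a <- e$peak_amp_V[e$channel == ch]
      if (length(a)) mean(a) else 0
    }, 1)
  }, numeric(2)))
  rownames(sig) <- ids
  colnames(sig) <- c("ch0_mean_V", "ch1_mean_V")
  dom <- apply(sig, 1, function(r) which.max(abs(r)) - 1L)
  pol <- vapply(seq_along(ids), function(i) sign(sig[i, dom[i] + 1L]), 1)
  key <- order(dom, -pol)         # channel 0 before 1, positive before negative
  ambiguous <- length(ids) == 2 && dom[1] == dom[2] && pol[1] == pol[2]
  fish <- c("A", "B")[order(key)]
  if (length(ids) == 1) fish <- "A"
  list(map = stats::setNames(fish[seq_along(ids)], ids),
       ambiguous = ambiguous, signatures = sig)
}

#' Separate the EODs of a two-fish recording
#'
#' End-to-end unsupervised separation: running-median baseline removal,
#' squared-signal threshold detection with refractory suppression, 31-sample
#' waveform extraction with polarity canonicalization, Morse-scalogram
#' feature vectors, t-SNE embedding at the configured perplexity, two-cluster
#' average-linkage cut, silhouette and CDbw quality indices, and
#' amplitude/polarity-based cluster-to-fish assignment. No training data is
#' required.
#'
#' @param recording an [eod_recording()] (raw; baseline removal is applied
#'   here).
#' @param detection a [detection_config()].
#' @param morse a [morse_params()].
#' @param config a [separation_config()].
#' @param domain feature representation; the pipeline default is the
#'   time-frequency scalogram, which separates individuals best.
#' @return `eod_separation` object: `events` (with fish labels), `embedding`
#'   (n x 2), `labels` (cluster ids), `ss`, `cdbw`, `identity`,
#'   `weak_separation` flag, `counts` and `timing_s` per stage, plus the
#'   configs used.
#' @export
separate <- function(recording, detection = detection_config(),
                     morse = morse_params(), config = separation_config(),
                     domain = "timefreq") {
  stopifnot(inherits(recording, "eod_recording"))
  tic <- function() proc.time()[["elapsed"]]
  timing <- c(); t0 <- tic()
  rec <- remove_baseline(recording, detection$baseline_kernel_ms)
  timing["baseline_s"] <- tic() - t0; t0 <- tic()
  events <- detect_eods(rec, detection)
  if (nrow(events) < 3 * config$perplexity)
    stop("only ", nrow(events), " EODs detected; t-SNE at perplexity ",
         config$perplexity, " needs >= ", ceiling(3 * config$perplexity),
         " - lower the perplexity or record longer")
  wf <- extract_waveforms(rec, events, detection)
  events <- attr(wf, "events")
  timing["detect_s"] <- tic() - t0; t0 <- tic()
  feats <- feature_matrix(wf, domain = domain, params = morse,
                          fs = recording$fs)
  timing["features_s"] <- tic() - t0; t0 <- tic()
  emb <- tsne_embed(feats, config)
  timing["tsne_s"] <- tic() - t0; t0 <- tic()
  labels <- hcluster2(emb, max_n = config$max_cluster_n, seed = config$seed)
  ss <- silhouette_score(emb, labels)
  cd <- tryCatch(cdbw(emb, labels, n_reps = config$n_reps),
                 error = function(e) NA_real_)
  identity <- assign_cluster_identity(events, labels)
  events$label <- unname(identity$map[as.character(labels)])
  timing["cluster_s"] <- tic() - t0
  structure(list(
    events = events, embedding = emb, labels = labels,
    ss = ss, cdbw = cd, identity = identity,
    weak_separation = ss < 0.45 || identity$ambiguous,
    counts = c(n_events = nrow(events),
               n_cluster0 = sum(labels == 0L), n_cluster1 = sum(labels == 1L)),
    timing_s = timing, domain = domain,
    detection = detection, morse = morse, config = config),
    class = "eod_separation")
}

#' @export
print.eod_separation <- function(x, ...) {
  cat(sprintf("<eod_separation> %d EODs -> clusters of %d / %d (%s features)\n",
              x$counts["n_events"], x$counts["n_cluster0"],
              x$counts["n_cluster1"], x$domain))
  cat(sprintf("  silhouette %.3f, CDbw %.4g%s\n", x$ss, x$cdbw,
              if (x$weak_separation) "  [weak separation]" else ""))
  cat("  identity:", paste(names(x$identity$map), "->", x$identity$map,
                           collapse = ", "),
      if (x$identity$ambiguous) "(ambiguous)" else "", "\n")
  invisible(x)
}

#' @export
summary.eod_separation <- function(object, ...) {
  print(object)
  cat("  per-fish EOD counts:\n")
  print(table(object$events$label))
  cat(sprintf("  total runtime %.2f s (%.2f ms/EOD)\n",
              sum(object$timing_s),
              1000 * sum(object$timing_s) / object$counts["n_events"]))
  invisible(object)
}

#' @export
plot.eod_separation <- function(x, ...) {
  cols <- c(A = "#1b6ca8", B = "#d1495b")
  graphics::plot(x$embedding, col = cols[x$events$label], pch = 20,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "EOD separation", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 20,
                   bty = "n")
  invisible(x)
}

#' Select the t-SNE perplexity on labeled dyad feature sets
#'
#' Runs embed -> cluster -> evaluate for every grid value over a collection
#' of labeled feature sets and returns the value with the best median MCC
#' (ties: median accuracy, then total runtime), together with the full score
#' table. The evaluated grid must lie within \[30, 120\].
#'
#' @param feature_sets list of `list(features = <n x d matrix>,
#'   truth = <labels>)`.
#' @param grid candidate perplexities, all in \[30, 120\].
#' @param config base [separation_config()]; the perplexity field is swept.
#' @return list: `perplexity` (selected), `scores` (data.frame with
#'   `perplexity`, `median_acc`, `median_mcc`, `time_s`).
#' @export
select_perplexity <- function(feature_sets, grid = c(30, 50, 70, 100, 120),
                              config = separation_config()) {
  if (!length(grid)) stop("empty perplexity grid")
  if (any(grid < 30 | grid > 120))
    stop("perplexity grid values must lie within [30, 120]")
  if (!length(feature_sets)) stop("no labeled feature sets supplied")
  rows <- list()
  for (g in grid) {
    cfg <- config; cfg$perplexity <- g
    t0 <- proc.time()[["elapsed"]]
    accs <- mccs <- numeric(length(feature_sets))
    for (i in seq_along(feature_sets)) {
      fsi <- feature_sets[[i]]
      emb <- tsne_embed(fsi$features, cfg)
      labels <- hcluster2(emb, max_n = cfg$max_cluster_n, seed = cfg$seed)
      al <- align_labels(labels, fsi$truth)
      accs[i] <- al$acc
      mccs[i] <- mcc(confusion_matrix(al$pred, fsi$truth))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      perplexity = g, median_acc = median(accs), median_mcc = median(mccs),
      time_s = proc.time()[["elapsed"]] - t0)
  }
  scores <- do.call(rbind, rows)
  best <- order(-scores$median_mcc, -scores$median_acc, scores$time_s)[1]
  list(perplexity = scores$perplexity[best], scores = scores)
}

#' Benchmark the separation pipeline on synthetic dyads
#'
#' Generates `n_dyads` ground-truth-labelled synthetic dyad recordings (one
#' per seed, divergence cycling through `divergence`), runs the full
#' unsupervised pipeline on each and evaluates against the simulator truth.
#' This is the desk-scale, ground-truth-available analogue of a real-tank
#' dyad comparison suite.
#'
#' @param seeds one simulation seed per dyad.
#' @param divergence waveform divergence(s), recycled across dyads.
#' @param duration_s recording length per dyad (s).
#' @param ipi_mean_s mean inter-pulse interval per fish (s).
#' @param noise_rms_mV recording noise RMS (mV).
#' @param config [separation_config()] used for every dyad.
#' @param detection [detection_config()].
#' @param verbose print one line per dyad.
#' @return data.frame, one row per dyad: seed, divergence, n_events, acc,
#'   mcc, ss, cdbw, rt_ms_per_eod.
#' @export
benchmark_dyads <- function(seeds = 1:10, divergence = c(0.7, 0.9),
                            duration_s = 120, ipi_mean_s = 0.125,
                            noise_rms_mV = 0.2,
                            config = separation_config(),
                            detection = detection_config(),
                            verbose = FALSE) {
  divergence <- rep_len(divergence, length(seeds))
  rows <- list()
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    fishA <- make_fish(seed = s * 2L + 1L, divergence = divergence[i],
                       ipi_mean_s = ipi_mean_s)
    fishB <- make_fish(seed = s * 2L + 2L, divergence = divergence[i],
                       ipi_mean_s = ipi_mean_s)
    sim <- simulate_dyad(fishA, fishB,
                         dyad_sim_config(duration_s = duration_s,
                                         noise_rms_mV = noise_rms_mV,
                                         seed = s))
    cfg <- config; cfg$seed <- s
    t0 <- proc.time()[["elapsed"]]
    res <- separate(sim$recording, detection = detection, config = cfg)
    elapsed <- proc.time()[["elapsed"]] - t0
    ev <- suppressMessages(evaluate_run(res$events, sim$truth, elapsed,
                                        tol_s = 1 / sim$recording$fs))
    rows[[i]] <- data.frame(seed = s, divergence = divergence[i],
                            n_events = nrow(res$events), acc = ev$acc,
                            mcc = ev$mcc, ss = res$ss, cdbw = res$cdbw,
                            rt_ms_per_eod = ev$rt_ms_per_eod)
    if (verbose)
      message(sprintf("dyad seed %d: n=%d acc=%.4f mcc=%.4f", s,
                      nrow(res$events), ev$acc, ev$mcc))
  }
  do.call(rbind, rows)
}
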