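# Supervised baselines: scalogram template correlation and an RBF-kernel SVM,
# both trained on solo recordings of the two individuals.

#' Build per-fish scalogram templates from solo recordings
#'
#' The template of each fish is the element-wise mean of its per-EOD
#' normalized Morse scalograms.
#'
#' @param solo_waveforms_per_fish named list (one entry per fish) of n x L
#'   waveform matrices from [extract_waveforms()].
#' @param morse a [morse_params()].
#' @param fs sampling rate (Hz).
#' @return `eod_templates`: list with `templates` (named list of S x L mean
#'   scalograms), `freqs_hz`, `morse`, `fs`.
#' @export
build_templates <- function(solo_waveforms_per_fish, morse = morse_params(),
                            fs = 50000) {
  if (!length(solo_waveforms_per_fish)) stop("no fish supplied")
  if (is.null(names(solo_waveforms_per_fish)))
    names(solo_waveforms_per_fish) <- c("A", "B")[seq_along(solo_waveforms_per_fish)]
  templates <- lapply(solo_waveforms_per_fish, function(wf) {
    wf <- as.matrix(wf)
    if (!nrow(wf)) stop("a fish has no waveforms")
    bank <- morse_filter_bank(morse, fs, ncol(wf) + 2 * morse$pad)
    acc <- 0
    for (i in seq_len(nrow(wf))) {
      sc <- morse_cwt_mag(wf[i, ], bank, morse$pad)
      acc <- acc + sc / max(sc)
    }
    acc / nrow(wf)
  })
  structure(list(templates = templates,
                 freqs_hz = morse_freq_grid(morse), morse = morse, fs = fs),
            class = "eod_templates")
}

#' Classify EODs by Pearson correlation with per-fish templates
#'
#' Each EOD's normalized scalogram is correlated (Pearson, on the flattened
#' coefficients) with every template; the EOD is assigned to the fish with
#' the higher coefficient. Exact ties, and zero-variance scalograms for which
#' the coefficient is undefined, go to the first fish; the tie count is
#' attached as an attribute and logged.
#'
#' @param waveforms n x L waveform matrix from [extract_waveforms()].
#' @param templates an [build_templates()] result.
#' @return character vector of fish labels with attribute `n_ties`.
#' @export
correlate_classify <- function(waveforms, templates) {
  stopifnot(inherits(templates, "eod_templates"))
  waveforms <- as.matrix(waveforms)
  fish <- names(templates$templates)
  tvecs <- lapply(templates$templates, as.numeric)
  L <- ncol(waveforms)
  if (any(vapply(templates$templates, ncol, 1L) != L))
    stop("waveform length does not match the template grid")
  bank <- morse_filter_bank(templates$morse, templates$fs,
                            L + 2 * templates$morse$pad)
  labels <- character(nrow(waveforms))
  n_ties <- 0L
  for (i in seq_len(nrow(waveforms))) {
    sc <- morse_cwt_mag(waveforms[i, ], bank, templates$morse$pad)
    v <- as.numeric(sc / max(sc))
    if (sd(v) == 0) {
      warning("zero-variance scalogram; assigned by tie rule")
      n_ties <- n_ties + 1L
      labels[i] <- fish[1]
      next
    }
    r <- vapply(tvecs, function(tv) cor(v, tv), 1)
    if (length(unique(r)) < length(r)) n_ties <- n_ties + 1L
    labels[i] <- fish[which.max(r)]
  }
  if (n_ties) message(n_ties, " tie(s) resolved toward ", fish[1])
  attr(labels, "n_ties") <- n_ties
  labels
}

#' SVM baseline configuration
#'
#' @param n_train_per_fish training EODs per fish, the ones with the highest
#'   SNR (ranked by pre-normalization absolute peak amplitude). The study
#'   default is 5000; smaller solo recordings use all EODs with a warning.
#' @param cv_folds cross-validation folds for the hyperparameter search.
#' @param search_budget maximum (C, gamma) pairs evaluated by the sequential
#'   search (coarse log grid, then a local zoom around the best point).
#' @param c_range,gamma_range log10 search bounds for cost and RBF gamma.
#' @param seed fold-assignment seed; training is deterministic given the
#'   seed.
#' @return `svm_config` list.
#' @export
svm_config <- function(n_train_per_fish = 5000, cv_folds = 10,
                       search_budget = 25, c_range = c(-2, 3),
                       gamma_range = c(-6, 1), seed = 1L) {
  if (n_train_per_fish < cv_folds)
    stop("n_train_per_fish must be >= cv_folds")
  structure(list(n_train_per_fish = n_train_per_fish, cv_folds = cv_folds,
                 search_budget = search_budget, c_range = c_range,
                 gamma_range = gamma_range, seed = as.integer(seed)),
            class = "svm_config")
}

svm_cv_accuracy <- function(X, y, folds, cost, gamma) {
  acc <- 0
  for (f in sort(unique(folds))) {
    te <- folds == f
    fit <- e1071::svm(X[!te, , drop = FALSE], y[!te], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    acc <- acc + sum(predict(fit, X[te, , drop = FALSE]) == y[te])
  }
  acc / length(y)
}

#' Train the RBF-SVM baseline on per-fish solo features
#'
#' The top-SNR `n_train_per_fish` feature vectors per fish are standardized
#' by the training-column mean and standard deviation (classes are balanced
#' by construction, so the weighted mean reduces to the plain one); (C,
#' gamma) are selected by a sequential search — a coarse log-spaced grid
#' followed by a local zoom — maximizing seeded k-fold cross-validated
#' accuracy within `search_budget` evaluations.
#'
#' @param features_per_fish named list, one per fish, of
#'   `list(features = <n x d matrix>, peak_amp_V = <n amplitudes>)` (the
#'   amplitudes rank SNR; omit to take rows in order).
#' @param config an [svm_config()].
#' @return `eod_svm` model: the fitted e1071 SVM plus standardization
#'   constants, the selected `(C, gamma)`, the CV accuracy and the fish
#'   levels.
#' @export
svm_train <- function(features_per_fish, config = svm_config()) {
  if (length(features_per_fish) < 2) stop("need two fish to train a classifier")
  if (is.null(names(features_per_fish)))
    names(features_per_fish) <- c("A", "B")[seq_along(features_per_fish)]
  picked <- lapply(names(features_per_fish), function(f) {
    e <- features_per_fish[[f]]
    X <- as.matrix(e$features)
    amp <- if (!is.null(e$peak_amp_V)) abs(e$peak_amp_V) else rev(seq_len(nrow(X)))
    if (nrow(X) < config$n_train_per_fish)
      warning("fish ", f, " has only ", nrow(X), " EODs (< n_train_per_fish); ",
              "using all of them")
    take <- head(order(amp, decreasing = TRUE),
                 min(config$n_train_per_fish, nrow(X)))
    list(X = X[take, , drop = FALSE], y = rep(f, length(take)))
  })
  X <- do.call(rbind, lapply(picked, `[[`, "X"))
  y <- factor(unlist(lapply(picked, `[[`, "y")))
  if (nlevels(y) < 2) stop("training data contains a single class")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  folds <- with_seed(config$seed,
                     sample(rep(seq_len(config$cv_folds), length.out = nrow(Xs))))
  n_coarse <- max(4, floor(sqrt(config$search_budget * 0.6))^2)
  side <- floor(sqrt(n_coarse))
  grid <- expand.grid(
    logC = seq(config$c_range[1], config$c_range[2], length.out = side),
    logG = seq(config$gamma_range[1], config$gamma_range[2], length.out = side))
  evals <- 0L
  score <- function(lc, lg) {
    evals <<- evals + 1L
    svm_cv_accuracy(Xs, y, folds, 10^lc, 10^lg)
  }
  grid$acc <- mapply(score, grid$logC, grid$logG)
  best <- grid[which.max(grid$acc), ]
  stepC <- diff(config$c_range) / side / 2
  stepG <- diff(config$gamma_range) / side / 2
  for (dc in c(-stepC, 0, stepC)) {
    for (dg in c(-stepG, 0, stepG)) {
      if (dc == 0 && dg == 0) next
      if (evals >= config$search_budget) break
      cand <- c(best$logC + dc, best$logG + dg)
      a <- score(cand[1], cand[2])
      if (a > best$acc) best <- data.frame(logC = cand[1], logG = cand[2],
                                           acc = a)
    }
  }
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = 10^best$logC,
                    gamma = 10^best$logG, scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sdev, C = 10^best$logC,
                 gamma = 10^best$logG, cv_acc = best$acc,
                 levels = levels(y), d = ncol(X)),
            class = "eod_svm")
}

#' Classify feature vectors with a trained SVM baseline
#'
#' @param model an [svm_train()] model.
#' @param features n x d matrix on the same feature grid as the training
#'   data.
#' @return character vector of fish labels.
#' @export
svm_classify <- function(model, features) {
  stopifnot(inherits(model, "eod_svm"))
  features <- as.matrix(features)
  if (ncol(features) != model$d)
    stop("feature dimension ", ncol(features), " does not match the model (",
         model$d, ")")
  Xs <- sweep(sweep(features, 2, model$mu), 2, model$sd, "/")
  as.character(predict(model$fit, Xs))
}

#' @export
print.eod_svm <- function(x, ...) {
  cat(sprintf("<eod_svm> RBF, C = %.3g, gamma = %.3g, CV accuracy %.3f (%s)\n",
              x$C, x$gamma, x$cv_acc, paste(x$levels, collapse = " vs ")))
  invisible(x)
}
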