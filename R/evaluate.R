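# Performance evaluation: label alignment (clusters are nominal), accuracy,
# Matthews correlation coefficient, prediction/truth event matching, and the
# body-parameter correlation analysis.

#' Align nominal two-class predictions with truth
#'
#' Cluster labels carry no identity, so of the two possible label
#' permutations the one maximizing accuracy is chosen and recorded.
#'
#' @param pred,truth equal-length vectors with at most two distinct values
#'   each.
#' @return list: `pred` (aligned to truth's coding), `permutation` (named map
#'   applied), `acc`.
#' @export
align_labels <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ")
  pv <- unique(pred); tv <- unique(truth)
  if (length(pv) > 2 || length(tv) > 2)
    stop("align_labels is defined for two-class labelings")
  if (length(tv) == 1) tv <- c(tv, tv)
  if (length(pv) == 1) pv <- c(pv, pv)
  maps <- list(stats::setNames(tv[1:2], pv[1:2]),
               stats::setNames(tv[2:1], pv[1:2]))
  accs <- vapply(maps, function(m) mean(unname(m[as.character(pred)]) == truth), 1)
  best <- which.max(accs)
  list(pred = unname(maps[[best]][as.character(pred)]),
       permutation = maps[[best]], acc = accs[best])
}

#' Confusion matrix of a two-class labeling
#'
#' @param pred,truth equal-length label vectors sharing a coding.
#' @return 2 x 2 integer matrix (rows = truth, cols = pred).
#' @export
confusion_matrix <- function(pred, truth) {
  lev <- sort(unique(c(as.character(pred), as.character(truth))))
  if (length(lev) == 1) lev <- c(lev, paste0(lev, "_"))
  table(factor(as.character(truth), levels = lev),
        factor(as.character(pred), levels = lev))[1:2, 1:2]
}

#' Matthews correlation coefficient from a 2 x 2 confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0 when
#' any marginal is zero. Robust to the class imbalance typical of dyads in
#' which one fish discharges far more than the other.
#'
#' @param confusion 2 x 2 nonnegative count matrix (rows = truth,
#'   cols = pred).
#' @return value in \[-1, 1\].
#' @export
mcc <- function(confusion) {
  m <- matrix(as.numeric(confusion), 2)  # doubles: the products overflow ints
  stopifnot(all(dim(as.matrix(confusion)) == 2))
  if (any(m < 0)) stop("confusion counts must be nonnegative")
  tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# 1:1 nearest-time matching of predicted to truth events within +/- tol_s.
match_events <- function(pred_t, truth_t, tol_s) {
  used <- logical(length(truth_t))
  map <- integer(length(pred_t))
  tol_s <- tol_s * (1 + 1e-9) + 1e-12   # times are sample-grid multiples
  for (i in order(pred_t)) {
    j <- which(!used & abs(truth_t - pred_t[i]) <= tol_s)
    if (length(j)) {
      j <- j[which.min(abs(truth_t[j] - pred_t[i]))]
      used[j] <- TRUE
      map[i] <- j
    }
  }
  map
}

#' Evaluate a labeled event table against simulator (or manual) truth
#'
#' Events are matched 1:1 by nearest time within `tol_s` (one sample at
#' 50 kHz by default); metrics are computed on the matched subset after label
#' alignment, and unmatched counts are reported. Runtime is normalized per
#' classified EOD; for SVM runs the caller includes training time in
#' `elapsed_s`.
#'
#' @param pred_events event table with a `label` column.
#' @param truth_events event table with a `truth` column.
#' @param elapsed_s wall time of the classification (s).
#' @param tol_s matching tolerance (s).
#' @return `eod_eval` list: `acc`, `mcc`, `rt_ms_per_eod`, `confusion`,
#'   `alignment`, `n_matched`, `n_pred_unmatched`, `n_truth_unmatched`.
#' @export
evaluate_run <- function(pred_events, truth_events, elapsed_s = NA_real_,
                         tol_s = 1 / 50000) {
  map <- match_events(pred_events$t_s, truth_events$t_s, tol_s)
  matched <- map > 0
  n_unmatched <- sum(!matched)
  if (n_unmatched)
    message(n_unmatched, " predicted event(s) had no truth match within tol")
  pred <- pred_events$label[matched]
  truth <- truth_events$truth[map[matched]]
  al <- align_labels(pred, truth)
  cm <- confusion_matrix(al$pred, truth)
  structure(list(
    acc = al$acc, mcc = mcc(cm),
    rt_ms_per_eod = if (is.na(elapsed_s)) NA_real_ else
      1000 * elapsed_s / nrow(pred_events),
    confusion = cm, alignment = al$permutation,
    n_matched = sum(matched), n_pred_unmatched = n_unmatched,
    n_truth_unmatched = nrow(truth_events) - sum(matched)),
    class = "eod_eval")
}

#' @export
print.eod_eval <- function(x, ...) {
  cat(sprintf("<eod_eval> ACC %.4f, MCC %.4f, %d matched EODs", x$acc, x$mcc,
              x$n_matched))
  if (!is.na(x$rt_ms_per_eod)) cat(sprintf(", RT %.2f ms/EOD", x$rt_ms_per_eod))
  cat("\n")
  invisible(x)
}

#' All dyadic combinations of a set of individuals
#'
#' @param ids vector of individual identifiers (or a single count).
#' @return two-column data.frame of unordered pairs; `choose(n, 2)` rows
#'   (24 individuals give 276 dyads, 5 give 10).
#' @export
dyad_pairs <- function(ids) {
  if (length(ids) == 1 && is.numeric(ids)) ids <- seq_len(ids)
  if (length(ids) < 2) stop("need at least two individuals")
  idx <- utils::combn(length(ids), 2)
  data.frame(a = ids[idx[1, ]], b = ids[idx[2, ]])
}

#' Correlate separation performance with body-parameter differences
#'
#' Pearson correlation (with the two-sided t-test p-value) between per-dyad
#' performance metrics and the dyad's absolute body-parameter differences,
#' asking whether classifier performance depends on how physically dissimilar
#' the two fish are.
#'
#' @param per_dyad_metrics data.frame of per-dyad metric columns (e.g. `acc`,
#'   `mcc`).
#' @param body_deltas data.frame of per-dyad absolute differences (e.g.
#'   `d_weight_g`, `d_total_length_cm`, `d_standard_length_cm`), same row
#'   order.
#' @return data.frame: `metric`, `delta`, `r`, `p` (NA when a column has zero
#'   variance).
#' @export
body_param_correlation <- function(per_dyad_metrics, body_deltas) {
  if (nrow(per_dyad_metrics) != nrow(body_deltas))
    stop("metric and delta tables must have the same rows")
  if (nrow(per_dyad_metrics) < 3)
    stop("need at least 3 dyads for a correlation")
  out <- list()
  for (m in names(per_dyad_metrics)) {
    for (d in names(body_deltas)) {
      x <- per_dyad_metrics[[m]]; y <- body_deltas[[d]]
      if (sd(x) == 0 || sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(metric = m, delta = d, r = r,
                                            p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
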