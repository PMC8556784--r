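#' Confusion counts at a threshold
#'
#' A cell is predicted positive when its score is `>= threshold`; the truth
#' class is 1 only for association value 1 (marked -1 cells count as class
#' 0, the task is binary).
#'
#' @param scores numeric prediction matrix or vector
#' @param truth association matrix or vector over \{-1, 0, 1\}, same shape
#' @param threshold decision cutoff
#' @param cells optional linear indices restricting the evaluation to a cell
#'   subset
#' @return named integer vector `c(TP, FP, FN, TN)`
#' @export
confusion_counts <- function(scores, truth, threshold, cells = NULL) {
  if (!is.null(cells)) {
    if (length(cells) == 0L) stop("empty evaluation cell set", call. = FALSE)
    scores <- scores[cells]
    truth <- truth[cells]
  }
  if (length(scores) == 0L) stop("empty evaluation cell set", call. = FALSE)
  pred <- scores >= threshold
  pos <- truth == 1
  c(TP = sum(pred & pos), FP = sum(pred & !pos),
    FN = sum(!pred & pos), TN = sum(!pred & !pos))
}

#' Precision, recall and F-score from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, with the zero
#' conventions `P = 0` when no cell is predicted positive, `R = 0` when there
#' are no positives, and `F = 0` when `P + R = 0`.
#'
#' @param counts named vector or list with `TP`, `FP`, `FN` (as from
#'   [confusion_counts()])
#' @return named numeric vector `c(precision, recall, f_score)`
#' @export
prf <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_score = f)
}

#' Rank-based ROC AUC
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted one half — identical to the trapezoidal
#' area under the ROC curve.
#'
#' @inheritParams confusion_counts
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(scores, truth, cells = NULL) {
  if (!is.null(cells)) {
    scores <- scores[cells]
    truth <- truth[cells]
  }
  pos <- truth == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  r <- rank(scores)             # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Best-F threshold selection
#'
#' Scans candidate thresholds — midpoints between consecutive distinct scores
#' plus sentinels above the maximum and below the minimum — and returns the
#' one maximizing the F-score.  Ties are resolved toward the lowest
#' (most inclusive) threshold.
#'
#' @inheritParams confusion_counts
#' @return a list with `threshold` and a report (`TP`, `FP`, `FN`, `TN`,
#'   `precision`, `recall`, `f_score`) at that threshold
#' @export
best_f_threshold <- function(scores, truth, cells = NULL) {
  if (!is.null(cells)) {
    scores <- scores[cells]
    truth <- truth[cells]
  }
  stopifnot(length(scores) == length(truth), length(scores) > 0L)
  pos <- truth == 1
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  p_sorted <- pos[ord]
  # last index of each distinct score value, scanning from the top
  boundary <- which(diff(s_sorted) != 0)
  cuts <- c(boundary, length(s_sorted))
  tp <- cumsum(p_sorted)[cuts]
  predp <- cuts
  n_pos <- sum(pos)
  prec <- ifelse(predp > 0, tp / predp, 0)
  rec <- if (n_pos > 0) tp / n_pos else rep(0, length(tp))
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # predict-nothing sentinel
  f <- c(0, f)
  distinct <- s_sorted[cuts]
  thr <- c(distinct[1] + 1,
           (distinct + c(distinct[-1], distinct[length(distinct)] - 1)) / 2)
  best <- which(f == max(f))
  pick <- best[length(best)]   # lowest threshold among ties
  counts <- confusion_counts(scores, truth, thr[pick])
  list(threshold = thr[pick], report = c(as.list(counts), as.list(prf(counts))))
}

#' Fold assignment over positive cells
#'
#' Partitions the cells with association value 1 into `n_folds` groups whose
#' sizes differ by at most one; deterministic given `seed`.
#'
#' @param assoc drug x disease matrix
#' @param n_folds number of folds (default 10)
#' @param seed integer seed
#' @return integer vector of fold ids, named by the linear indices of the
#'   positive cells
#' @export
cv_folds <- function(assoc, n_folds = 10L, seed = 1L) {
  positives <- which(assoc == 1)
  if (length(positives) < n_folds)
    stop("need at least n_folds positive cells", call. = FALSE)
  with_rng(seed, {
    shuffled <- sample(positives)
    folds <- rep_len(seq_len(n_folds), length(shuffled))
    stats::setNames(folds[order(shuffled)], sort(shuffled))
  })
}

#' Cross-validated evaluation of the full pipeline
#'
#' Tenfold cross-validation over the positive association cells.  For each
#' fold the held-out positives are reset to 0 in the training matrix, the
#' entire downstream pipeline is rerun on the masked matrix (side-effect
#' marking, disease similarity, per-source predictions, weight optimization,
#' fusion), and the held-out positives plus all never-positive cells form the
#' evaluation set.  The autoencoder code is computed once outside the loop:
#' drug features carry no association labels, so no information about the
#' held-out cells can leak through it.
#'
#' Metrics are pooled across folds (scores and truths concatenated); the
#' decision threshold is the single global best-F cutoff on the pooled
#' scores, and the per-fold confusion counts are computed at that same
#' cutoff so that their sums equal the pooled counts.
#'
#' @param assoc drug x disease matrix over \{0, 1\} (unmarked)
#' @param side_effects binary drug x side-effect matrix, drug-aligned
#' @param encoded autoencoder code matrix for the drugs (see [encode()])
#' @param top_k neighbor count for both prediction directions
#' @param n_folds number of folds (default 10)
#' @param seed fold-assignment seed
#' @param epsilon weight floor passed to [optimize_weights()]
#' @param keep_training if `TRUE`, each fold's masked training matrix is
#'   returned (for leakage audits)
#' @return a list with pooled reports for both fusion modes (`adaptive`,
#'   `uniform`), each containing `auc`, `threshold`, the confusion counts and
#'   P/R/F at the best-F threshold, and a per-fold breakdown; plus
#'   `fold_assignment` and per-fold optimized `weights`
#' @export
cross_validate <- function(assoc, side_effects, encoded, top_k = 50L,
                           n_folds = 10L, seed = 1L, epsilon = 1e-4,
                           keep_training = FALSE) {
  validate_labeled_matrix(assoc, binary = TRUE, what = "assoc")
  folds <- cv_folds(assoc, n_folds, seed)
  positives <- as.integer(names(folds))
  never_pos <- which(assoc != 1)

  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held_out <- positives[folds == f]
    if (length(held_out) == 0L)
      stop("fold ", f, " has no positive cells", call. = FALSE)
    train <- assoc
    train[held_out] <- 0
    marked <- mark_side_effects(train, side_effects)
    preds <- predict_sources(marked, encoded, side_effects, top_k)
    w <- suppressWarnings(optimize_weights(marked, preds, epsilon))
    eval_cells <- c(held_out, never_pos)
    truth <- c(rep(1, length(held_out)), rep(0, length(never_pos)))
    per_fold[[f]] <- list(
      held_out = held_out, eval_cells = eval_cells, truth = truth,
      weights = w$weights,
      scores = list(adaptive = fuse_predictions(preds, w)[eval_cells],
                    uniform = simple_average_fuse(preds)[eval_cells]),
      train_assoc = if (keep_training) train)
  }

  pooled_report <- function(mode) {
    scores <- unlist(lapply(per_fold, function(x) x$scores[[mode]]))
    truth <- unlist(lapply(per_fold, function(x) x$truth))
    bf <- best_f_threshold(scores, truth)
    fold_counts <- lapply(per_fold, function(x)
      confusion_counts(x$scores[[mode]], x$truth, bf$threshold))
    c(bf$report,
      list(auc = roc_auc(scores, truth), threshold = bf$threshold,
           fold_counts = fold_counts))
  }

  list(adaptive = pooled_report("adaptive"),
       uniform = pooled_report("uniform"),
       fold_assignment = folds,
       weights = lapply(per_fold, `[[`, "weights"),
       folds = per_fold)
}

#' Per-disease top-n recovery counts
#'
#' For each disease, drugs are ranked by fused score; for each requested
#' `top_n` the known treatments (truth value 1) appearing among the first
#' `top_n` ranks are counted across diseases, together with the fraction of
#' all known treatments recovered.
#'
#' @param scores drug x disease prediction matrix
#' @param truth drug x disease matrix over \{-1, 0, 1\}
#' @param top_n integer vector of list lengths to sweep
#' @return data frame with columns `top_n`, `count`, `fraction`
#' @export
threshold_sweep_counts <- function(scores, truth, top_n = c(1, 5, 10, 20, 30)) {
  stopifnot(identical(dim(scores), dim(truth)))
  total_pos <- sum(truth == 1)
  ranks <- apply(-scores, 2, rank, ties.method = "first")
  counts <- vapply(top_n, function(n) sum(ranks <= n & truth == 1),
                   numeric(1))
  data.frame(top_n = top_n, count = counts,
             fraction = if (total_pos > 0) counts / total_pos else 0)
}
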