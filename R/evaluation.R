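# Protein-grouped fold construction and performance measurement. Grouping by
# protein prevents homology leakage: all variants of one protein land in one
# fold, so train and test folds never share a protein.

#' Protein-grouped fold assignment
#'
#' Assigns whole proteins to folds so that no protein spans folds. Proteins
#' are taken in descending order of variant count (ties shuffled under
#' `seed`) and each is placed into the fold currently holding the fewest
#' variants — a greedy balance of fold sizes by variant count.
#'
#' @param labelled labelled variant table with a `protein_id` column.
#' @param k number of folds.
#' @param seed integer seed for the tie shuffle.
#' @return Named integer vector protein_id -> fold in `1..k`.
#' @export
grouped_folds <- function(labelled, k = 5L, seed = 17L) {
  counts <- table(labelled$protein_id)
  if (length(counts) < k) {
    stop(sprintf("need at least %d distinct proteins, have %d", k,
                 length(counts)), call. = FALSE)
  }
  rng <- local({
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sample.int(length(counts))
  })
  ord <- order(-as.integer(counts), rng)
  assignment <- integer(length(counts))
  names(assignment) <- names(counts)
  load <- numeric(k)
  for (i in ord) {
    f <- which.min(load)
    assignment[i] <- f
    load[f] <- load[f] + as.integer(counts[i])
  }
  assignment
}

#' Confusion-matrix metrics
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
#' `TP/(TP+FP)`. A metric with a zero denominator is returned as `NA` with
#' its flag set.
#'
#' @param labels binary truth (0/1).
#' @param calls binary predictions (0/1).
#' @return List with `sensitivity`, `specificity`, `precision`,
#'   `undefined` (character vector naming any undefined metrics), and the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(labels, calls) {
  stopifnot(length(labels) == length(calls),
            all(labels %in% c(0, 1)), all(calls %in% c(0, 1)))
  tp <- sum(labels == 1 & calls == 1)
  fp <- sum(labels == 0 & calls == 1)
  tn <- sum(labels == 0 & calls == 0)
  fn <- sum(labels == 1 & calls == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              precision = safe(tp, tp + fp),
              tp = tp, fp = fp, tn = tn, fn = fn)
  out$undefined <- names(which(vapply(out[1:3], is.na, TRUE)))
  out
}

#' ROC and precision-recall analysis
#'
#' Sweeps the decision threshold over the unique score values (ties grouped
#' at one threshold), producing the ROC curve from (0,0) to (1,1), its
#' trapezoidal AUC, and the precision-recall curve from the same sweep.
#'
#' @param labels binary truth (0/1), both classes present.
#' @param scores finite numeric scores, higher = more likely positive.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `pr` (data.frame `threshold`, `recall`, `precision`).
#' @export
roc_and_pr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  if (length(unique(labels)) < 2L) {
    stop("ROC analysis needs both labels present", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(labels == 1 & scores == t), 0))
  fp <- cumsum(vapply(thr, function(t) sum(labels == 0 & scores == t), 0))
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  thresholds <- c(Inf, thr, -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  precision <- tp / pmax(tp + fp, 1)
  list(roc = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
       auc = auc,
       pr = data.frame(threshold = thr, recall = tp / n_pos,
                       precision = precision))
}

#' Out-of-fold cross-validated predictions
#'
#' For each fold rotation (train on three folds, validate on one, test on
#' the remaining one) the rotation's calibrated member scores its test fold.
#' Pooling over rotations gives one leak-free probability per variant: the
#' member scoring a variant never saw its protein during training or
#' calibration.
#'
#' @param labelled labelled variant table.
#' @param X feature matrix aligned with `labelled`.
#' @param k number of folds.
#' @param seed fold-construction seed.
#' @param C_grid,j_grid hyperparameter grids, see [grid_optimise()].
#' @return List with `probability` (per-variant out-of-fold probability),
#'   `fold` (test-fold index per variant), `model` (the trained
#'   `varmod_ensemble`), `auc` (out-of-fold ROC AUC).
#' @export
cross_validated_predictions <- function(labelled, X, k = 5L, seed = 17L,
                                        C_grid = c(0.01, 0.1, 1, 10, 100),
                                        j_grid = c(0.5, 1, 2, 4)) {
  model <- train_ensemble(labelled, X, k = k, seed = seed,
                          C_grid = C_grid, j_grid = j_grid)
  folds <- unname(model$fold_table[labelled$protein_id])
  prob <- rep(NA_real_, nrow(labelled))
  for (r in seq_len(k)) {
    te <- folds == model$selection$test_fold[r]
    prob[te] <- member_probability(model$members[[r]],
                                   X[te, , drop = FALSE])
  }
  auc <- roc_and_pr(labelled$label, prob)$auc
  list(probability = prob, fold = folds, model = model, auc = auc)
}

#' Cross-validated evaluation of the full method
#'
#' Trains the ensemble on protein-grouped training folds and evaluates on
#' the held-out proteins, guaranteeing no protein overlap between train and
#' test.
#'
#' @param labelled labelled variant table.
#' @param X feature matrix aligned with `labelled`.
#' @param test_fraction fraction of proteins held out for testing.
#' @param seed seed for the protein split and the inner fold construction.
#' @param ... passed to [train_ensemble()].
#' @return List with `model`, `metrics` (sensitivity/specificity/precision at
#'   0.5), `roc_pr` (from [roc_and_pr()]), `test_proteins`, `predictions`.
#' @export
holdout_evaluation <- function(labelled, X, test_fraction = 0.2, seed = 17L,
                               ...) {
  proteins <- unique(labelled$protein_id)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  n_test <- max(1L, round(test_fraction * length(proteins)))
  test_proteins <- sample(proteins, n_test)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  te <- labelled$protein_id %in% test_proteins
  stopifnot(length(intersect(labelled$protein_id[!te],
                             labelled$protein_id[te])) == 0L)
  model <- train_ensemble(labelled[!te, , drop = FALSE],
                          X[!te, , drop = FALSE], seed = seed, ...)
  preds <- predict_ensemble(model, X[te, , drop = FALSE])
  y <- labelled$label[te]
  metrics <- confusion_metrics(y, as.integer(preds$call == "functional"))
  roc_pr <- if (length(unique(y)) == 2L) roc_and_pr(y, preds$probability)
            else NULL
  list(model = model, metrics = metrics, roc_pr = roc_pr,
       test_proteins = test_proteins,
       predictions = cbind(labelled[te, , drop = FALSE], preds))
}
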