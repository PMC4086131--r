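# Five-fold ensemble: for each fold rotation a linear classifier is fit on
# three folds, Platt-calibrated on the validation fold, and weighted by its
# validation accuracy; the deployed prediction is the accuracy-weighted,
# normalised mean of the five calibrated probabilities.

#' Train one calibrated ensemble member
#'
#' Standardises features with training-set statistics only, fits the linear
#' margin classifier at `(C, j)`, then fits the Platt sigmoid on the
#' validation set's decision values and records the validation accuracy at
#' the 0.5 probability threshold.
#'
#' @param X_train,y_train training fold features/labels (0/1).
#' @param X_val,y_val validation fold features/labels.
#' @param C,j hyperparameters of [fit_linear_svm()].
#' @return A `varmod_member`: list with `w`, `b`, `platt` (`A`, `B`),
#'   `validation_accuracy`, `scaler`, `C`, `j`.
#' @export
train_member <- function(X_train, y_train, X_val, y_val, C = 1, j = 1) {
  stopifnot(nrow(X_train) > 0L, nrow(X_val) > 0L)
  if (length(unique(y_train)) < 2L) {
    stop("training fold has a single label", call. = FALSE)
  }
  scaler <- fit_scaler(X_train)
  svm <- fit_linear_svm(apply_scaler(scaler, X_train), y_train, C = C, j = j)
  f_val <- decision_values(svm, apply_scaler(scaler, X_val))
  platt <- fit_platt(f_val, y_val)
  p_val <- platt_probability(platt, f_val)
  acc <- mean((p_val >= 0.5) == (y_val == 1))
  structure(list(w = svm$w, b = svm$b, platt = platt,
                 validation_accuracy = acc, scaler = scaler, C = C, j = j),
            class = "varmod_member")
}

#' Calibrated probability of one ensemble member
#'
#' @param member a `varmod_member`.
#' @param X feature matrix on the raw (unscaled) feature scale.
#' @return Probabilities in (0, 1).
#' @export
member_probability <- function(member, X) {
  f <- decision_values(list(w = member$w, b = member$b),
                       apply_scaler(member$scaler, X))
  platt_probability(member$platt, f)
}

#' Grid search of (C, j) per fold rotation
#'
#' For each rotation the classifier is trained on three folds and scored on
#' the validation fold for every grid point; the pair maximising validation
#' accuracy wins, ties broken toward smaller `C` then `j` closer to 1.
#'
#' @param X,y features and labels of all training variants.
#' @param folds integer fold index (1..k) per row of `X`.
#' @param C_grid,j_grid hyperparameter grids.
#' @return data.frame with one row per rotation: `test_fold`,
#'   `validation_fold`, `C`, `j`, `validation_accuracy`.
#' @export
grid_optimise <- function(X, y, folds,
                          C_grid = c(0.01, 0.1, 1, 10, 100),
                          j_grid = c(0.5, 1, 2, 4)) {
  k <- max(folds)
  grid <- expand.grid(C = C_grid, j = j_grid)
  # deterministic tie-break ordering: accuracy desc, then smaller C, then
  # |log(j)| asc; the first row in this order wins
  res <- lapply(seq_len(k), function(test_fold) {
    val_fold <- test_fold %% k + 1L
    tr <- !(folds %in% c(test_fold, val_fold))
    va <- folds == val_fold
    accs <- vapply(seq_len(nrow(grid)), function(g) {
      m <- train_member(X[tr, , drop = FALSE], y[tr],
                        X[va, , drop = FALSE], y[va],
                        C = grid$C[g], j = grid$j[g])
      m$validation_accuracy
    }, 0)
    ord <- order(-accs, grid$C, abs(log(grid$j)))
    best <- ord[1]
    data.frame(test_fold = test_fold, validation_fold = val_fold,
               C = grid$C[best], j = grid$j[best],
               validation_accuracy = accs[best])
  })
  do.call(rbind, res)
}

#' Train the five-member ensemble
#'
#' Builds protein-grouped folds, selects `(C, j)` per fold rotation by grid
#' search, refits each member at its selected hyperparameters, and weights
#' members by validation accuracy (normalised to sum to 1).
#'
#' @param labelled labelled variant table (`protein_id`, `wt`, `pos`, `mut`,
#'   `label`).
#' @param X feature matrix aligned with `labelled` rows.
#' @param k number of folds (the method uses 5).
#' @param seed seed controlling fold construction.
#' @param C_grid,j_grid hyperparameter grids; pass length-1 grids to skip
#'   optimisation.
#' @return A `varmod_ensemble`: list with `members` (length `k`), `weights`,
#'   `fold_table` (protein -> fold), `selection` (grid results),
#'   `schema_version`.
#' @export
train_ensemble <- function(labelled, X, k = 5L, seed = 17L,
                           C_grid = c(0.01, 0.1, 1, 10, 100),
                           j_grid = c(0.5, 1, 2, 4)) {
  fold_of_protein <- grouped_folds(labelled, k = k, seed = seed)
  folds <- unname(fold_of_protein[labelled$protein_id])
  sel <- grid_optimise(X, labelled$label, folds,
                       C_grid = C_grid, j_grid = j_grid)
  members <- lapply(seq_len(k), function(r) {
    tr <- !(folds %in% c(sel$test_fold[r], sel$validation_fold[r]))
    va <- folds == sel$validation_fold[r]
    train_member(X[tr, , drop = FALSE], labelled$label[tr],
                 X[va, , drop = FALSE], labelled$label[va],
                 C = sel$C[r], j = sel$j[r])
  })
  accs <- vapply(members, `[[`, 0, "validation_accuracy")
  if (sum(accs) <= 0) accs <- rep(1, k)  # degenerate: fall back to uniform
  structure(list(members = members, weights = accs / sum(accs),
                 fold_table = fold_of_protein, selection = sel,
                 schema_version = feature_schema()$version),
            class = "varmod_ensemble")
}

#' @export
print.varmod_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d members, validation accuracies %s>\n",
              length(x$members),
              paste(sprintf("%.3f", vapply(x$members, `[[`, 0,
                                           "validation_accuracy")),
                    collapse = ", ")))
  invisible(x)
}

#' Combine member probabilities into the final prediction
#'
#' The final probability is the weight-normalised sum of the per-member
#' calibrated probabilities — a convex combination, so it always lies
#' between the smallest and largest member probability.
#'
#' @param member_probs numeric matrix (rows = variants, cols = members).
#' @param weights member weights (proportional to validation accuracy).
#' @return Numeric vector of final probabilities.
#' @export
combine_probabilities <- function(member_probs, weights) {
  stopifnot(ncol(member_probs) == length(weights), all(weights >= 0))
  w <- weights / sum(weights)
  drop(member_probs %*% w)
}

#' Predict variant effect probabilities
#'
#' @param model a `varmod_ensemble`.
#' @param X feature matrix in schema order.
#' @param threshold probability threshold for the functional call.
#' @return data.frame with `probability`, `call`
#'   (`functional`/`non-functional`) and one `member_<i>` column per member.
#' @export
predict_ensemble <- function(model, X, threshold = 0.5) {
  if (!identical(model$schema_version, feature_schema()$version)) {
    stop("model was trained under feature schema version ",
         model$schema_version, "; current is ", feature_schema()$version,
         call. = FALSE)
  }
  P <- vapply(model$members, function(m) member_probability(m, X),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  p <- combine_probabilities(P, model$weights)
  out <- data.frame(probability = p,
                    call = ifelse(p >= threshold, "functional",
                                  "non-functional"),
                    stringsAsFactors = FALSE)
  colnames(P) <- paste0("member_", seq_along(model$members))
  cbind(out, as.data.frame(P))
}

#' Save an ensemble model to JSON
#'
#' The artefact holds all five members (weights, bias, Platt parameters,
#' scalers), the ensemble weights and the feature-schema version.
#'
#' @param model a `varmod_ensemble`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema_version = model$schema_version,
    weights = model$weights,
    fold_table = as.list(model$fold_table),
    selection = model$selection,
    members = lapply(model$members, function(m) {
      list(w = m$w, b = m$b, platt_A = m$platt$A, platt_B = m$platt$B,
           validation_accuracy = m$validation_accuracy,
           scaler_centre = m$scaler$centre, scaler_scale = m$scaler$scale,
           C = m$C, j = m$j)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an ensemble model from JSON
#'
#' @param path path written by [write_model()].
#' @return A `varmod_ensemble`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  members <- lapply(obj$members, function(m) {
    structure(list(
      w = as.numeric(unlist(m$w)), b = m$b,
      platt = list(A = m$platt_A, B = m$platt_B),
      validation_accuracy = m$validation_accuracy,
      scaler = list(centre = as.numeric(unlist(m$scaler_centre)),
                    scale = as.numeric(unlist(m$scaler_scale))),
      C = m$C, j = m$j), class = "varmod_member")
  })
  fold_table <- vapply(obj$fold_table, as.integer, 1L)
  structure(list(members = members,
                 weights = as.numeric(unlist(obj$weights)),
                 fold_table = fold_table,
                 selection = do.call(rbind, lapply(obj$selection,
                                                   as.data.frame)),
                 schema_version = as.character(obj$schema_version)),
            class = "varmod_ensemble")
}
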