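# Random-forest global-quality regressor: grouped cross-validated grid
# search over (ntree, mtry), prediction, and impurity-based feature
# importance.

## assign target ids to `folds` folds, seeded shuffle then round-robin
make_group_folds <- function(groups, folds, seed) {
  targets <- unique(groups)
  if (length(targets) < folds)
    stop("need at least ", folds, " distinct targets, have ", length(targets))
  set.seed(seed)
  targets <- sample(targets)
  fold_of_target <- stats::setNames(rep(seq_len(folds),
                                        length.out = length(targets)), targets)
  unname(fold_of_target[as.character(groups)])
}

#' Cross-validated grid search for the quality regressor
#'
#' Trains a random forest for every `(ntree, mtry)` grid point under
#' k-fold cross-validation with folds split by target (all models of one
#' target stay in the same fold, so correlated decoys never leak between
#' training and validation). The selection criterion is the mean per-fold
#' Pearson correlation between predicted and true scores; ties prefer the
#' smaller `ntree`, then the smaller `mtry`. The returned model is refit on
#' all rows at the selected parameters.
#'
#' The published default grid is `ntree` 500..5000 by 500 and `mtry`
#' 10..34; smaller grids are accepted for desk-scale runs.
#'
#' @param X numeric matrix, columns in [feature_names()] order.
#' @param y true GDT-TS scores in `[0, 100]`.
#' @param groups target id per row.
#' @param ntree_grid,mtry_grid parameter grids.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed; fixes folds and forests.
#' @return A `qa_model`: the fitted forest, selected parameters, the CV
#'   table, out-of-fold predictions at the selected point, and the feature
#'   manifest.
#' @export
qa_grid_search <- function(X, y, groups,
                           ntree_grid = seq(500, 5000, by = 500),
                           mtry_grid = 10:34, folds = 5, seed = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(y) == length(groups),
            !anyNA(X), !anyNA(y), all(y >= 0 & y <= 100), nrow(X) >= 10)
  if (is.null(colnames(X))) colnames(X) <- feature_names()
  fold_id <- make_group_folds(groups, folds, seed)
  grid <- expand.grid(ntree = ntree_grid, mtry = mtry_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$ntree, grid$mtry), , drop = FALSE]

  cv_one <- function(ntree, mtry) {
    rs <- numeric(folds)
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      te <- !tr
      if (length(intersect(groups[tr], groups[te])))
        stop("group leakage: a target id appears in both train and test folds")
      set.seed(seed + 7919 * f)
      fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                        ntree = ntree, mtry = mtry)
      pr <- stats::predict(fit, X[te, , drop = FALSE])
      oof[te] <- pr
      rs[f] <- if (stats::sd(pr) == 0 || stats::sd(y[te]) == 0) 0 else
        stats::cor(pr, y[te])
    }
    list(mean_r = mean(rs), oof = oof)
  }

  best <- NULL
  cv_table <- grid
  cv_table$mean_r <- NA_real_
  for (g in seq_len(nrow(grid))) {
    res <- cv_one(grid$ntree[g], grid$mtry[g])
    cv_table$mean_r[g] <- res$mean_r
    if (is.null(best) || res$mean_r > best$mean_r + 1e-12) {
      best <- list(ntree = grid$ntree[g], mtry = grid$mtry[g],
                   mean_r = res$mean_r, oof = res$oof)
    }
  }
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = best$ntree,
                                    mtry = best$mtry, importance = FALSE)
  structure(list(forest = fit, ntree = best$ntree, mtry = best$mtry,
                 cv_table = cv_table, cv_mean_r = best$mean_r,
                 cv_predictions = pmin(100, pmax(0, best$oof)),
                 feature_names = colnames(X), groups = groups,
                 seed = seed, version = 1L),
            class = "qa_model")
}

#' @export
print.qa_model <- function(x, ...) {
  cat(sprintf("<qa_model> ntree=%d mtry=%d, CV mean per-fold r=%.3f (%d grid points)\n",
              x$ntree, x$mtry, x$cv_mean_r, nrow(x$cv_table)))
  invisible(x)
}

#' Predict global quality scores
#'
#' @param object a `qa_model`.
#' @param X feature matrix with the model's 70 columns in training order.
#' @param ... unused.
#' @return Predicted GDT-TS scores, clipped to `[0, 100]`.
#' @export
predict.qa_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$feature_names))
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         length(object$feature_names))
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names))
    stop("feature columns do not match the model's manifest")
  colnames(X) <- object$feature_names
  pmin(100, pmax(0, unname(stats::predict(object$forest, X))))
}

#' Impurity-based feature importance
#'
#' @param model a `qa_model`.
#' @return Named non-negative importances over the 70 features, summing
#'   to 1 (all-zero if the forest never split).
#' @export
qa_feature_importance <- function(model) {
  imp <- randomForest::importance(model$forest, type = 2)[, 1]
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  stats::setNames(as.numeric(imp), model$feature_names)
}
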