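# CASP-style evaluation of global quality predictions: per-target Pearson
# correlations pooled through Fisher z, best-model loss, absolute score
# deviation, MCC and ROC AUC at the GDT-TS 50 threshold, and the
# potential-comparison statistics.

#' Fisher z-transform and its inverse
#'
#' `z = atanh(r) = 0.5 * ln((1 + r) / (1 - r))`; correlations are clamped to
#' `|r| <= 1 - 1e-6` first so the transform stays finite.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return `fisher_z`: z value(s); `inv_fisher_z`: correlation(s).
#' @export
fisher_z <- function(r) {
  r <- pmin(1 - 1e-6, pmax(-(1 - 1e-6), r))
  0.5 * log((1 + r) / (1 - r))
}

#' @param z Fisher z value(s).
#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) (exp(z) - exp(-z)) / (exp(z) + exp(-z))

## per-target correlation; constant arrays give 0 by policy (warned)
target_r <- function(pred, truth) {
  if (length(pred) < 2 || stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("constant or degenerate score array: per-target r set to 0")
    return(0)
  }
  stats::cor(pred, truth)
}

check_targets <- function(targets) {
  stopifnot(is.list(targets), length(targets) >= 1)
  for (t in targets)
    stopifnot(is.numeric(t$pred), is.numeric(t$truth),
              length(t$pred) == length(t$truth), length(t$pred) >= 1)
  invisible(targets)
}

#' Weighted mean per-target Pearson correlation
#'
#' Per-target Pearson correlations between predicted and true scores are
#' Fisher z-transformed, averaged arithmetically, and transformed back.
#'
#' @param targets list of targets, each a list with numeric `pred` and
#'   `truth` of equal length (scores on `[0, 100]`).
#' @return The pooled correlation, in `[-1, 1]`.
#' @export
wmpmcc <- function(targets) {
  check_targets(targets)
  rs <- vapply(targets, function(t) target_r(t$pred, t$truth), 0)
  inv_fisher_z(mean(fisher_z(rs)))
}

#' Average loss of best-model selection
#'
#' Per target: the absolute difference between the best true score and the
#' true score of the model ranked first by the predictor (ties broken by
#' first index), averaged over targets.
#'
#' @inheritParams wmpmcc
#' @return Mean loss, `>= 0`, on the score scale.
#' @export
ave_loss <- function(targets) {
  check_targets(targets)
  mean(vapply(targets, function(t) {
    abs(max(t$truth) - t$truth[which.max(t$pred)])
  }, 0))
}

#' Average absolute score deviation
#'
#' Mean of `|true - predicted|` over all models of all targets, reported
#' both on the input scale (`raw`, typically 0-100) and divided by 100
#' (`normalized`, the scale CASP tables print).
#'
#' @inheritParams wmpmcc
#' @return Named numeric vector `(raw, normalized)`.
#' @export
ave_dgdt <- function(targets) {
  check_targets(targets)
  devs <- unlist(lapply(targets, function(t) abs(t$truth - t$pred)))
  c(raw = mean(devs), normalized = mean(devs) / 100)
}

#' Good/bad classification at the GDT-TS 50 threshold
#'
#' A model is truly good when its true score is at least 50 and predicted
#' good when its predicted score is at least 50. Returns the confusion
#' counts and the Matthews correlation coefficient (0 when any denominator
#' factor vanishes).
#'
#' @inheritParams wmpmcc
#' @param threshold decision threshold (default 50).
#' @return List with `counts` (TP, TN, FP, FN) and `mcc`.
#' @export
mcc_at_50 <- function(targets, threshold = 50) {
  check_targets(targets)
  pred <- unlist(lapply(targets, `[[`, "pred"))
  truth <- unlist(lapply(targets, `[[`, "truth"))
  pg <- pred >= threshold
  tg <- truth >= threshold
  counts <- c(TP = sum(pg & tg), TN = sum(!pg & !tg),
              FP = sum(pg & !tg), FN = sum(!pg & tg))
  den <- prod(sqrt(c(counts["TP"] + counts["FP"], counts["TP"] + counts["FN"],
                     counts["TN"] + counts["FP"], counts["TN"] + counts["FN"])))
  mcc <- if (den == 0) 0 else
    (counts[["TP"]] * counts[["TN"]] - counts[["FP"]] * counts[["FN"]]) / den
  list(counts = counts, mcc = unname(mcc))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC of `scores` for separating good models (true score at
#' least `threshold`) from poor ones; ties contribute 1/2.
#'
#' @param scores predicted scores.
#' @param truth true scores on the same scale.
#' @param threshold goodness threshold on `truth` (default 50).
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, truth, threshold = 50) {
  stopifnot(length(scores) == length(truth))
  good <- truth >= threshold
  n1 <- sum(good)
  n0 <- sum(!good)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[good]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report
#'
#' @inheritParams wmpmcc
#' @return List of class `evaluation_report` with `wmpmcc`, per-target `r`
#'   and `z`, `ave_loss`, `ave_dgdt` (raw + normalized), `mcc`, confusion
#'   counts, `auc`, and the problem sizes.
#' @export
evaluate_predictions <- function(targets) {
  check_targets(targets)
  rs <- vapply(targets, function(t) suppressWarnings(target_r(t$pred, t$truth)), 0)
  zs <- fisher_z(rs)
  m <- mcc_at_50(targets)
  pred <- unlist(lapply(targets, `[[`, "pred"))
  truth <- unlist(lapply(targets, `[[`, "truth"))
  structure(list(
    wmpmcc = inv_fisher_z(mean(zs)),
    per_target_r = rs, per_target_z = zs,
    ave_loss = ave_loss(targets),
    ave_dgdt = ave_dgdt(targets),
    mcc = m$mcc, confusion = m$counts,
    auc = roc_auc(pred, truth),
    n_targets = length(targets), n_models = length(pred)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> %d targets, %d models\n",
                     "  wmPMCC %.3f | ave loss %.2f | ave dGDT %.2f (%.5f norm) | ",
                     "MCC %.3f | AUC %s\n"),
              x$n_targets, x$n_models, x$wmpmcc, x$ave_loss,
              x$ave_dgdt[["raw"]], x$ave_dgdt[["normalized"]], x$mcc,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Pairwise comparison of potential scores
#'
#' For a models-by-potentials score matrix: pairwise Pearson and Spearman
#' correlation matrices, and paired t-test / Wilcoxon signed-rank p-value
#' matrices computed on column-standardised scores (raw potentials differ
#' in scale). Zero-difference pairs (a column against itself or an
#' identical column) get p = 1; constant columns give `NA` correlations.
#'
#' @param score_matrix numeric matrix, models in rows, potentials in
#'   columns (at least 3 rows).
#' @return List of four matrices: `pearson`, `spearman`, `t_p`, `wilcoxon_p`.
#' @export
compare_potentials <- function(score_matrix) {
  S <- as.matrix(score_matrix)
  stopifnot(nrow(S) >= 3)
  if (is.null(colnames(S))) colnames(S) <- paste0("P", seq_len(ncol(S)))
  pear <- suppressWarnings(stats::cor(S, method = "pearson"))
  spear <- suppressWarnings(stats::cor(S, method = "spearman"))
  Z <- scale(S)
  Z[, apply(S, 2, stats::sd) == 0] <- 0
  k <- ncol(S)
  t_p <- w_p <- matrix(1, k, k, dimnames = list(colnames(S), colnames(S)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      dif <- Z[, a] - Z[, b]
      if (all(dif == 0)) next                 # identical columns: p = 1
      if (stats::sd(dif) == 0) {              # constant non-zero shift
        t_p[a, b] <- w_p[a, b] <- 0
        next
      }
      t_p[a, b] <- stats::t.test(dif)$p.value
      w_p[a, b] <- suppressWarnings(stats::wilcox.test(dif)$p.value)
    }
  }
  list(pearson = pear, spearman = spear, t_p = t_p, wilcoxon_p = w_p)
}
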