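# Evaluation: confusion-matrix metrics, ROC threshold sweep, stratified
# k-fold cross-validation, and per-activity error analysis.

#' Confusion matrix over windows
#'
#' @param tp,fn,fp,tn non-negative window counts, or (first argument) a
#'   logical truth vector paired with a `decision` vector
#'   (`"eating"`/`"non-eating"` or logical).
#' @param decision optional decision vector when `tp` is a truth vector.
#' @return Object of class `confusion_matrix` with fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(tp, fn = NULL, fp = NULL, tn = NULL,
                             decision = NULL) {
  if (!is.null(decision)) {
    truth <- as.logical(tp)
    pred <- if (is.character(decision)) decision == "eating" else as.logical(decision)
    stopifnot(length(truth) == length(pred))
    return(confusion_matrix(sum(truth & pred), sum(truth & !pred),
                            sum(!truth & pred), sum(!truth & !pred)))
  }
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' Accuracy, precision, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (FP + TN)`, each as
#' a percentage. Values are retained unrounded; the print method reports
#' two decimals. A ratio with zero denominator is `NA` (not applicable),
#' never 0.
#'
#' @param cm a `confusion_matrix` (total count must be positive).
#' @return List of class `metrics_report` with elements `accuracy`,
#'   `precision`, `sensitivity`, `specificity` (percent, unrounded).
#' @export
compute_metrics <- function(cm) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total <= 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    accuracy = ratio(cm$tp + cm$tn, total),
    precision = ratio(cm$tp, cm$tp + cm$fp),
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$fp + cm$tn)
  ), class = "metrics_report")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (windows): TP %d  FN %d  FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f%%", v)
  cat(sprintf("accuracy %s  precision %s  sensitivity %s  specificity %s\n",
              f(x$accuracy), f(x$precision), f(x$sensitivity), f(x$specificity)))
  invisible(x)
}

#' ROC threshold sweep
#'
#' Applies the inclusive decision rule (posterior `>=` threshold is
#' eating) at every threshold and records sensitivity and
#' 1 - specificity. As the threshold descends, sensitivity is
#' non-decreasing and specificity non-increasing; at threshold 0 every
#' window is classified eating. The trapezoidal AUC over the swept points
#' (anchored at (0,0) and (1,1)) is attached as attribute `auc`.
#'
#' @param posteriors numeric eating posteriors per window.
#' @param truth logical eating truth per window.
#' @param thresholds thresholds to sweep, descending (default
#'   `seq(1, 0, by = -0.05)`).
#' @return data.frame of class `roc_sweep`: `threshold`, `sensitivity`,
#'   `one_minus_specificity`, `tp`, `fn`, `fp`, `tn`; attribute `auc`.
#' @export
roc_sweep <- function(posteriors, truth, thresholds = seq(1, 0, by = -0.05)) {
  stopifnot(length(posteriors) > 0, length(posteriors) == length(truth),
            all(thresholds >= 0 & thresholds <= 1))
  thresholds <- sort(thresholds, decreasing = TRUE)
  truth <- as.logical(truth)
  rows <- lapply(thresholds, function(th) {
    pred <- posteriors >= th
    data.frame(threshold = th,
               sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
               one_minus_specificity = if (any(!truth)) mean(pred[!truth]) else NA_real_,
               tp = sum(truth & pred), fn = sum(truth & !pred),
               fp = sum(!truth & pred), tn = sum(!truth & !pred))
  })
  out <- do.call(rbind, rows)
  x <- c(0, out$one_minus_specificity, 1)
  y <- c(0, out$sensitivity, 1)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("roc_sweep", "data.frame")
  out
}

#' Stratified k-fold cross-validation of the full recognizer
#'
#' Splits windows into `k` seed-deterministic folds stratified by the
#' eating class (fold sizes differ by at most one); for each fold, fits
#' the stump bank and CPTs on the remaining folds and evaluates decisions
#' on the held-out fold at `threshold`. Reports per-fold metrics, their
#' mean and standard deviation, and the pooled confusion matrix.
#'
#' @param windows window feature data.frame from [segment_windows()].
#' @param contexts aligned context-truth data.frame (one row per window;
#'   logical columns per inference node plus `eating`).
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold shuffle.
#' @param threshold decision threshold (default 0.6).
#' @param structure network structure (default [build_default_structure()]).
#' @param alpha CPT smoothing (default 1).
#' @param fold_by optional grouping vector (e.g. subject ids) for
#'   group-level folds instead of window-level stratification.
#' @return List of class `cv_report`: `folds` (per-fold metric rows),
#'   `mean`, `sd`, `pooled_cm`, `pooled` (metrics of the pooled matrix),
#'   `assignment` (fold index per window), `scored` (posterior + truth
#'   per window).
#' @export
kfold_cv <- function(windows, contexts, k = 10, seed, threshold = 0.6,
                     structure = build_default_structure(), alpha = 1,
                     fold_by = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(k >= 2, nrow(windows) == nrow(contexts))
  cl <- contexts$eating
  if (length(unique(cl)) < 2L) stop("dataset must contain both classes")
  n <- nrow(windows)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(fold_by)) {
    i1 <- sample(which(cl)); i0 <- sample(which(!cl))
    fold[i1] <- rep_len(seq_len(k), length(i1))
    fold[i0] <- ((seq_along(i0) - 1L + length(i1)) %% k) + 1L
  } else {
    groups <- sample(unique(fold_by))
    gf <- stats::setNames(rep_len(seq_len(k), length(groups)), groups)
    fold <- unname(gf[as.character(fold_by)])
  }
  scored <- data.frame(posterior = rep(NA_real_, n), truth = cl, fold = fold)
  fold_rows <- list()
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_model(windows[!test, , drop = FALSE],
                         contexts[!test, , drop = FALSE],
                         structure = structure, alpha = alpha,
                         threshold = threshold)
    pred <- predict_windows(model, windows[test, , drop = FALSE])
    scored$posterior[test] <- pred$posterior
    if (length(unique(cl[test])) < 2L)
      warning("fold ", f, " contains a single class; some metrics not applicable")
    cm <- confusion_matrix(cl[test], decision = pred$decision)
    m <- compute_metrics(cm)
    fold_rows[[f]] <- data.frame(fold = f, n = sum(test),
                                 accuracy = m$accuracy, precision = m$precision,
                                 sensitivity = m$sensitivity,
                                 specificity = m$specificity)
  }
  folds <- do.call(rbind, fold_rows)
  pooled_cm <- confusion_matrix(cl, decision = classify(scored$posterior, threshold))
  met <- c("accuracy", "precision", "sensitivity", "specificity")
  structure(list(
    folds = folds,
    mean = colMeans(folds[met], na.rm = TRUE),
    sd = vapply(folds[met], stats::sd, numeric(1), na.rm = TRUE),
    pooled_cm = pooled_cm,
    pooled = compute_metrics(pooled_cm),
    assignment = fold,
    scored = scored[c("posterior", "truth")]
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d windows)\n",
              nrow(x$folds), sum(x$folds$n)))
  cat(sprintf("  pooled: ")); print(x$pooled)
  cat(sprintf("  mean accuracy %.2f%% +/- %.2f\n",
              x$mean[["accuracy"]], x$sd[["accuracy"]]))
  invisible(x)
}

#' Per-activity error rates and error shares
#'
#' For each activity: `error rate = errors / windows of that activity`,
#' `error share = errors / total errors` (shares sum to 1 when any error
#' exists, `NA` otherwise).
#'
#' @param labels activity indices per window.
#' @param decision decisions per window (`"eating"`/`"non-eating"` or
#'   logical).
#' @param truth logical eating truth per window.
#' @return data.frame: `label`, `activity`, `windows`, `errors`,
#'   `error_rate`, `error_share`.
#' @export
per_activity_error <- function(labels, decision, truth) {
  stopifnot(length(labels) > 0, length(labels) == length(decision),
            length(labels) == length(truth))
  pred <- if (is.character(decision)) decision == "eating" else as.logical(decision)
  err <- pred != as.logical(truth)
  lab <- factor(labels, levels = 1:10)
  windows <- as.integer(table(lab))
  errors <- as.integer(tapply(err, lab, sum, default = 0L))
  total_err <- sum(errors)
  data.frame(
    label = 1:10,
    activity = names(eatbn_activities),
    windows = windows,
    errors = errors,
    error_rate = ifelse(windows > 0, errors / windows, NA_real_),
    error_share = if (total_err > 0) errors / total_err else NA_real_,
    stringsAsFactors = FALSE)
}
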