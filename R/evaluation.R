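#' One-vs-rest confusion matrix for a target class
#'
#' @param y_true,y_pred equal-length class vectors.
#' @param target the class treated as positive.
#' @return An object of class `confusion_2x2` with integer counts `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
ovr_confusion <- function(y_true, y_pred, target) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty inputs")
  tpos <- y_true == target
  ppos <- y_pred == target
  confusion_2x2(sum(tpos & ppos), sum(tpos & !ppos),
                sum(!tpos & ppos), sum(!tpos & !ppos))
}

#' @rdname ovr_confusion
#' @param tp,fn,fp,tn non-negative counts.
#' @export
confusion_2x2 <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("total count must be positive")
  structure(as.list(counts), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("true +", "true -"), c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Performance metrics from a 2x2 confusion matrix
#'
#' Precision, recall (= sensitivity), specificity, accuracy, F1 (harmonic
#' mean of precision and recall) and the G-metric, the geometric mean of
#' sensitivity and specificity. Any metric whose denominator is zero is
#' defined as 0 (with a message).
#'
#' @param cm a [confusion_2x2()].
#' @return An object of class `class_metrics`; all values are fractions in
#'   `[0, 1]`.
#' @export
metrics_from_confusion <- function(cm) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      message("metrics: zero denominator for ", what, ", defining as 0")
      return(0)
    }
    num / den
  }
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  specificity <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  accuracy <- (cm$tp + cm$tn) / n
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, accuracy = accuracy,
                 f1 = f1, sensitivity = recall, specificity = specificity,
                 g = g_metric(recall, specificity)),
            class = "class_metrics")
}

#' Geometric mean of sensitivity and specificity
#'
#' @param se,sp sensitivity and specificity, as fractions or percentages
#'   (both on the same scale).
#' @return `sqrt(se * sp)`, on the input scale.
#' @examples
#' g_metric(96.76, 95.97)  # ~96.36
#' @export
g_metric <- function(se, sp) sqrt(se * sp)

#' Support-weighted summary of per-class metrics
#'
#' @param per_class list of [metrics_from_confusion()] results.
#' @param supports positive per-class instance counts.
#' @return Named vector with support-weighted `precision`, `recall`, `f1`.
#' @export
weighted_summary <- function(per_class, supports) {
  if (length(per_class) == 0) stop("empty metrics list")
  if (length(per_class) != length(supports) || any(supports <= 0))
    stop("supports must be positive and match per_class")
  wmean <- function(field) {
    vals <- vapply(per_class, `[[`, 0, field)
    sum(vals * supports) / sum(supports)
  }
  c(precision = wmean("precision"), recall = wmean("recall"), f1 = wmean("f1"))
}

#' ROC curve and AUC from graded scores
#'
#' The curve is swept over all unique score thresholds; the AUC is the
#' trapezoidal area, which equals the Mann-Whitney pair statistic (ties
#' counted 1/2).
#'
#' @param scores numeric scores, larger = more positive.
#' @param y binary labels (logical, 0/1, or 2-level factor; the second
#'   level / `TRUE` / 1 is positive).
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y) | y == 1)
  if (length(scores) != length(y)) stop("length mismatch")
  P <- sum(y == 1)
  N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  last_of_group <- c(ss[-length(ss)] != ss[-1], TRUE)
  cumtp <- cumsum(ys)[last_of_group]
  cumfp <- cumsum(1 - ys)[last_of_group]
  tpr <- c(0, cumtp / P)
  fpr <- c(0, cumfp / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(threshold = c(Inf, ss[last_of_group]),
                          fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Leave-one-subject-out evaluation of the hierarchical classifier
#'
#' For each subject, feature selection and node training are re-run on the
#' remaining subjects (no information from the held-out subject leaks into
#' selection), the held-out windows are predicted, and predictions are
#' pooled. Reports pooled one-vs-rest confusion matrices and metrics per
#' intensity class, a support-weighted summary, the pooled accuracy, and one
#' ROC/AUC per internal node (phi1 on all windows, phi2 on the true
#' light/moderate windows).
#'
#' @param X feature matrix.
#' @param y intensity labels (0/1/2).
#' @param subject subject identifier per row; each unique subject forms one
#'   test fold.
#' @param spec a [bhc_spec()].
#' @param verbose print per-fold progress.
#' @return An object of class `bhc_loso`.
#' @export
loso_bhc <- function(X, y, subject, spec = bhc_spec(), verbose = FALSE) {
  X <- as.matrix(X)
  y <- canonical_intensity(y)
  subject <- as.character(subject)
  subs <- unique(subject)
  if (length(subs) < 2) stop("LOSO needs at least 2 subjects")
  keep <- vapply(subs, function(s) sum(subject == s) > 0, TRUE)
  if (any(!keep)) {
    warning("skipping subjects with no windows: ",
            paste(subs[!keep], collapse = ", "))
    subs <- subs[keep]
  }
  pred <- integer(length(y))
  s1 <- numeric(length(y))
  s2 <- numeric(length(y))
  for (s in subs) {
    test <- subject == s
    if (verbose) message("fold: holding out ", s, " (", sum(test), " windows)")
    fit <- bhc(X[!test, , drop = FALSE], y[!test], spec)
    pred[test] <- predict(fit, X[test, , drop = FALSE])
    sc <- predict(fit, X[test, , drop = FALSE], type = "scores")
    s1[test] <- sc$s1
    s2[test] <- sc$s2
  }
  build_loso_report(y, pred, s1, s2, subject, folds = length(subs))
}

build_loso_report <- function(y, pred, s1, s2, subject, folds) {
  cms <- lapply(0:2, function(k) ovr_confusion(y, pred, k))
  mets <- lapply(cms, metrics_from_confusion)
  supports <- vapply(0:2, function(k) sum(y == k), 0L)
  act <- y > 0
  structure(list(
    predictions = data.frame(subject = subject, truth = y, pred = pred,
                             s1 = s1, s2 = s2),
    confusion = stats::setNames(cms, intensity_labels()),
    metrics = stats::setNames(mets, intensity_labels()),
    supports = stats::setNames(supports, intensity_labels()),
    weighted = weighted_summary(mets, supports),
    accuracy = mean(pred == y),
    auc = c(phi1 = roc_auc(s1, act)$auc,
            phi2 = roc_auc(s2[act], y[act] == 2)$auc),
    folds = folds), class = "bhc_loso")
}

#' @export
print.bhc_loso <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out evaluation (%d folds, %d windows)\n",
              x$folds, nrow(x$predictions)))
  tab <- do.call(rbind, lapply(names(x$metrics), function(cl) {
    m <- x$metrics[[cl]]
    cm <- x$confusion[[cl]]
    data.frame(class = cl, tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
               precision = round_half_up(100 * m$precision, 1),
               recall = round_half_up(100 * m$recall, 1),
               accuracy = round_half_up(100 * m$accuracy, 1),
               f1 = round_half_up(100 * m$f1, 1))
  }))
  print(tab, row.names = FALSE)
  cat(sprintf("pooled accuracy %.1f%% | weighted P/R/F1 %.1f/%.1f/%.1f%% | AUC phi1 %.3f, phi2 %.3f\n",
              round_half_up(100 * x$accuracy, 1),
              round_half_up(100 * x$weighted["precision"], 1),
              round_half_up(100 * x$weighted["recall"], 1),
              round_half_up(100 * x$weighted["f1"], 1),
              x$auc["phi1"], x$auc["phi2"]))
  invisible(x)
}

#' @export
summary.bhc_loso <- function(object, ...) object

#' Write a LOSO report as JSON and CSV
#'
#' The CSV mirrors the per-class report layout: one row per class with
#' counts and percentage metrics.
#'
#' @param report a `bhc_loso` object.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_loso_report <- function(report, json_path = NULL, csv_path = NULL) {
  rows <- do.call(rbind, lapply(names(report$metrics), function(cl) {
    m <- report$metrics[[cl]]
    cm <- report$confusion[[cl]]
    data.frame(class = cl, tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
               precision = round_half_up(100 * m$precision, 1),
               recall = round_half_up(100 * m$recall, 1),
               accuracy = round_half_up(100 * m$accuracy, 1),
               f1 = round_half_up(100 * m$f1, 1))
  }))
  if (!is.null(csv_path)) utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(format = "actiflow-loso-1",
                              folds = report$folds,
                              per_class = rows,
                              weighted = as.list(report$weighted),
                              accuracy = report$accuracy,
                              auc = as.list(report$auc)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
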