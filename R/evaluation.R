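safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion matrix and threshold metrics
#'
#' Progressed-to-AD (1) is the positive class. Overall precision, recall
#' (sensitivity) and specificity come from the confusion matrix;
#' per-class precision/recall/F1 are computed by swapping the positive
#' class. Undefined ratios (zero denominators) are reported as `NA`
#' rather than propagated.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return Object of class `evaluation_metrics`.
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) stop("empty vectors", call. = FALSE)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  cls_metrics <- function(tp, fp, tn, fn) {
    p <- safe_ratio(tp, tp + fp)
    r <- safe_ratio(tp, tp + fn)
    f1 <- if (is.na(p) || is.na(r) || (p + r) == 0) NA_real_ else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1)
  }
  pos <- cls_metrics(tp, fp, tn, fn)
  neg <- cls_metrics(tn, fn, tp, fp)  # positive class swapped
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    overall = c(precision = unname(pos["precision"]),
                recall = unname(pos["recall"]),
                specificity = safe_ratio(tn, tn + fp),
                accuracy = (tp + tn) / length(y_true)),
    per_class = data.frame(
      class = c("remained_MDD", "progressed_AD"),
      precision = c(neg["precision"], pos["precision"]),
      recall = c(neg["recall"], pos["recall"]),
      f1 = c(neg["f1"], pos["f1"]),
      row.names = NULL)
  ), class = "evaluation_metrics")
}

#' F1 score from precision and recall
#'
#' @param precision,recall Values in `(0, 1]`.
#' @return `2PR/(P+R)`, or `NA` when `P + R = 0`.
#' @export
f1_consistency <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

roc_points <- function(y_true, y_score) {
  r <- pROC::roc(y_true, y_score, quiet = TRUE, levels = c(0, 1),
                 direction = "<")
  d <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  d[order(d$fpr, d$tpr), , drop = FALSE]
}

roc_auc <- function(y_true, y_score) {
  as.numeric(pROC::auc(pROC::roc(y_true, y_score, quiet = TRUE,
                                 levels = c(0, 1), direction = "<")))
}

#' AUC with confidence interval and ROC points
#'
#' AUC is the trapezoidal area under the empirical ROC with midrank
#' handling of score ties (equivalently the normalized Mann-Whitney U
#' statistic), with the positive class fixed as outcome 1 — an AUC below
#' 0.5 is reported as such, never flipped. The default interval is a
#' stratified percentile bootstrap (2,000 resamples); an asymptotic
#' rank-based (DeLong) interval is available.
#'
#' @param y_true Binary outcomes (both classes required).
#' @param y_score Real-valued scores.
#' @param method `"bootstrap"` or `"delong"`.
#' @param boot_n Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @param conf_level Interval coverage.
#' @return Object of class `auc_ci`: `auc`, `ci_lower`, `ci_upper`, and a
#'   `roc` data frame of (fpr, tpr) points running (0,0) to (1,1).
#' @export
auc_with_ci <- function(y_true, y_score, method = c("bootstrap", "delong"),
                        boot_n = 2000, seed = 1, conf_level = 0.95) {
  method <- match.arg(method)
  if (length(unique(y_true)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- pROC::roc(y_true, y_score, quiet = TRUE, levels = c(0, 1),
                 direction = "<")
  a <- as.numeric(pROC::auc(r))
  ci <- if (method == "bootstrap") {
    withr::with_seed(seed, suppressWarnings(
      pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n,
                   boot.stratified = TRUE, conf.level = conf_level)))
  } else {
    pROC::ci.auc(r, method = "delong", conf.level = conf_level)
  }
  structure(list(auc = a, ci_lower = as.numeric(ci)[1],
                 ci_upper = as.numeric(ci)[3], method = method,
                 roc = roc_points(y_true, y_score)),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.2f (CI: %.2f - %.2f), %s interval\n",
              x$auc, x$ci_lower, x$ci_upper, x$method))
  invisible(x)
}

#' Full evaluation report for one classifier
#'
#' Threshold metrics (confusion matrix, per-class precision/recall/F1,
#' accuracy, overall precision/recall/specificity) plus AUC with its
#' confidence interval and ROC points.
#'
#' @param y_true Binary outcomes.
#' @param prob Predicted positive-class probabilities.
#' @param threshold Classification threshold.
#' @param ci_method,boot_n,seed Passed to [auc_with_ci()].
#' @return Object of class `evaluation_report`.
#' @export
evaluate_classifier <- function(y_true, prob, threshold = 0.5,
                                ci_method = "bootstrap", boot_n = 2000,
                                seed = 1) {
  m <- confusion_and_metrics(y_true, as.integer(prob >= threshold))
  a <- auc_with_ci(y_true, prob, method = ci_method, boot_n = boot_n,
                   seed = seed)
  structure(list(metrics = m, auc = a, n_test = length(y_true),
                 threshold = threshold,
                 y_signature = sum(y_true * seq_along(y_true))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cm <- x$metrics$confusion
  cat(sprintf("Evaluation on %d observations (threshold %.2f)\n",
              x$n_test, x$threshold))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  pc <- x$metrics$per_class
  pc[, -1] <- round(pc[, -1], digits)
  print(pc, row.names = FALSE)
  ov <- x$metrics$overall
  cat(sprintf("  accuracy %.2f | overall precision %.1f%%, recall %.1f%%, specificity %.1f%%\n",
              ov["accuracy"], 100 * ov["precision"], 100 * ov["recall"],
              100 * ov["specificity"]))
  print(x$auc)
  invisible(x)
}

#' Side-by-side model comparison
#'
#' Collates evaluation reports computed on the identical test partition
#' into one per-class metric table with an AUC row, flagging models whose
#' AUC crosses the clinical-relevance line (0.80 by default).
#'
#' @param reports Named list of `evaluation_report`s (e.g. MSM, MLP, IPM).
#' @param clinical_threshold AUC considered clinically relevant.
#' @return Object of class `model_comparison`: `table` (long metric
#'   table), `auc` (per-model AUC + CI + relevance flag).
#' @export
compare_models <- function(reports, clinical_threshold = 0.80) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  n <- vapply(reports, `[[`, 0, "n_test")
  sig <- vapply(reports, `[[`, 0, "y_signature")
  if (length(unique(n)) > 1 || length(unique(sig)) > 1) {
    stop("reports were not computed on the identical test set", call. = FALSE)
  }
  rows <- list()
  for (nm in names(reports)) {
    pc <- reports[[nm]]$metrics$per_class
    rows[[nm]] <- data.frame(model = nm, pc,
                             accuracy = reports[[nm]]$metrics$overall["accuracy"],
                             row.names = NULL)
  }
  auc <- data.frame(
    model = names(reports),
    auc = vapply(reports, function(r) r$auc$auc, 0),
    ci_lower = vapply(reports, function(r) r$auc$ci_lower, 0),
    ci_upper = vapply(reports, function(r) r$auc$ci_upper, 0),
    row.names = NULL)
  auc$clinically_relevant <- auc$auc > clinical_threshold
  structure(list(table = do.call(rbind, rows), auc = auc,
                 clinical_threshold = clinical_threshold),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  cat("Model performance by outcome class\n")
  tb <- x$table
  tb[, c("precision", "recall", "f1", "accuracy")] <-
    round(tb[, c("precision", "recall", "f1", "accuracy")], digits)
  print(tb, row.names = FALSE)
  cat(sprintf("\nAUC (clinical relevance above %.2f)\n", x$clinical_threshold))
  a <- x$auc
  a[, c("auc", "ci_lower", "ci_upper")] <- round(a[, c("auc", "ci_lower", "ci_upper")], digits)
  print(a, row.names = FALSE)
  invisible(x)
}
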