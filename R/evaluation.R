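#' Confusion counts for binary predictions
#'
#' Class 1 (cancer) is the positive class throughout: `tp` counts cancer
#' samples predicted as cancer, `fp` non-cancer samples predicted as
#' cancer, `tn` non-cancer predicted non-cancer, `fn` cancer predicted
#' non-cancer.
#'
#' @param labels True labels in \{0, 1\} (a [label_vector] or plain vector).
#' @param predicted Predicted labels in \{0, 1\}, same length.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predicted) {
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  if (length(labels) != length(predicted)) {
    stop("'labels' and 'predicted' lengths differ")
  }
  structure(list(tp = sum(labels == 1L & predicted == 1L),
                 fp = sum(labels == 0L & predicted == 1L),
                 tn = sum(labels == 0L & predicted == 0L),
                 fn = sum(labels == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' Build confusion counts directly
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (0/0); returning 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' Precision (positive predictive value)
#' @param c A `confusion_counts` object.
#' @return tp / (tp + fp); 0 with a warning when no sample is predicted
#'   positive.
#' @export
precision <- function(c) .safe_ratio(c$tp, c$tp + c$fp, "precision")

#' Sensitivity (recall of the cancer class)
#' @param c A `confusion_counts` object.
#' @return tp / (tp + fn); 0 with a warning when undefined.
#' @export
sensitivity <- function(c) .safe_ratio(c$tp, c$tp + c$fn, "sensitivity")

#' Specificity (recall of the non-cancer class)
#' @param c A `confusion_counts` object.
#' @return tn / (tn + fp); 0 with a warning when undefined.
#' @export
specificity <- function(c) .safe_ratio(c$tn, c$tn + c$fp, "specificity")

#' Accuracy
#' @param c A `confusion_counts` object.
#' @return (tp + tn) / n; 0 with a warning for an empty evaluation.
#' @export
accuracy <- function(c) {
  .safe_ratio(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn, "accuracy")
}

#' F1 score from precision and sensitivity
#' @param precision,sensitivity Reals in \[0, 1\].
#' @return Harmonic mean 2pr/(p + r); 0 when p + r = 0.
#' @export
f1_score <- function(precision, sensitivity) {
  if (precision + sensitivity == 0) return(0)
  2 * precision * sensitivity / (precision + sensitivity)
}

.per_class_f1 <- function(c) {
  # F1 of the positive class, and of the negative class with roles swapped
  f1_pos <- f1_score(suppressWarnings(precision(c)),
                     suppressWarnings(sensitivity(c)))
  swapped <- confusion_counts(tp = c$tn, fp = c$fn, tn = c$tp, fn = c$fp)
  f1_neg <- f1_score(suppressWarnings(precision(swapped)),
                     suppressWarnings(sensitivity(swapped)))
  c(pos = f1_pos, neg = f1_neg)
}

#' Macro F1: unweighted mean of the per-class F1 scores
#' @param c A `confusion_counts` object.
#' @return (F1 of actual positives + F1 of actual negatives) / 2.
#' @export
macro_f1 <- function(c) mean(.per_class_f1(c))

#' Weighted F1: per-class F1 averaged by class prevalence
#'
#' The default `"standard"` variant weights each class F1 by its actual
#' count and divides by the total sample count, so the result stays in
#' \[0, 1\]. The `"as_printed"` variant divides the count-weighted sum by
#' 2 instead; it can exceed 1 for n > 2 and is retained only for
#' side-by-side fidelity, with a warning.
#'
#' @param c A `confusion_counts` object.
#' @param variant `"standard"` or `"as_printed"`.
#' @return The weighted F1.
#' @export
weighted_f1 <- function(c, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  f1 <- .per_class_f1(c)
  n_pos <- c$tp + c$fn
  n_neg <- c$tn + c$fp
  num <- n_pos * f1[["pos"]] + n_neg * f1[["neg"]]
  if (variant == "as_printed") {
    warning("'as_printed' weighted F1 divides by 2 and can exceed 1",
            call. = FALSE)
    return(num / 2)
  }
  .safe_ratio(num, n_pos + n_neg, "weighted F1")
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Rank-based AUC with midranks for tied scores: the probability that a
#' random cancer sample scores above a random non-cancer sample, ties
#' counted half.
#'
#' @param labels True labels in \{0, 1\}; both classes must be present.
#' @param scores Real-valued scores, higher meaning more cancer-like.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop("'labels' and 'scores' lengths differ")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC-ROC requires both classes among the labels")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Seven-metric evaluation report
#'
#' Computes sensitivity, specificity, accuracy, precision, AUC-ROC,
#' macro F1 and weighted F1 for one binary evaluation, keeping the
#' confusion counts so every metric can be recomputed.
#'
#' @param labels True labels in \{0, 1\}.
#' @param predicted Predicted labels in \{0, 1\}.
#' @param scores Real scores for the cancer class (for AUC-ROC); when
#'   omitted, AUC is computed from the hard predictions.
#' @param seed,config_hash Optional run metadata stored in the report.
#' @return A list of class `metrics_report` with elements `metrics`
#'   (named numeric vector of the seven metrics), `confusion`, `seed`,
#'   `config_hash`.
#' @export
evaluate_predictions <- function(labels, predicted, scores = NULL,
                                 seed = NULL, config_hash = NULL) {
  cc <- confusion(labels, predicted)
  if (is.null(scores)) scores <- as.numeric(predicted)
  metrics <- c(sensitivity = suppressWarnings(sensitivity(cc)),
               specificity = suppressWarnings(specificity(cc)),
               accuracy = suppressWarnings(accuracy(cc)),
               precision = suppressWarnings(precision(cc)),
               auc_roc = auc_roc(labels, scores),
               macro_f1 = macro_f1(cc),
               weighted_f1 = weighted_f1(cc))
  metrics_report(metrics, cc, seed = seed, config_hash = config_hash)
}

#' Assemble a metrics report
#' @param metrics Named numeric vector with the seven metric values.
#' @param confusion A `confusion_counts` object.
#' @param seed,config_hash Optional run metadata.
#' @return A `metrics_report` object.
#' @export
metrics_report <- function(metrics, confusion, seed = NULL,
                           config_hash = NULL) {
  needed <- c("sensitivity", "specificity", "accuracy", "precision",
              "auc_roc", "macro_f1", "weighted_f1")
  if (!all(needed %in% names(metrics))) {
    stop("metrics must contain: ", paste(needed, collapse = ", "))
  }
  structure(list(metrics = metrics[needed],
                 confusion = confusion,
                 seed = seed, config_hash = config_hash),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (m in names(x$metrics)) {
    cat(sprintf("  %-12s %.4f\n", m, x$metrics[[m]]))
  }
  cc <- x$confusion
  cat(sprintf("  confusion    tp=%d fp=%d tn=%d fn=%d\n",
              cc$tp, cc$fp, cc$tn, cc$fn))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' The JSON document carries the seven metrics at full precision, the
#' confusion counts and the run metadata; [read_metrics_report()]
#' round-trips it exactly, and two writes of the same report are
#' byte-identical.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  cc <- report$confusion
  n_eval <- cc$tp + cc$fp + cc$tn + cc$fn
  if (n_eval <= 0) stop("confusion counts sum to zero; nothing was evaluated")
  doc <- list(metrics = as.list(report$metrics),
              confusion = cc[c("tp", "fp", "tn", "fn")],
              n_evaluated = n_eval,
              seed = report$seed,
              config_hash = report$config_hash)
  # digits = I(17): 17 significant digits round-trip doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metrics report written by [write_metrics_report()]
#' @param path JSON path.
#' @return A `metrics_report`.
#' @export
read_metrics_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- confusion_counts(doc$confusion$tp, doc$confusion$fp,
                         doc$confusion$tn, doc$confusion$fn)
  metrics_report(unlist(doc$metrics), cc, seed = doc$seed,
                 config_hash = doc$config_hash)
}
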