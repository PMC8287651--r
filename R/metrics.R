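undefined_metric <- function(msg) {
  stop(errorCondition(msg, class = c("gspsvm_undefined_metric", "error")))
}

#' Confusion counts from label vectors
#'
#' Tallies predictions against truth. For two classes the result carries the
#' binary fields TP, FP, FN, TN relative to `positive`; for K classes it is
#' a K x K contingency table with true classes in rows and predicted classes
#' in columns.
#'
#' @param truth,predicted Equal-length label vectors (any comparable coding).
#' @param positive The label treated as the positive class (binary only;
#'   default the larger of the two sorted labels).
#' @return A `confusion_counts` object: for binary input a list with
#'   `TP`, `FP`, `FN`, `TN` and the `table`; otherwise the K x K `table`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
#' @export
confusion <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` differ in length", call. = FALSE)
  }
  lev <- sort(unique(c(truth, predicted)))
  t_f <- factor(truth, levels = lev)
  p_f <- factor(predicted, levels = lev)
  tab <- table(truth = t_f, predicted = p_f)
  out <- list(table = unclass(tab), levels = as.character(lev))
  if (length(lev) == 2L) {
    if (is.null(positive)) positive <- lev[2]
    pos <- match(as.character(positive), as.character(lev))
    if (is.na(pos)) stop("`positive` is not one of the observed labels",
                         call. = FALSE)
    neg <- 3L - pos
    out$TP <- tab[pos, pos]; out$FN <- tab[pos, neg]
    out$FP <- tab[neg, pos]; out$TN <- tab[neg, neg]
    out$positive <- as.character(positive)
  }
  structure(out, class = "confusion_counts")
}

#' Assemble binary confusion counts directly
#' @param TP,FP,FN,TN Nonnegative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  if (any(c(TP, FP, FN, TN) < 0)) stop("counts must be nonnegative", call. = FALSE)
  tab <- matrix(c(TN, FN, FP, TP), 2L, 2L,
                dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  structure(list(table = tab, levels = c("0", "1"),
                 TP = TP, FP = FP, FN = FN, TN = TN, positive = "1"),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(x$table)
  invisible(x)
}

.need_binary <- function(cc) {
  if (is.null(cc$TP)) stop("binary counts required; got a multiclass table",
                           call. = FALSE)
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`: of the records the classifier calls positive, the share
#' that truly are. Signals a typed `gspsvm_undefined_metric` error when no
#' record was predicted positive, rather than silently returning 0.
#' @param cc Binary `confusion_counts`.
#' @return Value in [0, 1].
#' @export
precision <- function(cc) {
  .need_binary(cc)
  if (cc$TP + cc$FP == 0) undefined_metric("precision undefined: TP + FP = 0")
  cc$TP / (cc$TP + cc$FP)
}

#' Recall (sensitivity, true positive rate)
#'
#' `TP / (TP + FN)`: the share of true positives recovered. Sensitivity is
#' the same quantity.
#' @inheritParams precision
#' @return Value in [0, 1].
#' @export
recall <- function(cc) {
  .need_binary(cc)
  if (cc$TP + cc$FN == 0) undefined_metric("recall undefined: TP + FN = 0")
  cc$TP / (cc$TP + cc$FN)
}

#' @rdname recall
#' @export
sensitivity <- recall

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`: the share of true negatives recovered.
#' @inheritParams precision
#' @return Value in [0, 1].
#' @export
specificity <- function(cc) {
  .need_binary(cc)
  if (cc$TN + cc$FP == 0) undefined_metric("specificity undefined: TN + FP = 0")
  cc$TN / (cc$TN + cc$FP)
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(sensitivity * specificity)`, a balanced-performance summary robust
#' to class imbalance.
#' @param sens,spec Values in [0, 1].
#' @return Value in [0, 1].
#' @export
g_mean <- function(sens, spec) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1) {
    stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  sqrt(sens * spec)
}

#' F-beta score
#'
#' `(beta^2 + 1) * P * R / (beta^2 * P + R)`; `beta = 1` gives the familiar
#' F-measure (harmonic mean of precision and recall), `beta -> 0`
#' approaches precision.
#' @param precision,recall Values in [0, 1].
#' @param beta Nonnegative weighting of recall relative to precision.
#' @return Value in [0, 1].
#' @export
f_beta <- function(precision, recall, beta = 1) {
  denom <- beta^2 * precision + recall
  if (denom == 0) undefined_metric("F-beta undefined: beta^2*P + R = 0")
  (beta^2 + 1) * precision * recall / denom
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, the Pearson
#' correlation between the true and predicted binary indicators; in [-1, 1].
#' @inheritParams precision
#' @return Value in [-1, 1].
#' @export
mcc <- function(cc) {
  .need_binary(cc)
  m <- with(cc, c(TP + FN, TP + FP, TN + FP, TN + FN))
  if (any(m == 0)) undefined_metric("MCC undefined: a marginal sum is zero")
  with(cc, (TP * TN - FP * FN) / sqrt(prod(m)))
}

#' Area under the ROC curve
#'
#' Rank estimator on decision scores: the probability a random positive
#' scores above a random negative, ties counting one half (equals the
#' trapezoidal ROC area).
#' @param truth Binary truth labels.
#' @param scores Numeric decision scores, larger meaning more positive.
#' @param positive Label of the positive class (default the larger label).
#' @return Value in [0, 1].
#' @export
auc <- function(truth, scores, positive = NULL) {
  if (length(truth) != length(scores)) {
    stop("`truth` and `scores` differ in length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  lev <- sort(unique(truth))
  if (length(lev) < 2L) undefined_metric("AUC undefined: one class present")
  if (length(lev) > 2L) stop("AUC requires binary truth", call. = FALSE)
  if (is.null(positive)) positive <- lev[2]
  is_pos <- truth == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Overall accuracy
#'
#' `(TP + TN) / total` for binary counts; `trace / total` for a multiclass
#' table.
#' @param cc A `confusion_counts` (binary or multiclass).
#' @return Value in [0, 1].
#' @export
accuracy <- function(cc) {
  tab <- cc$table
  total <- sum(tab)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  sum(diag(tab)) / total
}

#' Micro-averaged precision, recall and F1
#'
#' Pools per-class TP, FP and FN over all classes into one global confusion
#' count before computing the scores. For a single-label task the three
#' micro scores all equal the accuracy.
#' @param cc A `confusion_counts` (typically multiclass).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
micro_scores <- function(cc) {
  tab <- cc$table
  total <- sum(tab)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  tp <- sum(diag(tab))
  fp <- sum(colSums(tab)) - tp   # per-class FP pooled
  fn <- sum(rowSums(tab)) - tp   # per-class FN pooled
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Hamming loss
#'
#' Fraction of predicted labels that differ from the true labels; for a
#' single-label task this is exactly `1 - accuracy`.
#' @param truth,predicted Equal-length label vectors.
#' @return Value in [0, 1].
#' @examples
#' hamming_loss(rep(1, 4), c(1, 1, 0, 1))
#' @export
hamming_loss <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` differ in length", call. = FALSE)
  }
  mean(truth != predicted)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` where `Po` is the
#' observed accuracy and `Pe` the agreement expected from the marginals,
#' `Pe = sum_i row_i * col_i / total^2`.
#' @param cc A `confusion_counts` (binary or multiclass).
#' @return Value at most 1 (negative for worse-than-chance agreement).
#' @export
cohen_kappa <- function(cc) {
  tab <- cc$table
  total <- sum(tab)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  po <- sum(diag(tab)) / total
  pe <- sum(rowSums(tab) * colSums(tab)) / total^2
  if (abs(1 - pe) < .Machine$double.eps) {
    undefined_metric("kappa undefined: expected agreement Pe = 1")
  }
  (po - pe) / (1 - pe)
}

#' Micro-averaged Jaccard similarity
#'
#' Pooled `TP / (TP + FP + FN)` over all classes; for a single-label task
#' this equals `accuracy / (2 - accuracy)`.
#' @param cc A `confusion_counts`.
#' @return Value in [0, 1].
#' @export
jaccard_micro <- function(cc) {
  tab <- cc$table
  total <- sum(tab)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  tp <- sum(diag(tab))
  fp <- sum(colSums(tab)) - tp
  fn <- sum(rowSums(tab)) - tp
  if (tp + fp + fn == 0) undefined_metric("Jaccard undefined: no labels")
  tp / (tp + fp + fn)
}

#' Full binary metric report
#'
#' Computes the binary diagnostic suite from truth/prediction vectors (and
#' optional scores for AUC). Metrics whose denominator is empty are
#' reported as `NA` rather than 0, so downstream averages are not silently
#' biased.
#' @param truth,predicted Label vectors.
#' @param scores Optional decision scores for AUC.
#' @param positive Positive-class label.
#' @return Named numeric vector of metrics.
#' @export
binary_report <- function(truth, predicted, scores = NULL, positive = NULL) {
  cc <- confusion(truth, predicted, positive = positive)
  safe <- function(expr) {
    tryCatch(expr, gspsvm_undefined_metric = function(e) NA_real_)
  }
  p <- safe(precision(cc)); r <- safe(recall(cc)); sp <- safe(specificity(cc))
  out <- c(
    precision = p, recall = r, specificity = sp,
    g_mean = if (is.na(r) || is.na(sp)) NA_real_ else g_mean(r, sp),
    f_measure = if (is.na(p) || is.na(r)) NA_real_ else safe(f_beta(p, r, 1)),
    mcc = safe(mcc(cc)),
    accuracy = accuracy(cc)
  )
  if (!is.null(scores)) {
    out["auc"] <- safe(auc(truth, scores, positive = positive))
  }
  out
}

#' Full multiclass metric report
#'
#' Accuracy, micro precision/recall/F1, Hamming loss, Cohen's kappa and
#' micro Jaccard from truth/prediction vectors.
#' @param truth,predicted Label vectors.
#' @return Named numeric vector of metrics.
#' @export
multiclass_report <- function(truth, predicted) {
  cc <- confusion(truth, predicted)
  ms <- micro_scores(cc)
  safe <- function(expr) {
    tryCatch(expr, gspsvm_undefined_metric = function(e) NA_real_)
  }
  c(accuracy = accuracy(cc),
    precision_micro = unname(ms["precision"]),
    recall_micro = unname(ms["recall"]),
    f1_micro = unname(ms["f1"]),
    hamming_loss = hamming_loss(truth, predicted),
    cohen_kappa = safe(cohen_kappa(cc)),
    jaccard_micro = safe(jaccard_micro(cc)))
}

#' Serialize a metric report to tidy CSV
#' @param report Named numeric vector from [binary_report()] or
#'   [multiclass_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(report, path) {
  df <- data.frame(metric = names(report), value = unname(report))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
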