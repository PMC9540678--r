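#' One-vs-rest confusion counts per class
#'
#' Reduces the K-class problem to K binary problems; for each class y the
#' counts are TP (true y predicted y), FN (true y predicted other),
#' FP (other predicted y), TN (other predicted other). Each class's four
#' counts sum to n, and total TP across classes equals the number of
#' exactly correct multiclass predictions.
#'
#' @param y_true,y_pred integer label vectors in `1..K` of equal length.
#' @param n_classes number of classes K.
#' @return A K x 4 data frame with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  n <- length(y_true)
  if (n == 0L) stop("empty label vectors")
  if (length(y_pred) != n) stop("label vectors must have equal length")
  if (any(c(y_true, y_pred) < 1L | c(y_true, y_pred) > n_classes))
    stop("labels must lie in 1..", n_classes)
  out <- t(vapply(seq_len(n_classes), function(y) {
    tp <- sum(y_true == y & y_pred == y)
    fn <- sum(y_true == y & y_pred != y)
    fp <- sum(y_true != y & y_pred == y)
    c(tp = tp, tn = n - tp - fn - fp, fp = fp, fn = fn)
  }, numeric(4)))
  data.frame(class = seq_len(n_classes), out)
}

#' Per-class performance measures from one-vs-rest counts
#'
#' Accuracy (TP+TN)/n, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' and positive predictive value TP/(TP+FP) per class. A zero-denominator
#' ratio is reported `NA` (missing, not zero) — except sensitivity when
#' the class does occur in truth but yields no true positives, which is a
#' genuine 0.
#'
#' @param counts a [confusion_counts()] result.
#' @return A K x 5 data frame: `class`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`.
#' @export
per_class_measures <- function(counts) {
  n <- counts$tp[1] + counts$tn[1] + counts$fp[1] + counts$fn[1]
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(
    class = counts$class,
    accuracy = (counts$tp + counts$tn) / n,
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    ppv = ratio(counts$tp, counts$tp + counts$fp)
  )
}

#' Macro-averaged performance measures
#'
#' Unweighted mean of each per-class measure across classes; classes with
#' a missing value are skipped with a warning. For K = 3 single-label
#' predictions, macro accuracy relates to plain multiclass accuracy by
#' `macro = (1 + 2 * plain) / 3`, because each misclassification is wrong
#' in exactly two of the three one-vs-rest problems.
#'
#' @param per_class a [per_class_measures()] result.
#' @return Named numeric vector: `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`.
#' @export
macro_measures <- function(per_class) {
  vapply(c("accuracy", "sensitivity", "specificity", "ppv"), function(m) {
    v <- per_class[[m]]
    if (anyNA(v)) {
      if (all(is.na(v))) return(NA_real_)
      warning("measure '", m, "' missing for class(es) ",
              paste(per_class$class[is.na(v)], collapse = ", "),
              "; skipped in macro average", call. = FALSE)
    }
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Plain multiclass accuracy
#'
#' @param y_true,y_pred integer label vectors.
#' @return Proportion of exactly correct predictions.
#' @export
plain_accuracy <- function(y_true, y_pred) mean(y_true == y_pred)

#' Calibration by ordered predicted probability
#'
#' For each class, observations are sorted by their predicted class-y
#' probability and cut into equal-count bins; each bin reports the mean
#' predicted probability and the proportion of observations truly in
#' class y. Under good calibration the two track each other.
#'
#' @param probs n x K probability matrix.
#' @param y_true integer labels.
#' @param n_bins number of equal-count bins (at least 2, at most n).
#' @return A data frame: `class`, `bin`, `n`, `mean_prob`, `obs_prop`.
#' @export
calibration_table <- function(probs, y_true, n_bins = 10) {
  probs <- validate_prob_matrix(probs)
  n <- nrow(probs)
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  if (n_bins > n) stop("'n_bins' exceeds the number of observations")
  y_true <- as.integer(y_true)
  out <- lapply(seq_len(ncol(probs)), function(y) {
    ord <- order(probs[, y])
    bin <- ceiling(seq_along(ord) / length(ord) * n_bins)
    data.frame(
      class = y, bin = seq_len(n_bins),
      n = as.integer(table(bin)),
      mean_prob = as.numeric(tapply(probs[ord, y], bin, mean)),
      obs_prop = as.numeric(tapply(y_true[ord] == y, bin, mean)))
  })
  do.call(rbind, out)
}
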