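#' Estimate class-specific conformal thresholds
#'
#' Split-conformal calibration for the least-ambiguous set-valued
#' classifier with bounded per-class error levels. For each class y the
#' calibration observations with true label y are gathered and their
#' predicted true-class probabilities \eqn{p_i = \hat P(Y_i | X_i)} ranked.
#' The threshold is the smallest such probability whose inclusive rank
#' strictly exceeds \eqn{(m_y + 1)\alpha_y - 1}, where \eqn{m_y} is the
#' class-y calibration count:
#' \deqn{\hat t_y = \min_i \{ p_i : \#\{j : p_j \le p_i\} > (m_y+1)\alpha_y - 1 \}.}
#' The threshold is always an element of the calibration probabilities
#' (an order statistic, never interpolated); ties are counted inclusively.
#' With exchangeable data this bounds each class's miscoverage at
#' \eqn{\alpha_y} in finite samples. At \eqn{\alpha_y = 0} the threshold is
#' the class minimum, so every calibration point of that class is covered.
#'
#' @param calib_probs n x K probability matrix for the calibration half
#'   (from an estimator fitted on the other half).
#' @param calib_labels true class labels of the calibration half.
#' @param alphas per-class error levels in `[0, 1)`; a scalar is recycled.
#' @return An object of class `"threshold_set"`: list with `thresholds`,
#'   `alphas`, `calibration_sizes` (all length K).
#' @examples
#' p <- matrix(c(.7, .2, .1, .1, .8, .1, .2, .2, .6), 3, byrow = TRUE)
#' estimate_thresholds(p, c(1, 2, 3), alphas = 0)
#' @export
estimate_thresholds <- function(calib_probs, calib_labels, alphas = 0.10) {
  calib_probs <- validate_prob_matrix(calib_probs)
  K <- ncol(calib_probs)
  calib_labels <- as.integer(calib_labels)
  if (length(calib_labels) != nrow(calib_probs))
    stop("labels and probability rows must align")
  if (any(calib_labels < 1L | calib_labels > K))
    stop("labels must lie in 1..", K)
  alphas <- rep_len(as.numeric(alphas), K)
  if (any(alphas < 0 | alphas >= 1)) stop("alphas must lie in [0, 1)")
  thresholds <- numeric(K)
  sizes <- integer(K)
  for (y in seq_len(K)) {
    idx <- which(calib_labels == y)
    m <- length(idx)
    if (m == 0L)
      stop("class ", y, " absent from calibration data; no threshold estimable")
    p <- sort(calib_probs[cbind(idx, y)])
    # inclusive rank of sorted p[k] is its last tied position
    ranks <- vapply(p, function(v) sum(p <= v), integer(1))
    ok <- ranks > (m + 1) * alphas[y] - 1
    thresholds[y] <- p[which(ok)[1L]]   # ok is monotone; min qualifying value
    sizes[y] <- m
  }
  structure(list(thresholds = thresholds, alphas = alphas,
                 calibration_sizes = sizes),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  print(data.frame(class = seq_along(x$thresholds),
                   threshold = round(x$thresholds, 4),
                   alpha = x$alphas, n_calib = x$calibration_sizes),
        row.names = FALSE)
  invisible(x)
}

#' Form conformal label sets
#'
#' Class y is a member of observation i's label set when
#' \eqn{\hat P(y | x_i) \ge \hat t_y} (inclusive comparison). Sets may be
#' empty (null sets) or contain several classes (ambiguous sets); both are
#' preserved as-is here — null sets are only filled downstream, during
#' bootstrap label selection.
#'
#' @param probs n x K probability matrix.
#' @param thresholds a [estimate_thresholds()] result, or a length-K
#'   numeric vector of thresholds.
#' @return An object of class `"label_set_matrix"`: list with `member`
#'   (n x K logical) and `set_size` (length-n integer).
#' @export
assign_label_sets <- function(probs, thresholds) {
  probs <- validate_prob_matrix(probs)
  t_y <- if (inherits(thresholds, "threshold_set")) thresholds$thresholds
         else as.numeric(thresholds)
  if (ncol(probs) != length(t_y))
    stop("probability matrix has ", ncol(probs), " columns but ",
         length(t_y), " thresholds supplied")
  member <- sweep(probs, 2L, t_y, `>=`)
  structure(list(member = member, set_size = as.integer(rowSums(member))),
            class = "label_set_matrix")
}

#' Per-class empirical coverage of label sets
#'
#' The coverage of class y is the proportion of true-class-y observations
#' whose label set contains y. Null sets never cover. A class with no
#' observations has undefined coverage, reported as `NA` (not zero).
#'
#' @param sets a [assign_label_sets()] result.
#' @param labels true class labels.
#' @return Length-K numeric vector of coverage proportions.
#' @export
empirical_coverage <- function(sets, labels) {
  stopifnot(inherits(sets, "label_set_matrix"))
  K <- ncol(sets$member)
  labels <- as.integer(labels)
  if (length(labels) != nrow(sets$member))
    stop("labels and label sets must align")
  vapply(seq_len(K), function(y) {
    in_class <- labels == y
    if (!any(in_class)) return(NA_real_)
    mean(sets$member[in_class, y])
  }, numeric(1))
}

#' Distribution of label-set sizes
#'
#' Tabulates the share of observations by number of assigned labels
#' (0 = null set, 1 = single label, 2.. = ambiguous), overall and — when
#' true labels are supplied — within each true class.
#'
#' @param sets a [assign_label_sets()] result.
#' @param labels optional true class labels.
#' @return A data frame with columns `class` (`"all"` or the class label),
#'   `set_size`, and `proportion`; proportions sum to 1 within each `class`.
#' @export
ambiguity_distribution <- function(sets, labels = NULL) {
  stopifnot(inherits(sets, "label_set_matrix"))
  K <- ncol(sets$member)
  tab_one <- function(sz) tabulate(sz + 1L, K + 1L) / length(sz)
  out <- data.frame(class = "all", set_size = 0:K,
                    proportion = tab_one(sets$set_size))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    for (y in seq_len(K)) {
      sz <- sets$set_size[labels == y]
      if (length(sz))
        out <- rbind(out, data.frame(class = as.character(y),
                                     set_size = 0:K,
                                     proportion = tab_one(sz)))
    }
  }
  out
}

#' Write label sets to CSV
#'
#' One row per observation: id, per-class membership flags, set size.
#'
#' @param sets a [assign_label_sets()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_sets <- function(sets, path) {
  stopifnot(inherits(sets, "label_set_matrix"))
  K <- ncol(sets$member)
  df <- data.frame(id = seq_len(nrow(sets$member)))
  for (y in seq_len(K)) df[[paste0("in_class_", y)]] <- as.integer(sets$member[, y])
  df$set_size <- sets$set_size
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
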