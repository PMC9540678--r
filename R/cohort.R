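#' Construct a cohort
#'
#' A cohort bundles a numeric feature matrix with (optionally) observed
#' class labels and right-censored survival outcomes. Development cohorts
#' carry labels; deployment cohorts may omit them. Survival columns are an
#' observed time in days plus an event indicator (1 = death observed,
#' 0 = censored).
#'
#' @param features numeric matrix or data frame of features (n x p).
#' @param labels integer class labels in `1..n_classes`, or `NULL` when the
#'   true class is unobserved.
#' @param time nonnegative observed event/censoring times in days, or `NULL`.
#' @param event logical or 0/1 event indicators; required with `time`.
#' @param n_classes number of classes K. Defaults to `max(labels)`.
#' @return An object of class `"cohort"`: a list with elements `features`,
#'   `labels`, `time`, `event`, `n_classes`, `n`.
#' @examples
#' ch <- cohort(matrix(rnorm(20), 10, 2), labels = rep(1:2, 5))
#' @export
cohort <- function(features, labels = NULL, time = NULL, event = NULL,
                   n_classes = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("'features' must be numeric")
  n <- nrow(features)
  if (n < 1L || ncol(features) < 1L) stop("'features' must be a non-empty matrix")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("'labels' length must match nrow(features)")
    if (anyNA(labels)) stop("'labels' must not contain NA")
    if (is.null(n_classes)) n_classes <- max(labels)
    if (any(labels < 1L | labels > n_classes))
      stop("'labels' must lie in 1..", n_classes)
  } else if (is.null(n_classes)) {
    n_classes <- NA_integer_
  }
  if (!is.null(time)) {
    time <- as.numeric(time)
    if (length(time) != n) stop("'time' length must match nrow(features)")
    if (any(time < 0, na.rm = TRUE)) stop("'time' must be nonnegative")
    if (is.null(event)) stop("'event' is required when 'time' is supplied")
    event <- as.integer(as.logical(event))
    if (length(event) != n) stop("'event' length must match nrow(features)")
  } else {
    event <- NULL
  }
  structure(
    list(features = features, labels = labels, time = time, event = event,
         n_classes = as.integer(n_classes), n = n),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> n =", x$n, ", p =", ncol(x$features))
  if (!is.null(x$labels))
    cat(", K =", x$n_classes,
        " (", paste(sprintf("%.2f", prop.table(tabulate(x$labels, x$n_classes))),
                    collapse = "/"), ")", sep = "")
  if (!is.null(x$time)) cat(", survival: yes")
  cat("\n")
  invisible(x)
}

#' Subset a cohort by row index
#'
#' @param x a [cohort()].
#' @param i integer row indices (may repeat, e.g. a bootstrap resample).
#' @param ... unused.
#' @return A cohort containing the selected rows.
#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$features[i, , drop = FALSE],
         labels = if (!is.null(x$labels)) x$labels[i],
         time = if (!is.null(x$time)) x$time[i],
         event = if (!is.null(x$event)) x$event[i],
         n_classes = x$n_classes)
}

#' Split a development cohort into fitting and calibration halves
#'
#' Performs a label-stratified random split of the development cohort into
#' two near-equal halves: the first half is used to fit the conditional
#' class-probability estimator, the second to calibrate the conformal
#' thresholds. Within each class stratum the observations are permuted and
#' divided; when a stratum has an odd count the extra observation goes to
#' the first half.
#'
#' @param dev a labeled [cohort()].
#' @param seed integer seed controlling the permutation.
#' @return A list of class `"split_index"` with integer index vectors
#'   `part1` and `part2` (disjoint, covering `1..n`).
#' @export
split_development <- function(dev, seed) {
  stopifnot(inherits(dev, "cohort"))
  if (is.null(dev$labels))
    stop("development cohort must carry labels for a stratified split")
  sizes <- tabulate(dev$labels, dev$n_classes)
  if (any(sizes < 2L))
    stop("class ", which(sizes < 2L)[1L],
         " has fewer than 2 observations; cannot split")
  part1 <- integer(0)
  part2 <- integer(0)
  set.seed(as.integer(seed))
  for (y in seq_len(dev$n_classes)) {
    idx <- which(dev$labels == y)
    idx <- idx[sample.int(length(idx))]
    n1 <- ceiling(length(idx) / 2)
    part1 <- c(part1, idx[seq_len(n1)])
    part2 <- c(part2, idx[-seq_len(n1)])
  }
  structure(list(part1 = sort(part1), part2 = sort(part2)),
            class = "split_index")
}

#' Read a cohort from a delimited text file
#'
#' @param path CSV file with a header row.
#' @param feature_cols character vector of feature column names.
#' @param label_col name of the class label column, or `NULL`.
#' @param time_col,event_col names of the survival columns, or `NULL`.
#' @param n_classes number of classes K (required when labels are absent
#'   but label sets are to be formed).
#' @return A [cohort()].
#' @export
read_cohort <- function(path, feature_cols, label_col = NULL,
                        time_col = NULL, event_col = NULL, n_classes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(
    c(feature_cols, label_col, time_col, event_col), names(df))
  if (length(missing_cols))
    stop("columns absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  cohort(as.matrix(df[feature_cols]),
         labels = if (!is.null(label_col)) df[[label_col]],
         time = if (!is.null(time_col)) df[[time_col]],
         event = if (!is.null(event_col)) df[[event_col]],
         n_classes = n_classes)
}

#' Write a cohort to a delimited text file
#'
#' @param x a [cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  df <- as.data.frame(x$features)
  if (!is.null(x$labels)) df$class <- x$labels
  if (!is.null(x$time)) {
    df$time <- x$time
    df$event <- x$event
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
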