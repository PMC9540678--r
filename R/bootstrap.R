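#' Naive argmax labels
#'
#' Assigns each observation the single most probable predicted class.
#' Ties are broken toward the lowest class index, so labeling is
#' deterministic.
#'
#' @param probs n x K probability matrix.
#' @return Integer label vector.
#' @export
naive_labels <- function(probs) {
  probs <- validate_prob_matrix(probs)
  max.col(probs, ties.method = "first")
}

#' Draw one label from a conformal label set
#'
#' Selects a label uniformly at random from the classes in the set; for a
#' null (empty) set all K classes are considered with equal probability.
#' Deterministic given the RNG state.
#'
#' @param set_row length-K logical membership vector.
#' @return A single integer label.
#' @export
select_label <- function(set_row) {
  set_row <- as.logical(set_row)
  if (length(set_row) < 2L) stop("at least 2 classes are required")
  drawn <- select_labels_from(matrix(set_row, nrow = 1L))
  drawn[1L]
}

# vectorized uniform draw of one member class per row; null rows are
# widened to the full label space first
select_labels_from <- function(member) {
  member[rowSums(member) == 0L, ] <- TRUE
  k <- rowSums(member)
  j <- pmin(floor(stats::runif(nrow(member)) * k) + 1L, k)
  cum <- member %*% upper.tri(diag(ncol(member)), diag = TRUE)
  as.integer(rowSums(cum < j) + 1L)
}

# deterministic per-resample child seeds derived from a root seed
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# shared engine behind the naive and weighted bootstrap runners
run_bootstrap_engine <- function(validation, n_boot, seed, draw_labels,
                                 horizons, compute_survival, resample_fn,
                                 method) {
  if (n_boot < 1) stop("'n_boot' must be at least 1")
  stopifnot(inherits(validation, "cohort"))
  if (is.null(validation$labels))
    stop("validation cohort must carry labels to evaluate classification")
  n <- validation$n
  K <- validation$n_classes
  seeds <- child_seeds(seed, n_boot)
  idx_mat <- matrix(NA_integer_, n_boot, n)
  lab_mat <- matrix(NA_integer_, n_boot, n)
  metrics <- vector("list", n_boot)
  surv <- if (compute_survival) vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    idx <- if (is.null(resample_fn)) sample.int(n, n, replace = TRUE)
           else resample_fn(n)
    y_sel <- draw_labels(idx)
    idx_mat[b, ] <- idx
    lab_mat[b, ] <- y_sel
    y_true <- validation$labels[idx]
    pc <- per_class_measures(confusion_counts(y_true, y_sel, K))
    mac <- suppressWarnings(macro_measures(pc))
    metrics[[b]] <- rbind(
      data.frame(resample = b, class = as.character(pc$class),
                 accuracy = pc$accuracy, sensitivity = pc$sensitivity,
                 specificity = pc$specificity, ppv = pc$ppv),
      data.frame(resample = b, class = "macro",
                 accuracy = mac["accuracy"], sensitivity = mac["sensitivity"],
                 specificity = mac["specificity"], ppv = mac["ppv"]),
      data.frame(resample = b, class = "plain",
                 accuracy = plain_accuracy(y_true, y_sel),
                 sensitivity = NA_real_, specificity = NA_real_,
                 ppv = NA_real_))
    if (compute_survival) {
      time <- validation$time[idx]
      event <- validation$event[idx]
      # horizon-past-follow-up warnings are expected on short resamples
      sp <- suppressWarnings(
        stratified_summaries(time, event, y_sel, K, horizons))
      so <- suppressWarnings(
        stratified_summaries(time, event, y_true, K, horizons))
      keep <- c("stratum", "n_obs", "median_days",
                paste0("surv_", horizons))
      surv[[b]] <- rbind(
        cbind(resample = b, stratification = "predicted", sp[keep]),
        cbind(resample = b, stratification = "observed", so[keep]))
    }
  }
  out <- list(method = method, n_boot = n_boot, seed = as.integer(seed),
              horizons = horizons,
              draws = list(indices = idx_mat, labels = lab_mat),
              metrics = do.call(rbind, metrics),
              survival = if (compute_survival) do.call(rbind, surv))
  rownames(out$metrics) <- NULL
  if (compute_survival) rownames(out$survival) <- NULL
  structure(out, class = "bootstrap_run")
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat("<bootstrap_run>", x$method, "method,", x$n_boot,
      "resamples, seed", x$seed, "\n")
  invisible(x)
}

#' Weighted-labeling bootstrap
#'
#' For each of `n_boot` resamples of the validation cohort (drawn with
#' replacement, same size), a single label is selected for every resampled
#' observation uniformly at random from its conformal label set (uniformly
#' over all classes for null sets). Classification metrics and — when
#' survival outcomes are present — stratified Kaplan-Meier summaries are
#' computed on each resample and stored. Labels are redrawn independently
#' for every resampled row in every resample, so a row appearing twice in
#' one resample may receive two different labels: this maximizes the label
#' uncertainty propagated downstream.
#'
#' A root seed spawns one child seed per resample, so runs are
#' reproducible and resamples mutually independent.
#'
#' @param validation a labeled [cohort()].
#' @param probs validation probability matrix from the estimator fitted on
#'   the first development half.
#' @param thresholds a [estimate_thresholds()] result from the calibration
#'   half.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer root seed.
#' @param horizons survival horizons in days.
#' @param survival compute per-resample survival summaries (requires
#'   survival outcomes on the cohort).
#' @param .resample internal test hook: replacement for the resampling
#'   function `function(n)`; `NULL` for the standard bootstrap.
#' @return A `"bootstrap_run"`: list with `method`, `n_boot`, `seed`,
#'   `draws` (resample indices and selected labels), `metrics`
#'   (per-resample per-class and macro measures), `survival`
#'   (per-resample stratified summaries), and for the weighted method
#'   `sets` and `thresholds`.
#' @export
run_weighted_bootstrap <- function(validation, probs, thresholds,
                                   n_boot = 500, seed = 1L,
                                   horizons = c(90, 365),
                                   survival = !is.null(validation$time),
                                   .resample = NULL) {
  probs <- validate_prob_matrix(probs)
  sets <- assign_label_sets(probs, thresholds)
  run <- run_bootstrap_engine(
    validation, n_boot, seed,
    draw_labels = function(idx)
      select_labels_from(sets$member[idx, , drop = FALSE]),
    horizons = horizons, compute_survival = survival,
    resample_fn = .resample, method = "weighted")
  run$sets <- sets
  run$thresholds <- thresholds
  run
}

#' Naive argmax bootstrap
#'
#' Labels are fixed at the argmax of the predicted probabilities before
#' resampling; only the row resampling varies across resamples, providing
#' bootstrap confidence intervals around the naive method's metrics and
#' survival estimates.
#'
#' @inheritParams run_weighted_bootstrap
#' @return A `"bootstrap_run"`; see [run_weighted_bootstrap()].
#' @export
run_naive_bootstrap <- function(validation, probs, n_boot = 500, seed = 1L,
                                horizons = c(90, 365),
                                survival = !is.null(validation$time),
                                .resample = NULL) {
  probs <- validate_prob_matrix(probs)
  labels_fixed <- naive_labels(probs)
  run <- run_bootstrap_engine(
    validation, n_boot, seed,
    draw_labels = function(idx) labels_fixed[idx],
    horizons = horizons, compute_survival = survival,
    resample_fn = .resample, method = "naive")
  run$labels_fixed <- labels_fixed
  run
}

#' Naive standard practice (single pass, no resampling)
#'
#' Argmax labels applied once to the validation cohort: classification
#' metrics, survival summaries stratified by predicted and by observed
#' class with Greenwood confidence intervals, and the bias of the
#' predicted-class estimates. No resampling distribution is produced.
#'
#' @inheritParams run_weighted_bootstrap
#' @return A list of class `"standard_practice"` with `labels`,
#'   `per_class`, `macro`, `plain_accuracy`, and (with outcomes)
#'   `survival_predicted`, `survival_observed`, `bias`.
#' @export
run_standard_practice <- function(validation, probs, horizons = c(90, 365),
                                  survival = !is.null(validation$time)) {
  stopifnot(inherits(validation, "cohort"))
  if (is.null(validation$labels))
    stop("validation cohort must carry labels to evaluate classification")
  probs <- validate_prob_matrix(probs)
  y_pred <- naive_labels(probs)
  K <- validation$n_classes
  pc <- per_class_measures(confusion_counts(validation$labels, y_pred, K))
  out <- list(labels = y_pred, per_class = pc,
              macro = suppressWarnings(macro_measures(pc)),
              plain_accuracy = plain_accuracy(validation$labels, y_pred))
  if (survival) {
    sp <- stratified_summaries(validation$time, validation$event, y_pred,
                               K, horizons)
    so <- stratified_summaries(validation$time, validation$event,
                               validation$labels, K, horizons)
    out$survival_predicted <- sp
    out$survival_observed <- so
    out$bias <- survival_bias(sp, so)
  }
  structure(out, class = "standard_practice")
}

#' Summarize a bootstrap run
#'
#' Bootstrap point estimates are the means of the per-resample statistics,
#' with percentile 95% intervals (2.5th and 97.5th percentiles), for every
#' stored metric, survival quantity, and the predicted-minus-observed
#' survival bias.
#'
#' @param run a `"bootstrap_run"`.
#' @param level interval level (percentile-based).
#' @return A list of data frames `metrics`, `survival`, `bias`, each with
#'   `mean`, `lower`, `upper` columns.
#' @export
summarize_bootstrap <- function(run, level = 0.95) {
  stopifnot(inherits(run, "bootstrap_run"))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  smry <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA_real_, lower = NA_real_,
                             upper = NA_real_))
    q <- stats::quantile(v, pr, names = FALSE, type = 7)
    c(mean = mean(v), lower = q[1], upper = q[2])
  }
  m <- run$metrics
  mets <- do.call(rbind, lapply(split(m, m$class), function(d) {
    do.call(rbind, lapply(c("accuracy", "sensitivity", "specificity",
                            "ppv"), function(msr) {
      data.frame(class = d$class[1], measure = msr, t(smry(d[[msr]])))
    }))
  }))
  rownames(mets) <- NULL
  out <- list(metrics = mets)
  if (!is.null(run$survival)) {
    s <- run$survival
    qty_cols <- c("median_days", paste0("surv_", run$horizons))
    key <- interaction(s$stratification, s$stratum, drop = FALSE)
    out$survival <- do.call(rbind, lapply(split(s, key), function(d) {
      do.call(rbind, lapply(qty_cols, function(qc) {
        data.frame(stratification = d$stratification[1],
                   stratum = d$stratum[1], quantity = qc, t(smry(d[[qc]])))
      }))
    }))
    rownames(out$survival) <- NULL
    sp <- s[s$stratification == "predicted", ]
    so <- s[s$stratification == "observed", ]
    stopifnot(identical(sp$resample, so$resample),
              identical(sp$stratum, so$stratum))
    out$bias <- do.call(rbind, lapply(split(seq_len(nrow(sp)), sp$stratum),
      function(i) {
        do.call(rbind, lapply(qty_cols, function(qc) {
          scale <- if (qc == "median_days") 1 else 100   # pp for probs
          data.frame(stratum = sp$stratum[i][1],
                     quantity = if (qc == "median_days") qc
                                else paste0(qc, "_pp"),
                     t(smry(scale * (sp[[qc]][i] - so[[qc]][i]))))
        }))
      }))
    rownames(out$bias) <- NULL
  }
  out
}
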