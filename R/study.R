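#' Run a Monte Carlo simulation study
#'
#' Reproduces the full simulation pipeline across scenarios and
#' replicates. For each replicate: generate a cohort, fit the probability
#' estimator (on the whole development cohort for the naive methods; on
#' the first development half for the weighted method), estimate conformal
#' thresholds on the calibration half, apply everything to the validation
#' cohort, and run the requested methods. Per-replicate records of
#' coverage, thresholds, ambiguity, classification metrics, and survival
#' bias are stored so that every summary table can be recomputed from
#' them.
#'
#' @param config a calibrated [sim_config()].
#' @param scenarios integer subset of `1:3`.
#' @param n_reps simulation repetitions per scenario.
#' @param n_boot bootstrap resamples for the bootstrap-based methods.
#' @param methods subset of `c("standard", "naive", "weighted")`.
#' @param alphas per-class conformal error levels.
#' @param seed root seed; replicate seeds are spawned from it so results
#'   do not depend on execution order.
#' @param horizons survival horizons in days.
#' @param survival compute survival outcomes.
#' @param estimator estimator spec passed to [fit_prob_estimator()].
#' @return An object of class `"study_result"`: list of per-replicate
#'   record data frames (`coverage`, `thresholds`, `ambiguity`, `metrics`,
#'   `survival_bias`), a `failures` data frame, and `meta`.
#' @export
run_study <- function(config = sim_config(), scenarios = 1:3,
                      n_reps = 1000, n_boot = 500,
                      methods = c("standard", "naive", "weighted"),
                      alphas = 0.10, seed = 1L, horizons = c(90, 365),
                      survival = TRUE, estimator = "multinom") {
  if (!config$calibrated)
    stop("config is not calibrated; run calibrate_scenarios() first")
  methods <- match.arg(methods, several.ok = TRUE)
  rep_seeds <- matrix(child_seeds(seed, length(scenarios) * n_reps),
                      nrow = length(scenarios))
  recs <- list(coverage = list(), thresholds = list(), ambiguity = list(),
               metrics = list(), survival_bias = list())
  failures <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    for (r in seq_len(n_reps)) {
      res <- tryCatch(
        run_replicate(sc, config, rep_seeds[si, r], methods, alphas,
                      n_boot, horizons, survival, estimator),
        error = function(e)
          structure(list(message = conditionMessage(e)), class = "rep_fail"))
      if (inherits(res, "rep_fail")) {
        failures[[length(failures) + 1L]] <-
          data.frame(scenario = sc, replicate = r,
                     seed = rep_seeds[si, r], message = res$message)
        next
      }
      tag <- function(df) cbind(scenario = sc, replicate = r, df)
      for (nm in names(recs))
        if (!is.null(res[[nm]]))
          recs[[nm]][[length(recs[[nm]]) + 1L]] <- tag(res[[nm]])
    }
  }
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(scenario = integer(), replicate = integer(),
                              seed = integer(), message = character())
  if (nrow(failures) > 0.01 * length(scenarios) * n_reps)
    stop("more than 1% of replicates failed; first message: ",
         failures$message[1])
  out <- lapply(recs, function(l) {
    d <- do.call(rbind, l)
    rownames(d) <- NULL
    d
  })
  out$failures <- failures
  out$meta <- list(scenarios = scenarios, n_reps = n_reps, n_boot = n_boot,
                   methods = methods, alphas = alphas, seed = seed,
                   horizons = horizons, estimator = estimator,
                   label_redraw = "independent per resampled row")
  structure(out, class = "study_result")
}

# one scenario replicate: all methods on one simulated data set
run_replicate <- function(scenario, config, seed, methods, alphas,
                          n_boot, horizons, survival, estimator) {
  rep_ <- make_replicate(scenario, config, seed)
  fs <- rep_$feature_set
  val <- rep_$validation
  val_x <- val$features[, fs, drop = FALSE]
  K <- val$n_classes
  out <- list()
  add <- function(lst, df) if (is.null(lst)) df else rbind(lst, df)

  if (any(c("standard", "naive") %in% methods)) {
    fit_n <- fit_prob_estimator(subset_features(rep_$development, fs),
                                spec = estimator)
    probs_n <- predict_proba(fit_n, val_x)
    y_hat <- naive_labels(probs_n)
    pc <- per_class_measures(confusion_counts(val$labels, y_hat, K))
    # naive coverage: the single assigned label contains the truth or not,
    # identical for both naive methods (computed before any resampling)
    out$coverage <- data.frame(method = "naive", class = pc$class,
                               coverage = pc$sensitivity)
    mac <- suppressWarnings(macro_measures(pc))
    out$metrics <- data.frame(
      method = "naive", class = c(as.character(pc$class), "macro", "plain"),
      accuracy = c(pc$accuracy, mac["accuracy"],
                   plain_accuracy(val$labels, y_hat)),
      sensitivity = c(pc$sensitivity, mac["sensitivity"], NA),
      specificity = c(pc$specificity, mac["specificity"], NA),
      ppv = c(pc$ppv, mac["ppv"], NA))
    if ("standard" %in% methods && survival) {
      std <- suppressWarnings(run_standard_practice(val, probs_n, horizons))
      b <- std$bias
      out$survival_bias <- add(out$survival_bias,
        data.frame(method = "standard", stratum = b$stratum,
                   quantity = b$quantity, bias = b$bias))
    }
    if ("naive" %in% methods && survival) {
      nb <- run_naive_bootstrap(val, probs_n, n_boot = n_boot, seed = seed,
                                horizons = horizons)
      bs <- summarize_bootstrap(nb)$bias
      out$survival_bias <- add(out$survival_bias,
        data.frame(method = "naive", stratum = bs$stratum,
                   quantity = bs$quantity, bias = bs$mean))
    }
  }

  if ("weighted" %in% methods) {
    sp <- split_development(rep_$development, seed = seed)
    d1 <- rep_$development[sp$part1]
    d2 <- rep_$development[sp$part2]
    fit_w <- fit_prob_estimator(subset_features(d1, fs), spec = estimator)
    p2 <- predict_proba(fit_w, d2$features[, fs, drop = FALSE])
    th <- estimate_thresholds(p2, d2$labels, alphas)
    probs_w <- predict_proba(fit_w, val_x)
    sets <- assign_label_sets(probs_w, th)
    out$coverage <- add(out$coverage,
      data.frame(method = "weighted", class = seq_len(K),
                 coverage = empirical_coverage(sets, val$labels)))
    out$thresholds <- data.frame(class = seq_len(K),
                                 threshold = th$thresholds)
    amb <- ambiguity_distribution(sets, val$labels)
    out$ambiguity <- amb
    wb <- run_weighted_bootstrap(val, probs_w, th, n_boot = n_boot,
                                 seed = seed, horizons = horizons,
                                 survival = survival)
    ws <- summarize_bootstrap(wb)
    m <- ws$metrics
    out$metrics <- add(out$metrics,
      data.frame(method = "weighted", class = m$class[m$measure == "accuracy"],
                 accuracy = m$mean[m$measure == "accuracy"],
                 sensitivity = m$mean[m$measure == "sensitivity"],
                 specificity = m$mean[m$measure == "specificity"],
                 ppv = m$mean[m$measure == "ppv"]))
    if (survival)
      out$survival_bias <- add(out$survival_bias,
        data.frame(method = "weighted", stratum = ws$bias$stratum,
                   quantity = ws$bias$quantity, bias = ws$bias$mean))
  }
  out
}

#' Summarize a simulation study into publication-style tables
#'
#' Aggregates the stored per-replicate records into: a coverage table with
#' means and Monte Carlo SEs (the SD of per-replicate coverages, not the
#' SE of the mean), a thresholds table, ambiguity shares overall and by
#' true class, a macro metrics table, and a survival bias table with
#' percentile 95% intervals across replicates. All tables are recomputable
#' deterministically from the per-replicate records.
#'
#' @param result a [run_study()] result.
#' @return A list of data frames: `coverage`, `thresholds`, `ambiguity`,
#'   `metrics`, `survival_bias`.
#' @export
summarize_study <- function(result) {
  stopifnot(inherits(result, "study_result"))
  agg <- function(df, keys, value) {
    if (is.null(df)) return(NULL)
    sp <- split(df, df[keys], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
      v <- d[[value]][!is.na(d[[value]])]
      cbind(d[1L, keys, drop = FALSE],
            data.frame(
              mean = if (length(v)) mean(v) else NA_real_,
              mc_se = if (length(v) > 1) stats::sd(v) else NA_real_,
              lower = if (length(v)) unname(stats::quantile(v, 0.025))
                      else NA_real_,
              upper = if (length(v)) unname(stats::quantile(v, 0.975))
                      else NA_real_,
              n_reps = length(v)))
    }))
    rownames(out) <- NULL
    out
  }
  list(
    coverage = agg(result$coverage,
                   c("scenario", "method", "class"), "coverage"),
    thresholds = agg(result$thresholds,
                     c("scenario", "class"), "threshold"),
    ambiguity = agg(result$ambiguity,
                    c("scenario", "class", "set_size"), "proportion"),
    metrics = agg(result$metrics,
                  c("scenario", "method", "class"), "accuracy"),
    survival_bias = agg(result$survival_bias,
                        c("scenario", "method", "stratum", "quantity"),
                        "bias"))
}

#' Apply the classification-and-survival pipeline to user cohorts
#'
#' Deployment-pattern entry point for tabular data: the development file
#' must carry labels; the validation file may omit them (label sets and
#' predicted-class survival only). The development cohort is split in
#' half, the estimator fitted on one half and conformal thresholds
#' calibrated on the other; sets, coverage (when validation labels exist),
#' the requested method outputs, and survival summaries are returned.
#'
#' @param development a labeled [cohort()] (or path to a CSV readable via
#'   the `schema`).
#' @param validation a [cohort()] or CSV path.
#' @param schema for CSV input: list with `feature_cols` and optionally
#'   `label_col`, `time_col`, `event_col`, `n_classes`.
#' @param alphas per-class conformal error levels.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param horizons survival horizons in days.
#' @param estimator estimator spec for [fit_prob_estimator()].
#' @return A list with `thresholds`, `sets`, `coverage`, `standard`,
#'   `naive_boot`, `weighted_boot`, `survival_predicted`.
#' @export
apply_to_cohort <- function(development, validation, schema = NULL,
                            alphas = 0.10, n_boot = 500, seed = 1L,
                            horizons = c(90, 365), estimator = "multinom") {
  load_one <- function(x) {
    if (inherits(x, "cohort")) return(x)
    if (is.null(schema)) stop("a schema is required for CSV input")
    read_cohort(x, schema$feature_cols, schema$label_col,
                schema$time_col, schema$event_col, schema$n_classes)
  }
  dev <- load_one(development)
  val <- load_one(validation)
  if (is.null(dev$labels)) stop("development cohort must carry labels")
  if (!identical(colnames(dev$features), colnames(val$features)))
    stop("development and validation feature columns differ: ",
         paste(union(setdiff(colnames(dev$features), colnames(val$features)),
                     setdiff(colnames(val$features), colnames(dev$features))),
               collapse = ", "))
  if (is.na(val$n_classes)) val$n_classes <- dev$n_classes
  have_labels <- !is.null(val$labels)
  have_surv <- !is.null(val$time)
  if (!have_surv)
    warning("no survival columns on the validation cohort; ",
            "survival estimation skipped", call. = FALSE)
  sp <- split_development(dev, seed = seed)
  fit_w <- fit_prob_estimator(dev[sp$part1], spec = estimator)
  p2 <- predict_proba(fit_w, dev$features[sp$part2, , drop = FALSE])
  th <- estimate_thresholds(p2, dev$labels[sp$part2], alphas)
  probs_w <- predict_proba(fit_w, val$features)
  sets <- assign_label_sets(probs_w, th)
  fit_n <- fit_prob_estimator(dev, spec = estimator)
  probs_n <- predict_proba(fit_n, val$features)
  out <- list(thresholds = th, sets = sets,
              ambiguity = ambiguity_distribution(sets, val$labels),
              naive_labels = naive_labels(probs_n))
  if (have_labels) {
    out$coverage <- empirical_coverage(sets, val$labels)
    if (have_surv) {
      out$standard <- run_standard_practice(val, probs_n, horizons)
      out$naive_boot <- summarize_bootstrap(
        run_naive_bootstrap(val, probs_n, n_boot, seed, horizons))
      out$weighted_boot <- summarize_bootstrap(
        run_weighted_bootstrap(val, probs_w, th, n_boot, seed, horizons))
    }
  } else if (have_surv) {
    # deployment mode: survival by predicted class only
    out$survival_predicted <- stratified_summaries(
      val$time, val$event, naive_labels(probs_n), val$n_classes, horizons)
  }
  out
}
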