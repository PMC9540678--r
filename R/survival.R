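#' Kaplan-Meier product-limit fit
#'
#' Fits the product-limit estimator \eqn{\hat S(t) = \prod_{t_i \le t}
#' (1 - d_i / n_i)} via [survival::survfit()] and re-expresses it as a
#' step function over the distinct event times, with at-risk counts,
#' event counts, and the Greenwood variance
#' \eqn{\hat S(t)^2 \sum_{t_i \le t} d_i / (n_i (n_i - d_i))}
#' accumulated per event time. Deaths precede censorings at tied times
#' (the standard product-limit convention).
#'
#' @param time nonnegative observed times in days.
#' @param event event indicators (1 = event, 0 = censored).
#' @return An object of class `"km_curve"`: list with `event_times`,
#'   `survival`, `at_risk`, `events`, `greenwood_var`, `n`, `max_time`.
#' @examples
#' km_fit(c(10, 20, 30), c(1, 0, 1))
#' @export
km_fit <- function(time, event) {
  time <- as.numeric(time)
  if (length(time) == 0L) stop("at least one observation is required")
  if (any(time < 0)) stop("negative survival times")
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain")
  keep <- fit$n.event > 0
  gw_var <- (fit$surv * fit$std.err)^2   # survfit std.err is se(log S)
  structure(
    list(event_times = fit$time[keep],
         survival = fit$surv[keep],
         at_risk = fit$n.risk[keep],
         events = fit$n.event[keep],
         greenwood_var = gw_var[keep],
         n = length(time),
         max_time = max(time)),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, ",", length(x$event_times), "event times\n")
  invisible(x)
}

# step-function lookup at time h: value at the largest event time <= h
km_step <- function(curve, h, what = c("survival", "greenwood_var")) {
  what <- match.arg(what)
  init <- if (what == "survival") 1 else 0
  i <- findInterval(h, curve$event_times)
  if (i == 0L) init else curve[[what]][i]
}

#' Survival summaries from a fitted curve
#'
#' Median survival is the smallest event time with \eqn{\hat S(t) \le 0.5},
#' reported missing (`NA`) when the curve never reaches 0.5 within
#' follow-up. Horizon survival probabilities are read off the step
#' function; a horizon beyond the last observed time returns the value at
#' the last time with a warning.
#'
#' @param curve a [km_fit()].
#' @param horizons numeric times (days) at which to report survival.
#' @param level confidence level for the Greenwood intervals.
#' @return A one-row data frame: `n_obs`, `median_days`, and per horizon h
#'   `surv_h`, `surv_h_lo`, `surv_h_hi`.
#' @export
km_summary <- function(curve, horizons = c(90, 365), level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  below <- which(curve$survival <= 0.5)
  med <- if (length(below)) curve$event_times[below[1L]] else NA_real_
  out <- data.frame(n_obs = curve$n, median_days = med)
  for (h in horizons) {
    if (h > curve$max_time)
      warning("horizon ", h, " beyond last observed time ", curve$max_time,
              "; reporting survival at the last time", call. = FALSE)
    ci <- greenwood_ci(curve, h, level = level)
    out[[paste0("surv_", h)]] <- ci["estimate"]
    out[[paste0("surv_", h, "_lo")]] <- ci["lower"]
    out[[paste0("surv_", h, "_hi")]] <- ci["upper"]
  }
  rownames(out) <- NULL
  out
}

#' Greenwood confidence interval for a survival probability
#'
#' Plain-scale normal interval \eqn{\hat S(h) \pm z \sqrt{\widehat{\mathrm
#' {Var}}\,\hat S(h)}} with the Greenwood variance, truncated to
#' \eqn{[0, 1]}. With no events before the horizon the variance is zero
#' and the interval degenerates at 1.
#'
#' @param curve a [km_fit()].
#' @param horizon time in days.
#' @param level confidence level in (0, 1).
#' @return Named numeric vector `estimate`, `lower`, `upper`.
#' @export
greenwood_ci <- function(curve, horizon, level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  s <- km_step(curve, horizon, "survival")
  v <- km_step(curve, horizon, "greenwood_var")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate = s,
    lower = max(0, s - z * sqrt(v)),
    upper = min(1, s + z * sqrt(v)))
}

#' Stratified Kaplan-Meier summaries
#'
#' One product-limit fit and summary per class stratum (e.g. by observed
#' or by predicted class label). Empty strata yield a row of `NA`.
#'
#' @param time,event survival outcome vectors.
#' @param strata_labels integer class labels in `1..n_classes` defining
#'   the strata.
#' @param n_classes number of strata K.
#' @param horizons survival-probability horizons in days.
#' @param level confidence level for Greenwood intervals.
#' @return A K-row data frame: `stratum` plus the [km_summary()] columns.
#' @export
stratified_summaries <- function(time, event, strata_labels,
                                 n_classes = max(strata_labels),
                                 horizons = c(90, 365), level = 0.95) {
  strata_labels <- as.integer(strata_labels)
  rows <- lapply(seq_len(n_classes), function(y) {
    i <- which(strata_labels == y)
    if (!length(i)) {
      out <- data.frame(n_obs = 0L, median_days = NA_real_)
      for (h in horizons) {
        out[[paste0("surv_", h)]] <- NA_real_
        out[[paste0("surv_", h, "_lo")]] <- NA_real_
        out[[paste0("surv_", h, "_hi")]] <- NA_real_
      }
      return(cbind(stratum = y, out))
    }
    cbind(stratum = y,
          km_summary(km_fit(time[i], event[i]), horizons, level))
  })
  do.call(rbind, rows)
}

#' Bias of predicted-class survival estimates against observed-class
#'
#' Compares stratified survival summaries computed under predicted class
#' labels with those computed under the observed (true) labels. Median
#' bias is reported in days; survival-probability bias in percentage
#' points (difference of survival probabilities times 100), with a
#' relative-percent column for completeness. Missing medians propagate a
#' missing bias with a reason code.
#'
#' @param pred_summaries,obs_summaries results of [stratified_summaries()]
#'   under predicted and observed labels (same strata and horizons).
#' @return A data frame per stratum and quantity with columns `stratum`,
#'   `quantity`, `predicted`, `observed`, `bias`, `relative_pct`, `reason`.
#' @export
survival_bias <- function(pred_summaries, obs_summaries) {
  stopifnot(identical(pred_summaries$stratum, obs_summaries$stratum))
  surv_cols <- grep("^surv_[0-9]+$", names(pred_summaries), value = TRUE)
  rows <- lapply(seq_len(nrow(pred_summaries)), function(i) {
    p <- pred_summaries[i, ]
    o <- obs_summaries[i, ]
    med <- data.frame(
      stratum = p$stratum, quantity = "median_days",
      predicted = p$median_days, observed = o$median_days,
      bias = p$median_days - o$median_days,
      relative_pct = if (!is.na(o$median_days) && o$median_days != 0)
        100 * (p$median_days - o$median_days) / o$median_days
      else NA_real_,
      reason = if (is.na(p$median_days) || is.na(o$median_days))
        "median not reached" else "")
    probs <- do.call(rbind, lapply(surv_cols, function(cl) {
      data.frame(
        stratum = p$stratum, quantity = paste0(cl, "_pp"),
        predicted = p[[cl]], observed = o[[cl]],
        bias = 100 * (p[[cl]] - o[[cl]]),
        relative_pct = if (!is.na(o[[cl]]) && o[[cl]] != 0)
          100 * (p[[cl]] - o[[cl]]) / o[[cl]] else NA_real_,
        reason = if (is.na(p[[cl]]) || is.na(o[[cl]])) "empty stratum"
        else "")
    }))
    rbind(med, probs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
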