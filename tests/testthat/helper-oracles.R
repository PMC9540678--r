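# Independent oracles used to cross-check the implementation.

# Brute-force conformal threshold: scan every candidate calibration
# probability of the class and test the displayed rank condition directly.
oracle_threshold <- function(p_true_class, alpha) {
  m <- length(p_true_class)
  ok <- vapply(p_true_class, function(cand) {
    sum(p_true_class <= cand) > (m + 1) * alpha - 1
  }, logical(1))
  min(p_true_class[ok])
}

# Hand product-limit estimator: deaths before censorings at tied times.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  gw <- numeric(length(ts))
  acc <- 0
  for (k in seq_along(ts)) {
    n_at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n_at_risk)
    acc <- acc + d / (n_at_risk * (n_at_risk - d))
    surv[k] <- s
    gw[k] <- s^2 * acc
  }
  list(event_times = ts, survival = surv, greenwood_var = gw)
}

# Survival step-function lookup on a km_curve.
km_step_surv <- function(cv, h) {
  i <- findInterval(h, cv$event_times)
  if (i == 0L) 1 else cv$survival[i]
}

# Small labeled cohort with survival outcomes for pipeline tests.
toy_cohort <- function(n = 90, seed = 7, K = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  labels <- sample.int(K, n, replace = TRUE, prob = c(.4, .4, .2))
  time <- pmin(rexp(n, rate = labels / 60), 365)
  event <- as.integer(time < 365)
  cohort(x, labels = labels, time = time, event = event, n_classes = K)
}
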