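test_that("product-limit estimate matches hand calculation", {
  cv <- km_fit(c(10, 20, 30), c(1, 1, 1))
  expect_equal(cv$event_times, c(10, 20, 30))
  expect_equal(cv$survival, c(2 / 3, 1 / 3, 0))

  cv2 <- km_fit(c(10, 20, 30), c(1, 0, 1))
  expect_equal(cv2$event_times, c(10, 30))
  expect_equal(cv2$survival, c(2 / 3, 0))   # 1 at risk after censoring
  expect_equal(cv2$at_risk, c(3, 1))

  cv3 <- km_fit(c(5, 6, 7), c(0, 0, 0))
  expect_length(cv3$event_times, 0)
  expect_equal(km_step_surv(cv3, 100), 1)
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("without censoring the curve equals the empirical survival", {
  set.seed(17)
  t <- round(rexp(80, 1 / 50), 1)
  cv <- km_fit(t, rep(1, 80))
  for (h in c(0, 10, 50, 120))
    expect_equal(km_step_surv(cv, h), mean(t > h))
})

test_that("greenwood variance matches the brute-force sum", {
  set.seed(23)
  for (r in 1:10) {
    n <- sample(5:60, 1)
    t <- sample(1:20, n, replace = TRUE)   # heavy ties
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    cv <- km_fit(t, e)
    oracle <- oracle_km(t, e)
    expect_equal(cv$event_times, oracle$event_times)
    expect_equal(cv$survival, oracle$survival)
    expect_equal(cv$greenwood_var, oracle$greenwood_var, tolerance = 1e-10)
  }
})

test_that("greenwood interval uses the hand-computed variance", {
  # n = 4, all events; after 2 events S = 0.5
  cv <- km_fit(c(1, 2, 3, 4), rep(1, 4))
  v_hand <- 0.5^2 * (1 / (4 * 3) + 1 / (3 * 2))
  ci <- greenwood_ci(cv, 2.5)
  expect_equal(unname(ci["estimate"]), 0.5)
  expect_equal(unname(ci["upper"] - ci["estimate"]),
               qnorm(0.975) * sqrt(v_hand))
  # before any event: variance 0, degenerate interval at 1
  ci0 <- greenwood_ci(cv, 0.5)
  expect_equal(unname(ci0), c(1, 1, 1))
  # truncation to [0, 1]
  cv2 <- km_fit(c(1, 2), c(1, 0))
  ci2 <- greenwood_ci(cv2, 1.5)
  expect_gte(ci2["lower"], 0)
  expect_lte(ci2["upper"], 1)
  expect_error(greenwood_ci(cv, 1, level = 1.2), "level")
})

test_that("median is the first time the curve falls to or below 0.5", {
  cv <- km_fit(c(10, 20, 30, 40), rep(1, 4))   # S: .75 .5 .25 0
  expect_equal(km_summary(cv, horizons = 15)$median_days, 20)
  cv2 <- km_fit(c(10, 20, 30, 40), c(1, 0, 0, 0))  # S stays at 0.75
  expect_true(is.na(km_summary(cv2, horizons = 15)$median_days))
  expect_warning(s <- km_summary(cv, horizons = 90), "beyond")
  expect_equal(s$surv_90, 0)   # step function past the last event
})

test_that("stratified summaries equal per-subset fits", {
  ch <- toy_cohort(n = 150, seed = 6)
  # follow-up in the toy data ends before day 365; the horizon warning is
  # expected on both computation paths and not under test
  s <- suppressWarnings(
    stratified_summaries(ch$time, ch$event, ch$labels, 3,
                         horizons = c(90, 365)))
  for (y in 1:3) {
    i <- ch$labels == y
    direct <- suppressWarnings(
      km_summary(km_fit(ch$time[i], ch$event[i]), horizons = c(90, 365)))
    expect_equal(s$median_days[y], direct$median_days)
    expect_equal(s$surv_90[y], direct$surv_90)
  }
  # single stratum equals the unstratified fit
  s1 <- stratified_summaries(ch$time, ch$event, rep(1L, ch$n), 1,
                             horizons = 90)
  expect_equal(s1$surv_90, km_summary(km_fit(ch$time, ch$event), 90)$surv_90)
  # an empty stratum is reported missing
  s2 <- stratified_summaries(ch$time, ch$event, rep(1L, ch$n), 2,
                             horizons = 90)
  expect_true(is.na(s2$median_days[2]))
  expect_equal(s2$n_obs[2], 0L)
})

test_that("identical stratifications have zero survival bias", {
  ch <- toy_cohort(n = 120, seed = 8)
  obs <- suppressWarnings(
    stratified_summaries(ch$time, ch$event, ch$labels, 3))
  b0 <- survival_bias(obs, obs)
  expect_true(all(b0$bias[!is.na(b0$bias)] == 0))
})

test_that("bias of one misclassified row matches hand recomputation", {
  time <- c(10, 20, 100, 110, 120, 130)
  event <- rep(1, 6)
  obs_lab <- c(1, 1, 1, 2, 2, 2)
  pred_lab <- c(1, 1, 2, 2, 2, 2)     # row 3 moves stratum 1 -> 2
  # the 90-day horizon deliberately exceeds stratum 1's last event time
  so <- suppressWarnings(
    stratified_summaries(time, event, obs_lab, 2, horizons = 90))
  sp <- suppressWarnings(
    stratified_summaries(time, event, pred_lab, 2, horizons = 90))
  b <- survival_bias(sp, so)
  # stratum 1 medians: observed {10,20,100} -> 20; predicted {10,20} -> 10
  expect_equal(b$bias[b$stratum == 1 & b$quantity == "median_days"],
               10 - 20)
  # stratum 2 medians: observed {110,120,130} -> 120;
  # predicted {100,110,120,130}: S(110) = 0.5 -> median 110
  expect_equal(b$bias[b$stratum == 2 & b$quantity == "median_days"],
               110 - 120)
  # stratum 1 90-day survival: observed 1/3, predicted 0
  expect_equal(b$bias[b$stratum == 1 & b$quantity == "surv_90_pp"],
               100 * (0 - 1 / 3))
})

test_that("class-stratified curves recover the generating exponential", {
  cfg <- sim_config(survival_effect = 0.3)
  set.seed(77)
  n <- 30000
  labels <- rep(1:3, length.out = n)
  sv <- generate_survival(labels, cfg)
  for (y in 1:3) {
    i <- labels == y
    cv <- km_fit(sv$time[i], sv$event[i])
    scale_y <- 90 * exp(-y * 0.3)
    for (h in c(30, 90, 200, 330)) {
      expect_lt(abs(km_step_surv(cv, h) - exp(-h / scale_y)), 0.02)
    }
  }
})
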