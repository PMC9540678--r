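test_that("argmax labeling breaks ties toward the lowest class", {
  p <- rbind(c(0.2, 0.5, 0.3), c(0.4, 0.4, 0.2), diag(3))
  expect_equal(naive_labels(p), c(2L, 1L, 1L, 2L, 3L))
})

test_that("label selection is uniform over the set (null -> full space)", {
  expect_equal(replicate(20, select_label(c(FALSE, TRUE, FALSE))),
               rep(2L, 20))
  set.seed(101)
  n_draw <- 20000
  pair <- replicate(n_draw, select_label(c(TRUE, FALSE, TRUE)))
  expect_setequal(unique(pair), c(1L, 3L))
  se2 <- sqrt(0.5 * 0.5 / n_draw)
  expect_lt(abs(mean(pair == 1) - 0.5), 3 * se2)
  nul <- replicate(n_draw, select_label(c(FALSE, FALSE, FALSE)))
  se3 <- sqrt((1 / 3) * (2 / 3) / n_draw)
  for (y in 1:3) expect_lt(abs(mean(nul == y) - 1 / 3), 3 * se3)
  trip <- replicate(n_draw, select_label(c(TRUE, TRUE, TRUE)))
  for (y in 1:3) expect_lt(abs(mean(trip == y) - 1 / 3), 3 * se3)
  expect_error(select_label(TRUE), "2 classes")
})

test_that("weighted and naive bootstraps coincide for argmax singletons", {
  ch <- toy_cohort(n = 60, seed = 44)
  # degenerate probabilities: every conformal set is the argmax singleton
  p <- matrix(0.025, 60, 3)
  p[cbind(1:60, ch$labels)] <- 0.95
  th <- structure(list(thresholds = rep(0.5, 3), alphas = rep(0.1, 3),
                       calibration_sizes = rep(20L, 3)),
                  class = "threshold_set")
  w <- run_weighted_bootstrap(ch, p, th, n_boot = 5, seed = 9)
  expect_true(all(assign_label_sets(p, th)$set_size == 1))
  nv <- run_naive_bootstrap(ch, p, n_boot = 5, seed = 9)
  expect_identical(w$draws$indices, nv$draws$indices)
  expect_identical(w$draws$labels, nv$draws$labels)
  expect_equal(w$metrics, nv$metrics)
})

test_that("bootstrap runs are reproducible from the root seed", {
  ch <- toy_cohort(n = 50, seed = 3)
  fit <- fit_prob_estimator(ch)
  p <- predict_proba(fit, ch$features)
  th <- estimate_thresholds(p, ch$labels, 0.1)
  r1 <- run_weighted_bootstrap(ch, p, th, n_boot = 8, seed = 21)
  r2 <- run_weighted_bootstrap(ch, p, th, n_boot = 8, seed = 21)
  expect_equal(r1$draws, r2$draws)
  expect_equal(r1$metrics, r2$metrics)
  expect_equal(r1$survival, r2$survival)
  r3 <- run_weighted_bootstrap(ch, p, th, n_boot = 8, seed = 22)
  expect_false(identical(r1$draws, r3$draws))
})

test_that("naive labels never change per original row across resamples", {
  ch <- toy_cohort(n = 40, seed = 13)
  fit <- fit_prob_estimator(ch)
  p <- predict_proba(fit, ch$features)
  run <- run_naive_bootstrap(ch, p, n_boot = 10, seed = 5,
                             survival = FALSE)
  fixed <- run$labels_fixed
  for (b in 1:10)
    expect_equal(run$draws$labels[b, ], fixed[run$draws$indices[b, ]])
  acc <- run$metrics$accuracy[run$metrics$class == "plain"]
  expect_gt(stats::sd(acc), 0)   # resampling varies the metric
})

test_that("identity resample reproduces standard practice exactly", {
  ch <- toy_cohort(n = 70, seed = 19)
  fit <- fit_prob_estimator(ch)
  p <- predict_proba(fit, ch$features)
  std <- suppressWarnings(run_standard_practice(ch, p))
  run <- run_naive_bootstrap(ch, p, n_boot = 1, seed = 2,
                             .resample = function(n) seq_len(n))
  m <- run$metrics
  expect_equal(m$accuracy[m$class == "plain"], std$plain_accuracy)
  expect_equal(m$accuracy[m$class == "macro"],
               unname(std$macro["accuracy"]))
  expect_equal(m$sensitivity[m$class == "2"], std$per_class$sensitivity[2])
  s <- run$survival
  expect_equal(s$median_days[s$stratification == "predicted"],
               std$survival_predicted$median_days)
})

test_that("standard practice on perfect probabilities is unbiased", {
  ch <- toy_cohort(n = 80, seed = 31)
  p <- matrix(1e-9, 80, 3)
  p[cbind(1:80, ch$labels)] <- 1 - 2e-9
  std <- suppressWarnings(run_standard_practice(ch, p))
  expect_equal(std$plain_accuracy, 1)
  expect_equal(unname(std$macro), rep(1, 4))
  expect_true(all(std$bias$bias[!is.na(std$bias$bias)] == 0))
  expect_null(std$draws)   # no resampling distribution
})

test_that("bootstrap summaries match recomputation from stored resamples", {
  ch <- toy_cohort(n = 60, seed = 55)
  fit <- fit_prob_estimator(ch)
  p <- predict_proba(fit, ch$features)
  th <- estimate_thresholds(p, ch$labels, 0.1)
  run <- run_weighted_bootstrap(ch, p, th, n_boot = 40, seed = 77)
  sm <- summarize_bootstrap(run)
  acc <- run$metrics$accuracy[run$metrics$class == "macro"]
  row <- sm$metrics[sm$metrics$class == "macro" &
                    sm$metrics$measure == "accuracy", ]
  expect_equal(row$mean, mean(acc))
  expect_equal(row$lower, unname(quantile(acc, 0.025)))
  expect_equal(row$upper, unname(quantile(acc, 0.975)))
  # per-resample metrics re-derivable from the stored draws
  b <- 17
  y_true <- ch$labels[run$draws$indices[b, ]]
  y_sel <- run$draws$labels[b, ]
  expect_equal(
    run$metrics$accuracy[run$metrics$resample == b &
                         run$metrics$class == "plain"],
    plain_accuracy(y_true, y_sel))
  expect_error(run_weighted_bootstrap(ch, p, th, n_boot = 0), "n_boot")
})
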