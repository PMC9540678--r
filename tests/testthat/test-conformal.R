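make_probs <- function(p_class, labels, K = 3) {
  # embed per-observation true-class probabilities into a valid matrix
  n <- length(p_class)
  probs <- matrix((1 - p_class) / (K - 1), n, K)
  probs[cbind(seq_len(n), labels)] <- p_class
  probs
}

# append one anchor row per remaining class so every class has a
# calibration observation (their thresholds are not inspected)
with_anchor_rows <- function(probs, labels, K = 3) {
  anchors <- matrix(1 / K, K - 1, K)
  list(probs = rbind(probs, anchors),
       labels = c(labels, setdiff(seq_len(K), labels[1])))
}

test_that("threshold rule reproduces worked rank-condition examples", {
  p9 <- seq(0.1, 0.9, by = 0.1)
  a9 <- with_anchor_rows(make_probs(p9, rep(1L, 9)), rep(1L, 9))
  th <- estimate_thresholds(a9$probs, a9$labels, alphas = c(0.1, 0, 0))
  # count > (9+1)*0.1 - 1 = 0 holds already at the minimum
  expect_equal(th$thresholds[1], 0.1)
  p3 <- c(0.2, 0.5, 0.8)
  a3 <- with_anchor_rows(make_probs(p3, rep(1L, 3)), rep(1L, 3))
  th <- estimate_thresholds(a3$probs, a3$labels, alphas = c(0.5, 0, 0))
  # count > (3+1)*0.5 - 1 = 1 first holds at the second smallest
  expect_equal(th$thresholds[1], 0.5)
  # a class with no calibration observations has no estimable threshold
  expect_error(estimate_thresholds(make_probs(p3, rep(1L, 3)),
                                   rep(1L, 3), 0.1), "class 2 absent")
})

test_that("alpha = 0 returns the class minimum and full coverage", {
  set.seed(21)
  for (r in 1:5) {
    labels <- sample.int(3, 60, replace = TRUE)
    p <- matrix(rexp(180), 60, 3)
    p <- p / rowSums(p)
    th <- estimate_thresholds(p, labels, alphas = 0)
    for (y in 1:3)
      expect_equal(th$thresholds[y], min(p[cbind(which(labels == y), y)]))
    cov <- empirical_coverage(assign_label_sets(p, th), labels)
    expect_equal(cov, rep(1, 3))
  }
})

test_that("thresholds match the brute-force oracle, ties included", {
  set.seed(42)
  for (r in 1:60) {
    m <- sample(2:50, 1)
    # coarse grid forces ties among calibration probabilities
    p_true <- sample(seq(0.05, 0.95, by = 0.05), m, replace = TRUE)
    alpha <- runif(1, 0, 0.9)
    a <- with_anchor_rows(make_probs(p_true / 2, rep(1L, m)), rep(1L, m))
    th <- estimate_thresholds(a$probs, a$labels, alphas = c(alpha, 0, 0))
    expect_equal(th$thresholds[1], oracle_threshold(p_true / 2, alpha),
                 info = sprintf("m=%d alpha=%.3f", m, alpha))
  }
})

test_that("raising alpha weakly raises thresholds and shrinks sets", {
  set.seed(9)
  labels <- sample.int(3, 120, replace = TRUE)
  p <- matrix(rexp(360), 120, 3)
  p <- p / rowSums(p)
  alphas <- c(0, 0.05, 0.1, 0.25, 0.5, 0.8)
  prev_t <- rep(-Inf, 3)
  prev_member <- matrix(TRUE, 120, 3)
  for (a in alphas) {
    th <- estimate_thresholds(p, labels, alphas = a)
    expect_true(all(th$thresholds >= prev_t))
    member <- assign_label_sets(p, th)$member
    expect_true(all(member <= prev_member))   # sets only shrink
    prev_t <- th$thresholds
    prev_member <- member
  }
})

test_that("thresholds are invariant to calibration row order", {
  set.seed(5)
  labels <- sample.int(3, 80, replace = TRUE)
  p <- matrix(rexp(240), 80, 3)
  p <- p / rowSums(p)
  th1 <- estimate_thresholds(p, labels, 0.1)
  perm <- sample.int(80)
  th2 <- estimate_thresholds(p[perm, ], labels[perm], 0.1)
  expect_equal(th1$thresholds, th2$thresholds)
})

test_that("label sets use inclusive comparison and allow null sets", {
  th <- structure(list(thresholds = c(0.40, 0.25, 0.25),
                       alphas = rep(0.1, 3),
                       calibration_sizes = rep(10L, 3)),
                  class = "threshold_set")
  probs <- rbind(c(0.50, 0.30, 0.20),
                 c(0.80, 0.10, 0.10),
                 c(0.40, 0.35, 0.25))   # exact ties at every threshold
  sets <- assign_label_sets(probs, th)
  expect_equal(sets$set_size, c(2L, 1L, 3L))
  expect_true(all(sets$member[3, ]))    # equality means membership
  sets0 <- assign_label_sets(rbind(c(0.40, 0.35, 0.25)),
                             c(0.50, 0.50, 0.50))
  expect_equal(sets0$set_size, 0L)      # null set preserved
  expect_error(assign_label_sets(probs[, 1:2] / rowSums(probs[, 1:2]), th),
               "thresholds")
})

test_that("coverage counts true-class containment per class", {
  member <- rbind(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE),
                  c(FALSE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  sets <- structure(list(member = member,
                         set_size = as.integer(rowSums(member))),
                    class = "label_set_matrix")
  labels <- c(1, 1, 1, 2)
  cov <- empirical_coverage(sets, labels)
  expect_equal(cov[1], 2 / 3)
  expect_equal(cov[2], 0)          # null set never covers
  expect_true(is.na(cov[3]))       # class absent -> missing, not zero
})

test_that("ambiguity distribution tabulates set sizes by class", {
  member <- rbind(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                  c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  sets <- structure(list(member = member,
                         set_size = as.integer(rowSums(member))),
                    class = "label_set_matrix")
  amb <- ambiguity_distribution(sets)
  expect_equal(amb$proportion[amb$class == "all"], rep(0.25, 4))
  amb2 <- ambiguity_distribution(sets, labels = c(1, 1, 2, 2))
  for (cl in c("all", "1", "2"))
    expect_equal(sum(amb2$proportion[amb2$class == cl]), 1)
  expect_equal(amb2$proportion[amb2$class == "1" & amb2$set_size == 1], 0.5)
})
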