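test_that("accuracy and baseline follow their definitions", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy(c("a", "a", "b", "b"), c("a", "b", "a", "b")), 50)

  expect_equal(baseline_accuracy(rep("Not_Skiing", 10)), 100)
  expect_equal(baseline_accuracy(rep(c("Not_Skiing", "Skiing"), c(90, 10))),
               90)
  # the baseline's constant prediction scores 0 on both clustering metrics
  truth <- rep(c("Not_Skiing", "Skiing"), c(90, 10))
  base_pred <- rep("Not_Skiing", 100)
  expect_equal(adjusted_rand_index(truth, base_pred), 0)
  expect_equal(as.numeric(nmi(truth, base_pred)), 0)
})

test_that("contingency Rand index equals the brute-force all-pairs oracle", {
  expect_equal(rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(rand_index(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0.5)  # 3 of 6 pairs
  expect_equal(rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)  # id permutation
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    a <- sample(1:sample(2:4, 1), n, replace = TRUE)
    b <- sample(1:sample(2:4, 1), n, replace = TRUE)
    expect_equal(rand_index(a, b), rand_index_bruteforce(a, b))
  }
})

test_that("ARI is 1 for identical labelings, 0 under independence and degeneracy", {
  lab <- rep(c("x", "y"), c(30, 70))
  expect_equal(adjusted_rand_index(lab, lab), 1)
  expect_equal(adjusted_rand_index(lab, ifelse(lab == "x", "B", "A")), 1)

  # chance-corrected: mean over many independent labelings is ~0
  set.seed(42)
  null_vals <- replicate(1000, {
    a <- sample(1:2, 200, replace = TRUE)
    b <- sample(1:2, 200, replace = TRUE)
    adjusted_rand_index(a, b)
  })
  expect_lt(abs(mean(null_vals)), 0.02)

  # agreement with an independent implementation on random cases
  set.seed(43)
  for (i in 1:50) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("NMI is normalised, symmetric, permutation-invariant, nonnegative", {
  lab <- rep(c("x", "y"), c(40, 60))
  expect_equal(as.numeric(nmi(lab, lab)), 1)
  relab <- ifelse(lab == "x", "B", "A")
  expect_equal(as.numeric(nmi(lab, relab)), 1)

  set.seed(44)
  null_vals <- replicate(200, {
    a <- sample(1:2, 1000, replace = TRUE)
    b <- sample(1:2, 1000, replace = TRUE)
    as.numeric(nmi(a, b))
  })
  expect_lt(mean(null_vals), 0.05)
  expect_true(all(null_vals >= 0))

  a <- sample(1:3, 100, replace = TRUE)
  b <- sample(1:2, 100, replace = TRUE)
  expect_equal(as.numeric(nmi(a, b)), as.numeric(nmi(b, a)), tolerance = 1e-12)

  both_const <- nmi(rep(1, 10), rep(2, 10))
  expect_equal(as.numeric(both_const), 1)
  expect_true(attr(both_const, "degenerate"))
})

test_that("per-sample truth expansion respects half-open segments and defaults", {
  segs <- activity_segments(c(0, 10), c(10, 20), c("Skiing", "Not_Skiing"))
  expect_equal(per_sample_classes(c(0, 9.99, 10, 19.99), segs),
               c("Skiing", "Skiing", "Not_Skiing", "Not_Skiing"))
  # uncovered time defaults to Not_Skiing
  expect_equal(per_sample_classes(c(25, 30), segs), rep("Not_Skiing", 2))
  expect_equal(per_sample_classes(1:5, activity_segments()),
               rep("Not_Skiing", 5))
})

test_that("segmentation reports score perfection, baseline, and splitting", {
  rec <- generate_static(quat_identity(), 100, 10, noise_sd = 0)
  truth <- activity_segments(c(0, 30, 70), c(30, 70, 100),
                             c("Not_Skiing", "Skiing", "Not_Skiing"))
  perfect <- evaluate_segmentation(truth, truth, rec)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$nmi, 1)
  expect_equal(perfect$ari, 1)
  expect_equal(perfect$detected_activities, perfect$true_activities)

  base <- evaluate_segmentation(
    activity_segments(0, 100, "Not_Skiing"), truth, rec)
  expect_equal(base$accuracy, base$baseline_accuracy)
  expect_equal(base$nmi, 0)
  expect_equal(base$ari, 0)

  # splitting one true activity in two detects one more and lowers ARI
  split <- evaluate_segmentation(
    activity_segments(c(0, 30, 48, 52, 70), c(30, 48, 52, 70, 100),
                      c("Not_Skiing", "Skiing", "Not_Skiing", "Skiing",
                        "Not_Skiing")),
    truth, rec)
  expect_equal(split$detected_activities, perfect$detected_activities + 1)
  expect_lt(split$ari, perfect$ari)
})
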