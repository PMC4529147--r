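test_that("equal-width binning partitions the half-range scale", {
  b <- bin_confidence(c(0.5, 0.6, 0.7, 0.8, 0.95), k = 5)
  expect_identical(as.integer(b), 1:5)
  expect_identical(as.integer(bin_confidence(rep(0.72, 10), k = 5)),
                   rep(3L, 10))
  expect_identical(as.integer(bin_confidence(1, k = 5)), 5L)  # top bin closed
  expect_error(bin_confidence(0.7, k = 1), "k")
  expect_error(bin_confidence(numeric(0)), "at least one")
  expect_error(bin_confidence(c(0.4, 0.7)), "0.5")
})

test_that("equal-count binning balances occupancy and sends ties down", {
  set.seed(10)
  conf <- runif(1000, 0.5, 1)
  b <- bin_confidence(conf, k = 5, mode = "equal_count")
  expect_identical(as.integer(table(b)), rep(200L, 5))
  # boundary values drop to the lower bin
  x <- c(0.6, 0.6, 0.6, 0.9)                 # inner edges all at 0.6
  b2 <- bin_confidence(x, k = 2, mode = "equal_count")
  expect_identical(as.integer(b2), c(1L, 1L, 1L, 2L))
})

test_that("type-2 ROC matches the brute-force cumulative construction", {
  correct <- c(rep(TRUE, 5), rep(FALSE, 5))
  confidence <- c(0.9, 0.9, 0.8, 0.6, 0.55, 0.85, 0.7, 0.6, 0.55, 0.5)
  roc <- type2_roc(correct, confidence, k = 5)
  bins <- bin_confidence(confidence, k = 5)
  expect_equal(roc$auc, oracle_binned_auc(correct, bins, 5))
  expect_equal(roc$auc, 0.72)                # frozen hand-computed value
  expect_equal(roc$points[1, ], data.frame(false_alarm_rate = 0, hit_rate = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]),
               c(false_alarm_rate = 1, hit_rate = 1))
  expect_true(all(diff(roc$points$false_alarm_rate) >= 0))
  expect_true(all(diff(roc$points$hit_rate) >= 0))
})

test_that("perfect separation yields the degenerate unit-area curve", {
  roc <- type2_roc(c(TRUE, TRUE, FALSE, FALSE), c(0.95, 0.9, 0.55, 0.5),
                   k = 2)
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$false_alarm_rate, c(0, 0, 1))
  expect_equal(roc$points$hit_rate, c(0, 1, 1))
})

test_that("degenerate accuracy raises an explicit error naming the participant", {
  expect_error(type2_roc(rep(TRUE, 10), runif(10, 0.5, 1),
                         participant_id = "p07"),
               "p07")
  expect_error(type2_roc(rep(FALSE, 4), rep(0.6, 4)), "undefined")
})

test_that("binned AUC agrees with the pairwise oracle", {
  # exact when every distinct confidence value occupies its own bin
  for (seed in 1:10) {
    tr <- make_trials(40, seed)
    conf <- sample(seq(0.5, 0.999, length.out = 4999), 40)  # distinct values
    roc <- type2_roc(tr$correct, conf, k = length(conf),
                     mode = "equal_count")
    expect_equal(roc$auc, oracle_pairwise_auc(tr$correct, conf),
                 tolerance = 1e-12)
  }
  # within binning coarseness at k = 5
  tr <- make_trials(10000, 77)
  roc5 <- type2_roc(tr$correct, tr$confidence, k = 5)
  expect_lt(abs(roc5$auc - oracle_pairwise_auc(tr$correct, tr$confidence)),
            0.05)
})

test_that("AUC is invariant under strictly increasing confidence transforms", {
  tr <- make_trials(600, 3)
  warp <- function(x) 0.5 + 0.5 * ((x - 0.5) * 2)^3
  a1 <- type2_roc(tr$correct, tr$confidence, k = 5, mode = "equal_count")$auc
  a2 <- type2_roc(tr$correct, warp(tr$confidence), k = 5,
                  mode = "equal_count")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("midpoint-confidence padding shrinks AUC toward 0.5 without crossing", {
  for (seed in c(2, 9)) {
    tr <- make_trials(300, seed)
    a0 <- type2_roc(tr$correct, tr$confidence, k = 5)$auc
    pad <- rep(0.75, 400)
    a1 <- type2_roc(c(tr$correct, rep(c(TRUE, FALSE), 200)),
                    c(tr$confidence, pad), k = 5)$auc
    expect_lt(abs(a1 - 0.5), abs(a0 - 0.5) + 1e-12)
    expect_gte((a0 - 0.5) * (a1 - 0.5), 0)
  }
})

test_that("calibration metrics are plain arithmetic on the trial table", {
  m <- calibration_metrics(rep(TRUE, 4), rep(1, 4))
  expect_equal(m$calibration_gap, 0)
  m2 <- calibration_metrics(c(rep(TRUE, 3), FALSE), rep(0.5, 4))
  expect_equal(m2$calibration_gap, -0.25)
  expect_equal(m2$accuracy, 0.75)
})

test_that("permutation null behaves as an exchangeability reference", {
  tr <- make_trials(400, 5)
  expect_identical(permutation_null_auc(tr$correct, tr$confidence, 0),
                   numeric(0))
  n1 <- permutation_null_auc(tr$correct, tr$confidence, 50, seed = 8)
  n2 <- permutation_null_auc(tr$correct, tr$confidence, 50, seed = 8)
  expect_identical(n1, n2)
  null <- permutation_null_auc(tr$correct, tr$confidence, 2000, seed = 1)
  expect_lt(abs(mean(null) - 0.5), 0.015)
})

test_that("score_participants summarises each participant once", {
  trials <- rbind(
    simulate_trials(observer_params(metacog_noise = 0.3), 0.05, 200,
                    participant_id = "a", seed = 1),
    simulate_trials(observer_params(metacog_noise = 1.5), 0.05, 200,
                    participant_id = "b", seed = 2))
  sc <- score_participants(trials, k = 5)
  expect_identical(sc$participant_id, c("a", "b"))
  expect_identical(sc$n_trials, c(200L, 200L))
  expect_true(all(sc$auc >= 0 & sc$auc <= 1))
  expect_equal(sc$accuracy[1],
               mean(trials$correct[trials$participant_id == "a"]))
})
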