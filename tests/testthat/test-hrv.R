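make_trace <- function(bpm, hz = 1) {
  data.frame(time_s = (seq_along(bpm) - 1) / hz, bpm = bpm)
}

test_that("windowed SD computes per-minute sample standard deviations", {
  expect_true(all(windowed_sd(make_trace(rep(70, 300)))$sd_bpm == 0))
  # 30 s sampling: each 60 s window holds exactly {60, 80}
  tr <- data.frame(time_s = seq(0, 570, by = 30),
                   bpm = rep(c(60, 80), 10))
  out <- windowed_sd(tr)
  expect_equal(out$sd_bpm, rep(sd(c(60, 80)), 10))
  expect_equal(out$sd_bpm[1], 14.1421356, tolerance = 1e-6)
  # trailing partial window discarded
  expect_identical(nrow(windowed_sd(make_trace(rep(70, 150)))), 2L)
  expect_error(windowed_sd(make_trace(rep(70, 30))), "shorter than one")
  expect_error(windowed_sd(make_trace(c(70, -1, 70, 70)), window_s = 2),
               "positive")
  bad <- data.frame(time_s = c(0, 1, 3, 4, 5, 6), bpm = rep(70, 6))
  expect_error(windowed_sd(bad, window_s = 2), "uniformly")
})

test_that("sinusoidal heart rate gives the closed-form A/sqrt(2) window SD", {
  A <- 8
  t <- seq(0, 599.9, by = 0.1)
  tr <- data.frame(time_s = t, bpm = 75 + A * sin(2 * pi * t / 5))
  out <- windowed_sd(tr)                      # 12 cycles per window
  expect_equal(out$sd_bpm, rep(A / sqrt(2), 10), tolerance = 0.01)
})

test_that("LOESS smoothing is exact on lines and contracts spikes and noise", {
  lin <- data.frame(start_s = (0:19) * 60, sd_bpm = 2 + 0.05 * (0:19))
  expect_equal(smooth_series(lin, span = 0.5)$sd_bpm, lin$sd_bpm,
               tolerance = 1e-8)
  spike <- data.frame(start_s = (0:19) * 60, sd_bpm = c(rep(4, 10), 30,
                                                        rep(4, 9)))
  expect_lt(max(smooth_series(spike, span = 0.4)$sd_bpm), 30)
  set.seed(6)
  noise <- data.frame(start_s = (0:39) * 60, sd_bpm = rnorm(40, 6, 1))
  expect_lt(var(smooth_series(noise, span = 0.5)$sd_bpm), var(noise$sd_bpm))
  expect_error(smooth_series(lin[1:4, ]), "at least 5")
  expect_error(smooth_series(lin, span = 0.05), "fewer than 3")
})

test_that("identical groups produce no clusters and p = 1 everywhere", {
  set.seed(8)
  m <- matrix(rnorm(20 * 6, 6, 1), 20, 6, dimnames = list(NULL, letters[1:6]))
  res <- group_cluster_test(m, m, n_boot = 500, seed = 1)
  expect_identical(nrow(res$clusters), 0L)
  expect_true(all(res$per_window$band1_low <= res$per_window$band1_high))
  expect_true(all(res$per_window$diff_low <= 0 & res$per_window$diff_high >= 0))
})

test_that("an injected SD elevation is recovered as an overlapping cluster", {
  set.seed(21)
  W <- 30
  mk <- function(n, elev) sapply(seq_len(n), function(i) {
    sdv <- rep(6.2, W); if (elev) sdv[10:15] <- 9.2
    vapply(seq_len(W), function(w) sd(rnorm(60, 78, sdv[w])), numeric(1))
  })
  g1 <- mk(9, TRUE); colnames(g1) <- paste0("h", 1:9)
  g2 <- mk(18, FALSE); colnames(g2) <- paste0("l", 1:18)
  res <- group_cluster_test(g1, g2, n_boot = 1000, seed = 4)
  hits <- unlist(Map(seq, res$clusters$start_window, res$clusters$end_window))
  expect_gt(length(intersect(hits, 10:15)), 0)
})

test_that("cluster output is invariant to participant ordering", {
  set.seed(5)
  g1 <- matrix(rnorm(15 * 5, 6, 1), 15, 5, dimnames = list(NULL, paste0("a", 1:5)))
  g2 <- matrix(rnorm(15 * 7, 7, 1), 15, 7, dimnames = list(NULL, paste0("b", 1:7)))
  r1 <- group_cluster_test(g1, g2, n_boot = 400, seed = 9)
  r2 <- group_cluster_test(g1[, c(3, 1, 5, 2, 4)], g2[, sample(7)],
                           n_boot = 400, seed = 9)
  expect_identical(r1, r2)
})

test_that("degenerate and mismatched inputs are handled explicitly", {
  m1 <- matrix(1:20 + 0, 10, 2)
  expect_error(group_cluster_test(m1, matrix(0, 8, 2)), "window grids")
  expect_error(group_cluster_test(m1, matrix(0, 10, 1)), "at least 2")
  # n_boot = 1: bands collapse to the single replicate, p floored at 1
  r <- group_cluster_test(m1, m1 + 1, n_boot = 1, seed = 2)
  expect_true(all(r$per_window$band1_low == r$per_window$band1_high))
  expect_true(all(r$per_window$p == 1))
})

test_that("hrv_matrix aligns participants on a shared window grid", {
  set.seed(12)
  hr <- do.call(rbind, lapply(c("b", "a"), function(id)
    data.frame(participant_id = id, time_s = 0:719,
               bpm = rnorm(720, 78, 6))))
  mat <- hrv_matrix(hr, span = NULL)
  expect_identical(dim(mat), c(12L, 2L))
  expect_identical(colnames(mat), c("a", "b"))
  raw <- windowed_sd(hr[hr$participant_id == "a", c("time_s", "bpm")])
  expect_equal(mat[, "a"], raw$sd_bpm)
})
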