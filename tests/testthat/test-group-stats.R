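test_that("RT filter keeps the closed analysis window and reports the fraction", {
  tr <- data.frame(participant_id = "p1", rt_ms = c(150, 500, 2100))
  out <- filter_rts(tr)
  expect_equal(out$kept$rt_ms, 500)
  expect_equal(out$excluded_fraction, 2 / 3)
  all_in <- data.frame(participant_id = "p1", rt_ms = c(200, 900, 2000))
  expect_equal(filter_rts(all_in)$excluded_fraction, 0)
  gone <- data.frame(participant_id = c("a", "a", "b"),
                     rt_ms = c(500, 700, 100))
  expect_error(filter_rts(gone), "participant\\(s\\): b")
})

test_that("one-way ANOVA and eta-squared match the stats::aov oracle", {
  set.seed(41)
  for (i in 1:5) {
    v <- rnorm(27, mean = rep(c(0, 0.4, 0.9), each = 9), sd = 1)
    g <- rep(c("low", "medium", "high"), each = 9)
    mine <- oneway_anova_eta2(v, g)
    or <- anova(stats::aov(v ~ factor(g)))
    expect_equal(mine$F, or$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, or$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(mine$eta2, or$`Sum Sq`[1] / sum(or$`Sum Sq`),
                 tolerance = 1e-10)
    expect_identical(c(mine$df_between, mine$df_within), c(2L, 24L))
    expect_true(mine$eta2 >= 0 && mine$eta2 <= 1)
  }
})

test_that("degenerate perfect separation returns the documented sentinels", {
  res <- oneway_anova_eta2(c(1, 1, 2, 2, 3, 3),
                           rep(c("a", "b", "c"), each = 2))
  expect_identical(res$F, Inf)
  expect_identical(res$p, 0)
  expect_equal(res$eta2, 1)
  expect_error(oneway_anova_eta2(1:5, c("a", "a", "b", "b", "c")),
               "fewer than 2")
})

test_that("Bonferroni post-hocs match pooled t-tests and the sign convention", {
  set.seed(17)
  v <- rnorm(27, rep(c(0, 0, 2), each = 9))
  g <- rep(c("low", "medium", "high"), each = 9)
  tab <- bonferroni_pairwise(v, g)
  expect_identical(tab$group1, c("low", "low", "medium"))
  expect_identical(tab$group2, c("medium", "high", "high"))
  for (i in 1:3) {
    a <- v[g == tab$group1[i]]; b <- v[g == tab$group2[i]]
    or <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(tab$t[i], unname(or$statistic), tolerance = 1e-10)
    expect_equal(tab$p_adjusted[i], min(1, or$p.value * 3),
                 tolerance = 1e-10)
    expect_equal(tab$mean_diff[i], mean(a) - mean(b), tolerance = 1e-12)
  }
  # only pairs involving the shifted group are significant
  expect_true(all(tab$p_adjusted[tab$group2 == "high"] < 0.01))
  expect_gt(tab$p_adjusted[1], 0.05)
  # identical groups cap at 1
  same <- bonferroni_pairwise(rep(c(1, 2, 1, 2, 1.5), 2),
                              rep(c("a", "b"), each = 5))
  expect_equal(same$p_adjusted, 1)
})

test_that("AUC-on-cortisol regression matches the lm oracle", {
  set.seed(23)
  c2 <- runif(27, 3, 13)
  auc <- 0.8 - 0.01 * c2 + rnorm(27, 0, 0.05)
  mine <- regress_auc_on_cortisol(auc, c2)
  or <- summary(stats::lm(auc ~ c2))
  expect_equal(mine$r2, or$r.squared, tolerance = 1e-10)
  expect_equal(mine$t, or$coefficients["c2", "t value"], tolerance = 1e-10)
  expect_equal(mine$p, or$coefficients["c2", "Pr(>|t|)"], tolerance = 1e-10)
  expect_identical(mine$df, 25L)
  expect_equal(mine$beta_std,
               or$coefficients["c2", "Estimate"] * sd(c2) / sd(auc),
               tolerance = 1e-10)
  # perfect negative line
  perfect <- regress_auc_on_cortisol(0.9 - 0.02 * c2, c2)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$beta_std, -1)
  expect_error(regress_auc_on_cortisol(rep(0.7, 27), c2), "zero variance")
  expect_error(regress_auc_on_cortisol(auc[1:3], c2[1:3]), "at least 4")
})

test_that("null r-squared has expectation 1/(n-1)", {
  set.seed(9)
  n <- 20
  r2 <- replicate(4000, {
    regress_auc_on_cortisol(rnorm(n), rnorm(n))$r2
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.005)
})

test_that("mixed pre/post ANOVA matches the aov Error-stratum oracle", {
  set.seed(55)
  for (i in 1:4) {
    n_per <- 5L
    g <- rep(c("a", "b", "c"), each = n_per)
    pre <- rnorm(15, 30, 4)
    post <- pre + rnorm(15, rep(c(5, 8, 11), each = n_per), 3)
    mine <- rm_anova_prepost(pre, post, g)
    d <- data.frame(y = c(pre, post),
                    time = factor(rep(c("pre", "post"), each = 15)),
                    group = factor(rep(g, 2)),
                    id = factor(rep(seq_len(15), 2)))
    or <- summary(stats::aov(y ~ group * time + Error(id / time), data = d))
    w <- or[["Error: id:time"]][[1]]
    expect_equal(mine$F_time, w["time", "F value"], tolerance = 1e-10)
    expect_equal(mine$p_time, w["time", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(mine$F_interaction, w["group:time", "F value"],
                 tolerance = 1e-10)
    expect_equal(mine$p_interaction, w["group:time", "Pr(>F)"],
                 tolerance = 1e-10)
    b <- or[["Error: id"]][[1]]
    expect_equal(mine$F_group, b["group", "F value"], tolerance = 1e-10)
    expect_equal(mine$eta2p_time,
                 w["time", "Sum Sq"] /
                   (w["time", "Sum Sq"] + w["Residuals", "Sum Sq"]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate pre/post designs return the documented conventions", {
  g <- rep(c("a", "b"), each = 4)
  pre <- c(30, 32, 28, 31, 40, 41, 39, 42)
  none <- rm_anova_prepost(pre, pre, g)
  expect_identical(none$F_time, 0)
  shift <- rm_anova_prepost(pre, pre + 10, g)
  expect_identical(shift$F_interaction, 0)
  expect_identical(shift$F_time, Inf)
  expect_equal(shift$eta2p_time, 1)
  expect_error(rm_anova_prepost(pre, pre[1:4], g), "pair")
  expect_error(rm_anova_prepost(pre, c(pre[-1], NA), g), "pair")
})

test_that("ANOVA p-values are uniform under label permutation", {
  set.seed(99)
  v <- rnorm(27)
  g <- rep(c("low", "medium", "high"), each = 9)
  pvals <- replicate(400, oneway_anova_eta2(v, sample(g))$p)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})
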