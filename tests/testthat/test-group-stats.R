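# Independent oracles: projection-based sums of squares for the ANOVA and
# stats::TukeyHSD / t.test for the pairwise procedure.

proj_anova_F <- function(values, groups) {
  g <- factor(groups)
  X <- stats::model.matrix(~g)
  X0 <- matrix(1, length(values))
  H <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  yhat <- H(X) %*% values
  ybar <- H(X0) %*% values
  ss_b <- sum((yhat - ybar)^2)
  ss_w <- sum((values - yhat)^2)
  df_b <- nlevels(g) - 1
  df_w <- length(values) - nlevels(g)
  (ss_b / df_b) / (ss_w / df_w)
}

test_that("anova_oneway matches the hand-computed example", {
  a <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 13.5, tolerance = 1e-12)
  expect_equal(a$ss_between, 13.5)
  expect_equal(a$ss_within, 4)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_resid, 4)
  expect_equal(a$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(a$p, 0.021312, tolerance = 1e-4)
})

test_that("anova_oneway edge cases behave as specified", {
  # identical group means with within-group variance: F = 0
  a <- anova_oneway(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(a$F, 0)
  # constant data: F undefined, reported as NA
  expect_true(is.na(anova_oneway(rep(5, 6), rep(c("a", "b"), 3))$F))
  # F = t^2 for two groups
  set.seed(407)
  x <- rnorm(8); y <- rnorm(9, 1)
  a2 <- anova_oneway(c(x, y), rep(c("a", "b"), c(8, 9)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-12)
  expect_error(anova_oneway(1:5, rep("a", 5)),
               class = "granulofit_invalid_argument")
  expect_error(anova_oneway(c(1, 2), c("a", "b")),
               class = "granulofit_invalid_argument")
})

test_that("anova F matches the projection oracle on random instances", {
  set.seed(408)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:8, k, replace = TRUE)
    g <- rep(paste0("g", seq_len(k)), n)
    v <- rnorm(sum(n), mean = rep(rnorm(k), n))
    expect_equal(anova_oneway(v, g)$F, proj_anova_F(v, g),
                 tolerance = 1e-10)
  }
})

test_that("tukey_pairwise matches TukeyHSD on random 3-group instances", {
  set.seed(409)
  for (i in 1:10) {
    n <- sample(4:9, 3, replace = TRUE)
    g <- rep(c("a", "b", "c"), n)
    v <- rnorm(sum(n), mean = rep(c(0, 1, 2), n))
    mine <- tukey_pairwise(v, g)
    oracle <- stats::TukeyHSD(stats::aov(v ~ factor(g)))[[1]]
    # oracle rows are b-a, c-a, c-b; mine are a-b, a-c, b-c
    expect_equal(mine$diff_means, -oracle[, "diff"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mine$ci_low, -oracle[, "upr"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mine$ci_high, -oracle[, "lwr"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mine$p_adjusted, oracle[, "p adj"], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("tukey reduces to the pooled-t procedure for two groups", {
  set.seed(410)
  x <- rnorm(9); y <- rnorm(9, 0.8)
  tk <- tukey_pairwise(c(x, y), rep(c("a", "b"), each = 9))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-10)
  # the identity q(conf; 2, df) = sqrt(2) t(conf) is exact; qtukey's
  # numerical accuracy (~1e-8) sets the achievable CI agreement
  expect_equal(c(tk$ci_low, tk$ci_high), unname(tt$conf.int),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(tk$diff_means, unname(tt$estimate[1] - tt$estimate[2]),
               tolerance = 1e-12)
})

test_that("structured 3-group case: distant pair has smaller p", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  tk <- tukey_pairwise(v, g)
  expect_equal(abs(tk$diff_means), c(3, 6, 3))
  expect_equal(tk$ci_high - tk$diff_means, tk$diff_means - tk$ci_low,
               tolerance = 1e-12)
  p13 <- tk$p_adjusted[tk$group_a == "g1" & tk$group_b == "g3"]
  expect_true(all(p13 < tk$p_adjusted[-which(tk$group_a == "g1" &
                                               tk$group_b == "g3")]))
  # label invariance modulo sign
  tk2 <- tukey_pairwise(v, factor(g, levels = c("g3", "g2", "g1")))
  m1 <- tk$diff_means[tk$group_a == "g1" & tk$group_b == "g3"]
  m2 <- tk2$diff_means[tk2$group_a == "g3" & tk2$group_b == "g1"]
  expect_equal(m1, -m2)
  expect_equal(sort(tk$p_adjusted), sort(tk2$p_adjusted), tolerance = 1e-12)
})

test_that("tukey adjustment is conservative versus unadjusted t for k > 2", {
  set.seed(411)
  for (i in 1:10) {
    n <- sample(4:8, 4, replace = TRUE)
    g <- rep(paste0("g", 1:4), n)
    v <- rnorm(sum(n))
    tk <- tukey_pairwise(v, g)
    a <- anova_oneway(v, g)
    for (j in seq_len(nrow(tk))) {
      se <- sqrt(a$mse * (1 / tk$n_a[j] + 1 / tk$n_b[j]))
      p_t <- 2 * stats::pt(abs(tk$diff_means[j]) / se, a$df_resid,
                           lower.tail = FALSE)
      expect_gte(tk$p_adjusted[j], p_t - 1e-12)
    }
  }
})

test_that("run_comparisons emits a tidy table with stratification", {
  set.seed(412)
  tab <- expand.grid(plant_id = 1:6, genotype = c("WT", "mutant"),
                     dpa = c(8, 14, 20, 30))
  tab$plant_id <- paste(tab$genotype, tab$plant_id)
  tab$b_volume_percent <- rnorm(nrow(tab), 20)
  cmp <- run_comparisons(tab, "b_volume_percent", stratum_col = "dpa")
  expect_equal(nrow(cmp), 4)
  expect_setequal(cmp$stratum, as.character(c(8, 14, 20, 30)))
  expect_true(all(cmp$ci_low <= cmp$diff_means &
                    cmp$diff_means <= cmp$ci_high))
  # unknown phenotype errors listing available columns
  err <- expect_error(run_comparisons(tab, "nope"),
                      class = "granulofit_invalid_argument")
  expect_match(conditionMessage(err), "b_volume_percent")
  # grain-level rows (duplicate plant within cell) are refused
  tab2 <- rbind(tab, tab[1, ])
  expect_error(run_comparisons(tab2, "b_volume_percent",
                               stratum_col = "dpa"),
               class = "granulofit_contract_error")
  # empty stratum is skipped with a warning
  tab3 <- tab[!(tab$dpa == 8 & tab$genotype == "mutant"), ]
  expect_warning(cmp3 <- run_comparisons(tab3, "b_volume_percent",
                                         stratum_col = "dpa"),
                 "skipping")
  expect_equal(nrow(cmp3), 3)
})

test_that("estimator is unbiased with nominal CI coverage (10-pt offset)", {
  set.seed(413)
  diffs <- numeric(200)
  cover <- logical(200)
  for (i in 1:200) {
    wt <- rnorm(9, 20, 3)
    mut <- rnorm(9, 30, 3)
    tk <- tukey_pairwise(c(mut, wt), rep(c("mutant", "wt"), each = 9))
    diffs[i] <- tk$diff_means
    cover[i] <- tk$ci_low <= 10 & 10 <= tk$ci_high
  }
  expect_lt(abs(mean(diffs) - 10), 0.5)
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})
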