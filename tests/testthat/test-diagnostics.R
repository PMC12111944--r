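test_that("AUC is the Mann-Whitney concordance with ties counted 1/2", {
  roc <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auc, 0.75)
  # perfectly separated and fully tied cases
  expect_equal(roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
  # se non-increasing, sp non-decreasing along thresholds
  set.seed(7)
  fx <- random_fixture(40)
  r <- roc_curve(fx$scores, fx$labels)
  expect_true(all(diff(r$se) <= 0))
  expect_true(all(diff(r$sp) >= 0))
})

test_that("AUC matches the exhaustive pairwise oracle and pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:20) {
    fx <- random_fixture(sample(8:50, 1))
    r <- roc_curve(fx$scores, fx$labels)
    expect_equal(r$auc, bf_auc(fx$scores, fx$labels))
    pr <- suppressMessages(pROC::roc(fx$labels, fx$scores, direction = "<"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  }
})

test_that("identical scores compare as equal AUCs with p = 1", {
  set.seed(5)
  s <- rnorm(40); lab <- runif(40) < 0.5; lab[1:2] <- c(TRUE, FALSE)
  cmp <- compare_auc(s, s, lab)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the paired AUC comparison agrees with an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    n <- 60
    lab <- runif(n) < 0.45; lab[1:2] <- c(TRUE, FALSE)
    x <- rnorm(n) + lab; y <- 0.5 * x + rnorm(n)
    cmp <- compare_auc(x, y, lab)
    expect_equal(cmp$delta, bf_auc(x, lab) - bf_auc(y, lab))
    pt <- pROC::roc.test(suppressMessages(pROC::roc(lab, x, direction = "<")),
                         suppressMessages(pROC::roc(lab, y, direction = "<")),
                         method = "delong", paired = TRUE)
    expect_equal(cmp$p_value, pt$p.value, tolerance = 1e-8)
  }
})

test_that("optimal cut-off maximises Se + Sp with ties to the lower threshold", {
  # separable toy: perfect threshold
  roc <- roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  opt <- optimal_cutoff(roc)
  perf <- opt$performance
  expect_equal(perf$estimate[perf$measure == "se"], 1)
  expect_equal(perf$estimate[perf$measure == "sp"], 1)
  # exhaustive check across random fixtures
  set.seed(13)
  for (i in 1:20) {
    fx <- random_fixture(sample(6:50, 1))
    r <- roc_curve(fx$scores, fx$labels)
    opt <- optimal_cutoff(r)
    j <- opt$performance$estimate[1] + opt$performance$estimate[2]
    expect_equal(j, bf_best_youden(fx$scores, fx$labels))
    # no other threshold beats it
    expect_true(all(r$se + r$sp <= j + 1e-12))
  }
  # degenerate: all scores equal, Se + Sp = 1 at any cut
  r0 <- roc_curve(rep(3, 8), rep(c(TRUE, FALSE), 4))
  o0 <- optimal_cutoff(r0)
  expect_equal(o0$performance$estimate[1] + o0$performance$estimate[2], 1)
})

test_that("rule cut-offs optimise under their floors and go absent when infeasible", {
  roc <- roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  rc <- rule_cutoffs(roc)
  expect_equal(rc$rule_in$threshold, rc$rule_out$threshold)
  set.seed(17)
  for (i in 1:20) {
    fx <- random_fixture(sample(6:50, 1))
    r <- roc_curve(fx$scores, fx$labels)
    rc <- rule_cutoffs(r, se_floor = 0.8, sp_floor = 0.74)
    expect_equal(rc$rule_out$threshold, bf_rule_out(fx$scores, fx$labels, 0.8))
    expect_equal(rc$rule_in$threshold, bf_rule_in(fx$scores, fx$labels, 0.74))
  }
  # overlapping scores cannot meet floors of 0.999
  ov <- roc_curve(c(1, 2, 3, 4, 1, 2, 3, 4),
                  c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  rc2 <- rule_cutoffs(ov, se_floor = 0.999, sp_floor = 0.999)
  expect_true(is.na(rc2$rule_out$threshold))
  expect_true(is.na(rc2$rule_in$threshold))
})

test_that("performance_at builds the confusion matrix with Wilson intervals", {
  perf <- performance_at(c(5, 3, 1, 4), c(TRUE, TRUE, FALSE, FALSE), 3)
  est <- setNames(perf$estimate, perf$measure)
  expect_equal(unname(est[c("se", "sp", "ppv", "npv")]), c(1, 0.5, 2/3, 1))
  # zero-denominator ratios are absent, not zero
  hi <- performance_at(c(5, 3, 1, 4), c(TRUE, TRUE, FALSE, FALSE), 99)
  est_hi <- setNames(hi$estimate, hi$measure)
  expect_equal(unname(est_hi["se"]), 0)
  expect_equal(unname(est_hi["sp"]), 1)
  expect_true(is.na(est_hi["ppv"]))
  lo <- performance_at(c(5, 3, 1, 4), c(TRUE, TRUE, FALSE, FALSE), -99)
  expect_true(is.na(setNames(lo$estimate, lo$measure)["npv"]))
  # intervals contain their point estimates
  ok <- !is.na(perf$estimate)
  expect_true(all(perf$ci_low[ok] <= perf$estimate[ok] + 1e-12))
  expect_true(all(perf$ci_high[ok] >= perf$estimate[ok] - 1e-12))
  # invariant under a joint monotone transform of scores and threshold
  sc <- c(5, 3, 1, 4); lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(performance_at(exp(sc), lab, exp(3))$estimate,
               performance_at(sc, lab, 3)$estimate)
})

test_that("spearman_ci returns rank correlation with a Fisher-z interval", {
  expect_equal(spearman_ci(1:10, 1:10)$rho, 1)
  expect_equal(spearman_ci(c(1, 2, 3, 4), c(3, 1, 2, 4))$rho, 0.4)
  expect_equal(spearman_ci(1:8, -(1:8))$rho, -1)
  # invariant to strictly monotone transforms
  set.seed(31)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  a <- spearman_ci(x, y)
  b <- spearman_ci(exp(x), y^3 + 5 * y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
  expect_lte(a$ci_low, a$rho); expect_gte(a$ci_high, a$rho)
  expect_error(spearman_ci(rep(1, 10), 1:10), "constant")
})

test_that("group_compare routes tests by variable type and normality", {
  # identical categorical composition -> chi-squared with p = 1
  g <- rep(c("a", "b"), each = 10)
  v <- factor(rep(c("x", "y"), 10))
  r <- group_compare(v, g)
  expect_equal(r$test_used, "chi_squared")
  expect_equal(r$p_value, 1)
  # two clean normal samples route to the t-test
  set.seed(2)
  r2 <- group_compare(c(rnorm(80), rnorm(80, 1)), rep(c("a", "b"), each = 80))
  expect_equal(r2$test_used, "t_test")
  # heavy-tailed data fail the KS gate and route to Mann-Whitney
  set.seed(3)
  r3 <- group_compare(c(rlnorm(80, 0, 2), rlnorm(80, 1.2, 2)),
                      rep(c("a", "b"), each = 80))
  expect_equal(r3$test_used, "mann_whitney")
  expect_error(group_compare(rnorm(10), rep("a", 10)), "two groups")
})

test_that("a one-SD mean shift at n = 500 per group is detected essentially always", {
  set.seed(19)
  rejections <- vapply(1:20, function(i) {
    v <- c(rnorm(500), rnorm(500, 1))
    group_compare(v, rep(c("a", "b"), each = 500))$p_value < 0.05
  }, TRUE)
  expect_true(all(rejections))
})

test_that("backward-stepwise logistic keeps signal and drops noise", {
  set.seed(101)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n); x4 <- rnorm(n)
  y <- runif(n) < plogis(-0.5 + 1.5 * x1)
  fit <- stepwise_logistic(y, data.frame(x1 = x1, x2 = x2, x3 = x3, x4 = x4))
  expect_true("x1" %in% fit$selected)
  expect_true(length(fit$dropped) >= 2)
  # odds ratios are exp(beta) with Wald intervals around them
  expect_equal(fit$coefficients$or, exp(fit$coefficients$beta))
  expect_true(all(fit$coefficients$or_low <= fit$coefficients$or))
  # null outcome: majority of replicates end intercept-only
  empties <- vapply(1:10, function(i) {
    set.seed(300 + i)
    y0 <- runif(400) < 0.4
    f <- stepwise_logistic(y0, data.frame(a = rnorm(400), b = rnorm(400)))
    length(f$selected) == 0
  }, TRUE)
  expect_gte(sum(empties), 6)
  expect_error(stepwise_logistic(y, data.frame(k = rep(1, n))), "constant")
})

test_that("perfect separation is flagged, not silently reported", {
  x <- c(rnorm(30, -3), rnorm(30, 3))
  y <- x > 0
  expect_warning(stepwise_logistic(y, data.frame(x = x)), "separation")
})
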