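test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  # hand oracle: group means 2,3,4, grand mean 3 -> SSB = 3*(1+0+1) = 6;
  # within each group SS = 2 -> SSW = 6; F = (6/2)/(6/6) = 3
  res <- one_way_anova(vals, grp)
  expect_equal(res$table$sum_sq, c(6, 6), tolerance = 1e-12)
  expect_equal(res$table$df, c(2, 6))
  expect_equal(res$table$statistic[1], 3.0, tolerance = 1e-12)
  expect_equal(res$table$eta_sq[1], 0.5, tolerance = 1e-12)

  flat <- one_way_anova(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(flat$table$statistic[1], 0, tolerance = 1e-12)

  set.seed(1)
  x <- rnorm(12)
  g2 <- rep(c("a", "b"), each = 6)
  tt <- t.test(x[g2 == "a"], x[g2 == "b"], var.equal = TRUE)
  expect_equal(one_way_anova(x, g2)$table$statistic[1],
               unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), ">= 2 observations")
})

test_that("two-way decomposition is additive and collapses to one-way", {
  set.seed(21)
  fa <- rep(rep(c("neutral", "fear", "anger"), each = 8), 2)
  fb <- rep(c("low", "high"), each = 24)
  dv <- rnorm(48) + (fa == "fear") * 0.5 + (fb == "high") * 0.3
  res <- two_way_anova(dv, fa, fb)
  sst <- sum((dv - mean(dv))^2)
  expect_equal(sum(res$table$sum_sq), sst, tolerance = 1e-8)
  expect_equal(sum(res$table$eta_sq), 1, tolerance = 1e-10)
  expect_equal(sum(res$table$df), length(dv) - 1)

  collapsed <- two_way_anova(dv, fa, rep("only", 48))
  expect_equal(collapsed$table$statistic[1],
               one_way_anova(dv, fa)$table$statistic[1], tolerance = 1e-10)
  expect_error(two_way_anova(dv[fb == "low" | fa == "fear"],
                             fa[fb == "low" | fa == "fear"],
                             fb[fb == "low" | fa == "fear"]),
               "empty design cell")
})

test_that("null two-way tables rarely reject any effect", {
  set.seed(99)
  non_reject <- matrix(0, 200, 3)
  fa <- rep(rep(c("a", "b", "c"), each = 4), 2)
  fb <- rep(c("lo", "hi"), each = 12)
  for (i in 1:200) {
    res <- two_way_anova(rnorm(24), fa, fb)
    non_reject[i, ] <- res$table$p.value[1:3] > 0.05
  }
  expect_true(all(colMeans(non_reject) >= 0.90))
})

test_that("unbalanced layouts error classically but fit with Type II", {
  set.seed(5)
  fa <- c(rep("a", 6), rep("b", 5), rep("c", 6))
  fb <- c(rep("lo", 3), rep("hi", 3), rep("lo", 3), rep("hi", 2),
          rep("lo", 3), rep("hi", 3))
  dv <- rnorm(17)
  expect_error(two_way_anova(dv, fa, fb), "unbalanced")
  res <- two_way_anova(dv, fa, fb, type = "II")
  a2 <- car::Anova(lm(dv ~ factor(fa) * factor(fb)), type = 2)
  expect_equal(res$table$sum_sq[1:3], a2[["Sum Sq"]][1:3], tolerance = 1e-10)
})

test_that("simple effects use the documented error terms", {
  set.seed(31)
  fa <- rep(rep(c("neutral", "fear", "anger"), each = 6), 2)
  fb <- rep(c("low", "high"), each = 18)
  dv <- rnorm(36) + (fa == "fear" & fb == "low") * 1.5
  # within-level error reproduces the one-way ANOVA restricted to the level
  sw <- simple_effects(dv, fa, fb, error = "within")
  for (lv in c("low", "high")) {
    ow <- one_way_anova(dv[fb == lv], fa[fb == lv])
    expect_equal(sw$table$statistic[sw$table$level == lv],
                 ow$table$statistic[1], tolerance = 1e-10)
  }
  # pooled error: F = MS_focal(level) / MSW of the full factorial model
  sp <- simple_effects(dv, fa, fb, error = "pooled")
  full <- two_way_anova(dv, fa, fb)
  msw <- full$table$mean_sq[4]
  for (lv in c("low", "high")) {
    d <- dv[fb == lv]
    f <- fa[fb == lv]
    ssb <- sum(tapply(d, f, length) * (tapply(d, f, mean) - mean(d))^2)
    expect_equal(sp$table$statistic[sp$table$level == lv],
                 (ssb / 2) / msw, tolerance = 1e-10)
    expect_equal(sp$table$df2[sp$table$level == lv], full$table$df[4])
  }
  # a flat focal factor inside one level gives F = 0 there
  dv2 <- dv
  dv2[fb == "high"] <- rep(tapply(dv[fb == "high"], rep(1, 18), mean), 18)
  s0 <- simple_effects(dv2, fa, fb, error = "pooled")
  expect_equal(s0$table$statistic[s0$table$level == "high"], 0,
               tolerance = 1e-12)
  expect_error(simple_effects(dv, fa, fb, levels = "mid"), "unknown")
  # direction strings accompany significant contrasts
  ph <- sp$posthoc$low
  expect_true("fear > anger" %in% ph$direction ||
                "fear > neutral" %in% ph$direction)
})

test_that("summary-statistics ANOVA round-trips the raw-data result", {
  set.seed(41)
  fa <- rep(rep(c("neutral", "fear", "anger"), each = 7), 2)
  fb <- rep(c("low", "high"), each = 21)
  dv <- rnorm(42) + (fa == "anger") * 0.8 + (fa == "fear" & fb == "high") * 0.5
  raw <- two_way_anova(dv, fa, fb)
  means <- tapply(dv, list(fa, fb), mean)[c("neutral", "fear", "anger"),
                                          c("low", "high")]
  sds <- tapply(dv, list(fa, fb), sd)[c("neutral", "fear", "anger"),
                                      c("low", "high")]
  ns <- tapply(dv, list(fa, fb), length)[c("neutral", "fear", "anger"),
                                         c("low", "high")]
  audit <- anova_from_summary(means, sds, ns)
  expect_equal(audit$table$statistic[1:3], raw$table$statistic[1:3],
               tolerance = 1e-8)
  expect_equal(audit$table$sum_sq, raw$table$sum_sq, tolerance = 1e-8)

  flat <- anova_from_summary(matrix(2, 3, 2), matrix(1, 3, 2),
                             matrix(5, 3, 2))
  expect_equal(flat$table$statistic[1:3], rep(0, 3), tolerance = 1e-12)

  one <- anova_from_summary(c(a = 2, b = 3, c = 4),
                            sds = rep(sd(c(1, 2, 3)), 3), ns = rep(3, 3))
  expect_equal(one$table$statistic[1], 3.0, tolerance = 1e-10)
  expect_error(anova_from_summary(c(1, 2), c(0.5, 0.5), c(1, 5)), "n >= 2")
})

test_that("regression recovers exact fits and matches the normal equations", {
  set.seed(51)
  X <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
  y_exact <- 2 + 1.5 * X$x1 - 0.7 * X$x2 + 0.2 * X$x3
  fit0 <- suppressWarnings(multiple_regression(y_exact, X))
  expect_equal(fit0$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit0$coefficients$estimate, c(2, 1.5, -0.7, 0.2),
               tolerance = 1e-10)

  y <- y_exact + rnorm(30)
  fit <- multiple_regression(y, X)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  expect_equal(fit$coefficients$statistic,
               fit$coefficients$estimate / fit$coefficients$std_error,
               tolerance = 1e-12)
  expect_equal(fit$coefficients$vif[-1],
               unname(car::vif(lm(y ~ ., data = X))), tolerance = 1e-8)
  expect_true(all(fit$coefficients$vif[-1] >= 1))
})

test_that("orthogonal predictors have unit VIF and collinear ones error", {
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  X <- as.data.frame(Q)
  set.seed(61)
  y <- rnorm(20)
  fit <- multiple_regression(y, X)
  expect_equal(fit$coefficients$vif[-1], rep(1, 3), tolerance = 1e-10)
  Xc <- X
  Xc$dup <- X[[1]] * 2
  expect_error(multiple_regression(y, Xc), "collinear")
  expect_error(multiple_regression(rnorm(3), data.frame(a = rnorm(3),
                                                        b = rnorm(3))),
               "more observations")
})
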