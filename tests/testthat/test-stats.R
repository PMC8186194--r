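test_that("Bland-Altman on identical pairs is all-zero", {
  a <- c(0.5, 0.6, 0.55)
  ba <- bland_altman(a, a)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
  expect_equal(ba$cv, 0)
})

test_that("Bland-Altman and CV match the hand-computed 3-pair table", {
  a <- c(0.50, 0.60, 0.55)
  b <- c(0.52, 0.58, 0.55)
  ba_abs <- bland_altman(a, b, units_mode = "absolute")
  expect_equal(ba_abs$bias, 0)
  expect_equal(ba_abs$sd_diff, 0.02)
  # cv = 100 * sd(diffs) / grand mean = 100 * 0.02 / 0.55
  expect_equal(ba_abs$cv, 100 * 0.02 / 0.55, tolerance = 1e-12)
  expect_equal(round(ba_abs$cv, 2), 3.64)
  expect_equal(cv_percent(a, b), ba_abs$cv)
})

test_that("percent-mode agreement statistics are scale invariant", {
  set.seed(11)
  a <- runif(50, 0.4, 0.7)
  b <- a * (1 + rnorm(50, 0, 0.02))
  base <- bland_altman(a, b)
  for (c_scale in c(0.5, 10)) {
    sc <- bland_altman(a * c_scale, b * c_scale)
    expect_equal(sc$bias, base$bias)
    expect_equal(sc$sd_diff, base$sd_diff)
    expect_equal(sc$cv, base$cv)
  }
})

test_that("Bland-Altman input contracts are enforced", {
  expect_error(bland_altman(0.5, 0.6), "insufficient")
  expect_error(bland_altman(c(0.5, -0.1), c(0.5, 0.4)), "domain")
})

test_that("CV recovers the closed form for independent relative errors", {
  set.seed(29)
  s1 <- 0.010; s2 <- 0.015; n <- 50000
  true_val <- runif(n, 0.4, 0.7)
  a <- true_val * (1 + rnorm(n, 0, s1))
  b <- true_val * (1 + rnorm(n, 0, s2))
  expect_lt(abs(cv_percent(a, b) - 100 * sqrt(s1^2 + s2^2)), 0.03)
})

test_that("linear fit matches a normal-equations oracle and bands correctly", {
  expect_equal(linear_fit_r2(1:10, 1:10)$r2, 1)
  expect_equal(linear_fit_r2(1:10, 1:10)$category, "excellent")

  set.seed(3)
  x <- rnorm(2000); y <- rnorm(2000)
  null_fit <- linear_fit_r2(x, y)
  expect_lt(null_fit$r2, 0.05)
  expect_equal(null_fit$category, "poor")

  x5 <- c(1.2, 2.5, 3.1, 4.8, 5.0)
  y5 <- c(0.9, 2.2, 3.5, 4.1, 5.6)
  fit <- linear_fit_r2(x5, y5)
  X <- cbind(1, x5)
  beta <- solve(t(X) %*% X, t(X) %*% y5)
  r2_oracle <- 1 - sum((y5 - X %*% beta)^2) / sum((y5 - mean(y5))^2)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$r2, r2_oracle, tolerance = 1e-10)

  # banding: boundary values belong to the lower band
  mk <- function(r2_target) {
    # fit component along x, residual orthogonal to x and mean-zero
    x <- c(1, 2, 3, 4); res <- c(1, -1, -1, 1)
    a <- 1; b2 <- 5 * a^2 * (1 - r2_target) / (4 * r2_target)
    y <- (x - mean(x)) * a + res * sqrt(b2)
    linear_fit_r2(x, y)
  }
  expect_equal(mk(0.45)$category, "poor")
  expect_equal(mk(0.74)$category, "moderate")
  expect_equal(mk(0.76)$category, "good")
  expect_equal(mk(0.95)$category, "excellent")
  expect_error(linear_fit_r2(rep(1, 5), 1:5), "degenerate")
})

test_that("paired t-test matches the textbook formula and handles degeneracy", {
  a <- c(0.52, 0.47, 0.55, 0.60, 0.49)
  b <- c(0.50, 0.48, 0.53, 0.57, 0.50)
  res <- paired_t_test(a, b)
  d <- a - b
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  same <- paired_t_test(a, a)
  expect_equal(c(same$t, same$p), c(0, 1))
  expect_true(same$degenerate)

  sym <- paired_t_test(c(1, -1, 2, -2) + 5, rep(5, 4))
  expect_equal(c(sym$t, sym$p), c(0, 1))
  expect_false(sym$degenerate)

  const <- paired_t_test(a + 0.1, a)
  expect_true(const$degenerate)
  expect_equal(const$t, Inf)
  expect_equal(const$p, 0)
})

test_that("classification metrics match hand-computed confusion counts", {
  # perfectly separated
  perfect <- classification_eval(c(0.4, 0.45, 0.6, 0.65), c(0, 0, 1, 1), 0.5)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  # the worked 4-point example
  v <- c(0.40, 0.52, 0.48, 0.55); l <- c(0, 0, 1, 1)
  r <- classification_eval(v, l, 0.5)
  expect_equal(r$sensitivity, 50)
  expect_equal(r$specificity, 50)
  expect_equal(r$accuracy, 50)
  expect_equal(r$f1, 0.5)
  expect_equal(r$auc, 0.75)

  # boundary: cutoff below every value
  low <- classification_eval(v, l, 0.1)
  expect_equal(low$sensitivity, 100)
  expect_equal(low$specificity, 0)

  expect_error(classification_eval(v, c(1, 1, 1, 1), 0.5), "undefined")
})

test_that("rank AUC equals trapezoidal ROC integration (exhaustive small instances)", {
  set.seed(61)
  for (trial in 1:200) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    values <- round(runif(n, 0.3, 0.7), sample(1:3, 1))  # induce ties
    auc <- classification_eval(values, labels, 0.5)$auc
    expect_equal(auc, trapezoid_auc(values, labels), tolerance = 1e-12)
  }
})

test_that("cutoff selection matches the worked example and brute force", {
  v <- c(0.40, 0.52, 0.48, 0.55); l <- c(0, 0, 1, 1)
  cuts <- find_cutoffs(v, l)
  expect_equal(cuts$standard$cutoff, 0.5)
  expect_equal(cuts$max_sensitivity$cutoff, 0.44)
  expect_equal(cuts$max_sensitivity$sensitivity, 100)
  expect_equal(cuts$max_sensitivity$specificity, 50)
  # Youden tie between 0.44 and 0.535 resolves to the lower cutoff
  expect_equal(cuts$optimum$cutoff, 0.44)

  sep <- find_cutoffs(c(0.4, 0.45, 0.6, 0.65), c(0, 0, 1, 1))
  expect_equal(sep$optimum$cutoff, sep$max_sensitivity$cutoff)
  expect_equal(sep$optimum$sensitivity, 100)
  expect_equal(sep$optimum$specificity, 100)

  set.seed(71)
  for (trial in 1:100) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    values <- round(runif(n, 0.3, 0.7), 2)
    got <- find_cutoffs(values, labels)$optimum
    oracle <- brute_force_youden(values, labels)
    expect_equal(got$sensitivity + got$specificity - 100,
                 100 * oracle$j, tolerance = 1e-9)
  }
})

test_that("method self-comparison is exact agreement", {
  pop <- small_pop(render = FALSE)
  st <- run_study(pop)
  row <- compare_methods(st$measurements, "manual", "manual",
                        cases = st$cases)
  expect_equal(row$bias, 0)
  expect_equal(row$cv, 0)
  expect_equal(row$r2, 1)
})

test_that("range restriction lowers expected R2 (Monte-Carlo, one-sided)", {
  set.seed(83)
  r2_full <- r2_sub <- numeric(60)
  for (i in 1:60) {
    x <- c(runif(300, 0.35, 0.50), runif(300, 0.50, 0.70))
    y <- x * (1 + rnorm(600, 0, 0.05))
    r2_full[i] <- linear_fit_r2(x, y)$r2
    keep <- x > 0.5
    r2_sub[i] <- linear_fit_r2(x[keep], y[keep])$r2
  }
  expect_lt(mean(r2_sub), mean(r2_full))
  expect_gt(mean(r2_full) - mean(r2_sub), 2 * sd(r2_full - r2_sub) / sqrt(60))
})
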