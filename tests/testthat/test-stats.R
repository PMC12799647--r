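test_that("McNemar statistic matches hand computation and base R", {
  tb <- paired_binary_table(2, 30, 0, 36)
  m <- mcnemar(tb)
  expect_equal(m$chi2, 29^2 / 30, tolerance = 1e-12)
  expect_lt(m$p, 0.001)
  m2 <- mcnemar(tb, continuity = FALSE)
  expect_equal(m2$chi2, 30, tolerance = 1e-12)
  # independent oracle: stats::mcnemar.test on the same table
  M <- matrix(c(2, 30, 0, 36), 2, byrow = TRUE)
  expect_equal(m$chi2, unname(stats::mcnemar.test(M)$statistic),
               tolerance = 1e-12)
  expect_equal(m2$chi2,
               unname(stats::mcnemar.test(M, correct = FALSE)$statistic),
               tolerance = 1e-12)
  # symmetric discordance
  ms <- mcnemar(paired_binary_table(5, 7, 7, 5))
  expect_gte(ms$p, 0.5)
  expect_lte(ms$chi2, 1 / 14)
  expect_error(mcnemar(paired_binary_table(5, 0, 0, 5)), "discordant")
})

test_that("ARR and NNT follow from the collision counts", {
  a <- arr_nnt(32, 2, 68)
  expect_equal(100 * a$rate_ref, 47.1, tolerance = 0.05)
  expect_equal(100 * a$rate_alt, 2.9, tolerance = 0.05)
  expect_equal(100 * a$arr, 44.1, tolerance = 0.05)
  expect_equal(a$nnt, 2.27, tolerance = 0.005)
  z <- arr_nnt(10, 10, 50)
  expect_equal(z$arr, 0)
  expect_identical(z$nnt, Inf)
  e <- arr_nnt(68, 0, 68)
  expect_equal(e$arr, 1)
  expect_equal(e$nnt, 1)
  expect_error(arr_nnt(5, 2, 0), ">= 1")
})

test_that("odds ratios with Woolf intervals reproduce reference subgroup tables", {
  sex <- odds_ratio_2x2(c(24, 26, 8, 10))
  expect_equal(round(sex$or, 2), 1.15)
  expect_equal(round(sex$ci_low, 2), 0.39)
  expect_equal(round(sex$ci_high, 2), 3.41)
  expect_gt(sex$fisher_p, 0.99)
  side <- odds_ratio_2x2(c(19, 20, 13, 16))
  expect_equal(round(side$or, 2), 1.17)
  expect_equal(round(side$ci_low, 2), 0.45)
  expect_equal(round(side$ci_high, 2), 3.07)
  null <- odds_ratio_2x2(c(10, 10, 10, 10))
  expect_equal(null$or, 1.0)
  expect_equal(null$fisher_p, 1.0)
  expect_warning(zr <- odds_ratio_2x2(c(5, 0, 3, 4)), "Haldane")
  expect_true(zr$corrected)
  expect_error(odds_ratio_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("logistic fit recovers a known AI effect and flags degeneracies", {
  set.seed(101)
  n <- 500
  beta <- log(2.8) / 0.1
  ai <- rnorm(n, 0.67, 0.08)
  y <- rbinom(n, 1, plogis(-beta * 0.67 + beta * ai))
  f <- logistic_fit(y, data.frame(AI = ai), "AI")
  row <- f$or[f$or$term == "AI", ]
  expect_true(row$or_per_0_1_ci_low < 2.8 && 2.8 < row$or_per_0_1_ci_high)
  expect_true(f$converged)
  expect_false(f$separation)
  # agrees with a direct glm fit
  g <- stats::glm(y ~ ai, family = binomial())
  expect_equal(unname(f$coefficients[2]), unname(coef(g)[2]),
               tolerance = 1e-9)
  expect_error(logistic_fit(rep(1, 20), data.frame(AI = rnorm(20))),
               "single class")
  xsep <- c(rnorm(20, 0), rnorm(20, 10))
  ysep <- rep(c(0, 1), each = 20)
  expect_warning(fs <- logistic_fit(ysep, data.frame(AI = xsep), "AI"),
                 "separation")
  expect_true(fs$separation)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(202)
  ps <- replicate(150, {
    ai <- rnorm(150, 0.67, 0.08)
    y <- rbinom(150, 1, 0.4)
    suppressWarnings(logistic_fit(y, data.frame(AI = ai), "AI"))$wald_p["AI"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ROC analysis: exact AUC, Youden tie rule, degenerate input", {
  r <- roc_youden(c(0.6, 0.7, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  expect_true(r$threshold > 0.7 && r$threshold < 0.8)
  expect_equal(r$youden_j, r$sensitivity + r$specificity - 1,
               tolerance = 1e-12)
  set.seed(77)
  rn <- roc_youden(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(rn$auc - 0.5), 0.03)
  expect_error(roc_youden(rnorm(5), rep(1, 5)), "both")
  # ties broken toward the higher (more specific) threshold
  rt <- roc_youden(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_gt(rt$threshold, 2)
})

test_that("AUC equals the normalized Mann-Whitney statistic, ties half-counted", {
  set.seed(88)
  for (k in 1:20) {
    sc <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)  # heavy ties
    lb <- rbinom(60, 1, 0.5)
    if (length(unique(lb)) < 2) next
    r <- roc_youden(sc, lb)
    U <- sum(outer(sc[lb == 1], sc[lb == 0],
                   function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, U / (sum(lb) * sum(1 - lb)), tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(100)
  lb <- rbinom(100, 1, plogis(2 * sc))
  r <- roc_youden(sc, lb)
  pr <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  thr <- pROC::coords(pr, "best", best.method = "youden",
                      ret = "threshold")$threshold
  expect_equal(r$threshold, max(thr), tolerance = 1e-9)
})

test_that("bootstrap percentile intervals behave as expected", {
  d <- data.frame(x = rnorm(100), const = 1)
  b <- bootstrap_validate(d, function(df) c(m = mean(df$const)), B = 100,
                          seed = 4)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$median, 1)
  set.seed(55)
  d2 <- data.frame(x = rnorm(100))
  b2 <- bootstrap_validate(d2, function(df) c(m = mean(df$x)), B = 2000,
                           seed = 6)
  half <- (b2$ci_high - b2$ci_low) / 2
  expect_lt(abs(half - 1.96 / sqrt(100)), 0.05)
  b3 <- bootstrap_validate(d2, function(df) c(m = mean(df$x)), B = 2000,
                           seed = 6)
  expect_identical(b2, b3)
  # degenerate resamples are counted and warned about
  d4 <- data.frame(x = c(rep(NA_real_, 10), rnorm(30)))
  expect_warning(
    b4 <- bootstrap_validate(d4, function(df) c(m = mean(df$x[1:3])), B = 50,
                             seed = 2),
    "degenerate")
  expect_gt(attr(b4, "n_degenerate"), 5)
  expect_lt(attr(b4, "n_degenerate"), 50)
})

test_that("Cohen's kappa matches hand computations", {
  r1 <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(as.numeric(cohens_kappa(r1, r1)), 1.0)
  expect_equal(as.numeric(cohens_kappa(r1, !r1)), -1.0)
  # agreement table (20, 5, 5, 20): p_o = 0.8, p_e = 0.5, kappa = 0.6
  a <- c(rep(1, 25), rep(0, 25))
  b <- c(rep(1, 20), rep(0, 5), rep(1, 5), rep(0, 20))
  expect_equal(as.numeric(cohens_kappa(a, b)), 0.6, tolerance = 1e-12)
  expect_warning(k <- cohens_kappa(rep(1, 5), rep(1, 5)), "convention")
  expect_equal(as.numeric(k), 1.0)
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
})

test_that("two-way ICC recovers variance ratios and handles degeneracies", {
  M <- cbind(1:20, 1:20)
  expect_equal(icc_two_way(M)$icc, 1.0, tolerance = 1e-9)
  set.seed(66)
  Mn <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(icc_two_way(Mn)$icc), 0.12)
  subj <- rnorm(200, 0, 3)
  Ms <- cbind(subj + rnorm(200), subj + rnorm(200))
  r <- icc_two_way(Ms)
  expect_lt(abs(r$icc - 0.9), 0.05)
  expect_true(r$ci_low < r$icc && r$icc < r$ci_high)
  ra <- icc_two_way(Ms, form = "agreement")
  expect_lt(abs(ra$icc - 0.9), 0.06)
  expect_warning(z <- icc_two_way(matrix(c(1, 1, 2, 2), 2, 2)), "zero")
  expect_equal(z$icc, 0)
  expect_error(icc_two_way(matrix(1:2, 2, 1)), ">= 2")
})

test_that("rank tests wrap Spearman and Mann-Whitney correctly", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  r <- rank_tests(x, y = x)
  expect_equal(r$spearman$rho, 1.0)
  r2 <- rank_tests(x, y = -x)
  expect_equal(r2$spearman$rho, -1.0)
  g <- rep(c("a", "b"), each = 6)
  r3 <- rank_tests(c(x, x), groups = g)
  expect_gte(r3$mannwhitney$p, 0.99)
  expect_error(rank_tests(rep(1, 5), y = rnorm(5)), "constant")
})

test_that("McNemar sample size is sane and monotone in the effect", {
  n1 <- mcnemar_sample_size(0.25, 0.05)
  n2 <- mcnemar_sample_size(0.35, 0.05)
  expect_gt(n1, n2)
  expect_gt(n1, 10)
  expect_error(mcnemar_sample_size(0.2, 0.2), "differ")
})
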