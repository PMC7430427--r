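test_that("Bland-Altman matches the direct formula oracle", {
  # d = (-1, 0, 1): mean 0, sd 1 -> LoA = -/+ 1.96
  ba <- bland_altman(c(9, 10, 11), c(10, 10, 10))
  expect_equal(ba$mean_diff, 0, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 1, tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96, tolerance = 1e-12)
  # frozen independent arithmetic: t(0.975, 2) = 4.302653,
  # se_mean = 1/sqrt(3), se_loa = sqrt(3/3) = 1
  tq <- qt(0.975, 2)
  expect_equal(ba$ci_mean, c(-tq / sqrt(3), tq / sqrt(3)), tolerance = 1e-9)
  expect_equal(ba$ci_loa_high, c(1.96 - tq, 1.96 + tq), tolerance = 1e-9)
  # general seeded data against the written-out formulas
  set.seed(42)
  a <- rnorm(40, 400, 60); b <- a + rnorm(40, 10, 25)
  ba <- bland_altman(a, b)
  d <- a - b; n <- 40
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$ci_loa_low,
               mean(d) - 1.96 * sd(d) + c(-1, 1) * qt(0.975, n - 1) *
                 sd(d) * sqrt(3 / n), tolerance = 1e-12)
})

test_that("Bland-Altman symmetries hold", {
  set.seed(7)
  a <- rnorm(20, 100, 10); b <- rnorm(20, 95, 12)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$loa_low, -ba$loa_high)
  # location equivariance
  sh <- bland_altman(a + 50, b + 50)
  expect_equal(sh$mean_diff, ab$mean_diff, tolerance = 1e-12)
  expect_equal(sh$loa_high, ab$loa_high, tolerance = 1e-12)
  sa <- bland_altman(a + 7, b)
  expect_equal(sa$mean_diff, ab$mean_diff + 7, tolerance = 1e-12)
  expect_equal(sa$loa_low, ab$loa_low + 7, tolerance = 1e-12)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
  expect_warning(bland_altman(c(1, 2, 3), c(1, 2, 3) - 1), "zero variance")
})

test_that("Spearman association has the expected invariances", {
  set.seed(3)
  x <- runif(30); y <- exp(2 * x) + 0    # strictly monotone in x
  expect_equal(spearman_assoc(x, y)$rho, 1)
  expect_equal(spearman_assoc(x, -y)$rho, -1)
  # invariance under strictly monotone transforms
  z <- rnorm(30)
  r1 <- spearman_assoc(x, z)$rho
  r2 <- spearman_assoc(x^3, log(z - min(z) + 1))$rho
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 10), z[1:10]), "constant")
})

test_that("tied data reproduce the hand-ranked mid-rank computation", {
  x <- c(1, 2, 2, 3, 3, 3)
  y <- c(2, 1, 4, 4, 6, 5)
  # mid-ranks: x -> 1, 2.5, 2.5, 5, 5, 5 ; y -> 2, 1, 3.5, 3.5, 6, 5
  rx <- c(1, 2.5, 2.5, 5, 5, 5); ry <- c(2, 1, 3.5, 3.5, 6, 5)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_assoc(x, y)$rho, rho_hand, tolerance = 1e-12)
})

test_that("Shapiro-Wilk separates normal from exponential samples", {
  p_norm <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    normality_test(rnorm(100))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    normality_test(rexp(100))$p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.90)
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(1:2), "3 <= n")
})

test_that("quadratic-versus-linear comparison behaves at the extremes", {
  x <- seq(-5, 5, length.out = 30)
  q <- quad_vs_linear(x, x^2)
  expect_lt(q$rss_quadratic, 1e-18)
  expect_gt(q$rss_linear, 1)
  l <- quad_vs_linear(x, 2 * x)
  expect_lt(abs(coef(l$quadratic)[3]), 1e-10)
  expect_lte(l$rss_quadratic, l$rss_linear + 1e-12)
  expect_error(quad_vs_linear(rep(c(1, 2), 5), rnorm(10)), "3 distinct")
})

test_that("a small quadratic effect is detected with high power", {
  hits <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    x <- runif(100, 0, 100)
    y <- 0.5 * x + 0.002 * x^2 + rnorm(100, sd = 2)
    quad_vs_linear(x, y)$p_quadratic_term < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("size cross-tabulation counts reclassification and tests marginal homogeneity", {
  a <- c("small", "small", "medium", "large", "medium", "large",
         "small", "medium", "large", "small")
  expect_equal(size_crosstab(a, a)$n_reclassified, 0L)
  expect_equal(size_crosstab(a, a)$p, 1)
  b <- a; b[1] <- "medium"
  ct <- size_crosstab(a, b)
  expect_equal(ct$n_reclassified, 1L)
  expect_equal(sum(ct$table), 10)
  expect_equal(sum(ct$table) - sum(diag(ct$table)), ct$n_reclassified)
  expect_error(size_crosstab(a, a[-1]), "lengths")
})

test_that("the Stuart-Maxwell statistic matches the hand computation", {
  # N = [[10,3,1],[2,8,2],[0,1,9]]; d = (2, 0, -2)
  # S_sub = [[6,-5],[-5,8]], det 23, chi2 = (2,0) S^-1 (2,0)' = 32/23
  a <- c(rep("small", 14), rep("medium", 12), rep("large", 10))
  b <- c(rep("small", 10), rep("medium", 3), rep("large", 1),
         rep("small", 2), rep("medium", 8), rep("large", 2),
         rep("medium", 1), rep("large", 9))
  ct <- size_crosstab(a, b)
  expect_equal(unname(ct$table["small", "medium"]), 3)
  expect_equal(ct$statistic, 32 / 23, tolerance = 1e-12)
  expect_equal(ct$df, 2L)
  expect_equal(ct$p, pchisq(32 / 23, 2, lower.tail = FALSE), tolerance = 1e-12)
})
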