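test_that("kendall tau handles perfect orderings and the textbook example", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  r <- kendall_tau(1:4, c(1, 3, 2, 4))
  expect_equal(r$tau, 4 / 6)   # 5 concordant, 1 discordant of 6 pairs
  expect_equal(r$concordant, 5)
  expect_equal(r$discordant, 1)
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "tied")
})

test_that("tau-b and pair counts match brute-force enumeration with ties", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    a <- kendall_tau(x, y)
    b <- brute_kendall(x, y)
    expect_equal(a$tau, b$tau_b, tolerance = 1e-14)
    expect_identical(c(a$concordant, a$discordant), c(b$C, b$D))
    expect_identical(c(a$ties_x, a$ties_y), as.numeric(c(b$ties_x, b$ties_y)))
  }
})

test_that("tau p-values agree with the reference implementation", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- x + sample(-3:3, n, replace = TRUE)
    a <- kendall_tau(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(a$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(a$p_value, ref$p.value, tolerance = 1e-9)
  }
  # exact small-sample option against the reference exact test
  x <- c(1, 3, 2, 5, 4, 6, 8, 7); y <- c(2, 1, 4, 3, 6, 5, 7, 8)
  expect_equal(kendall_tau(x, y, exact = TRUE)$p_value,
               cor.test(x, y, method = "kendall", exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("tau is invariant under monotone transforms and antisymmetric", {
  set.seed(14)
  x <- rnorm(40); y <- x + rnorm(40)
  t0 <- kendall_tau(x, y)$tau
  expect_equal(kendall_tau(exp(x), y)$tau, t0)
  expect_equal(kendall_tau(x, y^3 + 5)$tau, t0)
  expect_equal(kendall_tau(-x, y)$tau, -t0)
})

test_that("M-location is robust, equivariant and interior", {
  expect_equal(m_location(c(1, 2, 3)), 2)
  est <- m_location(c(1, 2, 3, 1000))
  expect_gte(est, 1); expect_lte(est, 3.5)
  x <- c(2.3, 4.1, 0.7, 9.9, 3.3, 2.8)
  expect_equal(m_location(x + 17), m_location(x) + 17, tolerance = 1e-8)
  expect_warning(z <- m_location(c(5, 5, 5, 5, 9)), "MAD")
  expect_equal(z, 5)
  # always between min and max; equals the mean when nothing is far out
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(30)
    est <- m_location(x)
    expect_gte(est, min(x)); expect_lte(est, max(x))
  }
  tight <- c(0.9, 1.0, 1.1, 1.05, 0.95)
  expect_equal(m_location(tight, bend = 10), mean(tight), tolerance = 1e-8)
})

test_that("OLS matches the normal equations and flags rank deficiency", {
  x <- seq(-2, 3, length.out = 30)
  y <- 1 + 2 * x
  f <- ols_regression(cbind(`(Intercept)` = 1, x = x), y)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  set.seed(16)
  X <- cbind(1, rnorm(40), runif(40))
  yy <- X %*% c(0.5, -1, 2) + rnorm(40)
  f2 <- ols_regression(X, yy)
  expect_equal(unname(coef(f2)), normal_eq_coef(X, yy), tolerance = 1e-10)

  # orthogonal response: zero slope
  xo <- rep(c(-1, 1), 20); yo <- rep(c(1, 1), 20)
  expect_equal(unname(coef(ols_regression(cbind(1, xo), yo))[2]), 0)

  expect_error(ols_regression(cbind(1, x, 2 * x), y), "rank deficient")
})

test_that("MM regression is exact on noiseless data and equivariant", {
  set.seed(17)
  x <- rnorm(60)
  y <- 1 + 2 * x
  # noiseless data is an exact fit: coefficients returned, inference flagged
  expect_warning(f <- mm_regression(cbind(1, x), y), "exact fit")
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-6)
  expect_true(all(is.na(f$p_value)))

  yn <- y + rnorm(60, sd = 0.7)
  f1 <- mm_regression(cbind(1, x), yn, seed = 99)
  f2 <- mm_regression(cbind(1, x), 3 * yn, seed = 99)
  expect_equal(unname(coef(f2)), 3 * unname(coef(f1)), tolerance = 1e-6)
  f3 <- mm_regression(cbind(1, x), yn + 5 * x, seed = 99)
  expect_equal(unname(coef(f3))[2], unname(coef(f1))[2] + 5, tolerance = 1e-6)

  expect_error(mm_regression(cbind(1, x[1:4]), yn[1:4]), "n > 2p")
})

test_that("MM regression agrees with an independent MM implementation", {
  set.seed(18)
  x <- rnorm(150)
  y <- 1 + 2 * x + rnorm(150, sd = 0.6)
  y[1:25] <- y[1:25] + 40
  ours <- mm_regression(cbind(1, x), y)
  ref <- MASS::rlm(y ~ x, method = "MM")
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 0.05)
})

test_that("Huber regression matches the reference IRLS implementation", {
  set.seed(19)
  x <- rnorm(120)
  y <- 0.5 - 1.5 * x + rnorm(120)
  y[1:10] <- y[1:10] + 30
  ours <- huber_regression(cbind(1, x), y)
  ref <- MASS::rlm(y ~ x, k2 = 1.345, scale.est = "MAD", maxit = 200)
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 0.02)
})

test_that("ANCOVA reduces to t^2 = F with two groups and no covariate effect", {
  set.seed(20)
  g <- rep(c("a", "b"), each = 25)
  y <- rnorm(50) + (g == "b") * 0.8
  cv <- rnorm(50)  # unrelated covariate
  res <- ancova_f(y, g, cv)
  # two-sample pooled t on covariate-adjusted responses, computed independently
  resid0 <- residuals(lm(y ~ cv))
  tt <- t.test(resid0[g == "a"], resid0[g == "b"], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 0.05)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 50 - 2 - 1)  # n - groups - 1 with one covariate
  expect_error(ancova_f(y, rep("a", 50), cv), ">= 2 groups")
})

test_that("paired Cohen's d follows its definition", {
  expect_equal(cohens_d_paired(c(4, 5, 6), c(3, 3, 3)), 2)  # diffs (1,2,3)
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d_paired(x, x), 0)            # identical pairs
  expect_equal(cohens_d_paired(x, rev(x)), 0)       # symmetric differences
  expect_error(cohens_d_paired(x, x - 2), "zero variance")
})
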