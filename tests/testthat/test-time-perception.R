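horizons <- c(3, 6, 9, 12, 18, 24, 30, 36, 48, 60)

test_that("power law evaluates correctly and rejects bad input", {
  expect_equal(powerlaw(12, 1, 1), 12)
  expect_equal(powerlaw(9, 2, 0.5), 6)
  expect_equal(powerlaw(37, 0, 1.3), 0)
  expect_error(powerlaw(0, 1, 1), "> 0")
  expect_error(powerlaw(-3, 1, 1), "> 0")
  expect_error(powerlaw(3, -1, 1), ">= 0")
})

test_that("noiseless observations are recovered essentially exactly", {
  pr <- data.frame(horizon_months = horizons,
                   slider_mm = 1.5 * horizons^0.7)
  fit <- fit_time_perception(pr)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-4)
  expect_equal(fit$beta, 0.7, tolerance = 1e-4)
  expect_false(fit$bound_hit)
  expect_lt(max(abs(residuals(fit))), 1e-3)
})

test_that("super-linear data drives a parameter to its bound and is flagged", {
  # beta_true = 6 over short horizons: the exponent is clipped at 5
  h <- c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6)
  pr <- data.frame(horizon_months = h, slider_mm = 0.003 * h^6)
  fit <- fit_time_perception(pr)
  expect_equal(fit$beta, 5, tolerance = 1e-6)
  expect_true(fit$bound_hit)

  # an extreme, slider-clipped exponent still ends on a bound and is flagged
  pr2 <- data.frame(horizon_months = horizons,
                    slider_mm = pmin(1e-3 * horizons^8, 150))
  fit2 <- fit_time_perception(pr2)
  expect_true(fit2$bound_hit)
})

test_that("the robust loss resists a pinned slider better than plain least squares", {
  set.seed(31)
  sl <- 1.5 * horizons^0.7 + rnorm(10, 0, 1.5)
  sl[7] <- 150  # one probe pinned at the slider maximum
  pr <- data.frame(horizon_months = horizons, slider_mm = pmax(sl, 0))
  robust <- fit_time_perception(pr)
  ols <- minpack.lm::nlsLM(slider_mm ~ alpha * horizon_months^beta, data = pr,
                           start = list(alpha = 1, beta = 1),
                           lower = c(0, 0), upper = c(5, 5))
  expect_lt(abs(robust$beta - 0.7), abs(coef(ols)[["beta"]] - 0.7))
  expect_lt(abs(robust$alpha - 1.5), abs(coef(ols)[["alpha"]] - 1.5))
})

test_that("fits are scale equivariant while inside the bounds", {
  set.seed(32)
  pr <- data.frame(horizon_months = horizons,
                   slider_mm = 1.2 * horizons^0.8 + rnorm(10, 0, 1))
  f1 <- fit_time_perception(pr)
  pr2 <- pr; pr2$slider_mm <- 2 * pr$slider_mm
  f2 <- fit_time_perception(pr2)
  expect_equal(f2$alpha, 2 * f1$alpha, tolerance = 1e-4)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-4)
})

test_that("input validation catches malformed probe sets", {
  expect_error(fit_time_perception(
    data.frame(horizon_months = c(3, 3, 3, 3), slider_mm = 1:4)), "distinct")
  expect_error(fit_time_perception(
    data.frame(horizon_months = c(-1, 3, 6), slider_mm = 1:3)), "non-positive")
})

test_that("boxplot stage flags parameter outliers among non-bound fits", {
  base <- data.frame(subject_id = sprintf("P%d", 1:6),
                     alpha = c(1, 1, 1, 1, 1, 4.9),
                     beta = rep(0.8, 6), bound_hit = FALSE)
  out <- flag_outlier_fits(base)
  expect_identical(out$boxplot_outlier, c(rep(FALSE, 5), TRUE))
  expect_identical(out$excluded, out$boxplot_outlier)

  # identical parameters: values sit on the fences, nothing flagged
  same <- base; same$alpha <- 1
  expect_false(any(flag_outlier_fits(same)$boxplot_outlier))

  # a bound-hit fit is excluded regardless of boxplot status, and does not
  # enter the quartiles
  bh <- base; bh$bound_hit[2] <- TRUE
  out2 <- flag_outlier_fits(bh)
  expect_true(out2$excluded[2])
  expect_false(out2$boxplot_outlier[2])

  # too few usable fits: warning, no boxplot flags
  few <- base[1:4, ]
  expect_warning(out3 <- flag_outlier_fits(few), "fewer than 5")
  expect_false(any(out3$boxplot_outlier))
})

test_that("exclusion accounting adds up without double counting", {
  cfg <- cohort_config(seed = 77)
  sim <- simulate_cohort(cfg)
  tp <- fit_tp_cohort(sim$time_probes)
  f <- tp$fits
  expect_equal(sum(f$excluded),
               sum(f$bound_hit) + sum(f$boxplot_outlier & !f$bound_hit))
  expect_true(all(f$excluded == (f$bound_hit | f$boxplot_outlier)))
  # careless responders drive an exclusion count of the published order
  expect_gt(tp$n_excluded, 20)
  expect_lt(tp$n_excluded, 90)
  # most careless responders are caught
  to_ids <- sim$truth$subject_id[sim$truth$is_time_outlier]
  caught <- sum(f$excluded[f$subject_id %in% to_ids])
  expect_gte(caught / length(to_ids), 0.8)
})
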