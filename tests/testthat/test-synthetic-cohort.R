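test_that("default configuration reproduces the study's group structure", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(cohort$subjects), 242)
  expect_equal(unname(table(factor(cohort$subjects$group_label,
                                   c("young", "middle", "older")))),
               c(84L, 54L, 104L), ignore_attr = TRUE)
  expect_equal(sum(cohort$truth$is_random_responder), 7)
  # age bias is exactly the stated difference
  expect_equal(cohort$subjects$age_bias,
               cohort$subjects$physical_age - cohort$subjects$chronological_age)
  # invariants on ranges
  expect_true(all(cohort$subjects$chronological_age > 0))
  expect_true(all(cohort$subjects$physical_health >= 1 &
                    cohort$subjects$physical_health <= 5))
  expect_true(all(cohort$subjects$childhood_ses >= 1 &
                    cohort$subjects$childhood_ses <= 7))
  expect_true(all(cohort$truth$k_true > 0))
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(group_sizes = c(2, 2, 2), male_counts = c(1, 1, 1), seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$choices, s2$choices)
  expect_identical(s1$time_probes, s2$time_probes)
})

test_that("marginal moments and the copula association hold at large n", {
  cfg <- cohort_config(group_sizes = rep(1000, 3), male_counts = rep(500, 3),
                       seed = 6)
  cohort <- generate_cohort(cfg)
  s <- cohort$subjects
  for (g in 1:3) {
    sub <- s[s$group_label == c("young", "middle", "older")[g], ]
    expect_equal(mean(sub$chronological_age), cfg$age_means[g], tolerance = 0.05)
    expect_equal(sd(sub$chronological_age), cfg$age_sds[g], tolerance = 0.05)
    expect_equal(mean(sub$childhood_ses), cfg$ses_mean[g], tolerance = 0.05)
    expect_equal(sd(sub$childhood_ses), cfg$ses_sd[g], tolerance = 0.05)
    expect_equal(mean(sub$lhs), cfg$lhs_mean[g], tolerance = 0.05)
    expect_equal(sd(sub$lhs), cfg$lhs_sd[g], tolerance = 0.05)
    expect_equal(mean(sub$physical_health), cfg$phys_health_mean[g],
                 tolerance = 0.05)
  }
  # empirical SES-LHS tau within +-0.05 of the configured 0.22 target
  expect_equal(cor(s$childhood_ses, s$lhs, method = "kendall"), 0.22,
               tolerance = 0.05 / 0.22)
})

test_that("structural couplings carry the configured signs at large n", {
  cfg <- cohort_config(group_sizes = rep(1000, 3), male_counts = rep(500, 3),
                       seed = 7)
  cohort <- generate_cohort(cfg)
  d <- merge(cohort$subjects, cohort$truth, by = "subject_id")
  expect_lt(cor(d$lhs, d$log_k_true, method = "kendall"), 0)
  young <- d[d$group_label == "young", ]
  older <- d[d$group_label == "older", ]
  expect_lt(cor(young$chronological_age, young$log_k_true, method = "kendall"), 0)
  expect_gt(cor(older$chronological_age, older$log_k_true, method = "kendall"), 0)
  # health-dependent age bias: feeling older goes with poorer health
  expect_lt(cor(d$physical_health, d$age_bias, method = "kendall"), 0)
})

test_that("the structural log-k surface evaluates as stated", {
  cfg <- cohort_config()
  # null structure: baseline everywhere
  cfg0 <- cohort_config(beta_lhs = 0, u_shape = c(0, 0))
  expect_equal(true_logk(c(2, 5, 7), c(20, 40, 60),
                         c("young", "middle", "older"), cfg0),
               rep(cfg0$baseline_logk, 3))
  # linearity in lhs
  d <- true_logk(5, 25, "young", cfg) - true_logk(4, 25, "young", cfg)
  expect_equal(d, cfg$beta_lhs)
  # direct evaluation of the young age slope: -0.05 * (20 - 30) = 0.5
  cfg2 <- cohort_config(u_shape = c(-0.05, 0.06))
  expect_equal(true_logk(5, 20, "young", cfg2) - true_logk(5, 30, "young", cfg2),
               0.5)
  # no age effect in the middle group
  expect_equal(true_logk(5, 36, "middle", cfg), true_logk(5, 46, "middle", cfg))
  expect_error(true_logk(5, 30, "adolescent", cfg), "unknown group")
})

test_that("choice generation follows the logistic rule in the long run", {
  one_item <- data.frame(item_id = "i1", ss_amount = 2000, ll_amount = 4000,
                         delay_days = 120)
  # closed-form probability for k = 0.02, sigma = 0.05
  sv <- 4000 / (1 + 0.02 * 120)
  p_true <- plogis(0.05 * (2000 - sv))
  truth <- data.frame(subject_id = sprintf("M%05d", 1:10000), k_true = 0.02,
                      sigma_true = 0.05)
  ch <- generate_choice_responses(truth, one_item, seed = 8)
  expect_equal(mean(ch$chose_ss), p_true, tolerance = 0.02 / max(p_true, 0.5))

  # zero sensitivity: indifference
  truth0 <- truth; truth0$sigma_true <- 0
  ch0 <- generate_choice_responses(truth0, one_item, seed = 9)
  expect_equal(mean(ch0$chose_ss), 0.5, tolerance = 0.04)

  # deterministic limit: SS valuable and sensitivity huge
  truth1 <- data.frame(subject_id = sprintf("D%03d", 1:200), k_true = 0.5,
                       sigma_true = 100)
  ch1 <- generate_choice_responses(truth1, one_item, seed = 10)
  expect_true(all(ch1$chose_ss == 1))

  expect_error(generate_choice_responses(truth, one_item[0, ], seed = 1))
})

test_that("time probes follow the power law with truncation and corruption", {
  # identity parameters, no noise
  tr <- data.frame(subject_id = "a", alpha_true = 1, beta_true = 1)
  pr <- generate_time_probes(tr, c(3, 12, 60), seed = 1, noise_sd = 1e-12)
  expect_equal(pr$slider_mm, c(3, 12, 60), tolerance = 1e-6)

  tr2 <- data.frame(subject_id = "b", alpha_true = 2, beta_true = 0.5)
  pr2 <- generate_time_probes(tr2, 9, seed = 1, noise_sd = 1e-12)
  expect_equal(pr2$slider_mm, 6, tolerance = 1e-6)

  # Monte-Carlo mean at t = 12 within +-0.2 of alpha * 12^beta
  trm <- data.frame(subject_id = sprintf("m%05d", 1:10000),
                    alpha_true = 1.5, beta_true = 1)
  prm <- generate_time_probes(trm, 12, seed = 2, noise_sd = 5)
  expect_equal(mean(prm$slider_mm), 1.5 * 12, tolerance = 0.2 / 18)

  # careless responders answer uniformly
  trc <- data.frame(subject_id = sprintf("c%04d", 1:2000),
                    alpha_true = 1.5, beta_true = 0.75, is_time_outlier = TRUE)
  prc <- generate_time_probes(trc, c(3, 60), seed = 3)
  expect_equal(mean(prc$slider_mm), 75, tolerance = 0.03)
  expect_true(all(prc$slider_mm >= 0 & prc$slider_mm <= 150))

  expect_error(generate_time_probes(tr, c(0, 3), seed = 1), "non-positive")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(cohort_config(group_sizes = c(0, 54, 104)), "positive")
  expect_error(cohort_config(age_sds = c(-1, 2, 2)), "SDs")
  expect_error(cohort_config(random_responder_rate = 1.2), "rates")
  expect_error(cohort_config(u_shape = c(0.1, 0.2)), "slope_young")
  expect_error(cohort_config(ses_lhs_tau = 1.5), "tau")
})
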