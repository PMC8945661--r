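test_that("subjective value discounts hyperbolically", {
  expect_equal(subjective_value(8190, 0, 939), 8190)     # k = 0: no discounting
  expect_equal(subjective_value(1000, 0.01, 100), 500)   # 1 + kD = 2
  expect_equal(subjective_value(2311, 0.25, 4), 1155.5)  # kD = 1
  expect_equal(subjective_value(500, 0.1, 0), 500)       # D = 0

  # strictly decreasing in k and in D
  ks <- seq(0.001, 0.5, length.out = 40)
  expect_true(all(diff(subjective_value(1000, ks, 30)) < 0))
  ds <- seq(1, 900, length.out = 40)
  expect_true(all(diff(subjective_value(1000, 0.02, ds)) < 0))

  expect_error(subjective_value(1000, -0.1, 10), "non-negative")
})

test_that("choice probability follows the logistic rule and conserves mass", {
  expect_equal(choice_probability(500, 500, 0.3), 0.5)    # indifference point
  expect_equal(choice_probability(900, 300, 0), 0.5)      # zero sensitivity
  # sigma * (SS - SV) = 1
  expect_equal(choice_probability(301, 300, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)

  # P(SS) + P(LL) = 1 to machine precision, including extreme arguments
  set.seed(42)
  for (i in 1:50) {
    ss <- runif(1, 100, 5000); sv <- runif(1, 100, 9000)
    sig <- exp(runif(1, log(1e-6), log(10)))
    p <- choice_probability(ss, sv, sig)
    q <- plogis(-sig * (ss - sv))
    expect_equal(p + q, 1, tolerance = 1e-15)
    expect_true(p >= 0 && p <= 1)
  }
  # overflow safety
  expect_equal(choice_probability(5000, 100, 1e6), 1)
  expect_equal(choice_probability(100, 5000, 1e6), 0)
  expect_error(choice_probability(1, 1, -1), "sigma")
})

test_that("negative log-likelihood matches hand evaluation", {
  items <- default_choice_items()
  resp <- data.frame(item_id = items$item_id, chose_ss = c(1, 0, 1, 0, 1, 0, 1))
  # sigma = 0: every choice has probability 1/2
  expect_equal(negative_log_likelihood(0.02, 0, resp, items), 7 * log(2),
               tolerance = 1e-12)

  # arbitrary (k, sigma) on a 3-choice set equals the sum of per-choice terms
  r3 <- resp[1:3, ]
  k <- 0.013; sig <- 0.004
  by_hand <- 0
  for (i in 1:3) {
    it <- items[items$item_id == r3$item_id[i], ]
    sv <- it$ll_amount / (1 + k * it$delay_days)
    p_ss <- 1 / (1 + exp(-sig * (it$ss_amount - sv)))
    by_hand <- by_hand - log(if (r3$chose_ss[i] == 1) p_ss else 1 - p_ss)
  }
  expect_equal(negative_log_likelihood(k, sig, r3, items), by_hand,
               tolerance = 1e-10)

  bad <- data.frame(item_id = "nope", chose_ss = 1)
  expect_error(negative_log_likelihood(0.02, 0.01, bad, items), "unknown item")
})

test_that("subject fit recovers parameters from dense choice data", {
  items <- sample_choice_items(500, seed = 21)
  truth <- data.frame(subject_id = "A", k_true = 0.02, sigma_true = 0.05)
  ch <- generate_choice_responses(truth, items, seed = 22)
  fit <- fit_dd_subject(ch, items, subject_id = "A")
  expect_true(fit$converged)
  expect_lt(abs(fit$log_k - log(0.02)), 0.15)
  expect_equal(fit$log_k, log(fit$k))
  expect_equal(fit$n_choices, 500)
})

test_that("degenerate and random response patterns are screened out", {
  items <- default_choice_items()
  all_ss <- data.frame(item_id = items$item_id, chose_ss = rep(1, 7))
  f1 <- fit_dd_subject(all_ss, items)
  expect_false(f1$converged)
  expect_identical(f1$exclusion_reason, "degenerate_choice_pattern")

  all_ll <- data.frame(item_id = items$item_id, chose_ss = rep(0, 7))
  expect_false(fit_dd_subject(all_ll, items)$converged)

  # items are ordered by decreasing indifference rate, so a pattern that is
  # maximally inconsistent with every rate cutoff has a near-flat likelihood
  zigzag <- data.frame(item_id = items$item_id, chose_ss = c(1, 0, 1, 0, 1, 0, 1))
  f2 <- fit_dd_subject(zigzag, items)
  expect_false(f2$converged)

  expect_error(fit_dd_subject(all_ss[0, ], items), "no responses")
})

test_that("cohort fitting excludes random responders but not genuine subjects", {
  # genuine subjects with adequate trials: no exclusions
  items <- sample_choice_items(60, seed = 5)
  truth <- data.frame(subject_id = sprintf("G%02d", 1:12),
                      k_true = exp(seq(-6, -2, length.out = 12)),
                      sigma_true = 0.05, is_random_responder = FALSE)
  ch <- generate_choice_responses(truth, items, seed = 6)
  fits <- fit_dd_cohort(ch, items)
  expect_equal(fits$n_excluded, 0)

  # excluded subjects never reach the analysis table
  truth$is_random_responder[1:3] <- TRUE
  ch2 <- generate_choice_responses(truth, items, seed = 7)
  fits2 <- fit_dd_cohort(ch2, items)
  tab <- dd_fits_table(fits2)
  excluded_ids <- fits2$fits$subject_id[!fits2$fits$converged]
  expect_true(all(!excluded_ids %in% tab$subject_id))
  expect_true(all(tab$converged))

  # duplicate (subject, item) rows are rejected
  expect_error(fit_dd_cohort(rbind(ch, ch[1, ]), items), "duplicate")
})

test_that("seven injected random responders are mostly caught at cohort scale", {
  cfg <- cohort_config(seed = 404)
  sim <- simulate_cohort(cfg)
  fits <- fit_dd_cohort(sim$choices, sim$items)
  rr_ids <- sim$truth$subject_id[sim$truth$is_random_responder]
  expect_length(rr_ids, 7)
  caught <- sum(!fits$fits$converged[fits$fits$subject_id %in% rr_ids])
  expect_gte(caught, 5)
  # genuine subjects are rarely lost to screening
  false_excl <- sum(!fits$fits$converged[!fits$fits$subject_id %in% rr_ids])
  expect_lte(false_excl, 6)
})

test_that("rate estimates preserve subject ordering with the 7-item set", {
  set.seed(88)
  n <- 100
  logk <- rnorm(n, -4, 1)
  logk <- pmin(pmax(logk, -6.5), -1.2)  # inside the set's discriminable range
  truth <- data.frame(subject_id = sprintf("R%03d", 1:n), k_true = exp(logk),
                      sigma_true = 0.05)
  ch <- generate_choice_responses(truth, default_choice_items(), seed = 89)
  fits <- fit_dd_cohort(ch)
  m <- merge(dd_fits_table(fits), truth, by = "subject_id")
  expect_gte(cor(m$log_k, log(m$k_true), method = "spearman"), 0.8)
})

test_that("dd_fit methods are coherent", {
  items <- default_choice_items()
  resp <- data.frame(item_id = items$item_id, chose_ss = c(0, 0, 0, 1, 1, 1, 1))
  fit <- fit_dd_subject(resp, items)
  expect_named(coef(fit), c("k", "sigma"))
  expect_equal(as.numeric(logLik(fit)), -fit$nll)
  pr <- predict(fit, items)
  expect_equal(pr$sv, subjective_value(items$ll_amount, fit$k, items$delay_days))
  sim <- simulate(fit, nsim = 3, seed = 1, items = items)
  expect_equal(nrow(sim), 21)
  expect_true(all(sim$chose_ss %in% 0:1))
  expect_output(print(fit), "Hyperbolic")
})
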