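# Independent oracles used across the suite.  These deliberately use naive,
# transparent algorithms (explicit loops, dense grids, textbook formulas) so
# they share no code path with the package implementations they check.

# O(n^2) pair counting for Kendall tau-b via an explicit double loop
brute_kendall <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L; tx <- 0L; ty <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
      else if (dx == 0) tx <- tx + 1L
      else if (dy == 0) ty <- ty + 1L
      else if (dx * dy > 0) C <- C + 1L
      else D <- D + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  list(C = C, D = D,
       tau_b = (C - D) / sqrt((n0 - tx) * (n0 - ty)),
       ties_x = tx, ties_y = ty)
}

# dense-grid minimum of the discounting negative log-likelihood, the
# acceptance oracle: 200 x 200 over log k in [-9, 0], sigma in [1e-4, 1]
grid_nll_min <- function(responses, items, n_grid = 200) {
  idx <- match(responses$item_id, items$item_id)
  ss <- items$ss_amount[idx]; ll <- items$ll_amount[idx]; d <- items$delay_days[idx]
  sq <- ifelse(responses$chose_ss == 1, 1, -1)
  kg <- exp(seq(-9, 0, length.out = n_grid))
  sg <- seq(1e-4, 1, length.out = n_grid)
  m <- Inf
  for (k in kg) {
    x <- ss - ll / (1 + k * d)
    v <- -colSums(plogis(outer(sq * x, sg), log.p = TRUE))
    m <- min(m, min(v))
  }
  m
}

# normal-equations OLS coefficients, independent of lm machinery
normal_eq_coef <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# classical (non-robust) product-of-paths mediation via lm, for robustness
# comparisons
ols_indirect <- function(x, m, y) {
  a <- coef(lm(m ~ x))[2]
  b <- coef(lm(y ~ x + m))[3]
  unname(a * b)
}

# small cohort config used where full Table-1 sizes are unnecessary
small_config <- function(n = 20, seed = 1, ...) {
  cohort_config(group_sizes = rep(n, 3),
                male_counts = rep(floor(n / 2), 3), seed = seed, ...)
}

# config with every structural effect zeroed (null cohort)
null_config <- function(n = 50, seed = 1) {
  cohort_config(group_sizes = rep(n, 3), male_counts = rep(floor(n / 2), 3),
                beta_lhs = 0, u_shape = c(0, 0), sex_logk_offset_young = 0,
                bias_logk_coupling_old = 0, health_age_coupling = 0,
                ses_lhs_tau = 0, ftp_lhs_tau = 0,
                random_responder_rate = 0, seed = seed)
}
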