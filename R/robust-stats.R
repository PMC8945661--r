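#' Kendall's tau-b rank correlation with significance test
#'
#' Tie-corrected Kendall rank correlation
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)},}
#' where \eqn{C}/\eqn{D} count concordant/discordant pairs, \eqn{n_0 =
#' n(n-1)/2} and \eqn{n_1}, \eqn{n_2} are the tied-pair counts in each
#' variable.  The two-sided p-value uses the normal approximation with the
#' tie-adjusted variance of \eqn{S = C - D}; for small untied samples an exact
#' p-value from the null distribution of \eqn{S} (inversion-count recursion) is
#' available.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param exact use the exact null distribution (untied data, n <= 10 only).
#' @return object of class `kendall_cor`: `tau`, `p_value`, `n`, `S`,
#'   `concordant`, `discordant`, `ties_x`, `ties_y`.
#' @export
#' @examples
#' kendall_tau(1:4, c(1, 3, 2, 4))$tau  # 2/3
kendall_tau <- function(x, y, exact = FALSE) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop_input("kendall_tau: need n >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop_input("kendall_tau: all values tied in x or y; tau undefined")

  up <- upper.tri(matrix(0, n, n))
  sx <- sign(outer(x, x, "-"))[up]
  sy <- sign(outer(y, y, "-"))[up]
  s <- sx * sy
  C <- sum(s > 0); D <- sum(s < 0)
  S <- C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  has_ties <- n1 > 0 || n2 > 0
  if (exact && !has_ties && n <= 10) {
    p <- kendall_exact_p(S, n)
  } else {
    if (exact) warning("exact p unavailable (ties or n > 10); using normal approximation")
    # tie-adjusted variance of S (Kendall 1970)
    t_ <- as.numeric(tx); u_ <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(t_ * (t_ - 1) * (2 * t_ + 5)); vu <- sum(u_ * (u_ - 1) * (2 * u_ + 5))
    v1 <- sum(t_ * (t_ - 1)) * sum(u_ * (u_ - 1)) / (2 * n * (n - 1))
    v2 <- sum(t_ * (t_ - 1) * (t_ - 2)) * sum(u_ * (u_ - 1) * (u_ - 2)) /
      (9 * n * (n - 1) * (n - 2))
    vS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(vS)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(tau = tau, p_value = min(p, 1), n = n, S = S,
                 concordant = C, discordant = D,
                 ties_x = n1, ties_y = n2),
            class = "kendall_cor")
}

# exact null distribution of S via the number-of-inversions recursion:
# S = n0 - 2*inversions for untied data.
kendall_exact_p <- function(S, n) {
  n0 <- n * (n - 1) / 2
  # counts[i+1] = number of permutations of 1..m with i inversions
  counts <- 1
  for (m in 2:n) {
    new <- numeric(length(counts) + m - 1)
    for (i in 0:(m - 1)) {
      new[(i + 1):(i + length(counts))] <- new[(i + 1):(i + length(counts))] + counts
    }
    counts <- new
  }
  probs <- counts / sum(counts)
  inv_obs <- (n0 - S) / 2
  svals <- n0 - 2 * (seq_along(probs) - 1)
  p <- sum(probs[abs(svals) >= abs(S)])
  min(p, 1)
}

#' @export
print.kendall_cor <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f  (n = %d, p = %.4g)\n", x$tau, x$n, x$p_value))
  cat(sprintf("  pairs: %d concordant, %d discordant; tied pairs x: %d, y: %d\n",
              x$concordant, x$discordant, x$ties_x, x$ties_y))
  invisible(x)
}

#' Huber M-estimate of location
#'
#' Iteratively reweighted location estimate with Huber psi and MAD scale:
#' observations further than `bend` MAD-scale units from the current centre
#' are downweighted proportionally.  Equals the sample mean when no
#' observation exceeds `bend` scale units from the centre; always lies between
#' the minimum and maximum of the data.
#'
#' @param x numeric, n >= 2.
#' @param bend Huber tuning constant (default 1.28, the usual convention in
#'   the robust-statistics literature this follows).
#' @param tol,maxit convergence controls.
#' @return scalar location estimate.  If the MAD is zero, returns the median
#'   with a warning.
#' @export
m_location <- function(x, bend = 1.28, tol = 1e-8, maxit = 500) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 2) stop_input("m_location: need n >= 2 finite values")
  s <- mad(x)
  if (s <= 0) {
    warning("m_location: MAD is zero; returning median")
    return(median(x))
  }
  mu <- median(x)
  for (i in seq_len(maxit)) {
    u <- (x - mu) / s
    w <- pmin(1, bend / pmax(abs(u), 1e-300))
    new <- sum(w * x) / sum(w)
    if (abs(new - mu) < tol * s) return(new)
    mu <- new
  }
  mu
}

# ---- linear-model machinery ------------------------------------------------

# lean weighted LS solve; X must be full column rank
wls_coef <- function(X, y, w = NULL) {
  if (is.null(w)) {
    fit <- .lm.fit(X, y)
  } else {
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, y * sw)
  }
  if (fit$rank < ncol(X)) stop_input("design matrix is rank deficient")
  fit$coefficients
}

# lean Huber IRLS regression used by the mediation bootstrap: returns
# coefficients only.  Scale is the MAD of current residuals, re-estimated each
# pass; tuning k = 1.345 for ~95% Gaussian efficiency.
huber_reg_fit <- function(X, y, k = 1.345, tol = 1e-8, maxit = 100,
                          b_init = NULL) {
  b <- if (is.null(b_init)) wls_coef(X, y) else b_init
  r <- y - X %*% b
  for (i in seq_len(maxit)) {
    s <- mad(r, center = 0)
    if (s < 1e-12) break
    w <- pmin(1, k * s / pmax(abs(r), 1e-300))
    bn <- wls_coef(X, y, as.numeric(w))
    if (max(abs(bn - b)) < tol * max(1, max(abs(b)))) { b <- bn; break }
    b <- bn
    r <- y - X %*% b
  }
  as.numeric(b)
}

new_robust_fit <- function(terms, b, se, sigma, r2, tag, n, converged = TRUE) {
  # se = 0 marks an exact fit (zero robust scale): inference is undefined there
  tstat <- ifelse(se > 0, b / se, NA_real_)
  p <- 2 * pt(-abs(tstat), df = n - length(b))
  structure(list(terms = terms, coefficients = setNames(b, terms),
                 se = setNames(se, terms), t = setNames(tstat, terms),
                 p_value = setNames(p, terms), sigma = sigma,
                 r_squared = r2, estimator = tag, n = n, df = n - length(b),
                 converged = converged),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("%s regression (n = %d, R^2 = %.3f%s)\n", x$estimator, x$n,
              x$r_squared, if (x$estimator != "OLS") " robust" else ""))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `t value` = x$t, `Pr(>|t|)` = x$p_value)
  print(round(tab, 4))
  if (!x$converged) cat("  WARNING: estimator did not converge\n")
  invisible(x)
}

#' @export
summary.robust_fit <- function(object, ...) object

#' @export
coef.robust_fit <- function(object, ...) object$coefficients

#' Ordinary least squares on a design matrix
#'
#' Classical least-squares fit with textbook standard errors; serves as the
#' non-robust baseline and the backbone of the ANCOVA tests.
#'
#' @param X full-rank design matrix (include an intercept column if wanted);
#'   column names become term names.
#' @param y response vector.
#' @return object of class `robust_fit` with `estimator = "OLS"`.
#' @export
ols_regression <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop_input("ols_regression: design matrix is rank deficient")
  fit <- lm.fit(X, y)
  r <- fit$residuals
  s2 <- sum(r^2) / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * s2)
  # R^2 about the mean if an intercept-like column is present
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(r^2) / tss
  new_robust_fit(colnames(X), fit$coefficients, se, sqrt(s2), r2, "OLS", n)
}

# normalized Tukey bisquare rho (rho(Inf) = 1) and psi
rho_bisq <- function(u, c) ifelse(abs(u) <= c, 1 - (1 - (u / c)^2)^3, 1)
psi_bisq <- function(u, c) ifelse(abs(u) <= c, u * (1 - (u / c)^2)^2, 0)
dpsi_bisq <- function(u, c) {
  z <- (u / c)^2
  ifelse(abs(u) <= c, (1 - z) * (1 - 5 * z), 0)
}

# M-scale: solve mean(rho(r/s)) = delta by fixed-point iteration
m_scale <- function(r, c = 1.5476, delta = 0.5, tol = 1e-9, maxit = 200) {
  s <- median(abs(r)) / 0.6745
  if (s <= 0) return(0)
  for (i in seq_len(maxit)) {
    m <- mean(rho_bisq(r / s, c))
    s_new <- s * sqrt(m / delta)
    if (abs(s_new - s) < tol * s) return(s_new)
    s <- s_new
  }
  s
}

# IRLS for a bisquare M-step at fixed scale
bisq_irls <- function(X, y, b0, s, c, tol = 1e-9, maxit = 500) {
  b <- b0
  conv <- FALSE
  for (i in seq_len(maxit)) {
    r <- as.numeric(y - X %*% b)
    u <- r / s
    w <- ifelse(abs(u) <= c, (1 - (u / c)^2)^2, 0)
    if (sum(w > 0) < ncol(X)) break
    bn <- tryCatch(wls_coef(X, y, w), error = function(e) NULL)
    if (is.null(bn)) break
    if (max(abs(bn - b)) < tol * max(1, max(abs(b)))) { b <- bn; conv <- TRUE; break }
    b <- bn
  }
  list(b = b, converged = conv)
}

#' MM-estimator of linear regression
#'
#' High-breakdown, high-efficiency robust regression: an S-estimate of scale
#' (Tukey bisquare tuned for 50% breakdown, from random p-subset resampling
#' with local refinement) followed by a bisquare M-step tuned for 95% Gaussian
#' efficiency (c = 4.685) holding the S-scale fixed.  Standard errors use the
#' standard M-estimation sandwich
#' \eqn{\widehat{var}(\hat b) = s^2 \, \frac{n}{n-p} \,
#' \frac{\overline{\psi^2}}{(\overline{\psi'})^2} (X'X)^{-1}}.
#' The reported robust \eqn{R^2} is
#' \eqn{1 - \sum\rho(r_i/s) / \sum\rho((y_i - \hat\mu_y)/s)} with
#' \eqn{\hat\mu_y} a bisquare M-location of the response.
#'
#' @param X full-rank design matrix (with intercept column if wanted).
#' @param y response.
#' @param n_resample number of random p-subsets for the S-stage.
#' @param efficiency_c bisquare tuning of the M-step.
#' @param breakdown_c bisquare tuning of the S-scale (1.5476 gives 50%
#'   breakdown).
#' @param seed seed controlling the subset resampling; fixed by default so
#'   identical inputs give identical fits.
#' @return object of class `robust_fit` with `estimator = "MM"`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 1 + 2 * x + rnorm(50, sd = 0.5)
#' mm_regression(cbind(1, x), y)
mm_regression <- function(X, y, n_resample = 500, efficiency_c = 4.685,
                          breakdown_c = 1.5476, seed = 1042L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop_input("mm_regression: design matrix is rank deficient")
  if (n <= 2 * p) stop_input("mm_regression: need n > 2p observations")

  with_seed(seed, {
    # S-stage: exact fits through random p-subsets, keep best few by M-scale,
    # refine with full IRLS at the breakdown tuning
    cand <- list()
    best <- list(s = Inf, b = NULL)
    keep <- list()
    for (i in seq_len(n_resample)) {
      idx <- sample.int(n, p)
      b <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]), error = function(e) NULL)
      if (is.null(b) || anyNA(b)) next
      r <- y - X %*% b
      s <- m_scale(as.numeric(r), c = breakdown_c)
      if (s < best$s) best <- list(s = s, b = as.numeric(b))
      keep[[length(keep) + 1]] <- list(s = s, b = as.numeric(b))
    }
    if (is.null(best$b)) stop_input("mm_regression: S-stage failed on every subset")
    ord <- order(vapply(keep, `[[`, 0, "s"))
    tops <- keep[ord[seq_len(min(5, length(keep)))]]

    s_best <- Inf; b_best <- NULL
    for (cnd in tops) {
      s_cand <- m_scale(as.numeric(y - X %*% cnd$b), breakdown_c)
      if (s_cand <= 0) { s_best <- 0; b_best <- cnd$b; break }
      ref <- bisq_irls(X, y, cnd$b, s_cand, breakdown_c, maxit = 50)
      s_ref <- m_scale(as.numeric(y - X %*% ref$b), breakdown_c)
      if (s_ref < s_best) { s_best <- s_ref; b_best <- ref$b }
    }
    if (s_best <= 0 || !is.finite(s_best)) {
      # zero robust scale: at least half the observations lie exactly on the
      # fitted hyperplane (possible with coarsely quantized responses, e.g.
      # interval-identified discount rates).  Coefficients are the exact-fit
      # solution; standard errors and p-values are undefined.
      warning("mm_regression: exact fit (zero robust scale); no inference available")
      b <- b_best %||% best$b
      return(new_robust_fit(colnames(X), as.numeric(b), rep(0, p), 0, 1, "MM", n))
    }

    # M-step at efficiency tuning, scale fixed at the S-scale
    mstep <- bisq_irls(X, y, b_best, s_best, efficiency_c)
    b <- as.numeric(mstep$b)
    r <- as.numeric(y - X %*% b)
    u <- r / s_best

    psi <- psi_bisq(u, efficiency_c)
    dpsi <- dpsi_bisq(u, efficiency_c)
    denom <- mean(dpsi)^2
    kappa <- (n / (n - p)) * mean(psi^2) / max(denom, 1e-12)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(pmax(diag(XtXinv) * s_best^2 * kappa, 0))

    mu_y <- m_location_bisq(y, efficiency_c, s_best)
    denom_r2 <- sum(rho_bisq((y - mu_y) / s_best, efficiency_c))
    r2 <- max(0, 1 - sum(rho_bisq(u, efficiency_c)) / max(denom_r2, 1e-12))

    new_robust_fit(colnames(X), b, se, s_best, r2, "MM", n,
                   converged = mstep$converged)
  })
}

# bisquare M-location at fixed scale (for the robust R^2 denominator)
m_location_bisq <- function(y, c, s, maxit = 200, tol = 1e-9) {
  mu <- median(y)
  for (i in seq_len(maxit)) {
    u <- (y - mu) / s
    w <- ifelse(abs(u) <= c, (1 - (u / c)^2)^2, 0)
    if (sum(w) <= 0) return(mu)
    new <- sum(w * y) / sum(w)
    if (abs(new - mu) < tol * max(1, abs(mu))) return(new)
    mu <- new
  }
  mu
}

#' Huber M-regression
#'
#' Linear regression by iteratively reweighted least squares with Huber
#' weights (`k = 1.345`) on the MAD residual scale; monotone psi, so less
#' breakdown-resistant than [mm_regression()] but fast and convex.  Used as
#' the default path estimator in [robust_mediation()].
#'
#' @param X full-rank design matrix.
#' @param y response.
#' @param k Huber tuning constant.
#' @return object of class `robust_fit` with `estimator = "Huber"`.
#' @export
huber_regression <- function(X, y, k = 1.345) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop_input("huber_regression: design matrix is rank deficient")
  b <- huber_reg_fit(X, y, k = k)
  r <- as.numeric(y - X %*% b)
  s <- mad(r, center = 0)
  if (s < 1e-12) {
    return(new_robust_fit(colnames(X), b, rep(0, p), 0, 1, "Huber", n))
  }
  u <- r / s
  psi <- pmax(pmin(u, k), -k)
  dpsi <- as.numeric(abs(u) <= k)
  kappa <- (n / (n - p)) * mean(psi^2) / max(mean(dpsi)^2, 1e-12)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * s^2 * kappa)
  mu_y <- m_location(y, bend = k)
  r2 <- max(0, 1 - sum(pmin(u^2, k^2)) /
              max(sum(pmin(((y - mu_y) / s)^2, k^2)), 1e-12))
  new_robust_fit(colnames(X), b, se, s, r2, "Huber", n)
}

#' ANCOVA F test for a group factor given a covariate
#'
#' Classical nested-model F comparing `y ~ covariate` against
#' `y ~ covariate + group` by ordinary least squares, i.e. the adjusted group
#' effect after controlling for the covariate.  df1 = (groups - 1),
#' df2 = n - groups - 1 for one covariate.
#'
#' @param y response.
#' @param group factor (>= 2 levels, each with >= 2 members).
#' @param covariate numeric covariate.
#' @return list with `F`, `df1`, `df2`, `p_value`, `n`.
#' @export
ancova_f <- function(y, group, covariate) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop_input("ancova_f: need >= 2 groups")
  if (any(table(group) < 2)) stop_input("ancova_f: every group needs >= 2 members")
  d <- data.frame(y = y, g = group, cv = as.numeric(covariate))
  m0 <- lm(y ~ cv, data = d)
  m1 <- lm(y ~ cv + g, data = d)
  a <- anova(m0, m1)
  list(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2], p_value = a$`Pr(>F)`[2],
       n = nrow(d))
}

#' Paired Cohen's d
#'
#' Standardised mean difference for paired observations:
#' \eqn{d = \bar{x - y} / s_{x - y}} with the sample standard deviation of the
#' differences.
#'
#' @param x,y paired numeric vectors.
#' @return scalar d.
#' @export
cohens_d_paired <- function(x, y) {
  if (length(x) != length(y)) stop_input("cohens_d_paired: x and y must be paired")
  d <- x - y
  if (length(d) < 2) stop_input("cohens_d_paired: need n >= 2 pairs")
  if (all(d == 0)) return(0)  # identical pairs: no effect by definition
  s <- sd(d)
  if (s == 0) stop_input("cohens_d_paired: zero variance of differences; d undefined")
  mean(d) / s
}
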