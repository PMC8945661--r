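#' Hyperbolic subjective value of a delayed reward
#'
#' Discounts a delayed reward to the present day under the hyperbolic model
#' \deqn{SV = A / (1 + kD),} where \eqn{A} is the delayed amount, \eqn{D} the
#' delay in days and \eqn{k} the discount rate (per day).  Higher \eqn{k} means
#' steeper devaluation; \eqn{k = 0} or \eqn{D = 0} leaves the amount intact.
#'
#' @param ll_amount delayed (larger-later) amount, > 0. Vectorised.
#' @param k hyperbolic discount rate per day, >= 0.
#' @param delay_days delay in days, >= 0.
#' @return subjective value on the same scale as `ll_amount`.
#' @export
#' @examples
#' subjective_value(1000, k = 0.01, delay_days = 100)  # 500
subjective_value <- function(ll_amount, k, delay_days) {
  if (any(ll_amount < 0) || any(k < 0) || any(delay_days < 0))
    stop_input("subjective_value: all inputs must be non-negative")
  ll_amount / (1 + k * delay_days)
}

#' Probability of choosing the immediate reward
#'
#' Logistic (softmax / Luce) choice rule on the value difference between the
#' immediate amount and the discounted delayed amount:
#' \deqn{P(SS) = 1 / (1 + e^{-\sigma (SS - SV)}).}
#' The sensitivity \eqn{\sigma} (per currency unit) measures how strongly
#' choice tracks the value difference; \eqn{\sigma = 0} or \eqn{SS = SV} gives
#' indifference (0.5).  Evaluation is overflow-safe for large
#' \eqn{|\sigma (SS - SV)|}.
#'
#' @param ss_amount immediate amount(s).
#' @param sv subjective value(s) of the delayed reward, e.g. from
#'   [subjective_value()].
#' @param sigma choice sensitivity, >= 0.
#' @return probability of the immediate option, in (0, 1) for finite sigma.
#' @export
choice_probability <- function(ss_amount, sv, sigma) {
  if (any(sigma < 0)) stop_input("choice_probability: sigma must be >= 0")
  plogis(sigma * (ss_amount - sv))
}

# log P(observed choice) for each response; stable via plogis(log.p = TRUE).
# chose_ss in {0,1}; x = ss - sv.
choice_loglik <- function(x, chose_ss, sigma) {
  q <- sigma * x
  # log P(SS) = log plogis(q); log P(LL) = log plogis(-q)
  plogis(ifelse(chose_ss == 1, q, -q), log.p = TRUE)
}

#' Negative log-likelihood of a subject's choices
#'
#' Sum of \eqn{-\log P} over a subject's binary choices under the hyperbolic
#' model with logistic choice rule ([subjective_value()],
#' [choice_probability()]).
#'
#' @param k,sigma model parameters (k > 0, sigma >= 0).
#' @param responses data.frame with columns `item_id`, `chose_ss` (0/1).
#' @param items data.frame as [default_choice_items()].
#' @return scalar negative log-likelihood (>= 0).
#' @export
negative_log_likelihood <- function(k, sigma, responses, items) {
  validate_items(items)
  idx <- match(responses$item_id, items$item_id)
  if (anyNA(idx)) {
    stop_input("responses reference unknown item ids: ",
               paste(unique(responses$item_id[is.na(idx)]), collapse = ", "))
  }
  sv <- subjective_value(items$ll_amount[idx], k, items$delay_days[idx])
  x <- items$ss_amount[idx] - sv
  -sum(choice_loglik(x, responses$chose_ss, sigma))
}

# Vectorised NLL over a grid of (k, sigma): x_i precomputed per (item, k).
# Returns length(k_grid) x length(sigma_grid) matrix.  Used for multi-start
# seeding of the optimizer; the acceptance oracle reimplements this
# independently in tests.
dd_nll_grid <- function(chose_ss, ss, ll, d, k_grid, sigma_grid) {
  n_k <- length(k_grid)
  out <- matrix(NA_real_, n_k, length(sigma_grid))
  sign_q <- ifelse(chose_ss == 1, 1, -1)
  for (i in seq_len(n_k)) {
    x <- ss - ll / (1 + k_grid[i] * d)             # n_items
    qs <- outer(sign_q * x, sigma_grid)            # n_items x n_sigma
    out[i, ] <- -colSums(plogis(qs, log.p = TRUE))
  }
  out
}

#' Control parameters for discount-rate fitting
#'
#' @param logk_bounds search bounds for log k (natural log, k per day).
#' @param sigma_bounds search bounds for sigma (per currency unit); spans
#'   indifference to near-deterministic choice at the item amounts.
#' @param n_starts_grid number of multistart points per axis (>= 3).
#' @param coarse_grid_n side of the internal coarse grid used to seed the local
#'   searches (0 disables).
#' @param flat_lr_cut flat-likelihood cut: the fit is declared non-converged
#'   when twice the log-likelihood improvement over pure chance falls below
#'   this value (default the chi-square(2) 0.95 quantile), the operational
#'   analogue of "failed to converge" for random or inconsistent responders.
#' @param boundary_tol tolerance for declaring an estimate on a search bound.
#' @return list of class `dd_control`.
#' @export
dd_control <- function(logk_bounds = c(-9, 0),
                       sigma_bounds = c(1e-6, 10),
                       n_starts_grid = 3,
                       coarse_grid_n = 36,
                       flat_lr_cut = stats::qchisq(0.95, 2),
                       boundary_tol = 1e-6) {
  stopifnot(logk_bounds[1] < logk_bounds[2], sigma_bounds[1] > 0,
            sigma_bounds[1] < sigma_bounds[2], n_starts_grid >= 3)
  structure(list(logk_bounds = logk_bounds, sigma_bounds = sigma_bounds,
                 n_starts_grid = n_starts_grid, coarse_grid_n = coarse_grid_n,
                 flat_lr_cut = flat_lr_cut, boundary_tol = boundary_tol),
            class = "dd_control")
}

#' Fit the hyperbolic discounting model to one subject
#'
#' Maximum-likelihood estimation of the discount rate \eqn{k} and choice
#' sensitivity \eqn{\sigma} from binary intertemporal choices.  Optimisation is
#' performed in \eqn{(\log k, \log \sigma)} space (removing the positivity
#' constraints) with box bounds, multistart local searches seeded both from a
#' fixed start grid and from the best cells of an internal coarse
#' likelihood grid, followed by a Nelder-Mead polish of the best point.
#'
#' A fit is declared non-converged (`converged = FALSE`, with an
#' `exclusion_reason`) when the optimizer fails, when \eqn{\log k} sits on a
#' search bound, when \eqn{\sigma} sits on its lower bound, when the choice
#' pattern is degenerate (all-SS or all-LL, which leaves \eqn{k} unidentified),
#' or when the likelihood is flat (improvement over chance below
#' `flat_lr_cut`), the signature of a random responder.  A sensitivity estimate
#' at the UPPER bound is not treated as failure: with a small item set a
#' noiseless, perfectly cutoff-consistent subject is expected to drive
#' \eqn{\hat\sigma} upward while \eqn{k} remains interval-identified.
#'
#' @param responses data.frame with columns `item_id`, `chose_ss` for one
#'   subject (>= 1 row).
#' @param items item table, see [default_choice_items()].
#' @param control a [dd_control()] list.
#' @param subject_id optional identifier carried into the result.
#' @return object of class `dd_fit`: list with `k`, `sigma`, `log_k`, `nll`,
#'   `converged`, `exclusion_reason`, `n_choices`, plus fitting metadata.
#' @export
#' @examples
#' items <- default_choice_items()
#' resp <- data.frame(item_id = items$item_id,
#'                    chose_ss = c(0, 0, 0, 1, 1, 1, 1))
#' fit <- fit_dd_subject(resp, items)
#' coef(fit)
fit_dd_subject <- function(responses, items = default_choice_items(),
                           control = dd_control(), subject_id = NA_character_) {
  if (is.null(responses) || nrow(responses) == 0)
    stop_input("fit_dd_subject: no responses")
  validate_items(items)
  idx <- match(responses$item_id, items$item_id)
  if (anyNA(idx)) stop_input("fit_dd_subject: responses reference unknown items")
  if (!all(responses$chose_ss %in% c(0, 1)))
    stop_input("fit_dd_subject: chose_ss must be 0 or 1")

  ss <- items$ss_amount[idx]; ll <- items$ll_amount[idx]; d <- items$delay_days[idx]
  y <- responses$chose_ss
  n <- length(y)
  sign_q <- ifelse(y == 1, 1, -1)

  lb <- c(control$logk_bounds[1], log(control$sigma_bounds[1]))
  ub <- c(control$logk_bounds[2], log(control$sigma_bounds[2]))

  nll_fun <- function(par) {
    k <- exp(par[1]); sigma <- exp(par[2])
    x <- ss - ll / (1 + k * d)
    v <- -sum(plogis(sign_q * sigma * x, log.p = TRUE))
    if (!is.finite(v)) v <- .Machine$double.xmax / 2
    v
  }

  # multistart points: fixed grid inside the box
  g <- control$n_starts_grid
  starts <- as.matrix(expand.grid(
    seq(lb[1] + 0.15 * diff(c(lb[1], ub[1])), ub[1] - 0.15 * diff(c(lb[1], ub[1])), length.out = g),
    seq(lb[2] + 0.15 * diff(c(lb[2], ub[2])), ub[2] - 0.15 * diff(c(lb[2], ub[2])), length.out = g)
  ))

  # coarse grid seeding: add the best three grid cells as extra starts
  if (control$coarse_grid_n > 0) {
    kg <- exp(seq(lb[1], ub[1], length.out = control$coarse_grid_n))
    sg <- exp(seq(lb[2], ub[2], length.out = control$coarse_grid_n))
    gm <- dd_nll_grid(y, ss, ll, d, kg, sg)
    ord <- order(gm)[1:3]
    ij <- cbind((ord - 1) %% nrow(gm) + 1, (ord - 1) %/% nrow(gm) + 1)
    starts <- rbind(starts, cbind(log(kg[ij[, 1]]), log(sg[ij[, 2]])))
  }

  # prune: local searches only from the most promising starts (by raw NLL),
  # always including the coarse-grid leaders appended above
  v0 <- apply(starts, 1, nll_fun)
  n_fixed <- g * g
  keep <- union(order(v0)[seq_len(min(3, nrow(starts)))],
                if (nrow(starts) > n_fixed) (n_fixed + 1):nrow(starts))
  best <- NULL
  any_ok <- FALSE
  for (s in keep) {
    fit <- tryCatch(
      optim(starts[s, ], nll_fun, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- any_ok || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(new_dd_fit(subject_id, NA, NA, NA, NA_real_, FALSE, "optimizer_failure", n))
  }
  # Nelder-Mead polish from the best point (clamped back into the box)
  pol <- tryCatch(
    optim(best$par, function(p) nll_fun(pmin(pmax(p, lb), ub)),
          method = "Nelder-Mead", control = list(maxit = 200, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) {
    best <- list(par = pmin(pmax(pol$par, lb), ub), value = pol$value, convergence = 0)
    any_ok <- TRUE
  }

  par <- unname(best$par)
  k_hat <- exp(par[1]); sigma_hat <- exp(par[2])
  nll <- best$value

  reason <- NULL
  tol <- control$boundary_tol
  if (all(y == 1) || all(y == 0)) {
    reason <- "degenerate_choice_pattern"
  } else if (!any_ok) {
    reason <- "optimizer_failure"
  } else if (par[1] <= lb[1] + tol || par[1] >= ub[1] - tol) {
    reason <- "k_at_boundary"
  } else if (par[2] <= lb[2] + tol) {
    reason <- "sigma_at_lower_bound"
  } else if (2 * (n * log(2) - nll) < control$flat_lr_cut) {
    reason <- "flat_likelihood"
  }

  new_dd_fit(subject_id, k_hat, sigma_hat, log(k_hat), nll,
             is.null(reason), reason %||% NA_character_, n)
}

new_dd_fit <- function(subject_id, k, sigma, log_k, nll, converged, reason, n) {
  structure(list(subject_id = subject_id, k = k, sigma = sigma, log_k = log_k,
                 nll = nll, converged = converged, exclusion_reason = reason,
                 n_choices = n),
            class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  cat("Hyperbolic discounting fit",
      if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]"), "\n", sep = "")
  cat(sprintf("  k = %.5g /day   log k = %.4f   sigma = %.5g\n",
              x$k, x$log_k, x$sigma))
  cat(sprintf("  -logLik = %.4f over %d choices;  converged: %s\n",
              x$nll, x$n_choices, x$converged))
  if (!x$converged) cat("  exclusion reason:", x$exclusion_reason, "\n")
  invisible(x)
}

#' @export
coef.dd_fit <- function(object, ...) c(k = object$k, sigma = object$sigma)

#' @export
logLik.dd_fit <- function(object, ...) {
  structure(-object$nll, df = 2, nobs = object$n_choices, class = "logLik")
}

#' Predicted subjective values and choice probabilities
#' @param object a `dd_fit`.
#' @param newdata item table (defaults to the standard 7-item set).
#' @param ... unused.
#' @return data.frame with `item_id`, `sv`, `p_ss`.
#' @export
predict.dd_fit <- function(object, newdata = default_choice_items(), ...) {
  validate_items(newdata)
  sv <- subjective_value(newdata$ll_amount, object$k, newdata$delay_days)
  data.frame(item_id = newdata$item_id, sv = sv,
             p_ss = choice_probability(newdata$ss_amount, sv, object$sigma))
}

#' Simulate choices from a fitted (or specified) discounting model
#' @param object a `dd_fit`.
#' @param nsim number of replicate choice sets.
#' @param seed optional seed.
#' @param items item table.
#' @param ... unused.
#' @return data.frame with `sim`, `item_id`, `chose_ss`.
#' @export
simulate.dd_fit <- function(object, nsim = 1, seed = NULL,
                            items = default_choice_items(), ...) {
  p <- predict(object, items)$p_ss
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nsim), function(i) {
      data.frame(sim = i, item_id = items$item_id,
                 chose_ss = rbinom(length(p), 1, p))
    }))
  })
}

#' Fit discount rates for a whole cohort
#'
#' Runs [fit_dd_subject()] for every subject in a long-format choice table and
#' assembles per-subject estimates with an exclusion report.  Non-converged
#' subjects carry their `exclusion_reason` and must be dropped from downstream
#' analyses of `log_k` (use `included_only = TRUE` or filter on `converged`).
#'
#' @param choices data.frame with columns `subject_id`, `item_id`, `chose_ss`.
#' @param items item table.
#' @param control a [dd_control()].
#' @return object of class `dd_cohort_fit`: list with `fits` (one row per
#'   subject: `subject_id`, `k`, `sigma`, `log_k`, `nll`, `converged`,
#'   `exclusion_reason`, `n_choices`) and `exclusions` (counts by reason).
#' @export
fit_dd_cohort <- function(choices, items = default_choice_items(),
                          control = dd_control()) {
  req <- c("subject_id", "item_id", "chose_ss")
  miss <- setdiff(req, names(choices))
  if (length(miss)) stop_input("choices table missing columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(choices[c("subject_id", "item_id")])
  if (any(dup)) {
    stop_input("duplicate (subject_id, item_id) rows in choices table: rows ",
               paste(head(which(dup), 5), collapse = ", "))
  }
  ids <- unique(choices$subject_id)
  rows <- lapply(ids, function(id) {
    f <- fit_dd_subject(choices[choices$subject_id == id, , drop = FALSE],
                        items, control, subject_id = id)
    data.frame(subject_id = id, k = f$k, sigma = f$sigma, log_k = f$log_k,
               nll = f$nll, converged = f$converged,
               exclusion_reason = f$exclusion_reason, n_choices = f$n_choices,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  excl <- table(fits$exclusion_reason[!fits$converged])
  excl_df <- if (length(excl)) {
    data.frame(reason = names(excl), n = as.integer(excl),
               stringsAsFactors = FALSE)
  } else data.frame(reason = character(0), n = integer(0))
  structure(list(fits = fits,
                 exclusions = excl_df,
                 n_subjects = length(ids),
                 n_excluded = sum(!fits$converged)),
            class = "dd_cohort_fit")
}

#' @export
print.dd_cohort_fit <- function(x, ...) {
  cat(sprintf("Discounting fits: %d subjects, %d excluded\n",
              x$n_subjects, x$n_excluded))
  if (nrow(x$exclusions)) {
    for (i in seq_len(nrow(x$exclusions)))
      cat(sprintf("  %-28s %d\n", x$exclusions$reason[i], x$exclusions$n[i]))
  }
  ok <- x$fits$log_k[x$fits$converged]
  if (length(ok))
    cat(sprintf("  log k: median %.3f, IQR [%.3f, %.3f]\n",
                median(ok), quantile(ok, .25), quantile(ok, .75)))
  invisible(x)
}

#' Converged per-subject estimates
#' @param x a `dd_cohort_fit`.
#' @param included_only drop non-converged subjects (default TRUE).
#' @return data.frame of per-subject fits.
#' @export
dd_fits_table <- function(x, included_only = TRUE) {
  stopifnot(inherits(x, "dd_cohort_fit"))
  f <- x$fits
  if (included_only) f <- f[f$converged, , drop = FALSE]
  f
}
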