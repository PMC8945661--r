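#' Power-law anticipatory time perception
#'
#' Subjective duration of a prospective calendar interval,
#' \deqn{T = \alpha t^{\beta},} with \eqn{t} the calendar horizon in months.
#' \eqn{\alpha} captures the overall level of time contraction and \eqn{\beta}
#' diminishing sensitivity to longer horizons (concave for \eqn{\beta < 1}).
#'
#' @param t calendar horizon(s) in months, > 0.
#' @param alpha,beta non-negative parameters.
#' @return subjective duration(s) on the response scale.
#' @export
#' @examples
#' powerlaw(9, alpha = 2, beta = 0.5)  # 6
powerlaw <- function(t, alpha, beta) {
  if (any(t <= 0)) stop_input("powerlaw: horizons must be > 0")
  if (any(alpha < 0) || any(beta < 0)) stop_input("powerlaw: parameters must be >= 0")
  alpha * t^beta
}

#' Control parameters for the time-perception fit
#'
#' @param bounds box bounds for both parameters (published bounds 0 and 5).
#' @param huber_k Huber tuning constant on the MAD residual scale.
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @param bound_tol tolerance for flagging an estimate on a bound.
#' @export
tp_control <- function(bounds = c(0, 5), huber_k = 1.345,
                       tol = 1e-8, maxit = 200, bound_tol = 1e-6) {
  structure(list(bounds = bounds, huber_k = huber_k, tol = tol,
                 maxit = maxit, bound_tol = bound_tol), class = "tp_control")
}

# one bounded weighted nonlinear LS solve (Levenberg-Marquardt) from several
# starts, keeping the lowest weighted SSE; a start sitting on a box bound is
# nudged inside so the solver can leave a boundary basin.  Falls back to
# L-BFGS-B on the weighted SSE if nlsLM errors out.
tp_wnls <- function(t, T_obs, w, starts, bounds) {
  df <- data.frame(t = t, T_obs = T_obs)
  sse <- function(p) sum(w * (T_obs - p[1] * t^p[2])^2)
  best <- NULL
  for (start in starts) {
    start <- pmin(pmax(start, bounds[1] + 1e-4), bounds[2] - 1e-4)
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(T_obs ~ alpha * t^beta, data = df,
                             start = list(alpha = start[1], beta = start[2]),
                             weights = w,
                             lower = rep(bounds[1], 2), upper = rep(bounds[2], 2),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      coef(m)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      o <- tryCatch(optim(start, sse, method = "L-BFGS-B",
                          lower = rep(bounds[1], 2), upper = rep(bounds[2], 2)),
                    error = function(e) NULL)
      fit <- if (is.null(o)) start else o$par
    }
    if (is.null(best) || sse(fit) < sse(best)) best <- as.numeric(fit)
  }
  setNames(best, c("alpha", "beta"))
}

#' Fit the time-perception power law for one subject
#'
#' Robust bounded fit of \eqn{T = \alpha t^\beta} to a subject's slider
#' readings.  The loss is Huber-type, implemented as iteratively reweighted
#' nonlinear least squares: each pass solves a weighted Levenberg-Marquardt
#' problem under the box bounds, then recomputes Huber weights
#' \eqn{w_i = \min(1, c\,s/|r_i|)} with \eqn{s} the MAD scale of the current
#' residuals, until the coefficients move less than `tol`.  Starting values
#' come from the log-log OLS fit of the positive observations (\eqn{\beta}
#' started at 1 when too few are positive).  Estimates within `bound_tol` of a
#' bound set `bound_hit`, the first stage of the two-stage outlier exclusion
#' (see [flag_outlier_fits()] for the boxplot stage).
#'
#' @param probes data.frame with columns `horizon_months`, `slider_mm` (and
#'   optionally `subject_id`); at least 3 distinct horizons.
#' @param control a [tp_control()].
#' @param subject_id optional identifier.
#' @return object of class `tp_fit`: `alpha`, `beta`, `residual_scale`,
#'   `bound_hit`, `n_probes`, plus the data for methods.
#' @export
#' @examples
#' pr <- data.frame(horizon_months = c(3, 6, 12, 24, 48),
#'                  slider_mm = 1.5 * c(3, 6, 12, 24, 48)^0.7)
#' fit_time_perception(pr)
fit_time_perception <- function(probes, control = tp_control(),
                                subject_id = NA_character_) {
  req <- c("horizon_months", "slider_mm")
  miss <- setdiff(req, names(probes))
  if (length(miss)) stop_input("probes missing columns: ", paste(miss, collapse = ", "))
  t <- probes$horizon_months; T_obs <- probes$slider_mm
  if (any(t <= 0)) stop_input("fit_time_perception: non-positive horizon")
  if (length(unique(t)) < 3)
    stop_input("fit_time_perception: need >= 3 distinct horizons")

  # start from log-log OLS on positive readings
  pos <- T_obs > 0
  if (sum(pos) >= 3) {
    cf <- coef(lm(log(T_obs[pos]) ~ log(t[pos])))
    start <- c(alpha = exp(cf[[1]]), beta = cf[[2]])
  } else {
    start <- c(alpha = max(mean(T_obs), 0.1), beta = 1)
  }
  b <- control$bounds
  start <- pmin(pmax(start, b[1] + 1e-6), b[2] - 1e-6)

  w <- rep(1, length(t))
  par <- start
  for (it in seq_len(control$maxit)) {
    new <- tp_wnls(t, T_obs, w, list(par, start), b)
    r <- T_obs - new[1] * t^new[2]
    s <- mad(r, center = 0)
    if (s < 1e-10) { par <- new; break }
    w <- pmin(1, control$huber_k * s / pmax(abs(r), 1e-300))
    if (max(abs(new - par)) < control$tol) { par <- new; break }
    par <- new
  }
  r <- T_obs - par[1] * t^par[2]
  s <- mad(r, center = 0)
  bound_hit <- any(par <= b[1] + control$bound_tol | par >= b[2] - control$bound_tol)

  structure(list(subject_id = subject_id, alpha = unname(par[1]),
                 beta = unname(par[2]), residual_scale = s,
                 bound_hit = bound_hit, n_probes = length(t),
                 data = data.frame(horizon_months = t, slider_mm = T_obs)),
            class = "tp_fit")
}

#' @export
print.tp_fit <- function(x, ...) {
  cat("Time-perception power-law fit",
      if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]"), "\n", sep = "")
  cat(sprintf("  alpha = %.4f  beta = %.4f  (robust scale %.3f, %d probes)\n",
              x$alpha, x$beta, x$residual_scale, x$n_probes))
  if (x$bound_hit) cat("  NOTE: estimate on a parameter bound (outlier stage 1)\n")
  invisible(x)
}

#' @export
coef.tp_fit <- function(object, ...) c(alpha = object$alpha, beta = object$beta)

#' @export
predict.tp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$horizon_months else newdata$horizon_months
  powerlaw(t, object$alpha, object$beta)
}

#' @export
residuals.tp_fit <- function(object, ...) {
  object$data$slider_mm - predict(object)
}

#' @export
plot.tp_fit <- function(x, ...) {
  d <- x$data
  plot(d$horizon_months, d$slider_mm, xlab = "calendar horizon (months)",
       ylab = "subjective duration (mm)", pch = 19, ...)
  tt <- seq(min(d$horizon_months), max(d$horizon_months), length.out = 200)
  lines(tt, powerlaw(tt, x$alpha, x$beta), col = 2, lwd = 2)
  invisible(x)
}

#' Fit time perception for a whole cohort
#'
#' Per-subject fits plus the two-stage outlier exclusion: bound hits from the
#' fits, then Tukey boxplot flags per parameter among the non-bound-hit fits
#' ([flag_outlier_fits()]).
#'
#' @param probes long table with `subject_id`, `horizon_months`, `slider_mm`.
#' @param control a [tp_control()].
#' @return object of class `tp_cohort_fit` with element `fits` (one row per
#'   subject: `alpha`, `beta`, `residual_scale`, `bound_hit`,
#'   `boxplot_outlier`, `excluded`).
#' @export
fit_tp_cohort <- function(probes, control = tp_control()) {
  req <- c("subject_id", "horizon_months", "slider_mm")
  miss <- setdiff(req, names(probes))
  if (length(miss)) stop_input("probes table missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(probes$subject_id)
  rows <- lapply(ids, function(id) {
    f <- fit_time_perception(probes[probes$subject_id == id, , drop = FALSE],
                             control, subject_id = id)
    data.frame(subject_id = id, alpha = f$alpha, beta = f$beta,
               residual_scale = f$residual_scale, bound_hit = f$bound_hit,
               stringsAsFactors = FALSE)
  })
  fits <- flag_outlier_fits(do.call(rbind, rows))
  structure(list(fits = fits, n_subjects = length(ids),
                 n_excluded = sum(fits$excluded)),
            class = "tp_cohort_fit")
}

#' @export
print.tp_cohort_fit <- function(x, ...) {
  cat(sprintf("Time-perception fits: %d subjects, %d excluded (%d bound hits, %d boxplot)\n",
              x$n_subjects, x$n_excluded, sum(x$fits$bound_hit),
              sum(x$fits$boxplot_outlier & !x$fits$bound_hit)))
  invisible(x)
}

#' Boxplot outlier stage for time-perception fits
#'
#' Applies the Tukey 1.5 IQR rule per parameter (alpha, then beta) among fits
#' that did not hit a bound; values strictly outside
#' \eqn{[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]} on either
#' parameter are flagged.  `excluded = bound_hit | boxplot_outlier`; bound-hit
#' fits are excluded regardless of boxplot status and do not enter the
#' quartile computation (no double counting).
#'
#' @param fits data.frame with columns `alpha`, `beta`, `bound_hit`.
#' @return `fits` with logical columns `boxplot_outlier` and `excluded` added.
#' @export
flag_outlier_fits <- function(fits) {
  stopifnot(all(c("alpha", "beta", "bound_hit") %in% names(fits)))
  fits$boxplot_outlier <- FALSE
  ok <- !fits$bound_hit
  if (sum(ok) < 5) {
    warning("fewer than 5 non-bound-hit fits; boxplot stage skipped")
  } else {
    for (p in c("alpha", "beta")) {
      v <- fits[[p]][ok]
      q <- quantile(v, c(.25, .75), names = FALSE)
      iqr <- q[2] - q[1]
      out <- fits[[p]] < q[1] - 1.5 * iqr | fits[[p]] > q[2] + 1.5 * iqr
      fits$boxplot_outlier <- fits$boxplot_outlier | (out & ok)
    }
  }
  fits$excluded <- fits$bound_hit | fits$boxplot_outlier
  fits
}
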