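#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the published cohort: three age groups of 84/54/104
#' subjects with the reported per-group moments for chronological age,
#' childhood SES, life-history score (Mini-K), future time perspective and
#' subjective health; a positive SES-LHS rank association (tau 0.22) induced
#' by a Gaussian copula; log discount rates that are linear in LHS and
#' U-shaped in age (declining slope in the young group, rising in the older
#' group, flat in between); a young-male offset in discounting; subjective
#' ages tied to chronological age and physical health; and power-law
#' anticipatory time perception with an age trend confined to the young group.
#' Observation noise, careless time-probe responders and random choice
#' responders are injected at configurable rates.
#'
#' Vector fields of length 3 are per group (young, middle, older); length-1
#' values are recycled.
#'
#' @param group_sizes subjects per age group.
#' @param age_bins contiguous half-open age bins `[18,34) [34,48) [48,70]`.
#' @param age_means,age_sds chronological-age moments per group (years).
#' @param male_counts males per group (remainder female).
#' @param ses_mean,ses_sd childhood SES moments (1-7 scale).
#' @param lhs_mean,lhs_sd Mini-K life-history moments (1-7 scale).
#' @param ftp_mean,ftp_sd future-time-perspective moments (1-7 scale).
#' @param phys_health_mean,phys_health_sd,psych_health_mean,psych_health_sd
#'   subjective health moments (1-5 scale).
#' @param physage_mean,psychage_mean subjective-age means per group (years).
#' @param physage_noise_sd,psychage_noise_sd subjective-age noise SDs.
#' @param health_age_coupling years of subjective physical age added per point
#'   of physical health below the scale midpoint 3; makes feeling older track
#'   poorer health (negative health/age-bias association).
#' @param ses_lhs_tau target Kendall tau between SES and LHS.
#' @param ftp_lhs_tau target Kendall tau between FTP and LHS.
#' @param baseline_logk grand mean of true log discount rate (log 1/day).
#' @param beta_lhs effect of LHS (per scale point) on true log k; negative.
#' @param u_shape `c(slope_young, slope_old)`: per-year age slopes of log k
#'   inside the young / older groups (slope_young <= 0 <= slope_old); the
#'   middle group carries no age effect, pivots at the inner bin edges keep
#'   the piecewise form continuous.
#' @param logk_noise_sd residual SD of true log k.
#' @param sex_logk_offset_young additive log-k offset for young males.
#' @param bias_logk_coupling_old effect of age bias (years) on log k in the
#'   older group only.
#' @param sigma_choice_range log-uniform range of true choice sensitivities
#'   (per RMB).
#' @param alpha_mean,alpha_sd,beta_mean,beta_sd time-perception parameter
#'   distribution.
#' @param alpha_age_slope_young,beta_age_slope_young per-year trends of the
#'   time-perception parameters inside the young group.
#' @param slider_noise_sd Gaussian noise SD on slider readings (mm).
#' @param slider_max slider length (mm).
#' @param horizons_months the ten probed calendar horizons.
#' @param random_responder_rate fraction of subjects answering the choice task
#'   at random (the non-convergence analogue; default 7/242).
#' @param time_outlier_rate fraction of subjects answering the time probes
#'   uniformly at random (careless responders driving time-fit exclusions).
#' @param discretize_likert round Likert-type scores to scale points instead
#'   of keeping them continuous.
#' @param seed integer seed; drives every stochastic stage deterministically.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(84, 54, 104),
                          age_bins = c(18, 34, 48, 70),
                          age_means = c(24.0, 39.7, 58.8),
                          age_sds = c(3.79, 2.71, 3.53),
                          male_counts = c(31, 26, 61),
                          ses_mean = c(3.73, 3.17, 3.59),
                          ses_sd = c(1.49, 1.40, 1.59),
                          lhs_mean = c(5.18, 4.73, 5.40),
                          lhs_sd = c(0.80, 0.83, 0.72),
                          ftp_mean = c(4.6, 4.4, 4.5),
                          ftp_sd = c(0.9, 0.9, 0.9),
                          phys_health_mean = c(3.92, 3.59, 3.86),
                          phys_health_sd = c(0.88, 1.00, 0.81),
                          psych_health_mean = c(3.88, 3.67, 4.25),
                          psych_health_sd = c(0.96, 1.03, 0.80),
                          physage_mean = c(24.2, 37.6, 53.3),
                          psychage_mean = c(25.4, 36.1, 47.7),
                          physage_noise_sd = c(2.5, 5.0, 6.0),
                          psychage_noise_sd = c(4.0, 9.0, 10.0),
                          health_age_coupling = 2.5,
                          ses_lhs_tau = 0.22,
                          ftp_lhs_tau = 0.35,
                          baseline_logk = -4.0,
                          beta_lhs = -0.25,
                          u_shape = c(-0.05, 0.06),
                          logk_noise_sd = 0.8,
                          sex_logk_offset_young = 0.35,
                          bias_logk_coupling_old = 0.10,
                          sigma_choice_range = c(0.01, 0.1),
                          alpha_mean = 2.0, alpha_sd = 0.5,
                          beta_mean = 0.75, beta_sd = 0.12,
                          alpha_age_slope_young = -0.05,
                          beta_age_slope_young = 0.01,
                          slider_noise_sd = 5,
                          slider_max = 150,
                          horizons_months = c(3, 6, 9, 12, 18, 24, 30, 36, 48, 60),
                          random_responder_rate = 7 / 242,
                          time_outlier_rate = 0.15,
                          discretize_likert = FALSE,
                          seed = NULL) {
  rec3 <- function(v) if (length(v) == 1) rep(v, 3) else v
  cfg <- list(
    group_sizes = as.integer(rec3(group_sizes)), age_bins = age_bins,
    age_means = rec3(age_means), age_sds = rec3(age_sds),
    male_counts = as.integer(rec3(male_counts)),
    ses_mean = rec3(ses_mean), ses_sd = rec3(ses_sd),
    lhs_mean = rec3(lhs_mean), lhs_sd = rec3(lhs_sd),
    ftp_mean = rec3(ftp_mean), ftp_sd = rec3(ftp_sd),
    phys_health_mean = rec3(phys_health_mean), phys_health_sd = rec3(phys_health_sd),
    psych_health_mean = rec3(psych_health_mean), psych_health_sd = rec3(psych_health_sd),
    physage_mean = rec3(physage_mean), psychage_mean = rec3(psychage_mean),
    physage_noise_sd = rec3(physage_noise_sd), psychage_noise_sd = rec3(psychage_noise_sd),
    health_age_coupling = health_age_coupling,
    ses_lhs_tau = ses_lhs_tau, ftp_lhs_tau = ftp_lhs_tau,
    baseline_logk = baseline_logk, beta_lhs = beta_lhs,
    u_shape = setNames(u_shape, c("slope_young", "slope_old")),
    logk_noise_sd = logk_noise_sd,
    sex_logk_offset_young = sex_logk_offset_young,
    bias_logk_coupling_old = bias_logk_coupling_old,
    sigma_choice_range = sigma_choice_range,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    beta_mean = beta_mean, beta_sd = beta_sd,
    alpha_age_slope_young = alpha_age_slope_young,
    beta_age_slope_young = beta_age_slope_young,
    slider_noise_sd = slider_noise_sd, slider_max = slider_max,
    horizons_months = horizons_months,
    random_responder_rate = random_responder_rate,
    time_outlier_rate = time_outlier_rate,
    discretize_likert = isTRUE(discretize_likert),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  err <- function(...) stop_input("cohort_config: ", ...)
  if (any(cfg$group_sizes <= 0)) err("group sizes must be positive")
  if (length(cfg$age_bins) != 4 || any(diff(cfg$age_bins) <= 0))
    err("age_bins must be 4 increasing cut points")
  sds <- c(cfg$age_sds, cfg$ses_sd, cfg$lhs_sd, cfg$ftp_sd, cfg$phys_health_sd,
           cfg$psych_health_sd, cfg$physage_noise_sd, cfg$psychage_noise_sd,
           cfg$logk_noise_sd, cfg$alpha_sd, cfg$beta_sd, cfg$slider_noise_sd)
  if (any(sds <= 0)) err("all SDs must be > 0")
  if (any(cfg$male_counts < 0) || any(cfg$male_counts > cfg$group_sizes))
    err("male_counts must lie in [0, group size]")
  for (r in c(cfg$random_responder_rate, cfg$time_outlier_rate))
    if (r < 0 || r >= 1) err("rates must lie in [0, 1)")
  if (abs(cfg$ses_lhs_tau) >= 1 || abs(cfg$ftp_lhs_tau) >= 1)
    err("tau targets must lie in (-1, 1)")
  if (cfg$u_shape[1] > 0 || cfg$u_shape[2] < 0)
    err("u_shape needs slope_young <= 0 <= slope_old")
  if (length(cfg$sigma_choice_range) != 2 || cfg$sigma_choice_range[1] <= 0 ||
      diff(cfg$sigma_choice_range) < 0)
    err("sigma_choice_range must be an increasing positive range")
  if (any(cfg$age_means < cfg$age_bins[1]) || any(cfg$age_means > cfg$age_bins[4]))
    err("age_means must lie inside the overall age range")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups (young/middle/older): %s subjects, age bins [%s)\n",
              paste(x$group_sizes, collapse = "/"),
              paste(x$age_bins, collapse = ", ")))
  cat(sprintf("  structure: beta_lhs = %.3f, u_shape = (%.3f, %.3f), bias coupling (older) = %.3f\n",
              x$beta_lhs, x$u_shape[1], x$u_shape[2], x$bias_logk_coupling_old))
  cat(sprintf("  rates: random responders %.3f, careless time probes %.3f; seed %s\n",
              x$random_responder_rate, x$time_outlier_rate,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

# ---- moment-matching helpers -----------------------------------------------
# Observed moments of clipped / truncated normals differ from the latent ones;
# these solve for latent (mu, sd) so the OBSERVED moments equal the configured
# targets, keeping generator marginals faithful to the printed table.

winsor_moments <- function(mu, sd, a, b) {
  za <- (a - mu) / sd; zb <- (b - mu) / sd
  Fa <- pnorm(za); Fb <- pnorm(zb); fa <- dnorm(za); fb <- dnorm(zb)
  dF <- Fb - Fa
  m <- a * Fa + b * (1 - Fb) + mu * dF - sd * (fb - fa)
  m2 <- a^2 * Fa + b^2 * (1 - Fb) + mu^2 * dF + 2 * mu * sd * (fa - fb) +
    sd^2 * (dF + za * fa - zb * fb)
  c(mean = m, sd = sqrt(max(m2 - m^2, 1e-12)))
}

trunc_moments <- function(mu, sd, a, b) {
  za <- (a - mu) / sd; zb <- (b - mu) / sd
  Z <- pnorm(zb) - pnorm(za)
  fa <- dnorm(za); fb <- dnorm(zb)
  m <- mu + sd * (fa - fb) / Z
  v <- sd^2 * (1 + (za * fa - zb * fb) / Z - ((fa - fb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 1e-12)))
}

# fixed-point solve for latent (mu, sd) whose observed moments hit the target
match_moments <- function(target_mean, target_sd, a, b, moments_fun,
                          maxit = 200, tol = 1e-8) {
  mu <- target_mean; sd <- target_sd
  for (i in seq_len(maxit)) {
    ob <- moments_fun(mu, sd, a, b)
    if (abs(ob[1] - target_mean) < tol && abs(ob[2] - target_sd) < tol * target_sd)
      break
    mu <- mu + (target_mean - ob[1])
    sd <- sd * min(max(target_sd / ob[2], 0.5), 2)
    sd <- min(sd, 5 * target_sd + (b - a))
  }
  ob <- moments_fun(mu, sd, a, b)
  if (abs(ob[1] - target_mean) > 0.02 * max(1, abs(target_mean)) ||
      abs(ob[2] - target_sd) > 0.05 * target_sd) {
    warning(sprintf(
      "moment matching imprecise on [%g, %g]: target (%.3g, %.3g), achieved (%.3g, %.3g)",
      a, b, target_mean, target_sd, ob[1], ob[2]))
  }
  c(mu = mu, sd = sd)
}
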