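GROUP_LABELS <- c("young", "middle", "older")

#' Structural (noise-free) log discount rate
#'
#' The generator's deterministic log-k surface: a grand baseline, a linear
#' life-history effect, and a piecewise-linear U-shaped age effect — a
#' declining slope inside the young group (pivoted at the young/middle bin
#' edge), a rising slope inside the older group (pivoted at the middle/older
#' edge) and no age effect in between, so the surface is continuous in age.
#'
#' @param lhs life-history score(s).
#' @param chronological_age age(s) in years.
#' @param group_label `"young"`, `"middle"` or `"older"` (recycled).
#' @param config a [cohort_config()].
#' @return log k (natural log, k per day), without sex, age-bias or noise
#'   components.
#' @export
true_logk <- function(lhs, chronological_age, group_label, config = cohort_config()) {
  if (!all(group_label %in% GROUP_LABELS))
    stop_input("true_logk: unknown group label(s): ",
               paste(setdiff(unique(group_label), GROUP_LABELS), collapse = ", "))
  n <- max(length(lhs), length(chronological_age), length(group_label))
  lhs <- rep_len(lhs, n)
  chronological_age <- rep_len(chronological_age, n)
  group_label <- rep_len(group_label, n)
  lhs_grand <- sum(config$lhs_mean * config$group_sizes) / sum(config$group_sizes)
  pivot_young <- config$age_bins[2]
  pivot_old <- config$age_bins[3]
  age_eff <- ifelse(group_label == "young",
                    config$u_shape[1] * (chronological_age - pivot_young),
             ifelse(group_label == "older",
                    config$u_shape[2] * (chronological_age - pivot_old), 0))
  config$baseline_logk + config$beta_lhs * (lhs - lhs_grand) + age_eff
}

# rejection sampler for one group's ages inside [lo, hi), moment-corrected
sample_ages <- function(n, target_mean, target_sd, lo, hi) {
  par <- match_moments(target_mean, target_sd, lo, hi, trunc_moments)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n + 10, par[1], par[2])
    out <- c(out, draw[draw >= lo & draw < hi])
  }
  out[seq_len(n)]
}

# clipped (winsorized) Likert-type scores from standard-normal copula margins
clipped_scores <- function(z, target_mean, target_sd, lo, hi, discretize = FALSE) {
  par <- match_moments(target_mean, target_sd, lo, hi, winsor_moments)
  x <- pmin(pmax(par[1] + par[2] * z, lo), hi)
  if (discretize) x <- pmin(pmax(round(x), lo), hi)
  x
}

#' Generate a synthetic subject cohort with ground truth
#'
#' Draws one subject table and the matching table of true generative
#' parameters.  Traits are drawn with the configured per-group moments
#' (moment-corrected for scale clipping), SES/LHS/FTP are coupled through a
#' Gaussian copula whose correlation is chosen by the
#' \eqn{\rho = \sin(\pi\tau/2)} map so the target Kendall taus hold in
#' expectation, subjective ages are chronological age plus a health-dependent
#' shift plus noise, and true log discount rates follow [true_logk()] plus the
#' young-male offset, the older-group age-bias coupling and Gaussian noise.
#' Deterministic given the seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with data.frames `subjects` (one row per subject: demographics,
#'   traits, subjective ages, `age_bias`, `group_label`) and `truth`
#'   (`k_true`, `sigma_true`, `alpha_true`, `beta_true`,
#'   `is_random_responder`, `is_time_outlier`, `log_k_true`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(group_sizes = c(10, 10, 10), seed = 1))
#' head(cohort$subjects)
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  with_seed(seed, {
    rho_sl <- sin(pi * config$ses_lhs_tau / 2)
    rho_fl <- sin(pi * config$ftp_lhs_tau / 2)

    subj <- list(); truth <- list()
    next_id <- 1L
    for (g in 1:3) {
      n <- config$group_sizes[g]
      lab <- GROUP_LABELS[g]
      ids <- sprintf("S%04d", seq(next_id, length.out = n))
      next_id <- next_id + n

      age <- sample_ages(n, config$age_means[g], config$age_sds[g],
                         config$age_bins[g], config$age_bins[g + 1])
      sex <- sample(rep(c("male", "female"),
                        c(config$male_counts[g], n - config$male_counts[g])))

      # copula: LHS is the hub; SES and FTP correlate with it
      z_lhs <- rnorm(n)
      z_ses <- rho_sl * z_lhs + sqrt(1 - rho_sl^2) * rnorm(n)
      z_ftp <- rho_fl * z_lhs + sqrt(1 - rho_fl^2) * rnorm(n)

      lhs <- clipped_scores(z_lhs, config$lhs_mean[g], config$lhs_sd[g], 1, 7,
                            config$discretize_likert)
      ses <- clipped_scores(z_ses, config$ses_mean[g], config$ses_sd[g], 1, 7,
                            config$discretize_likert)
      ftp <- clipped_scores(z_ftp, config$ftp_mean[g], config$ftp_sd[g], 1, 7,
                            config$discretize_likert)
      ph <- clipped_scores(rnorm(n), config$phys_health_mean[g],
                           config$phys_health_sd[g], 1, 5, config$discretize_likert)
      psyh <- clipped_scores(rnorm(n), config$psych_health_mean[g],
                             config$psych_health_sd[g], 1, 5, config$discretize_likert)

      cc <- config$health_age_coupling
      off_phys <- config$physage_mean[g] - config$age_means[g] -
        cc * (3 - config$phys_health_mean[g])
      phys_age <- pmax(age + off_phys + cc * (3 - ph) +
                         rnorm(n, 0, config$physage_noise_sd[g]), 1)
      psych_age <- pmax(age + (config$psychage_mean[g] - config$age_means[g]) +
                          rnorm(n, 0, config$psychage_noise_sd[g]), 1)
      bias <- phys_age - age

      logk <- true_logk(lhs, age, lab, config) +
        ifelse(lab == "young" & sex == "male", config$sex_logk_offset_young, 0) +
        (if (lab == "older") config$bias_logk_coupling_old * bias else 0) +
        rnorm(n, 0, config$logk_noise_sd)

      sigma <- exp(runif(n, log(config$sigma_choice_range[1]),
                         log(config$sigma_choice_range[2])))
      alpha <- pmin(pmax(config$alpha_mean +
                           (if (lab == "young") config$alpha_age_slope_young *
                              (age - config$age_means[1]) else 0) +
                           rnorm(n, 0, config$alpha_sd), 0.05), 4.9)
      beta <- pmin(pmax(config$beta_mean +
                          (if (lab == "young") config$beta_age_slope_young *
                             (age - config$age_means[1]) else 0) +
                          rnorm(n, 0, config$beta_sd), 0.05), 4.9)

      subj[[g]] <- data.frame(
        subject_id = ids, sex = sex, group_label = lab,
        chronological_age = age, physical_age = phys_age,
        psychological_age = psych_age,
        physical_health = ph, psychological_health = psyh,
        childhood_ses = ses, lhs = lhs, ftp = ftp, age_bias = bias,
        stringsAsFactors = FALSE)
      truth[[g]] <- data.frame(
        subject_id = ids, k_true = exp(logk), log_k_true = logk,
        sigma_true = sigma, alpha_true = alpha, beta_true = beta,
        stringsAsFactors = FALSE)
    }
    subjects <- do.call(rbind, subj)
    truth <- do.call(rbind, truth)
    n_all <- nrow(subjects)

    rr <- rep(FALSE, n_all)
    n_rr <- round(config$random_responder_rate * n_all)
    if (n_rr > 0) rr[sample.int(n_all, n_rr)] <- TRUE
    truth$is_random_responder <- rr

    to <- rep(FALSE, n_all)
    n_to <- round(config$time_outlier_rate * n_all)
    if (n_to > 0) to[sample.int(n_all, n_to)] <- TRUE
    truth$is_time_outlier <- to

    rownames(subjects) <- rownames(truth) <- NULL
    list(subjects = subjects, truth = truth)
  })
}

#' Simulate binary intertemporal choices from true parameters
#'
#' For every subject and item the immediate option is chosen with probability
#' \eqn{1/(1 + e^{-\sigma(SS - SV)})}, with \eqn{SV} the hyperbolic subjective
#' value at the subject's true rate; random responders choose each option with
#' probability one half.
#'
#' @param truth truth table from [generate_cohort()] (needs `subject_id`,
#'   `k_true`, `sigma_true`, `is_random_responder`).
#' @param items item table, see [default_choice_items()].
#' @param seed integer seed.
#' @return long data.frame: `subject_id`, `item_id`, `ss_amount`, `ll_amount`,
#'   `delay_days`, `chose_ss`.
#' @export
generate_choice_responses <- function(truth, items = default_choice_items(),
                                      seed = NULL) {
  validate_items(items)
  if (nrow(items) == 0) stop_input("generate_choice_responses: empty item list")
  with_seed(seed, {
    n_s <- nrow(truth); n_i <- nrow(items)
    sv <- outer(truth$k_true, seq_len(n_i),
                function(k, j) items$ll_amount[j] / (1 + k * items$delay_days[j]))
    x <- sweep(-sv, 2, items$ss_amount, "+")          # SS - SV
    p <- plogis(truth$sigma_true * x)
    rr <- if ("is_random_responder" %in% names(truth)) truth$is_random_responder
          else rep(FALSE, n_s)
    p[rr, ] <- 0.5
    chose <- matrix(rbinom(n_s * n_i, 1, as.numeric(p)), n_s, n_i)
    data.frame(
      subject_id = rep(truth$subject_id, each = n_i),
      item_id = rep(items$item_id, n_s),
      ss_amount = rep(items$ss_amount, n_s),
      ll_amount = rep(items$ll_amount, n_s),
      delay_days = rep(items$delay_days, n_s),
      chose_ss = as.integer(t(chose)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate anticipatory time-probe slider readings
#'
#' Readings follow \eqn{T = \alpha t^\beta} plus Gaussian noise, truncated to
#' the slider range `[0, slider_max]` mm; careless responders
#' (`is_time_outlier`) answer uniformly on the slider for every probe.
#'
#' @param truth truth table from [generate_cohort()].
#' @param horizons_months positive calendar horizons (months).
#' @param seed integer seed.
#' @param noise_sd Gaussian noise SD (mm).
#' @param slider_max slider length (mm).
#' @return long data.frame: `subject_id`, `horizon_months`, `slider_mm`.
#' @export
generate_time_probes <- function(truth,
                                 horizons_months = c(3, 6, 9, 12, 18, 24, 30, 36, 48, 60),
                                 seed = NULL, noise_sd = 5, slider_max = 150) {
  if (any(horizons_months <= 0))
    stop_input("generate_time_probes: non-positive horizon")
  with_seed(seed, {
    n_s <- nrow(truth); n_h <- length(horizons_months)
    mu <- outer(seq_len(n_s), horizons_months,
                function(i, t) truth$alpha_true[i] * t^truth$beta_true[i])
    obs <- mu + matrix(rnorm(n_s * n_h, 0, noise_sd), n_s, n_h)
    to <- if ("is_time_outlier" %in% names(truth)) truth$is_time_outlier
          else rep(FALSE, n_s)
    if (any(to)) {
      obs[to, ] <- matrix(runif(sum(to) * n_h, 0, slider_max), sum(to), n_h)
    }
    obs <- pmin(pmax(obs, 0), slider_max)
    data.frame(
      subject_id = rep(truth$subject_id, each = n_h),
      horizon_months = rep(horizons_months, n_s),
      slider_mm = as.numeric(t(obs)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience driver: [generate_cohort()] plus choice and time-probe tables,
#' with stage seeds derived deterministically from the one configured seed.
#'
#' @param config a [cohort_config()].
#' @param items item table for the choice task.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list of class `dd_cohort_sim` with `subjects`, `choices`,
#'   `time_probes`, `truth`, `items`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            items = default_choice_items(),
                            seed = config$seed) {
  base <- generate_cohort(config, seed = seed)
  choices <- generate_choice_responses(base$truth, items,
                                       seed = child_seed(seed, "choices"))
  probes <- generate_time_probes(base$truth, config$horizons_months,
                                 seed = child_seed(seed, "probes"),
                                 noise_sd = config$slider_noise_sd,
                                 slider_max = config$slider_max)
  structure(list(subjects = base$subjects, choices = choices,
                 time_probes = probes, truth = base$truth,
                 items = items, config = config, seed = seed),
            class = "dd_cohort_sim")
}

#' @export
print.dd_cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d choices, %d time probes\n",
              nrow(x$subjects),
              paste(table(factor(x$subjects$group_label, GROUP_LABELS)), collapse = "/"),
              nrow(x$choices), nrow(x$time_probes)))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `subjects.csv`, `choices.csv`, `time_probes.csv` and `truth.csv`
#' (ground truth for recovery tests) into `dir`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "dd_cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("subjects.csv", "choices.csv", "time_probes.csv",
                            "truth.csv", "items.csv"))
  write.csv(sim$subjects, paths[1], row.names = FALSE)
  write.csv(sim$choices[c("subject_id", "item_id", "ss_amount", "ll_amount",
                          "delay_days", "chose_ss")], paths[2], row.names = FALSE)
  write.csv(sim$time_probes, paths[3], row.names = FALSE)
  write.csv(sim$truth, paths[4], row.names = FALSE)
  write.csv(sim$items, paths[5], row.names = FALSE)
  invisible(paths)
}
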