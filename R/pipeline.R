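#' Assign subjects to age groups
#'
#' Labels subjects by half-open age bins, by default the contiguous bins
#' `[18,34) [34,48) [48,70]`.  Ages outside the configured range are left
#' unassigned (`NA`) with a warning.  Gapped cutpoints reproducing a sample
#' with unobserved ages can be supplied instead.
#'
#' @param subjects data.frame with `subject_id` and `chronological_age`.
#' @param cutoffs 4 increasing cut points.
#' @return data.frame `subject_id`, `group_label`, plus the cutoffs as an
#'   attribute.
#' @export
assign_age_groups <- function(subjects, cutoffs = c(18, 34, 48, 70)) {
  stopifnot(length(cutoffs) == 4, all(diff(cutoffs) > 0))
  age <- subjects$chronological_age
  lab <- as.character(cut(age, cutoffs, labels = GROUP_LABELS,
                          right = FALSE, include.lowest = TRUE))
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " subject(s) outside the configured age range left unassigned")
  }
  structure(data.frame(subject_id = subjects$subject_id, group_label = lab,
                       stringsAsFactors = FALSE),
            cutoffs = cutoffs)
}

#' Age bias score
#'
#' Subjective physical age minus chronological age, in years; positive means
#' the subject feels older than they are.
#'
#' @param physical_age,chronological_age positive ages in years.
#' @return numeric age-bias score(s).
#' @export
compute_age_bias <- function(physical_age, chronological_age) {
  if (any(physical_age <= 0) || any(chronological_age <= 0))
    stop_input("compute_age_bias: ages must be positive")
  physical_age - chronological_age
}

# merge subjects with per-subject estimates; excluded estimates become NA so
# each analysis drops exactly the subjects excluded for ITS variable.
analysis_table <- function(subjects, dd, tp, cutoffs = c(18, 34, 48, 70)) {
  grp <- assign_age_groups(subjects, cutoffs)
  df <- merge(subjects[setdiff(names(subjects), "group_label")], grp,
              by = "subject_id")
  ddf <- dd_fits_table(dd, included_only = FALSE)
  ddf$log_k[!ddf$converged] <- NA_real_
  df <- merge(df, ddf[c("subject_id", "log_k", "converged")],
              by = "subject_id", all.x = TRUE)
  tpf <- tp$fits
  tpf$alpha[tpf$excluded] <- NA_real_
  tpf$beta[tpf$excluded] <- NA_real_
  df <- merge(df, tpf[c("subject_id", "alpha", "beta", "excluded")],
              by = "subject_id", all.x = TRUE)
  names(df)[names(df) == "excluded"] <- "tp_excluded"
  df$age_bias <- compute_age_bias(df$physical_age, df$chronological_age)
  df[order(df$subject_id), ]
}

safe_tau <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) return(list(tau = NA_real_, p = NA_real_, n = sum(ok), note = "n < 3"))
  res <- tryCatch(kendall_tau(x[ok], y[ok]), error = function(e) NULL)
  if (is.null(res)) return(list(tau = NA_real_, p = NA_real_, n = sum(ok),
                                note = "undefined (constant variable)"))
  list(tau = res$tau, p = res$p_value, n = res$n, note = "")
}

#' Per-group and whole-sample Kendall correlations
#'
#' The correlation table of the analysis: within each age group, tau between
#' chronological age and each of FTP, log k, alpha, beta, physical and
#' psychological age; and the whole-sample pairs used by the mediation and
#' trait analyses (SES-LHS, LHS-log k, FTP-LHS, FTP-log k, physical
#' health-age bias, log k-alpha, log k-beta).  Subjects excluded upstream for
#' a variable enter as NA and are dropped pairwise, so exclusion is
#' analysis-specific.
#'
#' @param df merged analysis table (see [run_full_analysis()]), needing
#'   `group_label`, `chronological_age` and the trait/estimate columns.
#' @return data.frame: `scope`, `group`, `var1`, `var2`, `tau`, `p_value`,
#'   `n`, `note`.
#' @export
per_group_correlations <- function(df) {
  rows <- list()
  within_vars <- c("ftp", "log_k", "alpha", "beta", "physical_age",
                   "psychological_age")
  for (g in GROUP_LABELS) {
    sub <- df[!is.na(df$group_label) & df$group_label == g, , drop = FALSE]
    if (nrow(sub) < 3) {
      warning("group ", g, " has fewer than 3 subjects; skipped")
      next
    }
    for (v in intersect(within_vars, names(sub))) {
      r <- safe_tau(sub$chronological_age, sub[[v]])
      rows[[length(rows) + 1]] <- data.frame(
        scope = "within_group", group = g, var1 = "chronological_age",
        var2 = v, tau = r$tau, p_value = r$p, n = r$n, note = r$note,
        stringsAsFactors = FALSE)
    }
  }
  whole <- list(c("childhood_ses", "lhs"), c("lhs", "log_k"), c("ftp", "lhs"),
                c("ftp", "log_k"), c("physical_health", "age_bias"),
                c("log_k", "alpha"), c("log_k", "beta"))
  for (pair in whole) {
    r <- safe_tau(df[[pair[1]]], df[[pair[2]]])
    rows[[length(rows) + 1]] <- data.frame(
      scope = "whole_sample", group = "all", var1 = pair[1], var2 = pair[2],
      tau = r$tau, p_value = r$p, n = r$n, note = r$note,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# design matrix shared by the two interaction models; young + older only,
# dummy 0 = young, 1 = older, age left uncentred as in the reported models
model_design <- function(df, with_bias = FALSE) {
  d <- df[df$group_label %in% c("young", "older") & !is.na(df$log_k), , drop = FALSE]
  if (length(unique(d$group_label)) < 2)
    stop_input("interaction models need both young and older subjects")
  grp <- as.numeric(d$group_label == "older")
  X <- cbind(`(Intercept)` = 1, lhs = d$lhs, age = d$chronological_age,
             age_group = grp, age_x_group = d$chronological_age * grp)
  if (with_bias) {
    X <- cbind(X, age_bias = d$age_bias, age_bias_x_group = d$age_bias * grp)
  }
  list(X = X, y = d$log_k, data = d)
}

#' Interaction model of discounting on life history and age (Model 1)
#'
#' MM-regression of log k on life-history score, chronological age, age group
#' (dummy coded: 0 young, 1 older; middle-aged subjects excluded) and the
#' age-by-group interaction.  A positive interaction with a negative young-age
#' slope is the regression signature of the U-shaped age effect.
#'
#' @param df merged analysis table.
#' @param estimator `"mm"` (default) or `"ols"`.
#' @return a `robust_fit` with terms `(Intercept)`, `lhs`, `age`, `age_group`,
#'   `age_x_group`.
#' @export
run_model1 <- function(df, estimator = c("mm", "ols")) {
  estimator <- match.arg(estimator)
  m <- model_design(df, with_bias = FALSE)
  if (estimator == "mm") mm_regression(m$X, m$y) else ols_regression(m$X, m$y)
}

#' Age-bias interaction model (Model 2)
#'
#' Model 1 plus age-bias score (physical minus chronological age) and its
#' interaction with age group, probing whether feeling physically older
#' carries discounting information beyond chronological age among older
#' adults.
#'
#' @inheritParams run_model1
#' @return a `robust_fit` with the Model-1 terms plus `age_bias`,
#'   `age_bias_x_group`.
#' @export
run_model2 <- function(df, estimator = c("mm", "ols")) {
  estimator <- match.arg(estimator)
  m <- model_design(df, with_bias = TRUE)
  if (estimator == "mm") mm_regression(m$X, m$y) else ols_regression(m$X, m$y)
}

#' Sex differences in discounting
#'
#' Per group: classical ANCOVA F for sex on log k controlling life-history
#' score.  In the older group additionally: OLS of log k on sex, age and
#' sex-by-age (reporting the interaction), and per-sex Kendall tau between age
#' and log k.
#'
#' @param df merged analysis table.
#' @return list with `ancova` (data.frame: group, F, df1, df2, p_value, n),
#'   `older_interaction` (coefficient, t, p for sex x age) and `older_by_sex`
#'   (per-sex tau of age with log k).
#' @export
run_sex_tests <- function(df) {
  anc <- list()
  for (g in GROUP_LABELS) {
    sub <- df[df$group_label %in% g & !is.na(df$log_k), , drop = FALSE]
    if (length(unique(sub$sex)) < 2) {
      warning("group ", g, " has a single sex; ANCOVA skipped")
      next
    }
    f <- ancova_f(sub$log_k, sub$sex, sub$lhs)
    anc[[length(anc) + 1]] <- data.frame(group = g, F = f$F, df1 = f$df1,
                                         df2 = f$df2, p_value = f$p_value,
                                         n = f$n, stringsAsFactors = FALSE)
  }
  older <- df[df$group_label %in% "older" & !is.na(df$log_k), , drop = FALSE]
  inter <- NULL; by_sex <- NULL
  if (nrow(older) > 8 && length(unique(older$sex)) == 2) {
    male <- as.numeric(older$sex == "male")
    X <- cbind(`(Intercept)` = 1, sex = male, age = older$chronological_age,
               sex_x_age = male * older$chronological_age)
    fit <- ols_regression(X, older$log_k)
    inter <- list(b = unname(coef(fit)["sex_x_age"]),
                  t = unname(fit$t["sex_x_age"]),
                  p_value = unname(fit$p_value["sex_x_age"]))
    by_sex <- do.call(rbind, lapply(c("male", "female"), function(s) {
      sub <- older[older$sex == s, ]
      r <- safe_tau(sub$chronological_age, sub$log_k)
      data.frame(sex = s, tau = r$tau, p_value = r$p, n = r$n,
                 stringsAsFactors = FALSE)
    }))
  }
  list(ancova = do.call(rbind, anc), older_interaction = inter,
       older_by_sex = by_sex)
}

mediation_row <- function(fit, label) {
  cbind(data.frame(analysis = label, stringsAsFactors = FALSE), summary(fit))
}

#' Run the complete cohort analysis
#'
#' End-to-end driver: per-subject discounting MLE with convergence exclusion,
#' per-subject time-perception fits with two-stage outlier exclusion,
#' age-group assignment and age-bias scores, the per-group correlation table,
#' interaction Models 1-2, sex tests, and the mediation analyses (childhood
#' SES through life-history score to log k on the whole sample; physical
#' health through physical age to log k within each group).  Fully seeded:
#' the one `seed` drives the mediation bootstraps deterministically, and the
#' MM resampling is internally seeded, so the same inputs give an identical
#' report.  Subjects excluded at a fitting stage are dropped only from
#' analyses that use the excluded quantity.
#'
#' @param subjects,choices,time_probes data.frames (or paths to CSVs with the
#'   documented schemas, read via [read_table()]).
#' @param items item table or path.
#' @param cutoffs age-group cut points.
#' @param n_boot bootstrap replicates for each mediation.
#' @param seed integer seed.
#' @param dd_ctrl,tp_ctrl fitting controls.
#' @param config optional [cohort_config()] echoed into the report.
#' @return object of class `dd_report`.
#' @export
run_full_analysis <- function(subjects, choices, time_probes,
                              items = default_choice_items(),
                              cutoffs = c(18, 34, 48, 70),
                              n_boot = 2000, seed = 1L,
                              dd_ctrl = dd_control(), tp_ctrl = tp_control(),
                              config = NULL) {
  if (is.character(subjects)) subjects <- read_table(subjects, dd_schema("subjects"))
  if (is.character(choices)) choices <- read_table(choices, dd_schema("choices"))
  if (is.character(time_probes)) time_probes <- read_table(time_probes, dd_schema("time_probes"))
  if (is.character(items)) items <- read_table(items, dd_schema("items"))

  dd <- fit_dd_cohort(choices, items, dd_ctrl)
  tp <- fit_tp_cohort(time_probes, tp_ctrl)
  df <- analysis_table(subjects, dd, tp, cutoffs)

  correlations <- per_group_correlations(df)
  model1 <- run_model1(df)
  model2 <- run_model2(df)
  sex_tests <- run_sex_tests(df)

  med <- list()
  ok <- !is.na(df$log_k)
  med[["ses_lhs_dd"]] <- mediation_row(
    robust_mediation(df$childhood_ses[ok], df$lhs[ok], df$log_k[ok],
                     n_boot = n_boot, seed = child_seed(seed, "med_ses")),
    "ses -> lhs -> log_k (whole sample)")
  for (g in GROUP_LABELS) {
    sub <- df[df$group_label %in% g & !is.na(df$log_k), ]
    med[[paste0("health_physage_dd_", g)]] <- mediation_row(
      robust_mediation(sub$physical_health, sub$physical_age, sub$log_k,
                       n_boot = n_boot, seed = child_seed(seed, paste0("med_", g))),
      paste0("physical_health -> physical_age -> log_k (", g, ")"))
  }
  mediations <- do.call(rbind, med)
  rownames(mediations) <- NULL

  structure(list(
    table = df, correlations = correlations,
    model1 = model1, model2 = model2, sex_tests = sex_tests,
    mediations = mediations,
    exclusions = list(
      discounting = dd$exclusions, discounting_n = dd$n_excluded,
      time_perception_n = tp$n_excluded,
      time_perception_bound = sum(tp$fits$bound_hit),
      time_perception_boxplot = sum(tp$fits$boxplot_outlier & !tp$fits$bound_hit)),
    n_subjects = nrow(subjects),
    n_tests = nrow(correlations) + length(coef(model1)) + length(coef(model2)) +
      nrow(mediations) + NROW(sex_tests$ancova),
    config = config, cutoffs = cutoffs, seed = seed, n_boot = n_boot),
    class = "dd_report")
}

#' @export
print.dd_report <- function(x, digits = 3, ...) {
  cat("==== Life-span delay-discounting cohort report ====\n")
  cat(sprintf("%d subjects; %d excluded from discounting, %d from time perception (%d bound hits, %d boxplot)\n",
              x$n_subjects, x$exclusions$discounting_n, x$exclusions$time_perception_n,
              x$exclusions$time_perception_bound, x$exclusions$time_perception_boxplot))
  cat(sprintf("seed %s; %d bootstrap replicates per mediation; %d statistics reported (no multiplicity correction)\n\n",
              x$seed, x$n_boot, x$n_tests))
  cat("-- Kendall correlations --\n")
  cr <- x$correlations
  cr$tau <- round(cr$tau, digits); cr$p_value <- signif(cr$p_value, digits)
  print(cr, row.names = FALSE)
  cat("\n-- Model 1: log k ~ lhs + age + group + age:group (MM) --\n")
  print(x$model1)
  cat("\n-- Model 2: Model 1 + age bias + age bias:group (MM) --\n")
  print(x$model2)
  cat("\n-- Sex tests (ANCOVA of sex on log k, controlling lhs) --\n")
  if (!is.null(x$sex_tests$ancova)) print(x$sex_tests$ancova, row.names = FALSE)
  if (!is.null(x$sex_tests$older_interaction)) {
    oi <- x$sex_tests$older_interaction
    cat(sprintf("older group sex x age interaction: b = %.4g, t = %.3g, p = %.3g\n",
                oi$b, oi$t, oi$p_value))
  }
  cat("\n-- Mediation (percentile bootstrap of a*b) --\n")
  md <- x$mediations
  for (j in c("a", "b", "indirect", "direct", "ci_low", "ci_high"))
    md[[j]] <- round(md[[j]], digits)
  print(md[c("analysis", "a", "b", "indirect", "ci_low", "ci_high", "significant", "n")],
        row.names = FALSE)
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the report as machine-readable JSON, a rendered text version, and
#' the intermediate tables (merged analysis table, correlation table,
#' mediation table, model coefficient tables) as CSVs.
#'
#' @param report a `dd_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dd_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model_df <- function(m) data.frame(term = m$terms, estimate = m$coefficients,
                                     se = m$se, t = m$t, p_value = m$p_value,
                                     row.names = NULL)
  payload <- list(
    n_subjects = report$n_subjects, seed = report$seed, n_boot = report$n_boot,
    cutoffs = report$cutoffs, exclusions = report$exclusions,
    correlations = report$correlations,
    model1 = c(list(r_squared = report$model1$r_squared, n = report$model1$n),
               list(coefficients = model_df(report$model1))),
    model2 = c(list(r_squared = report$model2$r_squared, n = report$model2$n),
               list(coefficients = model_df(report$model2))),
    sex_tests = report$sex_tests,
    mediations = report$mediations,
    n_tests = report$n_tests,
    config = if (!is.null(report$config)) unclass(report$config))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(utils::capture.output(print(report)), file.path(dir, "report.txt"))
  write.csv(report$table, file.path(dir, "analysis_table.csv"), row.names = FALSE)
  write.csv(report$correlations, file.path(dir, "correlations.csv"), row.names = FALSE)
  write.csv(report$mediations, file.path(dir, "mediations.csv"), row.names = FALSE)
  write.csv(rbind(cbind(model = "model1", model_df(report$model1)),
                  cbind(model = "model2", model_df(report$model2))),
            file.path(dir, "models.csv"), row.names = FALSE)
  invisible(dir)
}
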