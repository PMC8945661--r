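# ddcohort

Life-span delay-discounting cohort analysis: per-subject hyperbolic
discount-rate estimation from binary intertemporal choices, power-law
anticipatory time perception, and the robust statistics (Kendall tau-b,
M-estimation, MM-regression, bootstrap mediation) needed to relate discounting
to life-history traits, age and subjective health — plus a seeded
synthetic-cohort generator so the whole pipeline runs and is tested without
access to any participant data.

## Who this is for

Researchers analysing intertemporal-choice studies across adult age groups:
each subject answers a handful of smaller-sooner (SS) vs larger-later (LL)
money questions and a set of "how long does this delay feel" slider probes,
alongside trait questionnaires (childhood socioeconomic status, Mini-K
life-history score, future time perspective, subjective ages and health).
Such data are typically non-normal and outlier-ridden, so every headline
statistic here has a robust form.

## The models

**Hyperbolic discounting with a softmax choice rule.** The present-day value
of a delayed reward is

    SV = A / (1 + kD)

with `A` the delayed amount, `D` the delay in days and `k` the subject's
discount rate (higher `k` = steeper devaluation). A choice picks the immediate
amount `SS` over `SV` with probability

    P(SS) = 1 / (1 + exp(-sigma * (SS - SV)))

where `sigma` is the choice sensitivity. `(k, sigma)` are estimated per
subject by maximum likelihood in `(log k, log sigma)` space with multistart
bounded optimisation; degenerate response patterns (all-SS/all-LL, flat
likelihoods typical of random responders, boundary estimates) are flagged
non-converged and excluded from downstream `log k` analyses.

**Anticipatory time perception.** Felt duration of a prospective horizon `t`
(months) follows the psychophysical power law `T = alpha * t^beta`
(`alpha` = overall time contraction, `beta` = diminishing sensitivity), fitted
per subject by Huber-robust bounded least squares on `[0, 5]^2`, with
two-stage outlier exclusion (parameter bound hits, then per-parameter Tukey
boxplot fences).

**Robust cohort statistics.** Tie-corrected Kendall tau-b with a tie-adjusted
normal (or exact small-sample) test; Huber M-location; Huber M-regression;
a high-breakdown MM-regression (50% breakdown bisquare S-scale, 95% efficiency
M-step); classical ANCOVA F for sex tests; and a single-mediator model whose
indirect effect `a*b` (predictor→mediator times mediator→outcome path) gets a
case-resampling percentile bootstrap interval.

The full pipeline (`run_full_analysis()`) assigns contiguous age groups
(young/middle/older), computes age-bias scores (physical minus chronological
age), builds per-group correlation tables, fits the two interaction models
(log k on life history, age, age group and interactions; plus age-bias terms),
runs the sex tests and the mediation analyses, and emits a deterministic,
seeded report (JSON + text + CSVs).

## Worked example

```r
library(ddcohort)

sim <- simulate_cohort(cohort_config(seed = 42))   # 84/54/104 subjects
dd  <- fit_dd_cohort(sim$choices)
dd
#> Discounting fits: 242 subjects, 7 excluded
#>   degenerate_choice_pattern    1
#>   flat_likelihood              2
#>   k_at_boundary                4
#>   log k: median -4.114, IQR [-4.114, -3.086]
```

Seven subjects are excluded — the synthetic cohort injects exactly seven
random responders, and the convergence screen catches them. One subject's fit:

```r
fit_dd_subject(sim$choices[sim$choices$subject_id == "S0007", ], sim$items)
#> Hyperbolic discounting fit
#>   k = 0.1653 /day   log k = -1.8000   sigma = 2.5119
#>   -logLik = -0.0000 over 7 choices;  converged: TRUE
```

A perfectly cutoff-consistent 7-item pattern pins `k` to an interval (here a
steep discounter) with a near-zero negative log-likelihood. Trait association
and the childhood-environment mediation chain:

```r
kendall_tau(sim$subjects$childhood_ses, sim$subjects$lhs)
#> Kendall tau-b = 0.1482  (n = 242, p = 0.0006041)
#>   pairs: 16712 concordant, 12395 discordant; tied pairs x: 39, y: 15

m <- merge(sim$subjects, dd_fits_table(dd), by = "subject_id")
robust_mediation(m$childhood_ses, m$lhs, m$log_k, n_boot = 2000, seed = 42)
#> Robust mediation (huber paths, n = 235)
#>   a (X -> M)          =   0.1315
#>   b (M -> Y | X)      =  -0.2285
#>   indirect a*b        =  -0.0301, 95% bootstrap CI [-0.0633, -0.0070] *
#>   direct (X -> Y | M) =  -0.0023   (2000 bootstrap replicates)
```

Higher childhood SES predicts a slower life-history score (`a > 0`), which in
turn predicts shallower discounting (`b < 0`); the negative indirect effect is
significant by the bootstrap interval. The one-call driver:

```r
report <- run_full_analysis(sim$subjects, sim$choices, sim$time_probes,
                            sim$items, seed = 42, config = sim$config)
write_report(report, "results/")
```

A command-line wrapper with `simulate` / `analyze` / `mediate` subcommands is
installed at `inst/scripts/ddcohort-cli.R`.

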