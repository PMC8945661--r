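---
title: "Estimating delay discounting across the adult life span: models, robust methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating delay discounting across the adult life span}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcohort)
```

# The scientific problem

Delay discounting — how steeply a person devalues a reward with delay — is a
core individual-difference measure in behavioural economics and life-history
research. Cohort studies relate it to traits calibrated in childhood (family
socioeconomic status, life-history strategy as measured by the Mini-K), to
chronological age, and to subjective markers of senescence (felt physical age
and health). `ddcohort` implements the full estimation and inference chain for
such a study and, because raw participant data of this kind are rarely
deposited, pairs it with a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes, so that every stage is testable.

# The discounting model and its estimator

Each intertemporal item offers an immediate amount $SS$ against a delayed
amount $A$ at delay $D$ days. The subjective value of the delayed option is
hyperbolic,
$$SV = \frac{A}{1 + kD},$$
and the probability of taking the immediate option follows a logistic (Luce /
softmax) rule in the value difference,
$$P(SS) = \frac{1}{1 + e^{-\sigma (SS - SV)}},$$
with $k > 0$ (day$^{-1}$) the discount rate and $\sigma \ge 0$ (per currency
unit) the choice sensitivity. Per subject, $(k, \sigma)$ maximise the Bernoulli
likelihood of the observed choices.

Numerical choices:

* **Parameterisation.** The search runs in $(\log k, \log\sigma)$, removing
  positivity constraints; box bounds are $\log k \in [-9, 0]$ and
  $\sigma \in [10^{-6}, 10]$, spanning indifference to effectively
  deterministic choice at the instrument's amounts.
* **Multistart.** A fixed $3\times3$ start grid plus the best cells of an
  internal coarse likelihood grid seed L-BFGS-B runs; a Nelder–Mead polish
  finishes from the best point. The surface is piecewise-smooth with one basin
  per inter-item rate interval, so grid seeding plus local search reliably
  finds the global optimum (the test suite certifies domination of a dense
  $200\times200$ reference grid on every subject tested).
* **Likelihood evaluation** uses `plogis(·, log.p = TRUE)`, which is
  overflow-safe for large $|\sigma(SS - SV)|$.

**Convergence screening.** With a 7-item instrument, "failure to converge" has
to be operationalised. A fit is excluded when (a) the optimizer fails, (b)
$\log k$ ends on a search bound, (c) $\sigma$ ends on its *lower* bound, (d)
the pattern is all-SS or all-LL (the rate is then unidentified), or (e) the
likelihood is flat: twice the log-likelihood improvement over pure chance
falls below the $\chi^2_2$ 0.95 quantile, which is the statistical signature
of a random responder. An estimate at the *upper* $\sigma$ bound is **not**
treated as failure: any noiseless, cutoff-consistent 7-item pattern drives
$\hat\sigma$ upward while $k$ remains interval-identified, and treating that
as non-convergence would discard most genuine subjects. Under the default
generator the screen catches ~6 of 7 injected random responders with
essentially no false exclusions, matching the scale of exclusion such studies
report. All downstream analysis uses $\ln \hat k$ (natural log).

**What 7 items can and cannot identify.** The default instrument (shipped in
`inst/extdata/`, overridable) places its seven items' indifference rates
$k^* = (A/SS - 1)/D$ approximately log-uniformly over $[0.0011, 0.44]$
day$^{-1}$ inside the published amount and delay ranges; the exact original
items are not public, so this set is a documented stand-in. Seven binary
answers interval-identify $k$ (rank correlation with truth $\approx 0.95$
under the default generator) but carry little information about $\sigma$.
Parameter *recovery* tests therefore use randomly sampled dense item sets,
where the estimate concentrates (median $|\ln\hat k - \ln k|$ about 0.07 /
0.03 / 0.01 at 50 / 100 / 500 choices).

# Anticipatory time perception

Slider readings $T$ (mm on a 150-mm line) against calendar horizons $t$
(months, ten probes from 3 to 60) follow the psychophysical power law
$$T = \alpha\, t^{\beta},$$
with $\alpha$ the overall time contraction and $\beta$ diminishing
sensitivity. The readings are fitted in mm as observed — the instrument is a
bounded slider and any mm-to-month rescaling would only change $\alpha$ by a
constant, to which the analysis (rank correlations, within-subject fits) is
indifferent.

The fit minimises a Huber-type loss (tuning $1.345$ on the MAD residual
scale) under box bounds $[0,5]^2$, implemented as iteratively reweighted
bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM` inside the
IRLS), iterated to a $10^{-8}$ coefficient tolerance (at most 200 passes).
Each pass refits from both the current iterate and the log–log OLS start and
keeps the better solution, because a first-pass boundary solution (e.g.
$\alpha$ at 5 pulled up by one pinned slider) can otherwise trap the
iteration. Starting values come from the log–log OLS fit of positive
readings; $\beta$ starts at 1 when too few are positive.

Outliers are excluded in two stages, in this order: (1) fits with a parameter
within $10^{-6}$ of a bound; (2) among the remaining fits, a Tukey boxplot
rule *per parameter* (strictly outside $[Q_1 - 1.5\,\mathrm{IQR},
Q_3 + 1.5\,\mathrm{IQR}]$ on $\alpha$ or on $\beta$; quartiles are type-7).
Applying the fences per parameter rather than jointly is a documented
assumption. Exclusion is analysis-specific: a subject excluded here still
contributes to analyses not involving $\alpha$ or $\beta$.

# Robust statistics

All headline inference uses robust counterparts of classical statistics,
implemented from scratch and cross-checked in the tests against independent
implementations:

* **Kendall tau-b** with full tie correction; two-sided p from the normal
  approximation with the tie-adjusted variance of $S$, matching common
  practice even at small $n$; an exact small-sample test (inversion-count
  recursion, untied data, $n \le 10$) is available by option.
* **Huber M-location** (bend 1.28, MAD scale, iterated to $10^{-8}$); returns
  the median with a warning when the MAD is zero.
* **Huber M-regression** (tuning 1.345, IRLS on the MAD scale) — fast, convex,
  the default path estimator for mediation.
* **MM-regression**: a 50%-breakdown S-estimate of scale (normalised Tukey
  bisquare, $c_0 = 1.5476$, 500 random $p$-subsets with IRLS refinement of the
  best candidates, seed-controlled and fixed by default so identical inputs
  give identical fits) followed by a bisquare M-step at 95% Gaussian
  efficiency ($c_1 = 4.685$) holding the S-scale fixed. Standard errors use
  the usual M-estimation sandwich with an $n/(n-p)$ correction; the robust
  $R^2$ is $1 - \sum\rho(r_i/s)\,/\,\sum\rho((y_i-\hat\mu_y)/s)$. The tuning
  constants are the conventional defaults of the robust-regression literature;
  the source study names the estimator but not its settings.
* **ANCOVA F** (sex tests) is deliberately classical OLS, as such F statistics
  are conventionally reported: nested-model comparison of `y ~ covariate`
  against `y ~ covariate + group`.

# Mediation

The single-mediator model defines the indirect effect as the product $a\times
b$ of the predictor→mediator and mediator→outcome (given predictor) path
coefficients, with the direct effect returned alongside. Paths are fitted by
Huber M-regression by default; the high-breakdown MM variant is selectable but
an order of magnitude slower in the bootstrap. Inference is a case-resampling
(pairs) bootstrap — valid under heteroscedasticity, and the convention of the
product-of-paths mediation literature — with a percentile interval
(default 2000 replicates, level 0.95, seeded); only the indirect effect drives
the significance flag. Bootstrap refits warm-start from the full-data solution
and use a $10^{-5}$ coefficient tolerance, far below the resolution of the
interval quantiles. Calibration is certified in the tests: 95% intervals cover
a true indirect effect of 0.25 in 92–97% of 500 seeded replicates at
$n = 200$, and the null false-positive rate stays below 7.5%.

# The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs. They emulate a published life-span cohort of 242 Chinese adults
in three groups (84 young / 54 middle-aged / 104 older; contiguous age bins
[18,34), [34,48), [48,70], since the gaps in the original sample's ranges were
a sampling artifact, and configurable cutoffs can reproduce the gapped
version) with that study's reported per-group means and SDs for chronological
age, childhood SES, Mini-K, subjective health and subjective ages, and its
sex counts per group.

Structure, with defaults chosen from the study's printed statistics before
the acceptance tests were first run:

* **Trait coupling.** SES, life-history score and future time perspective are
  linked through a Gaussian copula with correlations $\sin(\pi\tau/2)$ chosen
  to hit the reported Kendall targets ($\tau = 0.22$ SES–LHS, $0.35$
  FTP–LHS) in expectation.
* **Observed-moment fidelity.** Likert traits are drawn Gaussian and clipped
  to their scales (discretisation optional); ages are rejection-sampled
  within their bins. Both use closed-form winsorized/truncated-moment
  corrections so the *observed* moments match the configured ones — what
  "drawn with the configured moments" must mean once clipping exists.
* **Discounting surface.** $\ln k = -4 - 0.25\,(\mathrm{LHS} -
  \overline{\mathrm{LHS}}) + \text{age term} + \text{noise}(SD\,0.8)$, with a
  piecewise-linear U-shaped age term: slope $-0.05$/yr inside the young group
  (pivot at 34), $+0.06$/yr inside the older group (pivot at 48), zero in
  between — continuous in age. Young males carry a $+0.35$ offset (sized to
  reproduce a just-significant young-group sex ANCOVA at $n = 84$).
* **Subjective age.** Physical age = chronological age + group offset +
  $2.5\,(3 - \text{physical health})$ + noise, making feeling older track
  poorer health ($\tau(\text{health}, \text{age bias}) \approx -0.2$); the
  age-bias score adds $+0.10$ per year to $\ln k$ *in the older group only*,
  the generative analogue of the reported bias-by-group interaction. The
  health coupling and the published subjective-age SDs cannot both hold
  exactly (the implied young-group variance is already above the published
  value before any noise), so the coupling wins and subjective-age SDs run
  slightly high in the young group.
* **Time perception.** $\alpha \sim 2.0\,(SD\,0.5)$, $\beta \sim 0.75\,(SD\,
  0.12)$, with age trends confined to the young group ($-0.05$/yr on
  $\alpha$, $+0.01$/yr on $\beta$), reproducing the reported pattern of
  significant young-group age correlations; slider noise SD 5 mm, readings
  truncated to $[0, 150]$.
* **Contamination.** A `random_responder_rate` of $7/242$ injects coin-flip
  choosers (the analogue of the study's seven non-converging subjects — a
  flat likelihood in $\sigma$ reproduces that failure mode), and a
  `time_outlier_rate` of 0.15 injects subject-level careless slider
  responders (uniform on the slider), sized so time-perception exclusions
  land near the reported count (~47 of 242); these are two separate
  mechanisms because one shared rate cannot match both counts. Per-probe
  corruption would largely be absorbed by the robust loss, hence the
  subject-level mechanism.

**What the generator does *not* emulate** — and hence what passing tests do
not certify about real data: item-level response processes (response times,
question-order and platform effects), discrete Likert response styles (scores
are continuous by default), any sex-by-group structure beyond the marginal
counts, non-Gaussian trait tails, and real-world measurement nonstationarity.
Passing the structural acceptance checks shows the *pipeline* recovers the
structure it assumes, not that the structure is true of any real population.

# Reproducibility and problem sizes

Every stochastic stage is seeded: one cohort seed deterministically derives
stage seeds (choices, probes, each mediation bootstrap), and the
MM-regression's subset resampling is internally seeded, so
`run_full_analysis()` is bit-reproducible given inputs and seed. The test
suite's simulation sizes are chosen to estimate each property with adequate
precision while keeping the default run short: 100 subjects for
likelihood-grid domination, 200 subjects × {50, 100, 500} choices for
recovery, 500 replicates for bootstrap coverage (200 for the null rate), and
200 null-cohort replicates at 50 subjects per group (type-I control does not
depend on group size) with 500 bootstrap replicates per mediation.

# Known limitations

* Only the hyperbolic discounting form is implemented (no exponential or
  quasi-hyperbolic variants, no hierarchical shrinkage across subjects).
* The MM-regression p-values rest on asymptotic normal theory; at the default
  model sizes (~185 observations, 5–7 terms) they are accurate to the level
  certified by the null-cohort tests (false-positive rates ≤ 7.5%).
* The exact Kendall test is limited to untied data with $n \le 10$.
* With the 7-item instrument, $\hat k$ is interval-valued and $\hat\sigma$ is
  largely uninformative; cross-subject comparisons of $\hat\sigma$ from such
  data should not be interpreted. A side effect of the interval
  identification is that $\ln\hat k$ is quantized; if more than half of a
  (small) analysis sample lands on one quantized value, the 50%-breakdown
  MM-regression legitimately declares an exact fit with zero robust scale, in
  which case coefficients are returned but standard errors and p-values are
  flagged undefined.
* The mediation model is single-mediator only; no moderated mediation or
  effect-size standardisation.
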