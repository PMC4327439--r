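---
title: "Discovering precursors of health events in query logs: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering precursors of health events in query logs: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchsccs)
```

This vignette is the package's account of the statistics it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the points where the method's published description was open and a
design decision had to be made.

## The self-controlled case series model

For a given health condition we observe a cohort of users, each with
exactly one event day (the day they first self-identified, or first
queried the condition) inside a shared observation window of $D$ days.
For a candidate exposure label, user $i$'s days split into *risk days*
$r_{i,d} = 1$ — days inside the window $(d_e, d_e + W]$ following one of
their queries carrying the label — and baseline days. Events are assumed
to arise from a non-homogeneous Poisson process with daily rate

$$\lambda_{i,d} = \exp(\theta_i + \beta\, r_{i,d}),$$

so each user has their own baseline rate $e^{\theta_i}$ and the exposure
multiplies it by $e^\beta$ during risk days. The log-likelihood over all
users is

$$\ell(\theta, \beta) = \sum_i \sum_d \left[ y_{i,d}(\theta_i + \beta
r_{i,d}) - e^{\theta_i + \beta r_{i,d}} \right]$$

with $y_{i,d}$ the event indicator. Because every user contributes both
exposed and unexposed person-time, each user is their own control and any
confounder that is stable over the window cancels out of the comparison.
The price is the model's assumptions: one event per user, correct event
timing, and exposure that does not alter the length of observation.

**Profiling.** With exactly one event per user,
$\partial \ell / \partial \theta_i = 0$ has the closed-form solution
$\hat\theta_i(\beta) = -\log\!\big(n^0_i + n^1_i e^\beta\big)$ with
$n^1_i$ risk days and $n^0_i$ baseline days. Substituting it gives the
profile likelihood

$$\ell_p(\beta) = \sum_i \left[ \beta e_i - \log\!\big(n^0_i + n^1_i
e^\beta\big)\right] + \text{const},$$

where $e_i$ indicates the event fell on a risk day — the conditional
(multinomial) likelihood of the event day given that one event occurred.
$\ell_p$ is concave in $\beta$, depends on the data only through the
per-user triple $(n^1_i, n^0_i, e_i)$, and its maximizer equals the joint
maximizer over $(\theta, \beta)$, so profiling is exact, not an
approximation. `sccs()` therefore aggregates users into identical
$(n^1, n^0)$ strata and maximizes a one-dimensional function regardless of
cohort size; `sccs_joint()` maximizes the full $(N+1)$-dimensional
likelihood directly and is kept as an independent oracle for small series.

Significance is a likelihood-ratio test of $\beta = 0$ against
$\chi^2_1$; Wald intervals use the observed information of the profile
likelihood, $\mathcal{I}(\hat\beta) = \sum_i p_i(1 - p_i)$ with
$p_i = n^1_i e^{\hat\beta} / (n^0_i + n^1_i e^{\hat\beta})$.

On a homogeneous design (every user $n^1$ risk and $n^0$ baseline days,
$k_1$ of $k$ events in risk) the maximizer has the closed form
$e^{\hat\beta} = (k_1 n^0) / (k_0 n^1)$, which the test suite uses as an
exact oracle:

```{r closed-form}
s <- case_series(rep(3, 100), rep(7, 100), rep(c(TRUE, FALSE), c(60, 40)), W = 3)
sccs(s)$relative_hazard   # (60 * 7) / (40 * 3) = 3.5
```

## Pipeline parameters

| Parameter | Default | Meaning |
|---|---|---|
| `observation_length` | 183 days | shared observation window (about six months) |
| `W` | 15 days | post-exposure risk window |
| `min_siu` | 25 users | minimum self-identified users per analyzed condition |
| `min_fraction` | 0.01 | minimum fraction of the cohort querying a candidate label |
| `q` | 0.05 | FDR level, both for the temporal filter and the final screen |
| `min_monthly_clicks` | 10 | per-month click threshold for query-to-page mapping |
| `rho_target` | 0.3 | minimum incidence rank-correlation when tuning the classifier threshold |
| trigger phrases | 4 phrases | "i have", "i suffer from", "living with", "i was diagnosed with" |

The defaults are the method's published operating points where it has
them (the window lengths, the SIU and candidate thresholds, the click
threshold, the FDR level, the trigger phrases); `rho_target` generalizes a
single reported operating point (a correlation of about .32 accepted in
exchange for a roughly tenfold cohort) into a rule, since the raw score
scale of any particular classifier is arbitrary.

## Design decisions at open points

Several aspects of the procedure are not pinned down by its published
description; the package fixes them as follows, each configurable where
reasonable.

* **Risk window excludes the exposure day.** "The $W$ days following" is
  read as $(d_e, d_e + W]$; `include_exposure_day = TRUE` gives the
  closed variant.
* **Post-event exposures are retained.** Standard SCCS does not censor
  observation at the event; truncating exposure history at the event day
  would condition on the outcome. A `pre_event_only` mode exists for
  sensitivity analysis.
* **Event day for classified (non-SIU) users** is the day of their first
  query mentioning their assigned condition — by analogy with the
  assumption that self-identification happens at onset. This is the most
  consequential undefined point of the original procedure and is
  flagged prominently here: for classified users the "event day" is a
  proxy with unknown lag.
* **Threshold tuning** picks the largest cohort whose per-condition rates
  still rank-correlate with published incidence at `rho_target`; the
  literal smallest-threshold reading collides with the convention that
  threshold zero denotes the SIU-only (smallest) cohort.
* **Per-candidate significance** is an LRT against $\beta = 0$ (the
  standard SCCS test); the published description says only that an FDR
  test was applied across candidates.
* **Temporal filter correlation** is Pearson on raw daily counts
  (Spearman by flag); the description says only "correlation". Labels
  with a constant daily series in either population are kept: a flat
  series carries no evidence of a shared external driver.
* **Monthly click rule** is the strict reading — at least 10 clicks in
  *every* month of the span — with a `rule = "mean"` variant, since the
  published phrasing admits both.
* **Tautology guard.** A candidate label equal to the condition name or
  one of its synonyms is excluded from screening: post-event queries
  about one's own condition would otherwise dominate as a spurious
  "precursor".
* **Gradient rule.** The published dose-response categorization calls
  everything below $\rho = .5$ "negative", which would include weak
  positives; here $\rho \ge .5$ is positive, $\rho \le -.5$ negative,
  anything else (or fewer than three populated strata) undetermined.
* **Matching is token-based**, not substring ("hives" must not match
  "hiv"); overlapping matches resolve longest-span-first with
  lexicographic tie-breaks, so all downstream stages are deterministic.

## The synthetic-data generator

`simulate_querylog()` realizes **exactly the generative law the estimator
assumes**: conditions are assigned per user from the configured incidence
table (one condition per user); planted precursor exposure days define
risk windows; and the event day is drawn from the multinomial implied by
the Poisson model, with day weights $e^{\beta r_d}$. Because generator and
likelihood coincide, parameter recovery is a sharp test of the estimator
rather than a robustness exercise. On top of this the generator emits the
observable layers: self-identifying trigger queries on the event day for a
configurable fraction of affected users; own-condition queries at a mean
of 6.8 after the event versus 2.15 for background disease querying (the
two distributional anchors the method's description provides — the
pre-event mean is scaled by the fraction of the window preceding the
event); neutral background categories as uniform user-day Bernoulli
draws; and news-spike categories that burst across the whole population
for a few days, the planted temporal confounders. Exposure query days are
placed uniformly in the window, a choice the method's description leaves
open.

Default generator incidences (0.01–0.03) are one to two orders of
magnitude above typical published yearly incidences; at realistic rates a
desk-scale population would contain almost no cases, and the pipeline's
behavior per case is unaffected by the marginal rate. The defaults are
therefore chosen to give usable cohort sizes at a few thousand simulated
users, and tests that need a specific cohort size set the incidence
explicitly.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: natural-language query text (queries are
template strings over a toy lexicon of 40 terms, versus ~11,000 in a
production lexicon); negated or hypothetical self-statements ("i don't
have cancer" counts as self-identification here and in the original
method); comorbidity (one condition per user); event-dependent querying
changes other than the own-condition rate shift; per-user observation
windows (everyone shares one window); and the click-graph noise of a real
query-to-page mapping. Calibration results on synthetic data are
statements about the estimator under its own model, not about the many
ways real search behavior violates it.

## Numerical choices

* The profile likelihood is maximized with Nelder–Mead from $\beta = 0$
  (tolerance $10^{-8}$ on the objective, at most 500 iterations),
  followed by a few Newton steps on the analytic score — the function is
  smooth and concave, so the polish pins the maximizer to machine
  precision without changing it.
* $|\hat\beta|$ is capped at 10 ($e^{10} \approx 2.2\times10^4$). The MLE
  is infinite exactly when all informative events fall in risk days, or
  none do; both cases are detected analytically, returned at the cap, and
  flagged `converged = FALSE`. `run_screen()` excludes such candidates
  with a logged reason rather than reporting a boundary estimate.
* Users with zero risk days or zero baseline days contribute a constant
  to the profile likelihood; they are flagged non-informative and do not
  enter the fit (their baseline rates are still recoverable from
  $\hat\theta_i(\hat\beta)$).
* `sccs_joint()` restarts the simplex at its incumbent (plain
  Nelder–Mead stalls beyond roughly ten dimensions) and then polishes
  with BFGS using the analytic gradient; the polish can only sharpen the
  simplex result since the joint likelihood is concave. It is an oracle
  for tens of users, not a production path.
* All cross-validation folds are stratified and seeded; the background
  sample for the temporal filter is a seeded uniform draw of non-cohort
  users (10 times the cohort size by default). Two runs with the same
  inputs and seed produce byte-identical reports.

## Test and calibration scales

The statistical checks in the test suite and `scripts/acceptance.R` use
problem sizes chosen to make Monte-Carlo error small relative to the
tolerances while staying desk-scale: 100 replicates of 2,000-user case
series for recovery and interval coverage of a planted hazard of 3; 50
replicate global-null screens of 30 candidate labels for FDR calibration;
20 random series of up to 50 users for the profile-versus-joint
equivalence at $10^{-3}$; and one end-to-end log of 6,000 users (about
1,500 affected) with a planted hazard of 4 and a planted news spike.

## Known limitations

Everything the self-identification heuristic misses — users who never
phrase their condition in a trigger pattern, negations, conditions whose
sufferers do not search — biases cohort composition in ways the synthetic
data cannot reveal. The classifier expansion inherits an unverifiable
event-day proxy. The SCCS assumptions (single event, exposure-independent
observation) are untestable from the log alone. And an FDR-controlled
screen over hundreds of candidate labels still emits occasional borderline
false positives by construction; the output is a ranked hypothesis list
for traditional epidemiological follow-up, not a set of established risk
factors.
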