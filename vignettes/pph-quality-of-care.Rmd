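---
title: "Measuring the quality of care for severe postpartum hemorrhage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the quality of care for severe postpartum hemorrhage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphscore)
```

## The measurement problem

Postpartum hemorrhage (PPH) is the leading preventable cause of maternal
mortality. Whether a woman with severe PPH received adequate care is hard to
quantify: global expert judgement is subjective, and auditing one isolated
item of management (say, timely oxytocin) ignores the rest of the care
pathway. `pphscore` implements a composite, weighted quality-of-care score
over eight expert-selected components of prevention and first-line
treatment, together with the downstream machinery used to analyse its
determinants: percentile-based classification of "inadequate care",
random-intercept logistic regression at the maternity-unit level, multiple
imputation, and a synthetic nested-cohort generator so the whole pipeline is
testable without access to any real cohort.

## The score

Care is scored in one of four **clinical contexts** — mode of delivery
(cesarean / vaginal) crossed with whether the PPH cause was uterine atony —
because the expected items of management differ across them. Each criterion
is weighted *major* (2 points) or *minor* (1 point); the score is

$$ S \;=\; \frac{\text{points earned over applicable criteria}}
              {\text{maximum points in the context}} \in [0, 1], $$

with context maxima 11 (cesarean, no atony), 12 (cesarean, atony),
14 (vaginal, no atony) and 15 (vaginal, atony). The criteria and their
scoring rules:

| criterion | rule | points |
|---|---|---|
| prophylactic uterotonic (third stage) | done / not done | 2 / 0 |
| blood-loss estimate written in chart | done / not done | 2 / 0 |
| first-line uterotonic | ≤ 30 min / later or untimed / never | 2 / 1 / 0 |
| hemoglobin measured | ≤ 60 min / otherwise | 2 / 0 |
| hemostasis measured (PT, aPTT or fibrinogen) | ≤ 60 min / otherwise | 2 / 0 |
| manual uterine examination (vaginal only) | ≤ 30 min / otherwise | 2 / 0 |
| cervix & vagina examination (vaginal only) | done / not done | 1 / 0 |
| second-line uterotonic (sulprostone), atony | ≤ 30 min after first-line / otherwise | 2 / 0 |
| second-line uterotonic, no atony | administered at any time / never | 1 / 0 |

Delays are measured from PPH diagnosis, except the second-line uterotonic,
which is anchored at the first-line administration.

Three conventions deserve emphasis because they decide ambiguous charts:

* **Missing means not done.** A procedure not noted, or incompletely noted,
  in the chart earns no points. The scorer records which criteria were
  affected (`missing_as_not_done`), and `score_cohort()` can alternatively
  treat any record with a missing applicable criterion as unscoreable
  (`exclude_missing_criteria = TRUE`), mirroring audits that exclude
  un-assessable charts.
* **Cut-offs are inclusive.** A delay of exactly 30 (or 60) minutes earns
  the on-time points; 30 + ε does not.
* **Partial credit only where an "administered" row exists.** A first-line
  uterotonic given with unknown timing earns 1 (it was administered); a
  hemoglobin measurement with unknown timing earns 0 (the criterion is
  purely a timeliness criterion). A timed second-line dose whose first-line
  anchor is absent cannot satisfy the 30-minute rule: it falls to the
  any-timing row (0 under atony, 1 otherwise) and the result carries a
  `second_line_anchor_undefined` flag.

```{r}
ctx <- classify_context("vaginal", TRUE)
rec <- care_record(prophylactic_uterotonic = "done",
                   blood_loss_documented = "done",
                   first_line_uterotonic = 45,    # late: partial credit
                   hemoglobin_measured = 30, hemostasis_measured = 45,
                   manual_uterine_exam = 15, cervix_vagina_exam = "done",
                   second_line_uterotonic = 20)
compute_score(rec, ctx)
```

## Inadequate care

"Inadequate care" is a binary flag for a score **strictly below the
empirical 25th percentile** of the study population. Two definitional
choices are configurable because published audits rarely pin them down:

* **Quantile definition.** Default: linear interpolation between order
  statistics (R's type 7, the common default across scientific stacks);
  alternative: the lower order statistic (type 1). With the published
  cohort unavailable, the printed threshold (53.8% of expected items)
  cannot be re-derived, so the definition is exposed rather than hidden.
* **Strict vs non-strict comparison.** Default: strict `<`, the main-text
  definition; `<=` is available for sensitivity analysis.

A subtlety of the strict threshold: with an interpolated quantile and a
vector of *distinct* values whose length is ≡ 2 or 3 (mod 4), the flagged
fraction can exceed the 25% level by at most $0.75/n$ (the interpolated
threshold sits strictly above the relevant order statistic). Real score
vectors are heavily tied — scores live on at most a few dozen rational
values — and at the cohort sizes this package targets
($n = 1104$: $\lfloor 1 + 0.25 \cdot 1103\rfloor / 1104 = 25.0\%$) the
bound is exact. The test suite asserts the general bound
$\text{rate} \le 0.25 + 1/n$.

## Eligibility

`is_severe_pph()` applies the severity inclusion rule: major bleeding
(blood loss ≥ 1500 mL, ≥ 4 red-cell units transfused, surgical
procedure/embolization), acute hematologic dysfunction (hemoglobin nadir
≤ 7 g/dL, platelets ≤ 50,000/mm³, DIC), organ failure, ICU admission or
death — thresholds inclusive, missing values never qualifying (cases are
identified on positive evidence). Etiologies whose management is not
covered by the standard first-line pathway (placenta accreta spectrum,
uterine rupture, amniotic-fluid embolism, …) are excluded as a **union**
of flags: flags may overlap, so per-flag tallies may sum to more than the
number excluded, and `build_flow()` never assumes otherwise.

## Determinant analysis

The outcome is the inadequate-care flag; the exposures are five
maternity-unit characteristics (status, annual delivery volume, level of
care, 24/24 onsite obstetrician, 24/24 onsite anesthesiologist). Because
women are nested in units, every model — crude models included — is a
logistic regression with a **random intercept for the maternity unit**,
fitted by maximum marginal likelihood with adaptive Gauss–Hermite
quadrature (15 nodes by default; `nAGQ = 1` gives the Laplace
approximation). Estimation is delegated to `lme4::glmer()`; the package
carries its own quadrature evaluator (`ri_loglik()`), used for the
reported log-likelihood and cross-checked in the tests against brute-force
numerical integration (agreement to $10^{-6}$ on small problems; doubling
the node count moves the optimum log-likelihood by less than $10^{-4}$).

Reference levels are fixed: public-university status, ≥ 3500
deliveries/year, level-3 care, and 24/24 onsite presence for the staffing
indicators; reference rows carry an odds ratio of exactly 1 and no
interval. Confidence intervals are Wald intervals on the log-odds scale,
exponentiated. `run_model_suite()` fits, per stratum (all deliveries,
vaginal, cesarean), one crude and one adjusted model per characteristic
(adjusting for the PPH risk profile, maternal country of birth and
parity/previous cesarean), plus a combined status + volume model in the
vaginal stratum, where those characteristics are jointly informative;
`vif()` (VIF$_k = 1/(1-R^2_k)$) is provided to screen such combinations
for collinearity before trusting a joint model. Non-converged fits are
flagged, never silently dropped. Sparse clusters (many units contribute a
handful of women) are handled by the marginal likelihood itself; no unit
is excluded by size.

The **PPH risk profile** is a composite: previous PPH, multiple pregnancy,
pre-eclampsia, or birth weight ≥ 4000 g. With no positive flag and a
missing birth weight it is undetermined (and imputable).

## Missing data

Country of birth is the dominant source of missingness in the intended
analysis (~10% of records). `mice_impute()` implements chained equations:
each incomplete variable is drawn from a conditional model given all other
analysis variables — logistic regression with an approximate-posterior
coefficient draw for binary variables, multinomial regression on a
bootstrap resample for unordered categories, predictive mean matching
(5 donors) for numerics — for 10 cycles, producing m = 12 completed
datasets by default. Observed cells are never modified and a seed fully
determines the output. Per-imputation fits are combined with Rubin's
rules (`pool_rubin()`): pooled estimate $\bar q$, total variance
$T = W + (1 + 1/m)B$, classical degrees of freedom
$(m-1)\,(1 + W/((1+1/m)B))^2$, with $B = 0$ handled by infinite df and a
normal quantile. Pooling happens on the log-odds scale; odds ratios are
exponentiated afterwards. The imputation-model choices (all analysis
variables as predictors, outcome included, per-type defaults) follow
standard chained-equations practice.

## The synthetic cohort generator

`simulate_cohort()` generates units → women → criterion-level care events:

* **Units** (119 by default) are drawn from a joint table of realistic
  archetypes — university units are large, level-3 and fully staffed;
  private units tend to be small, level-1 and without 24/24 onsite staff —
  which reproduces the real-world collinearity between status, size and
  level of care. Each unit gets a latent quality effect
  $u_j \sim N(0, \sigma_u^2)$, $\sigma_u = 0.5$, shared by all criteria of
  all its women: this is what generates within-unit correlation of the
  binary outcome.
* **Women** are nested in units with negative-binomial unit sizes scaled
  by the volume band (≈ 1100 women at defaults), 35.7% cesarean, 69.8%
  atony, and maternal covariates at the prevalences of the published
  severe-PPH cohort. Country of birth is made missing at random at an
  overall 9.6% rate, with the per-row probability depending on observed
  covariates only (private-unit status and maternal age band) and recorded
  in the truth object — so the chained-equations assumptions hold by
  construction.
* **Care events**: each criterion's compliance is
  $\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + \text{effect}(unit) + u_j)$
  with base rates $p_0$ at the published audit levels; delays are
  log-normal in minutes, calibrated so that (for example) ~81% of
  first-line administrations fall within 30 minutes, reproducing both the
  administered-at-all and the on-time published margins. The second-line
  delay is only drawn when a first-line dose exists. The `effect_map`
  argument injects additive log-odds shifts for chosen unit-characteristic
  levels (zero by default): this is the hook used by the recovery studies.

What the generator deliberately does **not** emulate: criteria are
conditionally independent given the unit effect, so the share of perfect
scores (~6%) undershoots a real cohort, where one diligent team tends to
satisfy many criteria jointly (published: 16%); the latent effect also
shrinks realized compliance a point or two below the configured base rates
(Jensen's inequality). Passing recovery tests on this generator therefore
demonstrates the estimation machinery, not the realism of any particular
correlation structure.

## Numerical and design choices

* Percentages in reports are rounded half-away-from-zero to 1 decimal,
  matching clinical-audit table style; scores are kept as exact integer
  pairs (earned, max) alongside the float ratio.
* The quadrature re-centres the integrand at its per-cluster mode
  (located by golden-section search, curvature by central differences),
  which keeps 15 nodes accurate even for extreme clusters; $\sigma = 0$
  short-circuits to the ordinary Bernoulli likelihood.
* A boundary estimate $\hat\sigma_u = 0$ is reported explicitly
  (`singular = TRUE`), and agreement with ordinary logistic regression at
  that boundary is part of the test suite.
* Simulation studies in the tests and the acceptance script use 200
  replicates of 120 clusters × 10 women for parameter recovery and 50
  end-to-end replicates of full default cohorts for sign recovery — sizes
  at which the Monte-Carlo error of the checked summaries is comfortably
  inside the asserted bands.
* Factor levels absent from a dataset are dropped from designs with a
  warning; a characteristic with a single observed level yields an
  intercept-only design rather than an error, so model suites continue
  past degenerate strata.

## Limitations

The score is a process measure: it audits documentation of recommended
care, not outcomes, and inherits the charts' recording quality (the
missing-means-not-done convention is conservative by design). The
percentile threshold is population-relative — comparisons across cohorts
should fix the threshold, not recompute it per cohort. The generator's
unit-characteristic table is an archetype sketch, not an estimate of any
national distribution; and no attempt is made to reproduce the published
regression coefficients, which depend on individual-level data that are
not public.
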