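---
title: "Methods: two-stage SSI risk modelling, point-score conversion and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage SSI risk modelling, point-score conversion and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic world does
and does not emulate, the numerical choices, and the places where the
design was genuinely open and a choice had to be made. Nothing here states
an empirical result that the test suite or the acceptance script does not
itself compute.

## The model

The outcome is binary: any surgical site infection within 30 days of an
operation. Risk is modelled on the log-odds scale,

$$\operatorname{logit} P(\text{SSI}) = \beta_0 + \sum_i \beta_i x_i,$$

with patient covariates (age, sex, BMI, smoking, functional status,
comorbidity flags) and operative covariates (setting, wound class, ASA
class, anaesthesia type, multiple procedures, housestaff involvement,
operation duration). Two features of surgical data drive the design:

* **Nonlinearity of continuous covariates.** BMI and operation duration do
  not act linearly on the log-odds. Continuous covariates therefore enter
  through fractional polynomials: candidate bases $x^p$ with $p$ from
  $\{-2,-1,-\tfrac12,0,\tfrac12,1,2,3\}$ ($p=0$ meaning $\ln x$), degree 1
  (8 candidates) or degree 2 (36, with the repeated-power pair $(p,p)$
  spanning $x^p$ and $x^p\ln x$). The form is chosen by the standard
  closed test: best FP2 against the null (4 df), against linear (3 df),
  against best FP1 (2 df), each by a deviance difference against the
  chi-square critical value at $\alpha$; the simplest adequate form wins.
* **Between-procedure heterogeneity.** Procedures (3-digit CPT prefixes)
  differ in infection risk in ways patient covariates do not capture. The
  CPT3 score quantifies this by indirect standardization within the
  derivation half: for group $g$, $\text{CPT3}_g = O_g / E_g$, with $E_g$
  the sum of stage-1 predicted probabilities over the group's operations.
  Groups with $O_g = 0$ are defaulted — to 0 when $E_g > 0.5$ (enough
  exposure that observing no event is informative), to 1 (risk-neutral)
  when $E_g \le 0.5$. Prefixes never seen in derivation also score a
  risk-neutral 1 at lookup time; the low-expectation default has the same
  spirit, and anything else would impute risk information that the
  derivation data do not contain.

Model construction is two-staged: a stage-1 forward-selection logistic
model provides the expected counts for the CPT3 table; stage 2 reruns
forward selection over all covariates plus the CPT3 score at a strong
threshold, then tests a-priori interactions by likelihood ratio. The CPT3
score enters stage 2 as an ordinary continuous covariate, itself eligible
for a fractional-polynomial form.

Selection uses likelihood-ratio tests throughout, not Wald or score tests:
categorical covariates enter and leave as whole indicator blocks and FP
terms span one or two columns, so a multi-degree-of-freedom deviance test
is the only uniformly well-defined criterion.

## Point-score conversion and the score-to-risk map

The Sullivan system converts coefficients to integer points. One point is
anchored to a clinically interpretable increment — by default the log-odds
change induced by 5 BMI units, evaluated at the derivation-cohort median
and passed through BMI's stored transform, giving the unit $B$. Every
covariate is categorised; a category with representative value $W_{ij}$
and reference $W_{i\mathrm{REF}}$ is worth
$\mathrm{round}\!\left(\beta_i (W_{ij}-W_{i\mathrm{REF}})/B\right)$
points, negative values permitted. Expected risk at score $s$ is
$1/(1+e^{-(\hat\alpha+\hat\beta s)})$, with $\hat\alpha,\hat\beta$ from a
logistic regression of the outcome on the score alone, fitted on the
derivation half.

Choices Sullivan's presentation leaves open, fixed here:

* **Rounding**: half away from zero (documented; base R's half-to-even
  would make point values depend on parity).
* **Representatives**: interval midpoints for bounded categories; for
  open-ended top/bottom categories the category's observed
  derivation-cohort median (a finite, robust representative).
* **Reference category**: for continuous covariates, the category
  containing the derivation median; for categorical ones, the first
  declared (clinically baseline) level. Exactly one zero-point category
  per covariate.
* **Categorisation**: derivation-cohort quintiles by default; a
  `"published"` preset carries the printed boundary facts of the original
  bedside score (BMI 35; duration ½ h and 3½ h; CPT3 0.9 and 1.262) for
  users who want those cut points.
* **Base constant**: exposed, default 0 (whether the original score
  carries an offset is not recoverable from the available text).
* **Interactions** are excluded from the point table with a logged
  warning: a per-covariate additive card cannot represent them without a
  combinatorial category blow-up, and the score-to-risk refit absorbs the
  overall calibration consequences. The integer score is thus a
  main-effects approximation of the model — one reason its c-statistic
  can only be lower.

## Evaluation

All performance is measured on the validation half only, which no earlier
stage reads. Discrimination is the c-statistic (midrank AUC, identical to
exhaustive pair counting) with a DeLong placement-component 95% CI; the
report carries a method tag because the literature's CI conventions vary.
Calibration is assessed two ways: the Hosmer–Lemeshow deciles-of-risk test
(ties kept together; a group with zero expected events is merged with its
neighbour and logged; df = groups − 2), and per-score-level comparison of
the map's expected rate against the Clopper–Pearson exact 95% CI of the
observed rate — the headline summary counts levels with at least one
observed SSI, and the fraction of the population at within-CI levels is
reported alongside. The NNIS basic index is the comparator; its duration
criterion uses per-procedure 75th-percentile cutpoints computed from the
derivation half (the published external cutpoint tables would make the
artifact non-self-contained), with the overall 75th percentile as the
fallback for unseen prefixes.

## The synthetic world

The generator draws covariates from marginals mirroring a large 2010
general-surgery registry as qualitatively described: roughly one third
ambulatory, one half elective inpatient, 10% emergency; more than half
clean wounds and ASA 1–2; general anaesthesia > 90%; housestaff > 50%;
an additional procedure > a third; mean operative duration 1.8 h. The
source description is qualitative, so the continuous marginals are
plausibility choices fixed once: duration log-normal (meanlog 0.343,
sdlog 0.7 — mean 1.8 h with the long right tail of operative times), BMI
normal(29, 6.5) truncated to [14, 70], age normal(55, 16) truncated to
[18, 94]. True effects have the reported directions (risk up with smoking,
BMI, vascular disease, metastatic cancer, steroid use, sepsis,
inpatient/emergency setting, contaminated/dirty wounds, ASA 3+, general
anaesthesia, multiple procedures, longer operations) and realistic
single-digit odds ratios; BMI acts per 5 units, duration on the log scale.
Between-procedure heterogeneity is injected as per-group log-odds offsets
drawn once per group from N(0, 0.4) — the paper gives no generative model
for it, and offsets are the simplest mechanism that makes CPT3 recovery
testable. The intercept is tuned by monotone root finding so the mean true
risk equals the 3.9% target. A single seed governs everything; group
structure uses a stream decoupled from record-level draws so growing the
cohort never reshuffles the groups.

**Group-count scaling.** At full scale (363,040 operations) the default is
290 CPT prefixes, ≈ 1250 operations per group. When the cohort is scaled
down for desk-scale work, the default group count scales with it
(n/1250, clamped to [10, 290]) rather than staying at 290: holding 290
groups at n = 20,000 gives ~34 operations per group, a regime in which the
O/E score is mostly small-sample noise and zero-event defaults, and in
which its derivation-half fit badly overstates its validation value. The
quantity the scale-down preserves is the per-group sample size that
governs how the CPT3 mechanism behaves. Explicit `n_groups` overrides.

**What a green test establishes — and what it does not.** The synthetic
world has independent covariates (no confounding structure beyond the
shared group offsets), no missing data, exactly Bernoulli outcomes from a
logistic truth, and no secular or hospital-level clustering. Recovery
results on it verify the *machinery* — that selection finds real signals
at the advertised error rates, that the CPT3 score captures injected
heterogeneity, that points and maps reproduce their defining arithmetic —
not the clinical validity of any particular fitted score, and not the
original study's real-data performance figures, which required the
restricted registry.

## Numerical choices

* IRLS convergence: relative deviance change < 1e-10, ≤ 100 iterations.
* Rank deficiency is detected before fitting (QR pivot) and reported with
  the offending columns; a constant outcome is an explicit error (no MLE).
* Separation: fitted probabilities within 1e-8 of 0/1 together with a
  coefficient exceeding 15 log-odds flags the fit non-converged with a
  diagnostic; forward selection skips such candidates with a logged
  warning rather than aborting.
* FP preprocessing: shift 0 when min(x) > 0, else −min(x) plus the
  smallest observed increment; scale the power of 10 of the shifted
  median. Both are frozen into the stored transform so scoring reproduces
  training preprocessing exactly.
* Tie-breaks: FP candidates in lower-degree-then-lexicographic order with
  first-minimum selection (1e-9 deviance tolerance); forward selection
  breaks p-value ties by alphabetical candidate order. Reruns are
  bit-reproducible.
* Interval boundaries serialize at 17 significant digits (JSON has no
  Inf; open bounds are string-encoded) so scores survive a round trip
  unchanged.

## Open design points and how they were resolved

* **Stage-1 entry threshold**: the strong p < 0.0001 applies to stage 2;
  stage 1 defaults to the conventional 0.05 (configurable) — stage 2
  re-screens every covariate at the strong level anyway.
* **FP selection inside or before forward selection**: the form is chosen
  once per continuous candidate, adjusted for the locked terms, before
  the selection loop. An `"omit"` verdict falls back to the linear form
  and lets the entry test decide, so candidate entry is governed by a
  single level-α test and the null false-inclusion rate stays ≈
  candidates × p_entry.
* **Derivation/validation odd split**: derivation receives the extra
  record.
* **Point-scale anchor at small n**: if the anchor covariate (default
  BMI) is not selected into the final model, the pipeline falls back to
  the model's first continuous term at one point per derivation-cohort
  SD, logged; `build_point_table()` itself keeps its strict contract.
* **Hierarchy for interactions** (only tested and retained alongside both
  main effects) is this implementation's rule.

## Limitations

The score cannot reflect interventions (e.g. prophylactic antibiotics)
that alter risk after the covariates are measured; operation duration is
unknown before surgery, so preoperative use of the score approximates it;
the synthetic world's independence assumptions make it a verification
harness, not a clinical simulator; and the original published coefficient
and point values are not reproduced here because their source tables and
the underlying registry are not publicly available.
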