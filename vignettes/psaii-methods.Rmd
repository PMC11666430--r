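---
title: "Methods: serum-based screening for psoriatic arthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum-based screening for psoriatic arthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screening problem

Psoriatic arthritis (PSA) develops in roughly a fifth of psoriasis (PSO)
patients, usually years after the skin disease, and is frequently missed
because existing questionnaires (PEST, PASE, ToPAS) rely on symptoms and
self-report. Routine blood work offers an objective complement: complete
blood count components and C-reactive protein (CRP) differ systematically
between PSO patients with and without arthritis. `psaiiscreen` implements a
complete screening-development pipeline around that idea: it scores
subjects on a catalogue of composite inflammation indices, develops a new
index from penalized-regression output, benchmarks machine-learning
classifiers, and combines the index with a questionnaire threshold into a
two-branch triage rule.

The centre of the package is the Psoriatic Arthritis Inflammation Index,

$$\mathrm{PSAII} \;=\;
  \frac{\text{lymphocyte \%} \times \text{CRP (mg/dL)}}
       {\text{neutrophil count} \times \text{eosinophil count}
        \times 10},$$

with counts in $10^9$/L. Higher values indicate PSA; the published decision
cutoff is 18. The catalogue also carries SII, NLR, PLR, LMR, NPR, SIM, PAR
and CALLY (`index_catalogue()`); CALLY is the one index oriented so that
*lower* values indicate PSA.

## Synthetic cohorts from published summaries

No subject-level data for the source cohorts is deposited; what is
published is a per-group summary table: mean ± SD for approximately normal
variables, median (Q1, Q3) for skewed ones, and category counts, for a
US survey cohort (574 PSO / 145 PSA) and a Chinese hospital cohort
(98 PSO / 37 PSA). The generator (`generate_study()`, `generate_group()`)
re-creates labeled cohorts whose *marginals* match those printed summaries.
The shipped catalogue (`cohort_summary_specs()`, transcribed row by row into
`inst/extdata/`) records, per variable and group:

* **family** — variables printed as median (Q1, Q3) are treated as skewed
  and modeled on the log scale; variables printed as mean ± SD are modeled
  as normals truncated below at a positivity floor of 0.01 (and above at
  100 for percentages). The printed table reports summaries, not families;
  these are modeling choices, made once.
* **skewed-family parameterization** — the default is a *two-piece
  lognormal*: $X = \exp(\mu + \sigma_{\mathrm{lo}} Z)$ for $Z<0$ and
  $\exp(\mu + \sigma_{\mathrm{hi}} Z)$ for $Z\ge 0$, with
  $\mu=\ln(\text{median})$,
  $\sigma_{\mathrm{lo}} = (\ln \text{median}-\ln Q1)/z_{0.75}$ and
  $\sigma_{\mathrm{hi}} = (\ln Q3-\ln \text{median})/z_{0.75}$,
  $z_{0.75}=0.67449$. This reproduces all three printed quartiles exactly
  and reduces to a single lognormal when $Q1\,Q3=\text{median}^2$. The
  single-lognormal fit with the pooled spread
  $\sigma=(\ln Q3-\ln Q1)/(2 z_{0.75})$ is available as
  `fit_lognormal_from_quartiles()` / `lognormal_method = "symmetric"` and
  is what the headline simulation targets use.
* **printing artifacts** — a few printed rows are degenerate: quartiles
  equal to the median (e.g. monocyte count 0.5 (0.5, 0.7)) or zero
  (basophil count 0 (0, 0.1)). Zeros are floored at 0.01; a quartile
  collapsed onto the median gets half the informative side's log-spread —
  exactly the pooled-formula $\sigma$ evaluated on the one informative
  half. The US-cohort albumin row repeats the white-cell row verbatim in
  the source and contradicts the cross-cohort comparison table
  (albumin ≈ 4.2 g/dL); it is transcribed as printed, flagged with a
  warning, and left for the user to judge.
* **categoricals** — printed count proportions per group; the Chinese race
  row prints counts inconsistent with the group sizes (103/32 vs 98/37),
  so proportions use the group sizes.

Dependence is independence by default; a Gaussian copula with a
user-supplied rank-correlation matrix is available
(`generator_config(dependence = "gaussian-copula")`) because the source
reports a correlation heat map without numbers. Sampling is inverse-CDF
throughout, so truncation is exact and copula and independence paths share
one quantile transform.

**What the generator does not emulate.** Joint structure of the real
cohorts (under independence, variables that co-vary in blood are
uncorrelated here); leukocyte percentages are not constrained to sum
to 100 (the index formulas use them marginally); survey design, medication
effects and diagnostic misclassification are absent. Consequences: tests
passing on synthetic cohorts demonstrate that the *pipeline* recovers
planted structure, not that the published feature set is the unique answer
— on independence cohorts the LASSO legitimately selects more variables
than the published five, because every printed marginal difference (RDW,
basophils, rash extent, ...) is independently informative and no
correlation structure suppresses it. The recovery tests therefore pin the
dominant printed effect (CRP must survive selection in ≥ 18/20 seeded
runs) rather than the exact set.

## Feature selection

`screen_features()` composes three stages, mirroring the published
pipeline: (1) a univariate ROC screen — direction-free AUC
$\max(A, 1-A)$ per variable, flagged above 0.6 — which is *advisory*: it
flags but never excludes, because the published final feature set includes
a variable whose univariate group difference is non-significant; (2)
correlation exclusion — Pearson correlations on the encoded variables;
from every pair with $|r| \ge 0.8$ the lower-AUC member is dropped,
resolving the strongest pair first so the result is invariant to column
order; (3) an L1-penalized logistic regression (glmnet) over a descending
penalty path, penalty chosen by ten-fold cross-validation. The default
penalty rule is the one-standard-error rule; the source plots both dashed
lines without saying which was used, so the rule is configurable and the
recovery tests accept either.

Inputs are min-max normalized, $E(x) = (x-\min)/(\max-\min)$, with
parameters fitted on training rows only (`fit_minmax()` /
`minmax_normalize()`); applied rows may fall outside [0, 1] and a constant
training column maps to 0. The source does not state whether
normalization statistics were refit per fold; refitting per training
partition is the leakage-safe choice and is what `train_eval()` does
internally. Missing cells are imputed by chained random-forest regression
(`impute_missing()`): each incomplete variable is regressed on all others,
cycled until the relative change drops below $10^{-3}$ or 10 cycles, with
subjects missing more than a third of their variables dropped — the
learner is named in the source, the schedule is ours. Imputation is only
informative when variables co-vary; its accuracy test runs on a
copula-correlated cohort.

## Model benchmark

`train_eval()` runs one learner through a balanced five-fold plan
(`make_folds()`; 719 subjects give folds of 144/144/144/144/143):
normalization and the model are refit on each training partition,
hyperparameters are chosen by an inner 3-fold cross-validation (the source
reports tuning but no grids; defaults in `default_grids()` are
config-overridable), and the held-out fold is predicted. Training-partition
metrics are resubstitution on the four training folds — stated explicitly
because it explains why deep forests and boosted trees print near-perfect
training rows while their held-out rows fall back; the overfitting
contract is itself a test. Aggregation is the arithmetic mean of per-fold
metrics; confidence intervals are computed on the pooled predictions
(DeLong for AUC, Wilson for proportions, bootstrap percentile for kappa).
The five learners are logistic regression (`stats::glm`, optionally light
ridge), k-nearest neighbours (`caret::knn3`), random forest
(`randomForest`), gradient boosting (`xgboost`) and a single-hidden-layer
neural network (`nnet`); class imbalance is left unweighted, as in the
source. The logistic fit on the full table supplies coefficients and odds
ratios $\mathrm{OR} = e^\beta$.

`construct_index_from_ors()` encodes the published development rule:
eligible features with OR > 1 enter the numerator, OR < 1 the denominator,
OR = 1 contributes nothing (continuity of the sign rule). Eligibility is
an explicit argument restricted to serum features — the source includes
age in the model but omits it from the index without stating the rule.
Applied to the published odds ratios (lymphocyte % 1.01, CRP 1.77,
neutrophil count 0.96, eosinophil count 0.88) the rule reproduces PSAII
exactly. Note the odds ratios from `train_eval()` are per
min-max-normalized unit, so their magnitudes are range-dependent; only
their position relative to 1 feeds the construction.

## Evaluation conventions

Numerical conventions are fixed so every metric has one deterministic
answer:

* **AUC** (`roc_auc()`) is pairwise concordance with ties counted ½,
  computed by midranks; it is tested against brute-force enumeration and
  against an independent ROC implementation. DeLong intervals use the
  structural-components variance; bootstrap intervals are percentile over
  stratified resamples; both are clipped to [0, 1].
* **Classification against an index cutoff is strict**: positive iff value
  > cutoff (or < cutoff for lower-oriented indices); equality is negative.
* **Cutoff selection** (`select_cutoff()`) scans the distinct observed
  scores, minimizes |sensitivity − specificity|, breaks ties by larger
  Youden index and then by the smaller threshold. Candidates are observed
  values, not midpoints, so results are reproducible from printed data.
* **Decision curves** (`decision_curve()`) classify positive at
  probability ≥ t (probability thresholds are conventionally inclusive,
  unlike index cutoffs; both rules are deliberate and documented) and
  report net benefit $TP/n - (FP/n)\,t/(1-t)$ with treat-all and
  treat-none references.
* **Calibration** uses ten equal-width bins on [0, 1], reporting mean
  predicted probability, observed rate and count per nonempty bin.
* **Adjusted association** (`adjusted_logistic_or()`) is a
  maximum-likelihood logistic fit with Wald intervals; constant covariates
  are dropped with a warning and separation triggers a ridge-penalized
  refit flagged in the result. The dose-response analysis
  (`rcs_logistic()`) uses a restricted cubic spline (natural cubic basis,
  linear beyond the boundary knots) with knots at Harrell's quantiles
  (.05/.35/.65/.95 for the default four), the curve normalized to OR = 1
  at the exposure median, and a likelihood-ratio test against the linear
  fit for nonlinearity.
* **Degenerate inputs** are contracts, not crashes: single-class label
  vectors are errors; all-tied scores select a degenerate cutoff with a
  warning; zero-denominator metrics return `NA` with a warning; chance
  agreement $p_e = 1$ returns kappa 0 with a warning.

## Triage

`assign_risk()` implements the combined PSAII + ToPAS rule: patients are
first split by arthralgia complaint. In the arthralgia branch, PSAII ≥ 18
**or** ToPAS ≥ 7 assigns high risk; in the non-arthralgia branch, low risk
is PSAII < 18 **or** ToPAS < 7, so high risk requires both thresholds —
the exact complement, which is tested as a partition property. The
strategy boundary is inclusive (≥), deliberately different from the strict
rule used when an index is classified against its cutoff alone; both come
from the source and both are encoded. ToPAS itself is out of scope: the
pipeline accepts a precomputed ToPAS column and errors without one. The
end-to-end driver (`run_screening_study()`) simulates a labelled stand-in
for arthralgia and ToPAS (PSA subjects complain more often, prevalences
0.8 vs 0.2, and score higher, means 8 vs 4, SD 2, clamped to 0–12) purely
to exercise the rule; those parameters describe no published measurement.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible
given it; `run_screening_study()` derives all stage seeds from one master
seed and writes byte-identical reports on re-run. The test suite works at
deliberately modest sizes chosen to make each property sharp: exact-oracle
equivalence on instances up to n = 50; generator fidelity at 50,000 draws
per group (3% on centres, 5% on spreads, with an absolute floor of 0.015
where printed values sit at the reporting resolution and skipping
quartiles the printing collapsed onto the median); CRP selection recovery
over 20 seeded studies at the published cohort sizes; interval coverage
over 200 replicates of n = 2000; and headline PSAII AUC simulations at ten
times the published group sizes. The analysis scripts under `analysis/`
run the same pipeline at the published sizes.

## Known limitations

Independence is the default dependence model, so composite indices built
from several correlated blood components have somewhat different variances
than in real cohorts; external-validation rows computed on synthetic
hospital-like cohorts transfer the development cutoff across genuinely
different marginals and should be read as pipeline demonstrations, not
clinical estimates. The albumin inconsistency in the source table
propagates into any albumin-based index (PAR, CALLY) computed on the
survey-like cohort. Unit handling assumes CRP in mg/dL throughout; no
laboratory unit conversion is attempted.
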