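---
title: "Predicting HRQoL from longitudinal symptom change patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting HRQoL from longitudinal symptom change patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(symtraj)
```

## The problem

Adult survivors of childhood cancer accumulate late effects of their disease
and its treatment over decades. Symptom surveys administered repeatedly over
long follow-up carry information not just about current burden but about the
*direction* of change — a symptom that appears and persists means something
different from one that resolves. `symtraj` implements a pipeline that turns a
three-wave binary symptom panel (37 presence/absence items at surveys T1, T2,
T3) into trajectory-coded predictors, selects a sparse linear model for a
continuous health-related quality of life (HRQoL) outcome on the SF-36 scale
(population mean 50, SD 10), quantifies selection uncertainty by bootstrap,
and evaluates out-of-sample discrimination for *suboptimal* HRQoL (score
below 40, one SD below the population mean).

The cohorts this design mirrors are not publicly deposited, so the package
ships a synthetic cohort generator that reproduces the data *structure* and
makes every downstream stage testable end to end.

## Data structures and preprocessing

The 37 items are fixed by a packaged schema (`symptom_items()`) and grouped
into 10 individual domains; depression and anxiety (12 items) form the
psychological global domain, the remaining eight domains (25 items) the
physical one. Ingestion matches on the canonical identifiers, never free
text.

Missing responses (`impute_missing()`) are filled from the preceding wave
when available, otherwise from the nearest following wave; a trajectory
missing at all three waves is set to absent throughout — the predominant
state for every item. The rule is idempotent, and validation
(`validate_inputs()`) warns when missingness exceeds 2% of responses, the
level below which carry-over imputation is unlikely to matter.

## Feature engineering

At each wave, 48 cross-sectional measures are computed
(`build_cross_sectional_measures()`): the 37 item indicators plus 11 count
summaries — the eight multi-item domains, the two global domains, and the
overall count. Memory and gastrointestinal are single-item domains and are
not summarised separately (their items still feed the physical and overall
counts).

Ten longitudinal change patterns are then applied to every measure
(`derive_pattern_features()`), giving 48 × 10 = 480 predictors:

| Code | Pattern | T1 | T2 | T3 |
|------|---------------------------|----|----|----|
| P1 | Early escalation | − | + | |
| P2 | Late escalation | | − | + |
| P3 | Early resolution | + | − | |
| P4 | Late resolution | | + | − |
| P5 | Persistent presence | + | + | + |
| P6 | Early limited persistence | + | + | − |
| P7 | Late limited persistence | − | + | + |
| P8 | Consistent absence | − | − | − |
| P9 | Early limited absence | − | − | + |
| P10 | Late limited absence | + | − | − |

Item-level columns are 0/1. Two coding decisions were genuinely open and are
worth recording:

* **Summary escalation/resolution (P1–P4) are member counts.** A summary's
  P*k* (k ≤ 4) is the number of member items whose own trajectory exhibits
  the pattern. This lies in the documented range (0 to the member count),
  reduces to the item definition for a single-item measure, and satisfies
  exact conservation identities that the test suite uses as anchors:
  count(T2) = count(T1) + P1 − P3 and count(T3) = count(T2) + P2 − P4 for
  every summary and subject. The alternative — a signed wave-to-wave count
  difference — breaks the reduction property and was rejected.
* **Summary persistence/absence (P5–P10) use the any-symptom indicator**
  (count > 0) at each wave. A consequence worth knowing: a summary can code
  persistent presence without any single member item persisting (different
  members present at different waves). This is a property of the definition,
  not an artifact, and is left as-is.

Note the item-level exclusions P1·P3 = 0 and P2·P4 = 0 do *not* extend to
summaries: one member may escalate while another resolves.

The design matrix (`assemble_design_matrix()`) has two modes: `non_symptom`
(35 columns: 5 continuous ages/intervals in years, sex, race and education
indicators; 8 mutually exclusive diagnosis indicators with no reference
category dropped; 19 treatment indicators) and `symptom_enhanced`
(35 + 480 = 515 columns).

## The selection engine

`bien_fit()` selects and estimates a sparse Gaussian linear model in five
components:

1. **Candidate generation.** The elastic net at mixing α and penalty λ
   proposes the set of predictors with nonzero coefficients
   (`generate_candidate_set()`, solved by glmnet). Columns are standardized
   internally for penalization only.
2. **Estimation.** Each candidate subset is refit by ordinary least squares —
   the Gaussian MLE — on the original predictor scale (`refit_mle()`), with
   error variance RSS/n.
3. **Scoring.** BIC = −2·loglik + k·log(n), with k counting the intercept,
   the slopes, and the error variance (`score_bic()`). Counting the variance
   shifts every model's BIC by the same log(n) and cannot change a
   comparison; it is fixed here so reported values are reproducible.
4. **Search.** For each α in {0.1, 0.3, 0.5, 0.7, 0.9, 1.0}, a path of 100
   log-spaced λ values from λ_max (the smallest penalty selecting nothing)
   down to 10⁻⁴·λ_max is walked from strong to weak penalty
   (`truncated_grid_search()`). A path is abandoned after `patience = 5`
   consecutive *new* candidate sets fail to improve the path's best BIC.
   Two details matter: consecutive λ values that yield the *same* subset are
   one step, not several (otherwise flat path segments near λ_max exhaust
   the patience budget before any model grows); and the path is solved
   lazily in chunks, so abandoning it also skips the expensive dense tail.
   The intercept-only model is always a candidate, so the final BIC never
   exceeds it. Ties break toward the smaller subset, then the larger λ, then
   lexicographic column order.
5. **Pruning.** Backward elimination (`prune()`): refit, drop the predictor
   with the largest two-sided refit p-value while it exceeds 0.05 (one per
   iteration), refit again. "Contributes significantly" is not otherwise
   pinned down; 0.05 is the conventional default and is configurable.

Zero-variance and duplicate columns are set aside before fitting and
recorded in the result; collinear near-duplicates (an item's P8 versus its
domain summary's P8) are deliberately left to the penalty.

With `patience = Inf` the search provably equals exhaustive evaluation of
the grid, and on small designs (p = 8) its BIC tracks the all-subsets
optimum within log(n) — both are tested. A known behavior of any
minimum-BIC search over ~500 correlated candidates is a winner's curse: a
few proxy or noise columns whose in-sample deviance gain exceeds log(n) can
enter the selected model, and a weak true effect nested inside correlated
summaries can be substituted by its proxy. The support-recovery measurements
in the test suite and acceptance script quantify this under the documented
presets; users should read selected supports as parsimonious predictive
models, not as causal identifications.

## Post-selection inference

`bootstrap_bien()` resamples subjects with replacement and reruns the
*entire* procedure — grid search included — in each replicate (a `frozen`
mode that reuses the winning (α, λ) is available for speed). For each
predictor of the original final model, the replicate coefficient is recorded
as zero whenever the predictor is not reselected; selection probability is
the fraction of replicates selecting it.

Empirical 95% intervals use symmetric order statistics: lower = x₍ₖ₎,
upper = x₍B+1−k₎ with k = ⌈0.025·B⌉. With this construction the following is
a theorem, not a tendency: *if a predictor is selected in at most 97.5% of
replicates and all its nonzero draws share one sign, exactly one interval
endpoint equals 0* (the zero mass occupies the relevant tail). Interpolated
quantile definitions break the exactness of this statement at the boundary,
which is why they are not used. This reproduces, as a structural property,
the reported behavior of zero-filled bootstrap intervals in survivor-cohort
analyses. The premise matters: in heavily collinear symptom designs at
moderate n, resampled coefficients do occasionally flip sign, and the law is
then silent for that predictor.

Per-replicate seeds are derived deterministically from the master seed
(`spawn_seeds()`), so results are independent of execution order and stable
when B grows.

## Performance evaluation

`dichotomize()` labels scores strictly below 40 as suboptimal.
`cross_validated_auc()` partitions subjects into K = 10 random blocks whose
sizes differ by at most one (unstratified by default, matching the design it
mirrors; a stratified option exists), rebuilds the complete selection
procedure on each training set, and predicts continuous HRQoL on the
held-out block — no selection step, standardization statistic, or
hyperparameter choice ever sees held-out subjects, which a dedicated
leakage test enforces by corrupting held-out outcomes. The risk score is
the negative predicted HRQoL; AUC uses midranks (ties count one half),
identical to the normalized Mann–Whitney U statistic.

The headline number is the *pooled* out-of-fold AUC, with the per-fold
min–max range reported alongside; whether a single published AUC is pooled
or fold-averaged is ambiguous in general, so both are emitted and pooled is
primary (fold AUCs on ~n/10 subjects are noisy and single-class folds have
none). `compare_models()` enforces shared folds before differencing.

## The synthetic cohort generator

The generator is the package's stand-in for restricted cohort data, and its
defaults are the study conditions of the test suite.

Each item follows an independent two-state first-order Markov chain:
initial prevalence π, persistence ρ = P(present | previously present), onset
ω = P(present | previously absent). This is the simplest mechanism that
produces all eight full trajectories with tunable prevalence. Defaults
(`default_item_params()`): π = 0.22 for sensory/pain/anxiety items, 0.17
for depression/memory, 0.10 for the rest; ρ = 0.55, ω = 0.05 for all. These
put item-level consistent absence in the 0.67–0.81 range (inside the
reported 42–98% span), keep persistent presence at π·ρ² ≤ 6.7% (matching
the reported ≤ 6.8%), and make later escalation slightly more frequent than
early escalation — the qualitative orderings seen in survivor cohorts.
Waves are treated as exchangeable discrete times: the surveys the design
mirrors were separated by irregular calendar gaps, but nothing in the
feature coding uses gap lengths, so modulating transitions by gap was left
out.

Covariates are simulated independently of symptoms (so in null
configurations the symptom-enhanced model has nothing extra to find), with
ages and intervals matched to cohort-reported medians/IQRs, diagnoses as a
mutually exclusive multinomial, and treatments as independent Bernoulli
draws at cohort-typical prevalences. Outcomes are
y = 50 + Xβ + ε with ε ~ N(0, σ²) over a known sparse support of
(measure, pattern) columns and/or covariates.

Three documented presets (`cohort_preset()`): `null` (no effects, σ = 10);
`pattern_driven` (three item-level consistent-absence effects +4 to +5, a
depression-summary persistent-presence effect −5, a pain-summary late
escalation effect −3.5 per newly escalated item; σ = 8) — effect signs
follow the clinical hypothesis that absence predicts better and
persistence/escalation worse HRQoL; `covariate_driven` (female sex −3.2,
college education +3.6, age at T3 −0.33/year, abdominal radiation −2.8;
σ = 8).

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: within-subject correlation across items (an
optional shared frailty is deliberately off by default for analytic
tractability), informative dropout or missingness (masking is MCAR),
calendar-time effects, and the real cohorts' joint symptom correlation
structure. Markov marginals give the generator closed-form wave prevalences,
which the tests use as oracles.

## Problem sizes and numerical choices

The test suite exercises the coding laws on 1,000 simulated subjects,
support recovery on 50 replicates of n = 600 with all 515 predictors,
bootstrap behavior at B = 200 on n = 300, and cross-validated comparisons at
n = 600 — sizes chosen to match the cohort scale the design mirrors
(n = 576) while keeping a full run comfortably on one CPU. Other fixed
choices: glmnet convergence threshold 10⁻⁹; BIC comparisons use an absolute
tolerance of 10⁻⁹ before tie-breaking; candidate subsets whose OLS refit is
rank-deficient or larger than n − 2 are discarded with a logged reason
rather than crashing the search; AUC is refused (with a clear message) when
either outcome class is absent.

## Limitations

Beyond the generator's simplifications listed above: the engine's
minimum-BIC search is greedy along elastic net paths, so it inherits both
the winner's curse of model selection over many candidates and the path's
ordering of correlated predictors; post-selection p-values used for pruning
are not selection-adjusted (no selective-inference correction is attempted —
the bootstrap is the package's uncertainty statement); and the bootstrap's
zero-filled intervals are percentile-type, without bias correction or
acceleration, matching the plain empirical-CI description they implement.
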