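---
title: "Methods: GA-driven selection of neuropsychological test subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-driven selection of neuropsychological test subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gacog` selects subsets of a 37-measure neuropsychological and mood test
battery that predict 36-month conversion to MCI/AD (from healthy
cognition) or to AD (from MCI). This vignette documents the model, the
search, the synthetic-cohort generator, and the numerical and design
choices a maintainer should know about.

## The risk model

Conversion is a binary outcome `y` modelled by unpenalised logistic
regression on the selected measures: `E(y) = e^t/(1+e^t)` with
`t = b0 + b1 x1 + ... + bk xk`. The model is fitted by maximum likelihood
(IRLS). Discrimination is measured by AUC, computed as the Mann–Whitney
statistic — the probability a random converter outscores a random
non-converter, ties counting half. `compute_roc()` builds the full
`(1−SP, SE)` curve; collapsing tied scores into single steps makes its
trapezoidal integral equal the Mann–Whitney value exactly, which the
tests assert to 1e-12.

## Subset search

A feature subset is a 37-bit genome. Fitness is

```
fitness = AUC_cv + rho - rho * l / n
```

with `l` the subset size, `n = 37`, and `rho = 0.085` by default: at equal
AUC, each feature dropped buys `rho/37 ≈ 0.0023` fitness, so `rho` sets
how much cross-validated AUC the search will trade for a one-feature
smaller battery. `AUC_cv` is the repeated (5x) balanced stratified
five-fold CV estimate described below.

Default search parameters (all in `ga_config()`): population 50, 300
generations, tournament size 2, two-point crossover rate 0.90, single-bit
mutation rate 0.10, elitism. Batch analyses (`multi_run()`) run the GA 50
times by default with seeds derived from a master seed and summarise
per-feature selection frequencies.

Operator policy. The operator rates 0.90 and 0.10 sum to one, and the
pair-level procedure reads as exclusive: each selected parent pair
undergoes *either* crossover *or* copy-plus-mutation. That is the default
(`operators = "exclusive"`, drawing one uniform variate per pair; if the
rates summed to less than one the remainder would be plain copies, so
setting both rates to zero yields pure copying and a constant best
fitness, which a test asserts). The common alternative —
crossover-then-independent-mutation — is available as
`operators = "independent"` for sensitivity checks.

Crossover cut points are two *distinct* integers drawn uniformly from the
36 inter-bit boundaries; the inner segment is exchanged. Swapping the two
outer segments instead produces the same unordered pair of children, an
equivalence the tests assert, so the choice between the two conventions
is immaterial.

Degenerate genomes. The all-zero genome is scored as the intercept-only
model (AUC 0.5, hence fitness `0.5 + rho`) rather than an error, keeping
the search space closed under mutation.

Fitness caching and CV seeds. Within one run the CV fold draws are fixed
by a per-run seed, so a genome's fitness is a pure function of its bits
and can be memoised (the cache is exact, not approximate). Across runs
the CV seed differs, so the same subset may legitimately score slightly
differently in different runs. How the original workflow seeded its folds
is unknowable from the outside; the per-run policy is this package's
choice, made for cacheability and within-run stability.

No early stopping is used by default: runs execute their full generation
budget (`target_fitness` exists but is `NULL`).

## Cross-validation schemes

*Fitness-facing:* balanced stratified five-fold CV, repeated five times.
Each class is independently shuffled and split into five folds of exactly
equal size, enforced by dropping the remainder — at most one row per fold
per class (with 31/604 and k = 5: folds of 6 and 120, with 1 and 4 rows
dropped). The five held-out AUCs are averaged per repeat, and the five
repeat means averaged again. Dropped rows are re-randomised every repeat,
so no observation is systematically excluded. The fitness-facing value
equals the mean of all 25 fold AUCs since fold counts are equal.

*Reporting-facing:* Monte-Carlo CV — 1,000 random 80/20 train/validation
splits with the held-out AUC averaged. Splits are stratified within class
(80% of each class trains); plain unstratified splitting would
occasionally put zero or one converter in the validation set at 31/604,
making the AUC undefined. Whether the original analysis stratified its
Monte-Carlo splits is unstated; stratification is this package's choice
and is noted here rather than hidden.

## Logistic fitting: numerical choices

- IRLS on the weighted least-squares normal equations via C-level QR
  (`.lm.fit`), capped at 50 iterations, declared converged when the
  relative deviance change drops below 1e-8. Agreement with `glm()` to
  ~1e-6 in coefficients and standard errors is asserted in tests.
- Quasi-complete separation — likely when 31 converters meet a strong
  predictor — is *flagged* (any |beta| > 15), never fatal: the diverged
  fit still orders the held-out cases, and AUC depends only on that
  order. Halting on separation would bias the search against exactly the
  strong subsets it is supposed to find.
- No regularisation by default, keeping coefficient signs and magnitudes
  comparable to an unpenalised GLM. Only when the weighted Hessian is
  numerically singular is a tiny ridge (1e-6) applied so standard errors
  remain defined.
- Rank-deficient designs: user-facing fits raise an error naming the
  aliased columns; inside CV loops pivoted-out columns are pinned at zero
  so a fold with, say, a constant binary column still scores.
- Wald p-values are two-sided normal: `2(1 − Phi(|b/se|))`.

## The synthetic cohort generator

No participant-level data are deposited, so every analysis here runs on
simulated cohorts built to the published summary structure:

- **Class means.** Per-measure means for seven groups (HC/MCI/AD and the
  converter/non-converter subgroups of both tasks) are packaged verbatim;
  the two task profiles drive the simulator.
- **Scales.** Group SDs are not published. Convention: SD 1 for z-scored
  measures; for raw-scale measures, half the HC-to-AD mean gap, floored
  at 0.5. This makes between-group separations plausible (e.g. the HC
  task's converter gap on Logical Memory II is ~0.9 SD, putting its
  single-measure AUC near the published 0.80) without external data.
  Which measures are raw is itself partly a judgement call: the published
  battery marks some raw measures, but the group-mean magnitudes are the
  more reliable guide, and measures whose means are clearly not z-scores
  (v1–v3, v5, v16–v19, v22–v25, v33–v37) are treated as raw here.
- **Correlation.** Default: same-instrument block correlation, r = 0.5
  within an instrument and 0.2 across instruments — subtests of one
  instrument correlate more than scores from different instruments. An
  exchangeable model is available. Positive definiteness is checked at
  configuration time.
- **The binary measure.** Logical Memory Pass/Fail (v4) is Bernoulli with
  p equal to the class mean clipped to [0, 1], drawn independently of the
  Gaussian block (its published group means live in [0, 1] and it is the
  one measure tested by chi-square in group summaries).
- **Provenance.** The excluded baseline participants (for the HC task:
  148 unavailable at 36 months, 13 deceased, 1 other dementia, summing
  with 31 + 604 to the 797 baseline cohort) are carried as metadata only
  and never materialised as rows — the analysis set is what the model
  sees.
- **Planted signal.** `plant_signal()` makes the two class profiles
  identical except on a chosen subset, where they differ by `delta` SD
  units. This is the ground truth for end-to-end validation: with
  delta = 1.2 on {v3, v5, v18} at 31/604, the trio's population AUC is
  ~0.89 — the scale of the published models.

What the generator does **not** emulate: longitudinal trajectories,
diagnosis adjudication, missingness, floor/ceiling effects, non-Gaussian
score distributions, and the real battery's unknown covariance. Passing
tests therefore demonstrate that the *pipeline* is correct and that the
search recovers known structure under realistic sizes and correlation —
not that the published AUC values are reproduced; those depend on the
inaccessible records and are out of scope.

A note on correlated designs: under block correlation, measures sharing
an instrument with a planted feature carry no marginal signal but improve
the model conditionally (they explain noise variance in their planted
neighbour). The GA therefore legitimately selects supersets of the
planted trio; recovery is asserted as "every planted feature appears in
≥80% of runs", not as exact-set recovery.

## Baselines and reports

- **Random baseline:** 100 uniformly drawn subsets per GA-matched size,
  scored by the same repeated CV. Significance is reported both as a
  paired t-test across size-matched means (the pairing the study design
  implies) and a pooled two-sample t-test, since the exact pairing is
  underdetermined; both are emitted rather than choosing silently.
- **Stepwise baseline:** greedy backward elimination minimising AIC
  (`AIC = 2(k+1) − 2 logLik`, asserted per step). The AIC stopping point
  is recorded, but elimination continues to one feature so a snapshot of
  *every* size exists — a single stopping set cannot be compared
  size-by-size against GA subsets of sizes 3–11. The stopping set is
  cross-checked against `MASS::stepAIC` in tests.
- **Final models:** full-data refits with Wald z-tests and a rendered
  equation. P-values are reported unadjusted, matching the study-style
  tables; a Bonferroni column is emitted alongside for transparency
  rather than applied.
- **Group summaries:** per-group means with converter vs non-converter
  Welch t-tests (continuous) or chi-square (binary), dispatched by the
  battery's value kinds.

## Problem sizes used in the packaged analyses

The shipped analyses and checks run at sizes chosen to keep a full cycle
in the minutes range on a single core while leaving the conclusions
unambiguous: GA batches of 5–10 runs at 30 generations (population 50)
on the planted 31/604 cohort — enough for the search to settle there, as
the flat tail of the fitness trajectories shows; 100 random subsets per
size; 1,000-replicate null simulations for test calibration; moment
checks at 10,000 rows per class. Study-scale runs (300 generations, 50
runs) use the same code paths with larger arguments.

## Known limitations

- Fitness evaluation dominates runtime (25 logistic fits per uncached
  genome); very large cohorts would want a compiled inner loop.
- The generator's Gaussian copula understates tail dependence real
  batteries may show.
- `rho` is exposed but not auto-tuned; how its published value was chosen
  is not documented, so no tuning procedure is reimplemented.
- Backward elimination pre-drops aliased columns; it does not handle
  dynamic rank changes mid-path (none arise at the packaged sizes).
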