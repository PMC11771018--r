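---
title: "Methods behind penlm: penalized landmark supermodels and summary evaluation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind penlm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model the package implements, the
estimation and numerical choices behind it, what the simulation experiments
do and do not demonstrate, and the places where the design was genuinely
open and a choice had to be made.

## 1. The landmark supermodel

Dynamic prediction asks, at a prediction-origin time ("landmark") `s`, for
the probability of an event of interest in `(s, s + w]` given that the
subject is event-free at `s` and given the covariate values known at `s`.
Landmarking answers this by conditioning directly: at each landmark only
subjects still at risk enter, covariates are frozen at their most recent
value (LOCF, boundary inclusive: a measurement exactly at `s` is used at
`s`), and follow-up is administratively censored at `s + w` so each
landmark dataset sees only its own prediction window. A subject whose event
time equals the landmark exactly is *not* at risk there: prediction from
`s` presupposes being event-free at `s`.

Rather than fitting disjoint models per landmark, the supermodel stacks all
landmark datasets and fits one Cox-type model per cause in which both the
covariate effects and the baseline level vary smoothly with landmark time:

- covariate effects `β_j(s) = Σ_m b_{jm} f_m(s)` over a basis that must
  contain the constant (default `{1, s}`: main plus linear time-dependent
  effect);
- a landmark main effect `α_j(s) = Σ_q a_{jq} g_q(s − s_0)` (default
  `{u, u²}` in `u = s − s_0`). Anchoring at the first landmark makes
  `α_j(s_0) = 0`, so the Breslow baseline absorbs the overall level and the
  decomposition is identifiable for any grid, not only grids starting at 0.

The stacked fit maximizes the penalized log pseudo-partial likelihood.
"Pseudo" because the same subject contributes a row at every landmark where
it is at risk; the rows are dependent, which is why all inference in this
package is done on held-out test data via influence functions rather than
from the fit itself (the package deliberately reports no standard errors
for coefficients — with penalization these would be misleading anyway).

Two structural choices deserve note:

- **Pooled risk sets.** A stacked row is the left-truncated interval
  `(entry, exit] = (s, min(T, s+w)]`. The risk set of an event at time `t`
  contains every stacked row with `entry < t ≤ exit`, from *any* landmark
  dataset. This matches the double-sum denominator of the stacked
  pseudo-likelihood; it is implemented with counting-process interval
  lookups, not per-landmark stratification.
- **Breslow ties.** Consistent with the pooled-risk-set likelihood; the
  Breslow baseline increment at an event time is the event count divided by
  the risk-set sum of `exp(lp)`.

## 2. Penalized fitting

The penalty is elastic net, `λ (mixing ‖·‖₁ + (1 − mixing)/2 ‖·‖₂²)`, with
per-column penalty factors. Both covariate-effect columns and the `α`
columns are penalized by default (set the `α` factors to 0 to exempt the
landmark main effect). Because penalties are scale-sensitive, columns are
standardized to unit variance over the stacked rows before fitting and
coefficients are reported back on the original scale; centering is
irrelevant to a partial likelihood, and predictions at `λ = 0` are exactly
invariant to affine covariate rescaling (tested).

Optimization is iteratively reweighted least squares with a diagonal
curvature approximation; the inner penalized weighted least-squares problem
is solved by cyclic coordinate descent with soft-thresholding when an L1
component is present and in closed form otherwise. Each outer step is
accepted only if the exact penalized objective decreases (with step
halving), so the objective is monotone across sweeps. Convergence is
declared when the maximum relative coefficient change falls below `tol`
(default 1e-7, cap 10 000 sweeps); diverging coefficients (separation at
`λ = 0`) raise an error suggesting a positive penalty. `λ_max` — the
smallest penalty zeroing every penalized coefficient — is computed from the
score at zero on the standardized design, and the default cross-validation
grid is 100 log-spaced points spanning four decades below it.
`cv_lambda()` forms folds on *subject id* (all landmark rows of a subject
share a fold, otherwise the pseudo-replication leaks across folds) and
scores the Verweij–van Houwelingen cross-validated deviance; ties prefer
the larger, i.e. more parsimonious, `λ`.

## 3. Predicted cumulative incidence

With the per-cause linear predictor frozen at its landmark-`s` value over
the whole window (the landmarking convention), predicted cause-`j`
cumulative incidence accumulates baseline jumps inside `(s, s + w]` using
the discrete product-limit (Aalen–Johansen) form: at each pooled event time
the event-free survival is multiplied by `1 − Σ_j exp(lp_j) dH_j`, and each
cause's incidence gains `S(t⁻) exp(lp_j) dH_j(t)`. This form was chosen
over the exponential convention `S(t) = exp(−Σ exp(lp_j) H_j(t))` because
it telescopes exactly: `Σ_j F_j + S = 1` to machine precision, which the
exponential form satisfies only to `O(ΔH²)`. The two agree to
discretization error (e.g. a total window hazard of 0.1 gives risk
`≈ 1 − e^{−0.1}`).

When one cause is predicted for many subjects sharing a baseline, the risk
is a smooth monotone function of the linear predictor alone; for more than
200 subjects it is evaluated on a 512-point grid over the observed lp range
and linearly interpolated. The interpolation error is orders of magnitude
below Monte-Carlo noise, and subject *ranking* — all that discrimination
metrics use — is preserved exactly. Predicting beyond the last observed
event time warns and computes the risk on the available support.

## 4. IPCW metrics and the multivariate influence decomposition

At landmark `s` with horizon `τ = s + w`, among subjects at risk at `s`:

- **cases** are cause-1 events in `(s, τ]`; **controls** are subjects
  event-free at `τ` plus (by default, configurable) competing-cause events
  in the window — the "cumulative/dynamic" convention appropriate to a
  cause-specific risk;
- weights are `1/Ĝ(T⁻|s)` for observed events and `1/Ĝ(τ|s)` for
  survivors, with `Ĝ(·|s) = Ĝ(·)/Ĝ(s)` the conditional Kaplan–Meier
  estimator of the censoring distribution (marginal, not
  covariate-adjusted: the metrics are valid under independent censoring,
  and that assumption is stated, not tested);
- the AUC counts weighted case–control pairs with ties in predicted risk
  counting one half; the Brier score is the weighted mean squared
  difference between the cause-1 indicator and the predicted risk.

Each estimator's first-order influence function is computed per subject.
It has two parts: the centered weighted summand (for the AUC, the Hájek
projection of the two-sample U-statistic combined with the delta method for
its ratio normalization), plus the martingale term that accounts for
*estimating* `Ĝ` — for a weight evaluating `Ĝ` at `u`, the term integrates
`dM^c(v)/π(v)` over `(s, u]` against the summand's mass. Omitting that term
would misstate the variance whenever censoring is present. All weighted
sums are assembled with sorted cumulative sums in `O(n log n)`.

Landmark populations shrink over `s`, yet the cross-landmark covariance
needs one common empirical measure. Subjects not at risk at `s` therefore
carry influence value 0, and at-risk subjects' conditional influence values
are rescaled by `n/n_s` — exactly the influence function of the ratio
estimator that conditions on being at risk. Per landmark the influence
values average to zero by construction (tested to 1e-10), and with a single
landmark the machinery reduces to the standard single-time IPCW confidence
interval.

The summary metric is the unweighted landmark average `θ̄_w`; its variance
is `1'Σ̂1/|S|²` with `Σ̂[s,s'] = cov(φ(s), φ(s'))/n`, giving a Wald CI
truncated to `[0,1]` (no transformation; a logit-scale CI is a reasonable
alternative not implemented). Comparing two models evaluated on the *same*
test subjects uses the per-subject averaged influence differences, so the
strong positive correlation between the two models' estimates is retained
in the SE; swapping arguments negates the statistic and `SE = 0` with
`Δ = 0` reports `p = 1`. Landmark-wise differences with
Bonferroni/Benjamini–Hochberg adjustment (via `stats::p.adjust`) are
returned alongside as the traditional comparator.

## 5. The cohort simulator

`sim_scenario()`/`simulate_cohort()` generate the experiment conditions:

- three fixed covariates (`Z1, Z2 ~ N(0,1)`, `Z3 ~ Bernoulli(1/2)`) and one
  longitudinal covariate updated at `k` equally spaced landmarks
  `s_m = m·lmi`: `X(s_m) = X(0) + ρ s_m + e_m`, `X(0) ~ N(0,1)`,
  `e_m ~ N(0, 0.25)`;
- a piecewise-constant hazard with landmark form,
  `h(t) = h₀ exp((β + β_t s_m)'(Z, X(s_m)))` on `(s_m, s_{m+1}]`
  (persisting beyond the last landmark), inverted exactly per subject;
- defaults `β = (0.5, −0.5, 0.3, 0.7)`, `β_t = (0, 0, 0, −0.05)`,
  `h₀ = 0.05`, `ρ = 0.2`, `w = 5` — chosen once to give non-degenerate
  event fractions across all censoring settings, with the two
  standard-normal covariates given effects of equal magnitude and opposite
  sign (that symmetry is load-bearing for the type-I design below);
- independent exponential censoring whose rate is calibrated by
  root-finding on a pre-drawn sample of 100 000 event times so the censored
  fraction hits the target (0–50%). The generator applies no
  administrative cap: with these event-time distributions a cap at
  `s_L + w` would by itself censor more than the smaller targets, making
  them unattainable; administrative censoring at `s + w` is applied where
  the method needs it, inside the landmark stacking. Calibration is exact
  for the pre-drawn sample and cached per scenario; a 10 000-subject draw
  lands within ±0.02 of the target (tested).

What the generator emulates: longitudinal updating, landmark-form
time-dependent effects, heavy administrative-plus-random censoring. What it
does not: competing-risks scenarios (the validation experiments are
single-cause; competing risks are exercised by construction-based tests),
covariate-dependent or dependent censoring, measurement error, irregular
visit schedules, and high-dimensional noise covariates. Passing
experiments therefore demonstrate the inferential machinery under an
idealized longitudinal design, not robustness to those violations.

A deliberate feature: the true hazard keeps updating `X` inside the
prediction window while the supermodel freezes `X(s)`, so the fitted
longitudinal coefficient is attenuated (~14% at the defaults) even at
`n = 10⁴`. The fixed-covariate effects are recovered within a few percent.
This is the inherent landmarking approximation, not an estimation defect,
and the parameter-recovery test encodes it (10% band for fixed effects,
20% for the longitudinal one).

## 6. The validation experiments

**Coverage.** For each scenario (grid: `n ∈ {500, 750, 1500}`,
`lmi ∈ {2, 4, 6}`, censoring `∈ {0, 15, 30, 50}%`), each replicate draws
independent training and test cohorts, fits the supermodel (`λ = 0`; the
validation concerns the metrics, and four covariates need no shrinkage) on
the stacked training data, forms 95% CIs for the summary AUC and Brier
score on the test cohort, and scores whether each CI contains *that fitted
model's* population value — a Monte-Carlo oracle computed on an uncensored
cohort of 100 000 subjects (fixed per scenario and reused across
replicates; its Monte-Carlo error is an order of magnitude below the CI
widths, and doubling it moves the oracle by less than twice its SE,
tested). The acceptance script runs 100 replicates per scenario (the
reference design uses 500); the in-suite smoke version runs two scenarios
spanning the grid corners at 200 replicates. Mean coverage lands near 95%
for the summary AUC and slightly below for the Brier score, matching the
reference behavior.

**Type I error.** The comparison test needs two *equivalent* models — equal
population performance — fitted to training data and compared on a shared
test cohort (`n = 3000`). Fitting the *same* specification to two
independent training draws does not work: the two fits nearly coincide, the
test SE shrinks linearly in the model difference while the random gap in
the fits' population performance shrinks only quadratically, and the size
distortion is O(1) (measured ~0.13 at the 0.05 level). The package instead
exploits the generator's built-in symmetry: a model using `(Z1, Z3, X)` and
one using `(Z2, Z3, X)` have *exactly* equal population metric curves
because `(Z1, −Z2)` is exchangeable, giving an exact null with one shared
training draw. Measured rejection rates sit inside the binomial band at
the 0.01/0.05/0.10 levels. The driver warns if the scenario's `β₁, β₂`
magnitudes are changed so the symmetry no longer holds.

**Power.** The full model is compared against one omitting the
longitudinal covariate; per replicate the summary test's p-value competes
with the any-rejection family of `k` landmark-wise tests under Bonferroni
and BH adjustment. Under this generator the performance gap is
concentrated at the earliest landmarks (the `X` effect is `0.7 − 0.05 s`
and innovation noise accumulates), and power at the default effect sizes
is near saturation. Two consequences, both visible in the results and left
as honest findings: the summary test dominates the adjusted families at
`k = 3` and across the sample-size grid (often with ties at power 1), but
at `k = 7` the equal-weight average dilutes a signal that lives at `s = 0`
and the max-type family wins that cell — the classic average-vs-max
contrast under sparse alternatives. The family procedure is also
anticonservative there (null rejection 0.073 at the 0.05 level, against
0.047 for the summary test), so part of its apparent advantage is
miscalibration of late-landmark tests on small risk sets.

## 7. Problem sizes, determinism, degenerate inputs

All experiment drivers take a `reps` override and scenario-indexed seeds
derived from one integer; every generator call restores the caller's RNG
stream. The test suite uses 200 replicates for the coverage smoke check and
size check, 100 per scenario for the power grid, and `n = 10⁴`–`10⁵` draws
for distributional properties; the acceptance script uses the full
36-scenario grid at 100 replicates with 100 000-subject oracles.

Degenerate inputs are errors, not silent results: landmarks with no
cases or no controls, censoring survival hitting zero at a needed
evaluation point, causes without events, non-finite basis values,
covariates missing after LOCF. Zero-variance design columns (e.g. `α`
columns under a single landmark) are dropped from optimization with zero
coefficients — a constant column cancels from every partial-likelihood
ratio, so this is exact, and it is what makes the single-landmark
supermodel collapse to a plain Cox model.

## 8. Limitations

Inference assumes independent censoring and an independent test sample;
under dependence of either kind the coverage statements do not transfer.
Coefficients carry no standard errors. The summary metric weights
landmarks equally, which is interpretable but inefficient when risk sets
shrink sharply or the signal is landmark-concentrated (Section 6). The
simulator is single-cause; competing-risks prediction is exercised by
exact structural tests (conservation, cause-relabeling, exchangeable-cause
symmetry) rather than by a full simulation study.
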