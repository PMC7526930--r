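---
title: "Modelling and optimizing Agrobacterium-mediated chrysanthemum transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing Agrobacterium-mediated chrysanthemum transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrysfoa)
```

## The problem

Agrobacterium-mediated transformation of chrysanthemum depends on many
protocol factors at once: the bacterial strain, the optical density (OD) of
the inoculum, the co-culture period (CCP, days), four selection antibiotics
(kanamycin, hygromycin, paromomycin, geneticin, mg/L) and four
counter-selection antibiotics (vancomycin, cefotaxime, carbenicillin,
ticarcillin, µg/mL). Individual wet-lab studies vary only one or two of
these at a time. `chrysfoa` treats the accumulated literature — 49
GUS-reporter studies transcribed into a packaged CSV — as a single tabular
dataset, learns a response surface for transformation efficiency (%), and
then interrogates that surface twice: a fruit-fly optimization algorithm
(FOA) searches for the most promising 11-factor protocol, and a
variable-sensitivity analysis ranks which factors matter most.

## From literature table to model matrix

Literature cells are messy: efficiencies and doses are often reported as
ranges ("4.3–13.4"), several studies list more than one strain, and absent
antibiotics are printed as "-". The resolution policy is explicit and
configurable:

* **Ranges** collapse to their arithmetic midpoint by default (`"min"` and
  `"max"` policies are available). A midpoint is the least biased
  single-value summary when nothing is known about the distribution within
  the interval.
* **Multi-strain rows** expand to one row per strain with every other field
  duplicated, so strain remains a single categorical input and the
  association between the remaining factors and the outcome is preserved.
* **Absent doses** become 0 — not applying a compound is a zero dose, not a
  missing measurement. One study reports no co-culture period; the same
  zero rule is applied there rather than inventing an imputation.
* **OD wavelength** (540–660 nm) is validation metadata, not a feature: OD
  enters as a single magnitude, matching the convention of treating
  "optical density" as one variable.

Strains are integer-coded in order of first appearance (a single column, so
the sensitivity analysis can rank "strain" as one variable), and all eleven
features are min–max scaled to [0, 1] with the scaling stored for reuse.
Targets stay on the raw 0–100% scale so every error metric reads directly
in percentage points. Rows are split 70/20/10 into training/testing/
validation by seeded uniform sampling with largest-remainder rounding
(ties favour training, then testing).

## The three member models

All three regressors are implemented in the package and trained on the
scaled features; each is fully deterministic given its config seed.

**Multi-layer perceptron** — one hidden layer of 10 sigmoid units and a
linear output; mini-batch gradient descent (batch 16) on squared error at
learning rate 0.01 for 500 epochs. Two details matter: output weights start
at zero with the output bias at the target mean, so the net begins from the
best constant predictor; and updates carry classical momentum (0.9),
because plain first-order steps at this step size are an order of magnitude
too slow to converge within the epoch budget.

**RBF network** — 15 Gaussian bases centred by seeded k-means, a shared
width, and ridge-regularized (1e-6) linear output weights solved in closed
form. The width default is the mean nearest-center distance. The classical
rule σ = d_max/√(2c) is also available but is a trap in 11 dimensions:
k-means centres there are mutually far apart, the rule shrinks σ until
every activation is ~e⁻³ or smaller, and the solve compensates with
weights in the hundreds whose tails produce physically impossible
predictions (efficiencies of 150%+) away from the data. The
nearest-neighbour rule keeps activations O(1) at any dimension.

**ANFIS** — a first-order Takagi–Sugeno system. A grid partition over 11
inputs would need 2¹¹ rules at minimum, so the rule base is one rule per
fuzzy cluster (4 k-means clusters by default), each with Gaussian
memberships (product t-norm) and a linear consequent. Training is hybrid:
consequents by ridge least squares with premises fixed, premises by one
gradient step per epoch, alternating for 100 epochs. A premise step that
would raise the training loss is rejected and the step size halved, making
the recorded loss trace non-increasing by construction. Firing strengths
are computed in log space and renormalized after subtracting the row
maximum, so a sample far from every cluster can never divide by zero. The
consequent ridge defaults to 0.1: with 4 rules × 12 linear parameters
against training sets of ~50 rows, a near-zero ridge lets the consequents
interpolate the training data and extrapolate violently.

## Bagging fusion

Each member is refit on `B = 25` bootstrap resamples (seeded, with
replacement; a resample must contain at least two distinct rows); a
member's prediction is the mean over its refits. The fused prediction is a
convex combination of the three member predictions, so it always lies
inside the members' envelope and is invariant to member order.

The fusion weights are the design decision that was genuinely open. An
unweighted mean is the simplest reading, but whenever one member is
systematically weaker than the others — and the RBF network is, on both the
literature data and the synthetic testbed — an equal-weight average
provably loses to the best member, which contradicts the study design's
premise of fusing the members' *best-resulted* outputs. The default
therefore weighs each member by the reciprocal of its out-of-bag mean
squared error (every refit predicts the rows its bootstrap left out — an
honest skill estimate that costs nothing extra). Uniform weighting remains
available (`fusion = "uniform"`) and is used automatically when bagging is
disabled (`bag = FALSE`), in which case the fusion is exactly the plain
mean of the three single fits.

Model quality is always reported as the triple R² = 1 − SSE/SST (not a
squared correlation — the two differ off the 45° line), RMSE, and the
signed mean bias error MBE = mean(ŷ − y), positive for over-prediction;
RMSE and MBE are in percentage points.

## Fruit-fly optimization

The FOA searches the fused surface for the protocol with the highest
predicted efficiency. Each fly carries an independent (x, y) coordinate
pair per decision variable (the standard multi-dimensional extension);
per generation each fly jumps from the swarm axis by a uniform offset in
the flight range, its smell-concentration decision value S = 1/√(x² + y²)
(distance floored at 1e-12) is clamped to [0, 1] and mapped linearly onto
each variable's bounds, the strain dimension rounds to the nearest valid
integer code, and the objective is evaluated — exactly
`maxgen × sizepop` evaluations per run. The incumbent best is retained
unless beaten (elitist update; the axis moves only on improvement), so the
convergence trace is non-decreasing and a flat objective can never lose
ground. Non-finite objective values exclude a fly from the argmax; argmax
ties resolve to the lowest fly index.

Defaults mirror the study configuration: 100 generations, 10 flies,
initial axis in [0, 1], flight range [−10, 10], bounds taken from the
observed min–max of each resolved variable. One property of this
configuration is worth knowing: offsets of ±10 dwarf the unit axis scale,
so consecutive generations resample near-globally rather than refining
locally, and decision values concentrate below ~0.3 of each range. That is
faithful to the stated parameters and is what `run_study()` uses. For
experiments whose purpose is to *recover a known interior optimum* (the
synthetic ground-truth tests), the package instead runs the same budget
with a unit-scale flight range (`fr = c(-1, 1)`), which restores local
refinement around the incumbent; both configurations are exposed through
`foa_config()`.

## Sensitivity analysis (VSE / VSR)

The variable sensitivity error of an input is the ensemble's RMSE when
that input is "removed"; the variable sensitivity ratio is VSE divided by
the full-model RMSE, and inputs are ranked by descending VSR (ties resolve
in canonical variable order; a higher VSR means a more important input).
"Removed" defaults to mean substitution — the column is replaced by its
training-set mean, no retraining — which is fast, standard, and exactly
calibrated: an identity policy (replace the column with itself) returns
VSR = 1 to machine precision, and structurally null factors in the
synthetic testbed score within a few percent of 1. A retrain-without-column
policy is available behind a flag. VSE is evaluated on the full dataset by
default, consistent with ranking on all available evidence.

## The synthetic testbed

`generate_synthetic()` produces datasets with the same schema as the
resolved literature rows and a known ground truth, so every stage — fit,
fusion, optimization, ranking — can be tested against an analytic answer.
The response is an additive unimodal surface: a base efficiency, one
additive effect per strain level, and per-factor Gaussian bumps
w·exp(−(v−o)²/2τ²), plus Gaussian noise, clipped to [0, 100] (the clip rate
is reported and kept below 1% at the defaults).

Defaults, frozen as the package's study conditions: 500 rows; five strain
levels with effects 0/2/4/6/10 points; four active factors — kanamycin
(weight 18), CCP (12), vancomycin (9), paromomycin (8) — with bump widths
of 20% of each range and interior optima at 0.30/0.45/0.35/0.60 of their
ranges; the remaining six factors structurally zero, mirroring how most
antibiotics are absent from any given study; noise SD 2 points. The
weights follow an identifiability principle: every active factor's
marginal contribution SD (about 2.5–5.6 points under uniform sampling)
exceeds the noise SD, so each encoded effect is statistically detectable
without being trivial. `true_optimum()` returns the analytic argmax (best
strain level, bump centres) and its value; zero-weight factors have no
defined optimum and are reported at range midpoint and excluded from
recovery checks.

What the generator does *not* emulate: the literature table's clustered
dose levels (real studies reuse a few standard concentrations), its
correlated factor choices, between-study heterogeneity, and range-valued
reporting. Passing the synthetic tests therefore demonstrates that the
machinery recovers structure *when the assumed signal exists*; it says
nothing about whether the literature data contain such signal (see
Limitations).

## Validation experiments and problem sizes

The test suite runs four hard, property-style experiments plus a
reproduction sweep; sizes were chosen to keep the whole suite within a
routine CI run:

* **Metric oracle** — R²/RMSE/MBE agree with naive loop formulas to 1e-12
  on 1,000 random vectors.
* **Optimizer contract** — exactly 1,000 evaluations at the default
  budget; elitist non-decreasing history; a 2-D sphere optimum located
  within 0.05 in ≥ 18/20 seeds; a categorical-only search matches
  exhaustive enumeration in ≥ 19/20 seeds.
* **Ground-truth recovery** — 20 seeds at the generator defaults
  (n = 500, noise 2); per seed the pipeline (B = 15 refits per member, the
  1,000-evaluation FOA budget with unit flight range) must place every
  active factor within 10% of its range of the true optimum, and the
  dominant factor must rank 1 by VSR, each in ≥ 16/20 seeds.
* **Fusion dominance** — over 20 seeds (B = 10), the median fused
  validation RMSE must come within 5% of the best member's median, and the
  median fused validation R² within 0.02 of every member's.
* **Literature sweep** — `seed_sweep(1:20)` over the packaged database with
  full defaults; its medians are reported as diagnostics against the
  originally published single-split values (see Limitations for why they
  are not gates), and `scripts/acceptance.R` recomputes the same quantities
  from scratch.

## Numerical choices and degenerate inputs

* Min–max scaling is exactly invertible (checked to 1e-12); a constant
  column scales to 0 rather than dividing by zero.
* Constant observations make R² undefined: metrics return NA for R² with a
  warning while RMSE/MBE remain valid.
* k-means placements use 5 restarts and a 200-iteration cap, seeded; RBF
  and ANFIS refuse configurations with more centers/rules than distinct
  rows.
* The ANFIS premise step is accept/reject with step halving, so its loss
  trace cannot increase; the MLP records per-epoch loss and raises an
  error advising a smaller learning rate if the loss goes non-finite.
* Bootstrap resamples retry (bounded) until they contain two distinct
  rows.
* Model JSON serialization stores full-precision doubles with matrix
  dimensions; a reloaded model predicts identically to 1e-12.

## Known limitations

* **The literature database is small and noisy.** 75 resolved rows from 49
  heterogeneous studies, with range midpoints as targets, leave ~7-row
  validation splits whose R² is dominated by sampling noise; out-of-sample
  medians over 20 seeds are near or below zero for all models here, far
  from the originally published single-split values. The published split,
  preprocessing and hyperparameters are not recoverable, so the sweep
  reports distributions rather than asserting agreement.
* **Curse of dimensionality caps noiseless fidelity.** Even with the noise
  turned off, 350 training rows in an 11-D uniform design cannot pin down
  the surface between points: the members reach validation R² ≈ 0.7–0.8
  (and adding capacity raises training R² while *lowering* validation R²).
  The suite guards the attained level rather than an aspirational one.
* **Mean-substitution VSE** measures sensitivity around the data's own
  distribution; it does not detect interactions and shares the usual
  limitations of permutation-style importances. SHAP-style attributions
  are out of scope.
* Predictions are not clipped to [0, 100]; the FOA can in principle chase
  a model artefact outside the physically meaningful range, which the
  bagged fusion strongly dampens but does not forbid.
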