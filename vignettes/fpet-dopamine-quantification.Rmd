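---
title: "Quantifying task-specific dopamine synthesis with functional FDOPA PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying task-specific dopamine synthesis with functional FDOPA PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpetdopa)
```

## The measurement problem

6-[18F]FDOPA is a substrate of aromatic amino acid decarboxylase (AADC):
after transport into tissue it is decarboxylated to [18F]fluorodopamine and
trapped in synaptic vesicles, so its irreversible uptake rate indexes
dopamine synthesis. Because AADC activity is up-regulated within minutes by
neuronal firing, a cognitive task performed *during* a single scan leaves a
measurable imprint on the uptake rate. The functional-PET (fPET) approach
quantifies that imprint: the tracer is given as a 20:80 bolus plus constant
infusion so that plasma and free tissue concentrations are near
steady state, the task is presented in short blocks, and a general linear
model (GLM) separates block-wise extra uptake from baseline synthesis. Net
influx constants come from the Gjedde–Patlak plot.

This package implements that chain end to end, together with a synthetic
generator that produces sessions with known ground truth, which is how the
implementation is validated: every quantity the pipeline reports can be
compared against the constant that generated the data.

## Signal model

For a region with transport `K1` (mL/cm3/min), clearance `k2` (1/min) and
trapping `k3` (1/min), the parent tracer follows the irreversible
two-tissue compartment system

    dC1/dt = K1 Cp(t) - (k2 + k3) C1,      dC2/dt = k3 C1,

driven by the parent arterial plasma `Cp`. The implied net influx constant
is `Ki = K1 k3 / (k2 + k3)`. The dominant metabolite, 3-O-methyl-FDOPA
(3-OMFD), crosses the blood–brain barrier and adds a one-tissue component
driven by the metabolite plasma curve. The measured concentration is

    C_meas = (1 - vB) (C1 + C2 + C_omfd) + vB C_wholeblood,

with the blood volume fraction fixed at `vB = 0.05` everywhere.

### Task modulation and the two response modes

Task blocks are parameterised as additive changes of `k3`. The generator
offers two renderings:

* **`uptake` (default).** The extra influx implied by the `k3` change,
  `dKi * Cp(t)`, is added to the trapped compartment while the block is
  active. This is the instantaneous-equilibration limit and exactly the
  signal model the GLM's ramp-and-hold regressor assumes (a constant change
  of the uptake *rate* during the block).
* **`ode`.** `k3` itself switches at block boundaries and the full
  transient is integrated. A step in `k3` initially diverts tracer from the
  free to the trapped compartment without changing their sum; the total
  signal responds only as the free compartment re-equilibrates, with time
  constant `1/(k2 + k3)` — 10–15 min for physiologic FDOPA constants,
  i.e. much longer than a 5-min block.

The distinction matters: with `ode`-mode data the ramp regressor
systematically under-recovers the generative per-block `dKi` (by 25–100%
across the default blocks in our experiments), not because the GLM is
wrong, but because a slow-relaxation kinetic model and a
constant-uptake-change regressor describe different physics. The `uptake`
mode is therefore the package default and defines the working points for
recovery testing; the `ode` mode remains available precisely to expose this
sensitivity.

## The synthetic generator

`bloodModel()` describes the plasma response to a unit bolus: the parent as
a three-exponential decay (defaults 3.0, 0.35 and 0.12 /min), the
metabolite by first-order conversion from the parent (formation 0.012/min,
elimination 0.006/min), and whole blood as total plasma divided by a linear
plasma-to-whole-blood ratio (1.0 + 0.004 t). Administration superposes this
response under the 20:80 bolus-plus-infusion protocol
(`makeInputFunctions()`), all on a 1-s internal grid with an exact
exponential-integrator update per step (no stiff-solver dependence; the
update is exact for inputs linear within a step and doubles as a reusable
oracle). Compartment solutions are verified against an independent
`deSolve` integration in the test suite.

`kineticScene()` assembles the default "brain": a striatal target
(`K1 = 0.04`, `k2 = 0.07`, `k3` set from the requested baseline `Ki`),
four gray-matter regions sharing the striatal `k2`/`k3` with scaled `K1`,
and an occipital reference region (`K1 = 0.06`, `k2 = 0.05`, `k3 = 0`).
The 3-OMFD tissue kinetics are uniform and equal to the reference parent
kinetics — the exact assumptions the metabolite correction makes.

Two generator choices deserve justification, because they were made so
that the data satisfy the *quantification's own* assumptions (which is the
generator's stated job — recovery tests are only meaningful when the
estimator's model holds):

* **Late-flat parent plasma.** The default plasma exponentials make the
  parent input near-constant from about 15 min, the design goal of a
  bolus-plus-infusion protocol.
* **Striatal `k2 + k3` near 0.08/min.** A 20:80 split over a 50-min
  infusion has an effective bolus-to-infusion ratio `Kbol = 12.5` min; a
  protocol with `Kbol ~ 1/(k2 + k3)` preloads the free compartment so that
  the Patlak transient has essentially decayed by `t* = 25` min. With the
  default constants the residual Patlak bias at the two baseline working
  points (0.009 and 0.012/min) is below 1%; with substantially slower
  exchange (`k2 + k3 ~ 0.05`/min) the same estimator would overestimate
  the 25–50-min Patlak slope by 10–25%, a genuine property of graphical
  analysis at finite `t*`, not an implementation artifact.

What the generator deliberately does **not** emulate: scanner physics
(attenuation, scatter, resolution), motion-induced image artifacts (motion
parameters are simulated and regressed, but never corrupt the TACs),
anatomical heterogeneity of gray matter (the gray set is shape-matched to
the target baseline; real gray matter is not proportional to striatum, so
real-data GLM separation carries an additional, unquantified bias), and
tracer delay/dispersion in the arterial line. Passing recovery tests
therefore demonstrate correctness of the estimation chain under its stated
assumptions, not accuracy on arbitrary real data.

The MID simulator reproduces the task logic: a one-up/one-down staircase
(15 ms default step) holds the hit rate near 0.5, and a limit bias injected
at the start and middle of each block (+120/−120 ms by default) makes gain
blocks profitable and loss blocks costly, which is what the
performance weights (gain attained over gain possible; loss avoided over
loss avoidable) feed on.

## The quantification chain

1. **Input functions** (`fitPlasmaRatio`, `adaptMetaboliteFraction`,
   `assembleInputFunctions`). Plasma/whole-blood ratios are fitted with a
   line in ratio space; the literature bolus 3-OMFD fraction is adapted to
   bolus + infusion by superposing total and metabolite bolus responses
   separately (the fraction is the ratio of two administration-rate
   convolutions); parent input = whole blood × ratio × (1 − fraction).
   The adaptation reports the percent reduction of the fraction AUC; with
   the package's default bolus curve this is ~40%, but the number depends
   entirely on the input bolus curve, so only its sign is asserted in
   tests.
2. **Reference fit** (`fitReference1TC`). The occipital TAC is fitted with
   a one-tissue model, `vB` fixed, multi-start nonlinear least squares
   (deterministic log-spaced lattice over [0.005, 0.3]^2, relative
   tolerance 1e-8, lowest residual wins). Two deliberate choices:
   the model is driven by **total** plasma — under the equal-distribution-
   volume assumption the reference tissue responds to parent and
   metabolite with one impulse response, so a parent-only drive could not
   recover the true constants from a metabolite-containing TAC — and task
   and motion contamination are removed by **joint estimation**: nuisance
   regressors (task ramps, motion PC1) are profiled out by OLS inside the
   NLS objective. A two-pass variant (GLM-adjust first, then fit) was
   rejected because the gray-matter baseline regressor cannot represent
   reversible reference kinetics, and the resulting spurious task betas
   distort the fit by ~15% and downstream baseline `Ki` by 7–23% on
   clean data; the joint fit is exact there and equally applicable to
   contaminated data.
3. **Metabolite and blood correction** (`estimateOmfdTissue`,
   `correctTacs`, `removeBloodComponent`). The 3-OMFD tissue curve is the
   fitted impulse response convolved with the metabolite input;
   `(1 − vB)` times it is subtracted from every region, and the fixed
   whole-blood component is removed. Negative corrected values are
   permitted and surfaced in QC.
4. **GLM** (`lowpassFilter`, `buildGlmDesign`, `fitGlm`). Regressors: one
   ramp-and-hold per block (slope exactly 1 kBq/mL per frame inside the
   block — frame-averaged, so the i-th in-block frame takes value
   i − 0.5 — held constant afterwards, because trapped activity persists),
   the baseline (mean of non-excluded gray-matter TACs) and the motion PC1
   (sign fixed positive on the largest-variance column). No
   orthogonalisation; collinearity is reported as a condition number. The
   zero-phase raised-cosine low-pass (half-power at the 2.5-min period,
   unity below 0.3 of the cutoff frequency, mirror-padded FFT realisation)
   is applied to the response *and* to every design column: filtering both
   sides leaves coefficients of design-generated signals exactly unbiased,
   which a response-only filter does not.
5. **Influx constants** (`taskKi`, `baselineKi`, `fitKi`). Task `Ki` per
   block is the ramp coefficient divided by frame length and the mean
   parent plasma over that block; this is the normative rule, with the
   Patlak-difference construction (`patlakDiffTaskKi`: extend the fitted
   block uptake rate over the whole scan, Patlak both curves, subtract)
   kept as a cross-check — the two agree within 2% on clean data.
   Baseline `Ki` is the Patlak slope of the reconstructed baseline
   component from `t* = 25` min (frame midpoints at or after `t*`,
   inclusive; plasma integral by trapezoid on the input grid; evaluation
   at frame midpoints, time origin at injection).
6. **Condition averaging** (`performanceWeights`, `weightAndAverage`,
   `percentSignalChange`). Per-condition `Ki` is the performance-weighted
   mean over that condition's blocks; the unweighted variant is always
   reported alongside, and `PSC = Ki_task / Ki_baseline × 100`. Subject-
   level PSC and group means do not commute; both orders are available to
   the caller (per-subject `ConditionKi` objects retain everything).

Order of operations: metabolite correction precedes the GLM for target and
gray regions; the reference preparation runs on uncorrected data (its
purpose is to *produce* the correction). Proof-of-concept sessions use a
single combined task regressor and blocks from 20 min.

## Behavioral analysis

Reaction times are mean-centered within blocks (the staircase makes
absolute RTs non-stationary). The RT-versus-amount relation is modelled by
forward stepwise selection over linear and quadratic terms
(entry-only, alpha = 0.05; entry-only because with two candidates a removal
step can only churn, and the selection events of interest are additions).
Group fits pool all subjects' trials; subject-level fits reuse the
group-selected terms. Group tests are two-sided t-tests Holm-corrected as
one family per analysis table (`holmAdjust` wraps `p.adjust`); zero-variance
fast paths keep degenerate synthetic cases exact. `Ki`–behavior
correlations use Spearman's rank correlation with the p-value computed by
complete enumeration of all n! orderings for n ≤ 9 (the fPET subgroups
have n = 7 and 9; ties handled by average ranks) and the t approximation
otherwise.

## Numerical choices and degenerate inputs

* Internal time grid 1 s; times in minutes, activities in kBq/mL
  everywhere in memory; files declare seconds and are converted on read.
* Frame schedule: 60-s frames over 50 min by default (the framing enters
  the regressor math only through the frame length, which is a config
  constant).
* Frame averaging by exact trapezoid (vectorised as differences of the
  running integral when frame edges lie on the grid); conserves integral
  activity to quadrature tolerance.
* Multi-start fits are deterministic (no RNG); ties broken by lowest
  residual; non-convergence from all starts is an error, as are
  non-positive parameter estimates, a zero driving input, rank-deficient
  designs, plasma non-positive in the Patlak window, fewer than 3 points
  past `t*`, all-zero condition weights, and negative task-modulated `k3`.
* Seeds: every stochastic step (TAC noise, motion walk, MID trials) is
  reproducible from the config seed; identical seeds give byte-identical
  output tables.

## Problem sizes used in the validation suite

Recovery tests run noise-free single-subject sessions (seven regions,
50 frames, 1-s input grid, about a second per full pipeline run) at the
published working points: task-specific `Ki` of 0.017 and 0.022/min
(proof-of-concept), condition means 0.014/0.009 (men) and 0.012/0.019
(women), baselines 0.009 and 0.012/min, a seven-subject group with a
common gain-minus-loss difference of −0.006/min, and trial-level
behavioral simulations (18 subjects × 60 trials, 200 selection
replicates). These sizes keep the full suite under half a minute while
matching the study's dimensions where they matter (subjects per group,
trials per amount level).

## Known limitations

* The homogeneous gray-matter scene makes GLM separation exact by
  construction; on real data the baseline regressor is only an
  approximation to any region's baseline shape and the resulting bias is
  not characterised here.
* Baseline `Ki` from a 25–50-min Patlak window inherits the usual
  finite-`t*` bias when tissue exchange is slow relative to the protocol's
  `Kbol`; the reported `r2` and the cross-check against the closed form in
  the tests bound this only under the default kinetics.
* The metabolite correction is literature-based, exactly as in the
  modelled protocol: absolute `Ki` scales with the assumed bolus fraction
  curve, while within-scan contrasts (gain vs. loss, PSC) are insensitive
  to it.
* The `ode` task mode documents, but does not solve, the mismatch between
  slow trapping kinetics and ramp regressors; recovering `k3` steps from
  their lagged total-activity response would require a different estimator
  (e.g. fitting the compartment model per block), which is out of scope.
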