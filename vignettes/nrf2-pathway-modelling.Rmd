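---
title: "Dynamic modelling of Nrf2 pathway activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic modelling of Nrf2 pathway activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the numerical design of
`nrf2dyn`: the reaction network and its two mechanistic variants, the
observation and error model, the steady-state constrained
parametrisation, replicate alignment, maximum-likelihood fitting with
profile-likelihood identifiability, and the synthetic-data generator that
stands in for the study's unpublished microscopy/qPCR/glutathione
measurements. It also records the choices made where the design was
genuinely open, and what the tests do and do not establish.

## The reaction network

The model tracks 15 species (`species_names()`): free Keap1, free
cytoplasmic Nrf2, free p62, the double-bound Keap1-Nrf2 latch complex,
the stress-modified ETGE-only complex, the Keap1-p62 complex, the
autophagosomal Keap1 pool, nuclear Nrf2, the four mRNAs (KEAP1, NFE2L2,
SQSTM1, SRXN1), Srxn1 protein, total glutathione and the intracellular
active electrophile ("Stress"). Concentrations are in arbitrary units;
the parametrisation convention pins basal free Keap1 at 1 a.u., which
fixes the concentration scale (see *Gauge fixing* below). Time is in
hours, doses in uM.

Reactions are mass action except for transcription of KEAP1, SQSTM1 and
SRXN1 mRNA and for glutathione synthesis, which are basal plus
Hill-activated by nuclear Nrf2 (`V x^h / (K^h + x^h)`); NFE2L2
transcription is constitutive, which makes its mRNA structurally
dose-independent — the model-level counterpart of the observation that
NFE2L2 mRNA does not respond to electrophile treatment. Every species
carries first-order turnover. The backbone:

* basal synthesis of Nrf2, Keap1 and p62, plus mRNA-driven translation of
  Keap1, p62 and Srxn1;
* reversible Keap1 + Nrf2 association into the latch complex; proteasomal
  degradation of Nrf2 out of that complex with Keap1 recycled;
* p62 + Keap1 association and routing into the autophagosomal pool
  (the foci observable), which is cleared in first order;
* nuclear import/export of Nrf2;
* electrophile input (treatment), first-order clearance, conjugation by
  GSH, and modification of Keap1.

The two variants differ in a single reaction, the action of Stress on the
latch complex:

* **hinge-latch**: `Stress + K1N2_latch -> K1N2_mod` — the complex
  persists, bound at the ETGE motif only, and no longer degrades Nrf2;
* **dissociation**: `Stress + K1N2_latch -> Nrf2` — Nrf2 is released and
  the modified Keap1 leaves the latch-competent pool.

Stress also modifies *free* Keap1 (rate = `mod_free_frac` times the
complex-modification rate). The state vector carries no separate
"modified free Keap1" pool: a modified free Keap1 molecule can neither
close the latch nor be distinguished by any observable, so it is routed
out of the latch-competent pool and counted as Keap1 clearance in the
mass bookkeeping. This keeps the state minimal while preserving the only
consequences modification has in this model — loss of degradation
capacity and of sequestration capacity.

The network is built from a declarative reaction table
(`build_model()`), so the structure can be inspected
(`write_reaction_table()`) or swapped without touching the solver. Two
evaluation paths exist: an interpreted evaluator compiled from the
reaction table, and a hand-written C right-hand side used by default for
speed. The test suite asserts their trajectories agree; the interpreted
path is the structural reference, the C path the workhorse.

## Treatment, vehicle background and knock-downs

A treatment is a Gauss-shaped electrophile bolus switched on at the
treatment onset; its height equals the nominal dose. Defaults place the
peak 0.5 h after onset with a width (sd) of 0.25 h — the bolus is a brief
exposure event, not a sustained input; both values are configurable and
shared across compounds. All treated wells additionally carry a constant
low-amplitude vehicle background input (`dmso_bg`, default 0.3 a.u./h),
reflecting that part of the pathway activation under the experimental
conditions is caused by the DMSO vehicle itself; it switches on with the
treatment and is an estimable parameter.

Per-compound parameters are the Keap1-modification rate and the
electrophile clearance rate (`kmod_*`, `kclear_*` for DEM, DCF, OMZ); all
other kinetics are shared across compounds. For omeprazole two further
parameters may replace their shared counterparts — the Srxn1 turnover
rate and the Hill Vmax of SRXN1 transcription — reflecting that Srxn1
regulation can differ under that compound; `fit_extension()` frees them
and `anova()` quantifies the improvement of the nested models.

siRNA knock-downs multiply the production rates (basal synthesis and,
where present, mRNA-driven translation) of the targeted protein by an
efficiency factor in (0, 1]. Because knock-down is never complete, the
factors `f_KEAP1`, `f_NFE2L2`, `f_SQSTM1` are free parameters of the
model, one per siRNA, shared across reporter lines. Time convention:
t = 0 is the start of the knock-down; the system starts in the untreated
steady state, the switch acts from t = 0, treatment starts 72 h later,
and observation times are reported relative to treatment onset.

## Steady state and parameter reduction

The system is assumed to be in equilibrium at t = 0. `solve_steady_state()`
offers two methods: damped Newton root-finding (with a finite-difference
Jacobian and non-negativity clamping) and long pre-simulation (1e4 h).
The default tries root-finding first and falls back to pre-simulation.

One numerical subtlety: the p62 loop (nuclear Nrf2 up-regulates SQSTM1,
p62 removes Keap1, less Keap1 means more nuclear Nrf2) is a positive
feedback, and for some parameter sets away from the reference values the
model is genuinely bistable. A Newton iteration started from an
algebraic guess can then land on an equilibrium that the cell, started
from that same guess, would never reach. Root-finding therefore first
relaxes the heuristic start by a 1000 h integration — long against the
slowest basal timescales (tens of hours) — and then polishes with
Newton, so both methods answer the same question: *the equilibrium in
the dynamically reached basin*. The two methods agree to better than
1e-6 relative across random positive parameter draws (the test discards
the rare draws where either fails to converge).

`constrain_parameters()` uses the equilibrium assumption to eliminate
parameters: for each anchored species, its production-rate parameter
(`Keap1 -> p_Keap1`, `Nrf2 -> p_Nrf2`, `p62 -> p_p62`, `GSH -> b_GSH`)
is re-solved so the steady state passes exactly through the anchor. The
production rates enter their balance equations linearly, so solving the
augmented system (free concentrations plus log production rates) with
the same damped Newton is exact; infeasible anchors (which would require
a non-positive rate) are rejected with the offending anchor named.

### Gauge fixing

The likelihood is invariant under jointly rescaling any species
trajectory by c and its observation scale by 1/c. Rather than detecting
such symmetries algorithmically, the package removes them by convention:
the steady-state anchor pins free Keap1 at 1 a.u. (and, in the synthetic
studies, Nrf2 at 0.05, p62 at 1 and GSH at 10), and observation scales
are estimated relative to that gauge. Any residual non-identifiability
shows up at run time as a flat profile likelihood, which is exactly how
the test suite exercises the detector (freeing both `kt_Srxn1` and the
Srxn1 observation scale creates an exact symmetry; the profile is flat
and classified structurally non-identifiable).

## Observation and error model

Measured signals relate to states by `y = log(s x + b) + eps` with
`eps ~ N(0, sigma^2)`: `s` is the unknown concentration scale of the
assay, `b` a background offset, and `sigma` a constant per-target noise
sd on the log scale (log-normal noise on the natural scale). Offsets are
estimable for the three GFP reporters (background fluorescence) and fixed
to 0 for qPCR and glutathione observables, which are ratio-type
measurements without an additive background. The default observable map:
Keap1-GFP foci read the autophagosomal Keap1 pool, nuclear Nrf2-GFP reads
nuclear Nrf2 (the imaging quantification is nuclear-mean intensity, so
cytoplasmic Nrf2 is deliberately excluded), Srxn1-GFP reads Srxn1, the
qPCR targets read their mRNAs, and total glutathione reads the GSH pool.

The fitting objective is
`-2 log L = sum_i [((yhat_i - y_i)/sigma_i)^2 + log sigma_i^2]`.
Minimising over a per-target `sigma` alone has the closed form
`sigma^2 = mean squared residual`, so by default the noise sds are
concentrated out analytically at every evaluation; they can instead be
fixed when the noise level is known (as in the coverage studies below).
`sigma` is floored at 1e-3 log units to keep the objective bounded on
noise-free synthetic data.

## Replicate alignment

Biological replicates differ by systematic multiplicative factors (cells
per well, illumination). The scaling model `S_ikn = y_in / s_k` with
log-normal noise is linear in log space, so `align_replicates()` fits it
by exact two-way least squares per observable (gauge: first experiment
has s = 1) — no iterative optimisation, no starting values. Merging two
experiment series that also differ by an additive offset uses the mixed
model `S = y/s + b`, which breaks log-linearity; `merge_series()` fits
(s, b) by 2-parameter trust-region least squares on the log residuals
over the bridging conditions and transfers series B onto the common
scale as `(S_B - b) s`. Noise-free constructions are recovered to 1e-8;
under 0.1 log-units of noise and time courses of the study's richness
(tens of points per experiment), scaling ratios come back within a few
percent.

## Fitting and identifiability

`nrf2_fit()` performs multi-start maximum likelihood: Latin-hypercube
start points over box bounds on log10 parameters (default bounds: five
decades either side of the template values), a trust-region
least-squares local fit (`minpack.lm::nls.lm`) from each start with the
noise sds re-estimated in closed form between rounds, and results sorted
by objective. Failed starts (no steady state, infeasible anchors,
integration failure, negative concentrations beyond tolerance) are
recorded, not fatal. Start generation is deterministic given the seed.

Two numerical details matter. First, the forward-difference step of the
optimiser is set to `epsfcn = 1e-6`: the objective carries ODE-solver
noise of roughly the integration tolerance (1e-6 relative during
fitting), and differencing below that floor produces spurious gradients
that stall convergence. Second, every objective evaluation re-derives
the anchored production rates and the equilibrium from scratch, so the
steady-state constraint holds exactly along the whole optimisation path.

`profile_likelihood()` steps a parameter away from its estimate in both
directions with adaptive step control (targeting a rise of ~0.4 units
per step), re-optimising all other free parameters warm-started from the
neighbouring point, and stops at a rise of 5, at a bound, or after a
step budget. The 95% confidence interval is read off at 3.84
(chi-square, 1 df); the bracketing interval around each crossing is
refined by bisection to within 0.02 in the objective, so the interval
end points do not depend on the step sequence. Classification: a profile
whose total spread stays below 0.01 is structurally non-identifiable; an
interval open at a bound is practically non-identifiable; otherwise the
parameter is identifiable. On a constructed quadratic problem the
interval matches the textbook closed form; in repeated synthetic studies
with known noise the intervals cover the generating value at close to
the nominal 95% (the package's acceptance script recomputes this
coverage over 100 repetitions).

`compare_variants()` reports both variants' objectives and the
post-treatment signature of the total Keap1-Nrf2 complex
(`complex_total()`: latch plus modified pools): baseline, minimum within
two hours of the bolus, and whether it dips below baseline. Equal-quality
fits do not exclude either hypothesis — the discrimination is carried by
the internal complex dynamics, not by the likelihood.

## The synthetic-data generator

`reference_parameters()` is a hand-tuned ground truth whose simulations
reproduce the qualitative hallmarks of the measured system, each of
which is asserted by the test suite: nuclear Nrf2 peaks 3-5 h after a
DEM 316 uM bolus and relaxes slowly; KEAP1/SQSTM1/SRXN1 mRNA peak at the
8 h point of the 3/8/24 h qPCR design; NFE2L2 mRNA is flat; total
glutathione rises by well under 30% even at DEM 561 uM; the
autophagosomal Keap1 pool dips by 5-10% over the first three hours
before rising above baseline; and Srxn1 is still rising at 48 h at the
top dose. The slow relaxation arises mechanistically: autophagy is the
dominant Keap1 sink and p62 induction keeps free Keap1 suppressed for
tens of hours after the electrophile is gone.

Rates were chosen by that tuning, not estimated from data. Where the
study conditions fix a quantity (dose lists for DEM/DCF/OMZ, hourly
imaging over 48 h, qPCR at 3/8/24 h, GSH at 7 time points, 72 h
knock-down, at least three replicates) the generator defaults follow
them. Where they do not, the defaults are: noise sd 0.1 log units
(the study states the noise family, not its magnitude; 0.1 corresponds
to ~10% multiplicative error, typical for imaging-based readouts),
per-experiment scalings drawn log-uniformly from [0.5, 2], knock-down
efficiency factors 0.2-0.25.

`generate_dataset()` simulates every condition at the ground truth,
applies the observation map, divides by the per-experiment scaling,
multiplies by log-normal noise, and returns replicates together with the
noise-free truth — deterministic per seed. `knockdown_scenario()`
produces the four siRNA arms and shows the predicted baseline shifts:
lower autophagosomal Keap1 under siSQSTM1, elevated nuclear Nrf2 under
siKEAP1 (the knock-down is counteracted by the feedback), and a blunted
Srxn1 response under siNFE2L2.

What the generator does *not* emulate: image-level artefacts (foci
segmentation, cell-to-cell heterogeneity, photobleaching), outliers, or
time-correlated noise. Passing the recovery and coverage tests therefore
shows that the estimation machinery is correct and well calibrated under
the model's own assumptions — it does not certify performance on real
microscopy data, where error-model misspecification would surface first.

## Numerical choices

* Integration: `deSolve::lsoda`; reporting tolerances rtol 1e-8 /
  atol 1e-10, fitting tolerances 1e-6 / 1e-8. The narrow bolus is
  protected by capping the step size at half the bolus width inside the
  pulse window, and integration is segmented at the treatment onset.
* Negative concentrations: the solver runs unclipped; the result is
  asserted to be above -1e-6 (evaluations violating this are rejected,
  which matters only for absurd multi-start draws) and then clamped to 0.
* Steady state: Newton tolerance 1e-8 on the max-norm residual;
  pre-simulation horizon 1e4 h; basin-committing relaxation 1000 h
  before Newton (see above).
* Degenerate inputs: zero dose without vehicle background reduces to the
  steady state (drift below 1e-6 over 120 h); a zero-length horizon
  returns the equilibrium itself; zero production of a protein empties
  the corresponding pools exactly.
* Ties and gauges: first experiment s = 1 in alignment; first series
  b = 0 in merging; free Keap1 = 1 a.u. in the model.

## Problem sizes used by the tests

The unit tests run on reduced designs (single compound, imaging every
4-12 h, 1-3 replicates) chosen so the whole suite exercises every code
path in a few minutes; the end-to-end recovery uses the full DEM design
(five doses, hourly imaging, three replicates, ~830 aligned records)
with 50 Latin-hypercube starts, and the coverage study uses 100
repetitions of a single-dose, single-observable design with one free
parameter and known noise. These sizes are the package's own choice of a
convincing-but-compact validation; nothing prevents running the same
harness at larger sizes.

## Known limitations

* The network is a deliberately compact representation: competitive ETGE
  binders (WTX, p21, PALB, DPP3), beta-TRCP/PKC-dependent Nrf2 turnover,
  and stochastic or spatial effects are out of scope.
* Two-site hinge/latch binding is lumped into a single association step;
  the ETGE-only intermediate appears explicitly only as the
  stress-modified complex. The internal-state read-outs distinguish
  exactly the two pools that matter for the hypothesis comparison.
* The error model is homoscedastic per target on the log scale; mixed
  absolute/relative error models are not implemented.
* Profile likelihoods are computed per parameter; prediction profiles
  and formal model reduction are not implemented.
* For parameter sets far from the reference values the model can be
  bistable; all fitting starts from the dynamically reached equilibrium,
  but users exploring exotic parameter regions should check
  `solve_steady_state()`'s convergence flags.
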