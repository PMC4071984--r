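---
title: "Methods: EMU-based 13C flux estimation, stationary and nonstationary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMU-based 13C flux estimation, stationary and nonstationary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## The estimation problem

A 13C tracer experiment feeds an isotopically labeled carbon source to
cells at metabolic steady state and measures, by mass spectrometry, the
*mass distribution vector* (MDV) of metabolite fragments: the fractions
`m+0, m+1, ..., m+n` of molecules carrying 0..n heavy carbons, summing
to 1.  Because carbon atoms are rearranged differently by different
pathways, the MDVs are informative about the intracellular flux
distribution `v`.  `emuflux` fits `v` by minimizing the
covariance-weighted sum of squared differences (SSD)

```
Phi(v) = sum_k sum_j  D' C^-1 D,    D = MDV_obs(j, t_k) - MDV_sim(j, t_k; v)
```

subject to the steady-state mass balance `S v = 0` and any
predetermined rates (substrate uptake, biomass drains, excretion), with
`C` the diagonal covariance of the measurement SDs.  Two regimes are
supported:

* **stationary**: labeling has reached steady state; the simulated MDVs
  solve linear per-size EMU balances and are invariant to scaling `v`
  (only the predetermined rates set the absolute scale);
* **nonstationary (INST)**: the transient enrichment time course is
  fitted; the MDV dynamics depend on the metabolite pool sizes `X`,
  which the package treats as known constants (estimating `X` jointly
  is a known limitation, see below).

## Model input and roles

The network is declared as a table with one row per reaction: a flux
id, the reaction equation, and the carbon transitions written as
letter strings, e.g. `ACCOA + OAA -> IsoCit` with `ab + cdef ->
fedbac`.  The k-th letter of a species' string is its k-th carbon;
letters must balance between the two sides.  Roles are encoded in
names: `Subs_` marks an extracellular source, `Ind_` a species excluded
from mass balance (CO2), `Sym_` a rotationally symmetric molecule, and
a bracketed product (`[AKG_B]`) a biomass sink that is neither balanced
nor traced.  Reactions with an empty transition cell (drains) enter the
stoichiometry only.  A `Net flux` tag column pairs forward/backward
rows of reversible reactions; both directions are kept as separate
nonnegative fluxes.

Carbon counts are inferred from the transition strings; a metabolite
appearing only in unmapped reactions is not traceable and never enters
the labeling simulation.

## EMU decomposition

Simulating only the measured fragments does not require full
isotopomer distributions.  An *elementary metabolite unit* (EMU) is a
subset of a metabolite's carbons; the package closes the set of EMUs
needed for the measured fragments by walking every producing reaction's
atom map backwards (`build_emu_network()`).  Within one EMU size `s`
the steady-state balances are linear,

```
A_s Z_s = B_s Y_s
```

where rows of `Z_s` are unknown EMU MDVs, `Y_s` collects source EMUs
and convolutions of already-solved smaller EMUs (a condensation joining
two precursor units multiplies their generating functions, i.e.
convolves their MDVs), the diagonal of `A_s` carries minus the total
consumption flux of each EMU's metabolite, and off-diagonal entries of
`A_s` / `B_s` the inter-EMU fluxes.  Sizes are solved in ascending
order; `emuflux` validates against an exhaustive positional-isotopomer
fixed-point solver in its test suite.

Two conventions the input format does not pin down are resolved as
follows:

* **Symmetric metabolites** (`Sym_`): every producing and consuming
  atom map is split into two half-weight variants, written and fully
  reversed — the standard treatment of molecules like succinate whose
  orientation is not distinguished chemically.  The split weights of
  one (reaction, product EMU) pair always sum to 1.
* **Unbalanced carbon donors** (`Ind_CO2` consumed by the anaplerotic
  reaction): treated as a source EMU with a fixed unlabeled MDV unless
  the user supplies CO2 labeling explicitly.  The intracellular CO2
  pool is not tracked, consistent with its exclusion from mass balance.

## Nonstationary simulation

During the transient, every unknown EMU follows the pool-size-weighted
labeling ODE

```
dMDV_j/dt = (1/X_j) [ sum_i v_i_in MDV_i  -  (sum_l v_l_out) MDV_j ]
```

with condensation inflows convolved from the current state.  The
integrator is deliberately plain: fixed-step explicit Euler without
adaptive step-size control, with every MDV renormalized to sum 1 after
each step.  This per-step standardization suppresses the slow drift a
first-order method would otherwise accumulate in the simplex
constraint; stiffness must instead be handled by choosing the step
small enough (the integrator aborts with a clear message when the
state leaves the physically meaningful range).  The compiled core makes
a full 17-sample, 8,500-step TCA time course cost a few milliseconds,
so finite-difference Jacobians over it remain cheap.

Numerical conventions:

* initial condition: all intracellular MDVs fully unlabeled at the
  tracer switch (t = 0);
* sampling: the recorded state of a requested time `t_k` is the Euler
  grid point landing on, or latest before, `t_k`; no interpolation;
* default step `h = 0.01` s for the TCA-scale benchmark; `h` must not
  exceed the smallest sampling interval;
* first-order convergence is verified by step-halving tests.

A point worth emphasizing for convergence checks: the time to isotopic
stationarity is governed by the slowest eigenmode of `diag(1/X) A_s`,
not by any single pool's turnover `X/flux`.  Cycles that recycle label
(e.g. OAA -> SUC -> OAA in the TCA benchmark) make the slowest
relaxation severalfold slower than the slowest pool turnover;
`labeling_timescales()` reports both.

## Flux fitting

Equality constraints are eliminated exactly, not penalized: a
particular solution and an orthonormal null-space basis of
`[S; fixed-flux rows]` give `v = v_p + K u`, and the optimizer works in
the free coordinates `u` (`p = ncol(K)` free fluxes; 3 in the TCA
benchmark).  Nonnegativity of all fluxes (irreversibility of each
directed reaction) is enforced by shortening any trial step to the
feasible cone.

The search is Levenberg-Marquardt on the whitened residuals:
forward-difference Jacobian (relative step 1e-6, absolute floor 1e-8,
reflected at the nonnegativity boundary), damping `lambda` starting at
1e-3, divided by 10 on an accepted step and multiplied by 10 on a
rejection, convergence when the relative SSD improvement falls below
1e-8 or the gradient norm below 1e-6, iteration cap 200.  Because the
objective is nonconvex, the fit is restarted from `restarts` random
feasible points (default 10) drawn by rejection sampling of `u`; the
best result is returned together with the per-restart log.  Standard
errors come from the linearized covariance `K (J'J)^-1 K'` at the
optimum.

The number of independent data points is counted as the sum over
fitted MDVs of (length - 1) — the unit-sum constraint removes one
degree of freedom per spectrum — and the model degrees of freedom as
the number of free fluxes `p`.  These counts enter the profile
threshold below and are reported in the fit object.

## Confidence intervals

Per-reaction confidence intervals use grid-search profiling: the flux
of reaction `r` is fixed at `v_opt,r + d` (one added equality row, new
null-space basis), all other fluxes are reoptimized warm-started from
the neighboring solution, and `|d|` grows geometrically (initial
`max(1% |v_opt,r|, 1e-4)`, factor 2) until the reoptimized SSD crosses
the threshold

```
Phi_res * (1 + F_alpha(1, n - p) / (n - p))
```

after which the crossing is located by bisection to a relative
tolerance of 1e-4.  The interval is the range of fixed values whose
reoptimized SSD stays below the threshold.  A lower search never
crosses zero (fluxes are nonnegative); an upper search that reaches the
configured cap without crossing is flagged unbounded.  On a linear
toy problem the procedure reproduces the closed-form least-squares
interval to bisection tolerance, and the threshold formula is checked
against the squared-t-quantile identity for `F(1, m)`.

## Natural isotope abundance correction

Raw spectra convolve the tracer signal with the natural isotope
envelope of every atom in the measured fragment (including
derivatization atoms such as Si).  `build_correction_matrix()` builds
the matrix whose column `j` is the observable distribution of a
fragment with exactly `j` tracer carbons: the fixed envelope of all
non-skeleton atoms, optionally convolved with the binomial natural-13C
distribution of the remaining unlabeled skeleton positions (enabled by
default; a flag disables it since practice varies), shifted up by `j`
and truncated to the measured window.  `correct_spectrum()` inverts by
nonnegative least squares (plain least squares available for
diagnostics) and renormalizes.  The abundance constants are the IUPAC
representative isotopic compositions tabulated in
`natural_abundances()`.

## The synthetic benchmark and what it does (not) show

Because no public dataset accompanies the method, all end-to-end tests
run on a fully synthetic experiment (`tca_experiment()`): a 16-reaction
TCA cycle fed by pyruvate (50% [1-13C] + 50% [U-13C]) and glutamate
(100% [1-13C]), with the pyruvate influx and six biomass drains
predetermined, leaving three free fluxes (anaplerosis R7, glutamate
uptake R14, and the succinate/oxaloacetate back-flux R15).  The
ground-truth flux vector is a documented feasible point of this
network: published flux values for the benchmark exist only in
graphical form, so recovery tests are self-referential — they ask
whether the estimator returns the fluxes that generated the data, not
whether any literature value is reproduced.

Choices the generator makes, and why:

* **Pool sizes** 2.5-10 umol/gDCW, in the realistic range for central
  carbon intermediates, sized so the 17 x 5 s sampling window spans
  roughly three slowest-relaxation times (~29 s): the enrichment rise
  is visible across most samples and approximately stationary at the
  end — the regime a nonstationary design targets.
* **Sampling** at t = 5, 10, ..., 85 s (17 samples at 5-second
  intervals after the tracer switch).
* **Noise**: additive Gaussian with SD 0.01 per mass channel, on the
  fractional abundances, then clipping of negative channels to zero and
  renormalization.  "1% noise" is ambiguous between absolute and
  relative; absolute-on-fractions is used and the stored measurement
  covariance matches it.
* **Stationary fragments**: the four measured amino acids of the
  stationary benchmark are proteinogenic reporters of their precursor
  skeletons, but the benchmark network carries no amino-acid atom maps
  (they are drains), so the generator measures the precursor skeletons
  directly: PYR (valine reporter), OAA (aspartate), AKG
  (glutamate/lysine pathway), and succinate.  The nonstationary mode
  measures OAA and SUC only.

What passing these tests shows: the EMU construction, both simulators,
the optimizer and the interval search are internally consistent and
recover known ground truth under the stated noise model.  What they do
not show: robustness to the things real data add — fragment-specific
and heteroscedastic measurement error, imperfect natural-abundance
correction, inaccurate pool-size measurements, metabolic non-steady
state, and model misspecification (missing reactions, channeling).

A consequence of the self-referential design worth stating explicitly:
how much narrower time-course confidence intervals are than
conventional ones depends strongly on where the true fluxes and pool
sizes lie.  Under this benchmark the time course roughly halves the
intervals of throughput fluxes while leaving exchange-dominated
reactions essentially unchanged; configurations in which the advantage
is severalfold exist, but are a property of the flux/pool values, not
of the estimator.

## Known limitations

* Pool sizes are constants supplied by the user; they are never fitted.
* Only EMU representations are implemented (no cumomers/bondomers); no
  SBML import; no automatic atom mapping; no raw instrument-file
  parsing.
* The reference ODE path is fixed-step Euler by design; very stiff
  systems need small steps.
* Grid-search profiling re-optimizes hundreds of times per reaction;
  for large networks this, not the fit itself, dominates runtime.
* Exchange fluxes of fast reversible pairs are weakly identified from
  stationary data; expect wide or cap-limited intervals for them.
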