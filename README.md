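# emuflux

Metabolic flux analysis from 13C tracer labeling data, for systems
biologists who measure mass isotopomer distributions of intracellular
metabolites by MS and want the intracellular flux distribution behind
them — including from the *isotopically nonstationary* (INST) transient,
which is what makes flux analysis possible for photoautotrophs on CO2
and for cells in quasi-steady states where stationary labeling carries
little information.

## What it computes

A metabolic network with carbon-atom transitions, declared in a plain
worksheet (`FluxID`, `Rxns`, `Carbon_transitions` columns, e.g.
`ACCOA + OAA -> IsoCit` / `ab + cdef -> fedbac`), is decomposed
automatically into the cascade of elementary metabolite units (EMU)
needed to simulate the measured fragments. Mass distribution vectors
(MDVs, fractions of molecules with 0..n tracer carbons) are simulated

* at isotopic steady state, from the size-stratified linear EMU
  balances `A_s Z_s = B_s Y_s`, or
* along the labeling transient, by integrating the pool-size-weighted
  labeling ODE `dMDV_j/dt = (1/X_j)(Σ v_in MDV_in − Σ v_out MDV_j)`
  with fixed-step Euler and per-step renormalization,

and the flux vector `v` is estimated by minimizing the
covariance-weighted SSD `Φ(v) = Σ_k Σ_j Dᵀ C⁻¹ D` subject to the hard
constraints `S v = 0` and the predetermined rates, via
Levenberg–Marquardt over an exact null-space parameterization with
multiple random restarts. Per-reaction 95% confidence intervals come
from grid-search profiling of `Φ` against the F-distribution threshold
`Φ_res (1 + F_α(1, n−p)/(n−p))`. Natural-isotope correction of raw
spectra (correction-matrix inversion by nonnegative least squares) and
a fully synthetic TCA-cycle benchmark generator are included, so every
part of the pipeline is testable without external data.

## Worked example

Simulate the benchmark nonstationary experiment (16-reaction TCA cycle,
50% [1-13C] + 50% [U-13C] pyruvate plus [1-13C] glutamate, OAA and
succinate sampled 17 times at 5-s intervals with 1% noise) and estimate
the fluxes:

```r
library(emuflux)

exp <- tca_experiment()          # model, truth, pools, labeling, schedule
exp$model
#> <mfa_model> 16 reactions, 6 balanced metabolites (rank 6)
#>   kinds: biomass_drain=6, internal=8, substrate_input=2
#>   fixed: R1, R8, R9, R10, R11, R12, R13

ms <- simulate_dataset(exp, "inst", seed = 42)
fit <- fit_fluxes(exp$model, ms, exp$labeling, mode = "inst",
                  pools = exp$pools, h = exp$h, restarts = 3, seed = 42)
fit
#> <mfa_fit> mode inst; SSD = 149.545; converged: TRUE
#>   free fluxes p = 3, data points n = 136
#>  flux    value       se fixed
#>    R1 1.000000 0.000000  TRUE
#>    R2 1.049257 0.005327 FALSE
#>    ...
#>    R7 0.402977 0.012647 FALSE
#>    ...
#>   R14 0.499257 0.005327 FALSE
#>   R15 0.360077 0.076416 FALSE
#>   R16 0.752234 0.015520 FALSE

grid_search_ci(fit, "R7")
#> <mfa_ci> R7: 95% CI [0.376941, 0.430587] around 0.402977 (SSD threshold 153.944)
```

The SSD of ~150 against n = 136 fitted channels is what a correct noise
model predicts; the anaplerotic flux R7 (truth 0.4), the glutamate
uptake R14 (truth 0.5) and the succinate/OAA back-flux R15 (truth 0.3)
are recovered within their standard errors, and the profile interval
for R7 spans about ±7% of its value. Fixed rows are the predetermined
uptake/drain rates held exactly by the constraint parameterization.

The same pipeline runs from the shell via the thin front end in
`inst/cli/emuflux` (`fit` and `ci` subcommands over a model/data bundle
directory; see `?emuflux_cli` and `?read_model_bundle`).

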