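# densemble

Simultaneous determination of structure and dynamics from cryo-EM density
maps by Bayesian metainference, in R.

## The problem

A single-particle cryo-EM map is an average over millions of molecules.
When the imaged system interconverts between conformations, no single model
can explain the map: apparently "low-resolution" regions may be genuine
dynamics, noise, or both. densemble models a **thermodynamic ensemble** — a
set of conformations with populations — whose *ensemble-averaged* predicted
map matches the data, while inferring the local noise level of the map at
the same time. It is aimed at method developers and structural biologists
who want a self-contained, fully testable implementation of the approach at
desk scale.

## The model

The experimental map is represented as a Gaussian mixture (the data-GMM)

```
phi_D(x) = sum_i w_Di * G(x | x_Di, Sigma_Di),
```

each component serving as one independent data point `d_i = ov_DDi`, its
overlap with the whole data-GMM. A structural model predicts the map with
one Gaussian per heavy atom or bead (the model-GMM `phi_M`), and is
compared with the data through analytic overlap integrals, averaged over N
replicas: `f_i(X) = ov_MDi averaged over replicas`. A Gaussian noise model
with per-component uncertainties, marginalized under a Jeffreys prior,
gives the metainference energy

```
E_MI = E_prior - kBT * sum_i log[ erf(Delta_i / (sqrt(2) sigma_i)) / (2 Delta_i) ],
Delta_i = ov_DDi - mean_r ov_MDi^r,    sigma_i = alpha * ov_DDi,
```

which is harmonic for small deviations and logarithmic for outliers —
unexplainable density is automatically down-weighted, and its inferred
noise level `sigma_B` is recovered a posteriori from the sampled ensemble.
Multi-replica overdamped Langevin sampling (optionally with well-tempered
metadynamics) generates the ensemble; GROMOS clustering, free-energy
surfaces over collective variables and per-component noise maps turn it
into the analysis products.

## Worked example

The synthetic two-state benchmark builds a 30-bead hinge chain with open
and closed conformers, averages their maps 1:1 into an "experimental" map,
and runs the full pipeline — data-GMM fit, 4-replica metainference,
clustering, population recovery:

```r
library(densemble)
bench <- make_two_state_benchmark(w = 0.5)
print(bench$maps$mixture)
#> density map 43x30x10, voxel 0.3 x 0.3 x 0.3 nm, origin (-1.35, -1.35, -1.35) nm
#>   values in [0, 2.718], sum*voxvol = 13.5418

data_gmm <- fit_gmm_dc(bench$maps$mixture, fit_config(budget = 64, seed = 1))
cat("fit CC:", tail(attr(data_gmm, "report")$cc, 1), "\n")
#> fit CC: 0.9974336

report <- run_two_state_experiment(bench, seed = 1, steps = 2e6)
print(report)
#> two-state benchmark report
#>   data-GMM: 64 components, fit CC 0.9974
#>   2 major cluster(s): open 0.500, closed 0.498
#>   recovered open fraction 0.501 (truth 0.50)
```

The 64-component data-GMM reaches a 0.997 voxel correlation with the input map; the
sampled ensemble splits into exactly two conformational clusters whose
populations recover the planted 1:1 mixture. With
`spurious_fraction = 0.1` the same pipeline also flags injected off-model
density with severalfold higher inferred relative noise than clean
components — the noise-inference half of the method.

The methods vignette (`vignettes/metainference-cryoem.Rmd`) documents the
model, every tunable parameter, the synthetic-data design and the known
limitations.

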