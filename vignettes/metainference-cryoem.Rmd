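---
title: "Bayesian metainference of structural ensembles from cryo-EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian metainference of structural ensembles from cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densemble)
```

## The problem

A single-particle cryo-EM reconstruction is an average over up to millions of
individual molecules. When the imaged system populates several conformations,
the deposited density map is an *ensemble average*: no single structure can
explain it, and regions of apparently "low resolution" may reflect genuine
conformational dynamics, noise, or both. densemble implements a Bayesian
metainference treatment of this situation: it models a *thermodynamic
ensemble* — a set of conformations with statistical weights — whose
ensemble-averaged predicted map matches the data, while simultaneously
inferring how noisy each piece of the map is.

## The model

**Data representation.** The experimental map is compressed into a Gaussian
mixture model, the *data-GMM* $\phi_D(x) = \sum_i \omega_{D,i}\,
G(x \mid x_{D,i}, \Sigma_{D,i})$ with normalized weights. Each component is
treated as one independent data point. Compared to raw voxels, the GMM
decorrelates neighbouring observations and can represent the map at any
chosen resolution. Fitting is by density-weighted expectation-maximization
(every voxel center is a point weighted by its clipped density), refined by
divide and conquer: a coarse global fit partitions the voxels by maximum
responsibility, the heaviest components are recursively split and re-fitted
locally, and after every level a few global EM iterations re-polish the
assembled mixture (`fit_gmm_dc()`).

**Forward model.** A structural model predicts a map as one isotropic
Gaussian per heavy atom, with amplitude and width obtained by collapsing the
tabulated five-Gaussian electron scattering factor of each element to a
single Gaussian by least squares over spatial frequencies 0–0.5 Å$^{-1}$
(`scattering_table()`; the coefficient table ships as text and the fit is
re-run on load, so the parameterization is regenerable). Coarse-grained
beads get a Gaussian of width `0.5 * size` and amplitude proportional to
the bead size.

**Observable.** The model and the data are compared through overlap
integrals, $ov_{MD,i} = \int \phi_M(x)\,\phi_{D,i}(x)\,dx$, available in
closed form for Gaussians (`pair_overlap()`). The corresponding "experimental
value" is the self-overlap $ov_{DD,i}$ of component $i$ with the whole
data-GMM. For an ensemble of $N$ replicas, the forward model is the
arithmetic replica average $\overline{ov}_{MD,i}$.

**Noise model and marginalized score.** Each data point carries a Gaussian
noise model with two uncertainty scales: a statistical error
$\sigma^{SEM}_i = \alpha\, ov_{DD,i}$ from averaging over finitely many
replicas, and an unknown noise level $\sigma^B_i \ge 0$. Marginalizing
$\sigma^B$ with a Jeffreys prior over the total uncertainty
$\sigma \in [\sigma^{SEM}, \infty)$ gives the per-component energy

$$E_i = -k_BT \,\log\!\left[\frac{1}{2\Delta_i}\,
  \mathrm{erf}\!\left(\frac{\Delta_i}{\sqrt{2}\,\sigma^{SEM}_i}\right)\right],
\qquad \Delta_i = ov_{DD,i} - \overline{ov}_{MD,i}.$$

The substitution $u = 1/\sigma$ reduces the marginalization integral exactly
to this error-function form; `marginal_score()` reproduces the numerical
marginalization to machine precision. The score is even in $\Delta_i$,
harmonic near $\Delta_i = 0$ (curvature $k_BT/3(\sigma^{SEM}_i)^2$) and
grows only logarithmically for $|\Delta_i| \gg \sigma^{SEM}_i$ — outliers
and unexplainable density are automatically down-weighted rather than
fought.

**Noise inference.** After sampling, the posterior of each $\sigma^B_i$
given the whole trajectory of deviations $\{\Delta_{i,t}\}$ is integrated by
1-D quadrature under the Jeffreys prior and summarized by its median
(`estimate_noise_posterior()`); the relative error
$\hat\sigma^B_i / ov_{DD,i}$ can be painted onto a voxel grid as an error
density map (`error_density_map()`). A Metropolis-within-Gibbs sampler for
$\sigma^B$ (`gibbs_sample_sigma()`) implements the non-marginalized path;
the marginalized score is the default throughout, matching how the method
is used in practice.

## Sampling

`run_metainference()` propagates $N$ replicas in lockstep with overdamped
Langevin dynamics under prior + restraint forces. Numerical choices:

* **Integrator.** The Leimkuhler–Matthews (BAOAB-limit) scheme,
  $x_{n+1} = x_n + \frac{\Delta t}{\gamma}F_n + \sqrt{2k_BT\Delta t/\gamma}\,
  \tfrac{1}{2}(\xi_n + \xi_{n+1})$, whose configurational sampling error is
  an order of $\Delta t$ better than plain Euler–Maruyama — important
  because the stiffest bending modes set the step size.
* **Multiple time stepping.** The map restraint is recomputed every
  `stride` steps (default 2, with neighbor lists rebuilt every 100 steps at
  exponent-factor cutoff 0.01) and applied scaled by `stride`.
* **Model normalization.** The data-GMM is weight-normalized, so the
  restraint internally rescales the model-GMM weights to mass fractions;
  without this the overlaps of model and data live on incompatible scales
  and the restraint pushes the model off the map.
* **Determinism.** One counter-based random stream per replica is derived
  from the master seed (splitmix64 + an explicit Box–Muller), so identical
  seeds give bit-identical trajectories regardless of scheduling.
* **Stability of the erf score.** Below $|u| = 0.1$
  ($u = \Delta/\sqrt2\sigma$), $\log[\mathrm{erf}(u)/u]$ and its derivative
  switch to Maclaurin series, removing the $0/0$ at $\Delta = 0$.
* **Force bound.** A force component beyond `fmax` is capped once with a
  warning; a second overflow aborts with diagnostics.

Well-tempered metadynamics (`metadynamics_bias()`) can flood either the
per-replica restraint score or, for hinge-chain priors, the per-replica
hinge angle (the method itself does not prescribe the collective variable;
both are provided). Hills of height $W_0 e^{-V(s)/k_B\Delta T}$,
$\Delta T = (\gamma - 1)T$, are deposited on a shared grid by all replicas.
Deposition can be restricted to an initial window and the accumulated bias
then *faded linearly to zero* — an adiabatic release that leaves the final
segment of the trajectory exactly unbiased, so populations need no
reweighting (final-bias reweighting via `metad_weights()` is available for
fully biased runs).

## The synthetic two-state benchmark

`make_two_state_benchmark()` builds the study system: a 30-bead hinge chain
(bond 0.45 nm, bond stiffness 300 kJ/mol/nm², bending stiffness
1000 kJ/mol/rad²) whose hinge angle sits in a quartic double well centered
at 90° with minima at 60° ("closed") and 120° ("open") and a 2.5 kJ/mol
barrier. The two minimized conformers (backbone RMSD ≈ 1.6 nm) are
rasterized through the bead forward model on a ~48³ grid of 0.3 nm voxels,
and the benchmark "experimental" map is their weighted average
$w\,\rho_{open} + (1-w)\,\rho_{closed}$ — the defining construction of an
ensemble-averaged map with known ground truth. Deliberate design choices:

* **Symmetric wells in free energy.** In internal coordinates the hinge
  marginal is $\sin\theta\, e^{-V(\theta)/k_BT}$; wells at $90° \pm 30°$
  make $\sin\theta$ equal at both minima, so the prior populations are
  exactly 50/50 and any recovered asymmetry is attributable to the data.
* **Aperiodic bead sizes** ($0.45(1 + 0.3\sin 2.4i)$ nm). A homogeneous
  chain produces featureless rods of density along which a model can slide
  freely; real macromolecules are lumpy. The size pattern locks the
  model-map registration so that composition errors cannot be absorbed by
  sliding.
* **Center-of-mass tether** (10 kJ/mol/nm² on the chain centroid). The
  analogue of center-of-mass motion removal in nonperiodic MD: replicas
  whose density overlap is momentarily poor feel almost no restraint force
  (the marginalized score is outlier-tolerant by design) and would
  otherwise diffuse bodily out of the map region on the benchmark
  timescale.
* **Stratified initialization.** The prior's equilibrium composition is an
  exact 50/50 mixture of the two minima, so replicas start alternating
  open/closed in the map frame (`initial_ensemble()`), the minimum-variance
  draw from the prior — the analogue of seeding production replicas from an
  equilibrated run after rigid-body docking.
* **Run protocol** (`run_two_state_experiment()` defaults): the restraint
  ramps to full strength over the first 5% of the run; hinge-angle
  metadynamics ($W_0 = 2$ kJ/mol, $\gamma = 8$, width 0.12 rad, pace 1000)
  deposits during the first 30% and fades adiabatically to zero by 70%;
  the final 25% of saved frames is the production window used for
  clustering and noise inference. Defaults: $N = 4$ replicas,
  $2\times10^6$ steps of $1.2\times10^{-5}$ ps, $\alpha = 0.1$ (the coarse
  bead model and 64-component data-GMM warrant a larger statistical error
  scale than a near-atomistic fit), 64-component data-GMM.
* **Clustering cutoff 0.5 nm** for the benchmark reports: it lies between
  the thermal RMSD spread within one state of the bead chain (≈0.3 nm
  pairwise) and the open/closed separation (≈1.6 nm). `gromos_cluster()`
  keeps the conventional 0.35 nm default for protein-scale work; GROMOS
  ties are broken deterministically by lowest frame index.

Cluster populations are mapped to ground-truth states by RMSD of the
cluster centers to the generating conformers; ambiguous mappings (two major
clusters claiming the same state while both states truly exist) are
reported as failures, never silently fixed. With spurious density injected
into the data-GMM (`inject_spurious_density()`, an off-structure shell of
components carrying a chosen weight fraction), the inferred per-component
relative errors separate cleanly: spurious components receive severalfold
higher noise, emulating how unmodelled ligand/detergent density is flagged
in real maps.

## What the benchmark does and does not show

The generator emulates the *logic* of validating ensemble recovery on
mixture maps: known conformers, known mixing weights, known noise. It does
not emulate atomistic force fields, experimental noise statistics,
CTF/reconstruction artifacts, or maps with pseudo-symmetry. Passing it
demonstrates that the scoring, averaging, sampling and analysis machinery
recover planted ensembles at desk scale; it says nothing about force-field
accuracy on real proteins.

Known limitations, found and kept documented rather than tuned away:

* Replica state *conversions* on the benchmark are diffusion-limited: the
  hinge drags two ~7-bead-lever lobes, so a conversion costs about
  $5\times10^5$ integration steps even with the metadynamics flood. The
  1:1 mixture (whose correct composition is preserved from the stratified
  start and confirmed by the restraint) and the single-state control
  (where the unheld replicas convert reliably) are robust across seeds;
  recovery of *unequal* mixtures depends on one stochastic conversion
  during the bias release and succeeds in only part of the seeds at the
  default run length. Longer runs sharpen this; the acceptance machinery
  reports what the configured run actually produces.
* Recovery is asymmetric: conversions into the more bent (60°) state are
  kinetically harder than into the straighter state, because the swinging
  lobe must pass close to the fixed lobe's density. A mixture with
  $w = 0.3$ therefore converges more slowly than $w = 0.7$.
* The a-posteriori noise estimator treats saved frames as independent;
  autocorrelation inflates the effective frame count, which is harmless
  for the relative (clean vs spurious) comparisons reported here.

## Problem sizes

The shipped tests and the acceptance script use: 30-bead chains with
64-component data-GMMs and $2\times10^6$-step runs for ensemble
experiments; a 60-bead, 200-component fit on a ~48³ grid for the map-fit
quality check; $10^4$ synthetic frames for noise-estimator recovery; and
≤ 50-frame instances for exact clustering comparisons. These sizes were
chosen so the full validation runs on a single desktop CPU in minutes while
every pipeline stage is still exercised end to end.
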