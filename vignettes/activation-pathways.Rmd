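---
title: "Adaptive biasing along activation pathways: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive biasing along activation pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(actipath)
```

# The problem

G-protein-coupled receptors interconvert between inactive and active
conformations separated by free-energy barriers of a few kcal/mol; ligands
of different efficacy shift the relative depths of those basins.  Direct
unbiased simulation of such transitions is hopeless on accessible
timescales, so this package implements the combined adaptive-biasing
strategy used in that field: a ratchet bias to *find* a transition pathway,
path collective variables to *parameterize* it, well-tempered metadynamics
to *reconstruct* the free energy along it, and reweighting to *project*
that free energy onto mechanistically meaningful descriptors (the ionic
lock, the toggle switch, the TM6 outward displacement).  All of it is
exercised on synthetic systems whose thermodynamics are known exactly.

Units everywhere: A, kcal/mol, degrees, ps, K; `k_B = 0.0019872041`
kcal/(mol K).  The ratchet order parameter chi is kept in nm so that its
elastic constant carries the conventional units kcal/(mol nm^2).

# The ratchet (adiabatic bias)

`ratchet_bias()` applies a one-sided harmonic penalty on an order parameter
chi(R) (here the fitted Calpha RMSD from the target state, flexible loops
excluded): whenever `chi - chi0` exceeds the smallest value reached so far,
the energy is `0.5 k (chi - chi0 - best)^2`; whenever it improves, the
penalty is zero and the record is updated.  Thermal motion toward the
target is therefore never opposed, and (weakly, for small `k`) never given
back.  The default `k = 10` kcal/(mol nm^2) holds backsliding only on the
order of `sqrt(k_B T / k)` ~ 0.25 nm, so on a toy system the ratchet is a
gentle pawl, not a winch: runs cross barriers thermally and are merely
prevented from undoing progress.  `k = 0` is legal and reproduces unbiased
dynamics bit-exactly (same random stream), which the tests rely on.

# Path collective variables

Given ordered references `R_1..R_n` and the metric `d(R, R_j)` = squared
fitted Calpha RMSD (A^2), the progress and distance variables are

    s = sum_j (j-1) exp(-gamma d_j) / ((n-1) Z),   Z = sum_j exp(-gamma d_j)
    z = -(1/gamma) log Z

Both are evaluated through log-sum-exp, so conformations far from every
reference still yield finite values.  The `(j-1)/(n-1)` normalization makes
s run from 0 (inactive end) to 1 (active end); the unnormalized variant
with s in [1, n] is available via `convention = "index"` for comparison
with the other common dialect.  z may dip slightly below zero when
references overlap; `validate_path()` flags this rather than hiding it.

The metric exponent `gamma` defaults to 4 A^-2 (= 1/0.25), the
canonical value for reference sets whose consecutive metric is about
0.25 A^2.  What matters physically is the product `gamma * d(R_j, R_{j+1})`;
`validate_path()` therefore reports `1/mean(consecutive d)` as the
recommended exponent, and the pipeline examples rebuild the reference set
with that value when the reference spacing differs from the canonical one.

Gradients of s and z with respect to coordinates use the envelope theorem
at the optimal superposition (`d(fit-RMSD^2)/dx = (2/N) (x_fit - r)R^T`),
chained through the linear coordinate map of the toy systems; they are
verified against finite differences at 1e-4 relative tolerance.

# Well-tempered metadynamics

Hills of height `w_t = w exp(-V(s,t)/(k_B dT))` are deposited every tau ps
(defaults `w = 0.4` kcal/mol, `tau = 8` ps, `dT = 10 T`, widths
`sigma_s = 0.1`, `sigma_z = 1` A^2), and the free energy is estimated as
`F = -(T + dT)/dT * V`, min-shifted.  Implementation choices:

* **Exact vs gridded evaluation.**  Hill heights at deposition and all
  recorded bias values use exact Gaussian summation; only the per-step
  *force* is interpolated linearly from gradient grids with spacing
  `sigma/5`.  Grids auto-expand (and replay all hills) whenever a CV
  leaves them -- hills are never silently truncated.
* **Walls.**  When `s` is biased it is confined to [-0.2, 1.2] by quartic
  walls (`k = 100` kcal/mol per unit^4); the physical range is [0, 1] and
  the margin leaves the endpoint basins undistorted.
* **Tail averaging.**  `free_energy_estimate(average_tail = 0.5)`
  time-averages the bias over the final half of the run before applying
  the prefactor.  The instantaneous estimator converges like 1/t from the
  early uneven filling; averaging damps both that transient and the
  hill-by-hill ripple without changing the asymptote.  The default is 0,
  so the estimator identity `F = -(T+dT)/dT V` holds exactly.
* **Integrators.**  BAOAB (inertial, default) and Euler-Maruyama
  overdamped; one Gaussian draw per step per coordinate, consumed
  identically whatever the bias, so `w = 0` runs are bit-identical to
  unbiased ones at the same seed.

# Reweighting

Two schemes, cross-validated against each other and against long unbiased
runs:

* `final_bias`: `w_i ~ exp(+V_final(cv_i)/kT)`; valid once the bias has
  stopped evolving.  Analyses discard the filling transient (the first
  30-40% of frames) before histogramming.
* `time_dependent`: `w_i ~ exp(+(V(cv_i, t_i) - c(t_i))/kT)` with the
  standard well-tempered offset
  `c(t) = kT log( int e^{(g/(g-1))V/kT} / int e^{V/((g-1)kT)} )`
  (g the bias factor), evaluated on a grid spanning the deposited hills.

Projections (`project_fes()`) use 100 bins in 1D and 60 x 60 in 2D by
default; no Jacobian correction is applied to angular order parameters
(documented, not silently assumed).  Unoccupied bins are flagged `NA`,
never extrapolated.  `find_basins_and_barriers()` prunes minima whose
prominence is below `min_depth` (default 0.25 kcal/mol), reports each
transition state as the segment maximum (1D) or the flooding saddle --
the min-max path barrier -- (2D), and stars the most stable basin, breaking
ties below 0.05 kcal/mol toward the lower coordinate.

# Building the path from ratchet runs

Pooled ratchet trajectories are clustered with average linkage (UPGMA, via
`stats::hclust`) on the same fitted-RMSD dissimilarity used for chi.  The
tree is cut at 30 clusters and 10 references are selected (defaults from
the canonical protocol): each cluster is represented by its *medoid*
(stays in sampled conformation space, unlike a mean structure), medoids
are ordered by the progression coordinate `rmsd(., inactive) -
rmsd(., active)`, and "homogeneously covering the pathway" is
operationalized as equal spacing in cumulative consecutive-RMSD arc
length, always anchoring the endpoint-nearest medoids as j = 1 and j = n.

# The synthetic systems, and what they do and do not show

`make_double_well()` provides 1D potentials whose stationary points and
energies are solved exactly from the cubic `dU/dx = 0`, so recovery,
barrier and population tests compare against closed forms, not against
another simulation.

`make_mini_receptor()` is a 31-atom bead model: four pseudo-helices of six
CA beads, one flexible linker bead excluded from every mask, and labelled
pseudo-residues 2.41, 3.50 (NH1/NH2), 6.30 (OE1/OE2), 6.35 and 6.48
(N/CA/CB/CG).  The two end states are built to the canonical descriptor
values -- ionic lock 3 A vs 12 A, toggle switch 163 deg vs 55 deg, TM6
displacement 0 vs 5.9 A -- with the TM6 outward swing calibrated by root
finding so the *post-alignment* displacement is exact.  Its conformational
energy is a double well in the activation progress coordinate (barrier
3 kcal/mol, active state 1 kcal/mol below inactive by default, the scale
of agonist-shifted landscapes) plus three stiff transverse modes
(50 kcal/(mol A^2)) orthogonal to rigid motions and to the activation
mode.  On the carboxylate naming: glutamate's terminal oxygens carry PDB
names OE1/OE2 (epsilon in IUPAC terms); the traditional "delta-oxygen"
phrasing for the ionic lock maps to exactly these two atoms.

Because conformations depend linearly on a handful of coordinates, the
model has real geometry (fits, dihedrals, clustering all operate on
Cartesian coordinates) but idealized energetics: no rugged landscape, no
anisotropic diffusion along the path, no slow orthogonal degrees of
freedom, no solvent friction gradients.  Passing tests therefore
demonstrate the *estimators and the plumbing* are correct -- they say
nothing about force-field accuracy or sampling adequacy on a real
receptor, where convergence must be judged with `convergence_monitor()`
on the actual run.

# Problem sizes used by the tests and the acceptance script

Chosen so each estimate is comfortably converged for its tolerance:
double-well recovery, 2.4e6 overdamped steps (dt 0.004 ps, hills every
250 steps) per seed, three seeds; reweighting oracle, 1.5e6 unbiased steps
vs a 10x shorter biased run; mini-receptor pipeline, 10 ratchet runs of
12000 steps, ~150 pooled frames, 80000 biased steps on (s, z).  The
mini-receptor pipeline uses `sigma_z = 0.05` A^2: with its recommended
gamma ~ 12 A^-2 the sampled z range is a few tenths of an A^2, and sigma_z
is chosen as roughly a fifth of it -- the same proportionality the
canonical `sigma_z = 1` A^2 has to a receptor-scale z range.

# Known limitations

1D/2D bias grids only (matching the two path variables); no multiple
walkers; no kinetic rates from the biased runs; no block-error analysis on
the surfaces (the block standard errors in `population_estimate()` cover
the population summaries); no periodic-boundary imaging; descriptors
assume identical atom ordering between query and reference conformations.
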