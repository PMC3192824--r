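# actipath

Adaptive biasing along receptor activation pathways, in R.

GPCRs (and many other proteins) switch between inactive and active
conformations over free-energy barriers far beyond unbiased simulation.
`actipath` implements the standard combined strategy for mapping such
landscapes, end to end and fully testable at desk scale:

1. **Ratchet-and-pawl (adiabatic biased) dynamics** generate transition
   pathways: a harmonic penalty `½k(χ − χ₀ − min_{s<t} χ)²` acts only when
   the order parameter χ (fitted Cα RMSD from the target, in nm) worsens
   relative to its best value so far.
2. **Average-linkage clustering** of the pooled runs and medoid selection
   produce an ordered set of reference conformations R₁..Rₙ
   (tree cut at 30 clusters, n = 10 references by default).
3. **Path collective variables** measure progress along and distance from
   that pathway, with d(R, Rⱼ) the squared fitted Cα RMSD:

       s = Σⱼ (j−1) e^(−γ d(R,Rⱼ)) / ((n−1) Z),   Z = Σⱼ e^(−γ d(R,Rⱼ))
       z = −(1/γ) ln Z,                            γ = 4 Å⁻² by default

4. **Well-tempered metadynamics** on (s, z): Gaussian hills (σ_s = 0.1,
   σ_z = 1 Å², w = 0.4 kcal/mol, τ = 8 ps) whose height decays as
   `w·exp(−V/(k_B ΔT))` with ΔT = 10 T; the free energy is
   `F = −(T+ΔT)/ΔT · V`.
5. **Reweighting** (final-bias and time-dependent schemes) projects the
   unbiased statistics onto activation descriptors computed from labelled
   structures via Ballesteros–Weinstein maps: the ionic-lock distance
   d_IL (R3.50 ↔ E6.30), the toggle-switch dihedral χ_TS (χ₁ of W6.48),
   and the TM6 outward displacement Δd_TM6.

Analytic double wells and a labelled 31-bead "mini-receptor" with
constructed inactive/active end states (d_IL 3 → 12 Å, χ_TS 163° → 55°,
Δd_TM6 0 → 5.9 Å) make every stage verifiable against exact results —
no structure downloads, no force fields.

## Worked example

Recover a known 3 kcal/mol double well with well-tempered metadynamics:

```r
library(actipath)

pot <- make_double_well(barrier = 3, asymmetry = 0)   # exact minima at ±1
sys <- potential_system(pot, q0 = -1)
cfg <- wt_config(w = 0.4, tau = 1, temperature = 300, sigma = c(x = 0.1))
run <- run_metadynamics(sys, cfg, steps = 2400000, dt = 0.004,
                        integrator = "overdamped", seed = 1, pace = 250)
fes <- free_energy_estimate(run$bias, average_tail = 0.5)
find_basins_and_barriers(fes)
```

```
  type          x          F  barrier  star
1  min -0.9821165 0.01417161       NA  TRUE
2   ts -0.1478988 3.10814525 3.108145 FALSE
3  min  1.0245154 0.00000000       NA FALSE
```

Two minima at x ≈ ±1 with near-equal free energy (the well is symmetric;
the 0.014 kcal/mol split is residual sampling noise, and the star lands on
the lower-x basin by the documented ≤ 0.05 kcal/mol tie-break) separated
by a barrier within ~0.1 kcal/mol of the exact 3.0.

The same machinery runs the full receptor pipeline:

```r
mr   <- make_mini_receptor(seed = 1)           # barrier 3, active −1 kcal/mol
sys  <- mini_receptor_system(mr)
pool <- run_abmd(sys, mr$active, k = 10, n_runs = 10, steps = 12000, seed = 5)
confs <- c(list(mr$inactive), pool_conformations(pool, sys, every = 16),
           list(mr$active))
D    <- pairwise_rmsd(confs, mr$ca_mask)
prs  <- select_references(average_linkage(D), confs, D, k_cut = 30,
                          n_refs = 10, inactive = mr$inactive,
                          active = mr$active, mask = mr$ca_mask)
prs  <- path_reference_set(prs$refs, gamma = validate_path(prs)$gamma_recommended,
                           mask = prs$mask)
md   <- run_metadynamics(attach_path_cv(sys, prs),
                         wt_config(sigma = c(s = 0.1, z = 0.05)),
                         steps = 80000, seed = 7, pace = 200)
w    <- frame_weights(md$frames, md$bias)
project_fes(md$frames, w, fes_axis("s", 40, c(-0.05, 1.05)))
```

A thin command-line wrapper (`inst/cli/actipath`) exposes the same steps
as subcommands (`simulate-toy`, `abmd`, `build-path`, `metad`, `reweight`,
`descriptors`, `fes`) over plain-text PDB/XYZ/HILLS/COLVAR files.

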