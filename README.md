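# cdslab

Trajectory analysis for protein formulations with cyclodextrin
excipients at air-water and ice-water interfaces.

Proteins in liquid formulations denature at interfaces; cyclodextrins
(CDs) — seven-glucose rings with a hydrophobic cavity bounded by a
primary (C6) and a secondary (C2/C3) rim — are excipients that can
protect or destabilise a protein depending on where they accumulate,
how their cavity is oriented at the surface, and whether they include
protein residues. `cdslab` provides the analysis layer for
molecular-dynamics studies of such systems:

* **Interfacial statistics** — per-frame interface location (air:
  50%-of-plateau water density; ice: top of the frozen group),
  bulk-normalised density profiles along z, CD rim-orientation profiles
  (cos θ of the cavity axis vs +z), and per-frame proximity counts
  (CDs within a cutoff of the protein or ice surface).
* **Host-guest geometry** — cavity centroid/axis/radius from rim atoms,
  cylinder-test detection of residue inclusion, per-residue inclusion
  frequencies, CD self-aggregation (contact-graph components), and a
  hydration-layer partition coefficient.
* **Collective variables** — radius of gyration; α-helix content as a
  smooth switching-function count over six-residue windows,
  S(x) = (1 − x⁸)/(1 − x¹²) with x = RMSD/r₀, r₀ = 0.08 nm; distance of
  the protein COM from the interface; and dRMSD,
  sqrt[(1/P) Σ (d(xᵢ,xⱼ) − d(xᵢᴮ,xⱼᴮ))²] over reference pairs with
  0.1 nm < d_ref < 3.0 nm.
* **Metadynamics reweighting** — Tiwary-Parrinello weights
  w_t ∝ exp((V(s_t,t) − c(t))/kT) with
  c(t) = kT·ln[∫e^{γV/((γ−1)kT)}ds / ∫e^{V/((γ−1)kT)}ds] by grid
  quadrature; weighted CV distributions, free-energy surfaces,
  multiple-walker pooling, and last-window convergence drift.
* **Conformational mapping** — GROMOS (Daura) greedy clustering at
  0.1 nm backbone RMSD with deterministic tie-breaking, Kabsch
  superposition, per-residue Q scores
  q_i = ⟨exp(−(r_ij − r'_ij)²/(2|i−j|^0.15))⟩ (CA-CA distances in Å),
  unstable patches (q < 0.5), cross-system patch frequencies and
  overlap with inclusion frequencies and aggregation-prone regions.
* **Synthetic systems** — slab trajectories with planted density /
  orientation / inclusion structure, RMSD-controlled conformational
  ensembles, and a 1-D well-tempered metadynamics toy sampler with an
  analytically known unbiased distribution. These drive the whole test
  suite; no MD engine is required.

File formats: PDB and GRO structures, multi-model PDB and DCD
trajectories, PLUMED-style COLVAR/HILLS whitespace text.

## Worked example

Generate a slab with a surface-peaked CD layer (planted peak at
z = 4.5 nm, planted mean cos θ = 0.8) around a helical protein, and
analyse it:

```r
library(cdslab)

tr <- make_slab_trajectory(30,
        profile_spec("surface_peaked", peak_z = 4.5, n_molecules = 20),
        orientation_spec("mean_cos", mean_cos = 0.8),
        protein = list(n_res = 12, center = c(3, 3, 3)), seed = 7)

density_profile(tr, "cd", n_bins = 60, liquid_region = c(0, 6))
#> cdx_density_profile of 'cd': 60 bins, 30 frames, peak 7.35 at z = 4.50 nm

rim_orientation_profile(tr)$global_mean
#> [1] 0.7997817

proximity_count(tr, reference = "protein", cutoff = 2)[1:5]
#> [1] 12 12 12 11 13

head(cv_series(tr), 3)
#>   time    rg alpha d_interface drmsd weight
#> 1    0 0.554     7       3.001    NA      1
#> 2    1 0.554     7       3.001    NA      1
#> 3    2 0.554     7       3.001    NA      1
```

The density profile recovers the planted peak bin exactly (7.35 means a
7-fold enrichment over bulk), the orientation estimator recovers the
planted mean cosine to three digits, and the CV series shows a fully
helical protein (α = 7 of 7 possible windows) sitting 3 nm below the
interface.

Reweighting a toy well-tempered metadynamics run (bias factor 15,
initial height 2 kJ/mol, 1 hill/ps, 10⁵ steps) recovers the analytic
double well U(s) = 5(s² − 1)² within a fraction of kT:

```r
run <- sample_metad_double_well(metad_params(), n_steps = 1e5, seed = 42)
f   <- toyrun_fes(run)$fes
#>       s   fes  analytic
#>  -1.00  0.000    0.000
#>   0.04  5.052    4.984
#>   1.00  0.455    0.000
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cdx.R", package="cdslab"))')" \
    profile slab_traj.pdb --group cd --kind air --out profile.tsv
```

Subcommands: `info`, `profile`, `cv`, `reweight`, `cluster`, `qres`,
`inclusion`, `aggregates`, `simulate-fixtures`.

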