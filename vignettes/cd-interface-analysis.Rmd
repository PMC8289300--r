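---
title: "Analysing cyclodextrin-protein systems at interfaces with cdslab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing cyclodextrin-protein systems at interfaces with cdslab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdslab)
```

## The problem

Proteins in liquid formulations denature at interfaces: the air-water
surface of a shaken vial and the ice-water front of a freezing cycle both
present an anisotropic environment that can unfold adsorbed molecules.
Cyclodextrins (CDs) — cyclic oligosaccharides of seven glucose units with a
hydrophilic outer surface, a hydrophobic cavity, a *primary* rim of C6
atoms and a *secondary* rim of C2/C3 atoms — are surface-active excipients
used to protect protein drugs against exactly this stress. Whether a given
CD protects or harms depends on where it accumulates (surface vs bulk),
how its cavity is oriented at the surface, whether it includes protein
side chains in its cavity, and how all of that changes the protein's
conformational ensemble.

`cdslab` implements the trajectory-analysis pipeline needed to answer
those questions from molecular-dynamics output: interfacial density and
orientation statistics, cavity-inclusion detection, the collective
variables of parallel-bias metadynamics together with Tiwary-Parrinello
reweighting, GROMOS-style conformational clustering, and per-residue
structural-similarity (Q) mapping of unstable patches. Running MD itself
is out of scope; the package consumes structures (PDB/GRO), trajectories
(multi-model PDB or DCD) and PLUMED-style COLVAR/HILLS text.

Because production trajectories are hundreds of nanoseconds of atomistic
MD, every statistical operation here is validated instead on *synthetic*
systems with planted, analytically known structure. The synthetic module
is first-class code: its generators define the conditions under which the
pipeline's estimators are tested.

## Conventions

* Units: nm, ps, kJ/mol throughout; PDB Angstrom values are converted on
  input. The one deliberate exception is the Q score (below).
* Slab geometry: the interface normal is +z. z is treated as
  non-periodic in all interface analyses even if the box is formally
  periodic — a vacuum or frozen slab breaks the symmetry.
* Residue numbering is 1-based, matching PDB labels.
* Frozen (ice) atoms are identified by an explicit `frozen` tag in the
  topology, never inferred from coordinates.

## Interfaces and density profiles

`locate_interface()` finds, per frame, the z where the water density
first falls to 50% of its bulk plateau (air), or the top of the frozen
group (ice). Per-frame location means protein-induced surface deformation
does not bias interface distances.

`density_profile()` histograms molecular heavy-atom centres of mass along
z and normalises by the mean density over the liquid region, so bulk
reads 1.0 and surface enrichment reads directly as values above 1. The
bin width default (0.1 nm) resolves the CD rim separation (~0.4 nm)
without starving counts. Orientation is summarised per CD as
cos θ between the cavity axis (primary-rim centroid to secondary-rim
centroid) and +z: cos θ → 1 means the secondary rim, hence the open
cavity, faces the gas phase.

```{r density-example}
tr <- make_slab_trajectory(20,
        profile_spec("surface_peaked", peak_z = 4.5, n_molecules = 20),
        orientation_spec("mean_cos", mean_cos = 0.8), seed = 1)
dp <- density_profile(tr, "cd", n_bins = 60, liquid_region = c(0, 6))
dp
rim_orientation_profile(tr)$global_mean
```

## Inclusion, aggregation, hydration layer

The inclusion criterion is a transparent one-point cylinder test: a
residue is included when its side-chain heavy-atom centroid (CA for
glycine and backbone-only models) lies within `radial_max` (0.45 nm) of
the cavity axis and `axial_max` (0.40 nm) of the cavity centre. The
criterion is monotone in both thresholds and checkable against a
brute-force geometric oracle, which is exactly how the tests treat it.
Both thresholds are configuration knobs, not claims about any particular
published criterion.

CD self-aggregation is the connected-component structure of the CD-CD
contact graph (any heavy-atom pair within 0.35 nm); the mean aggregate
size is the number of CDs divided by the number of components.

The hydration-layer partition coefficient
K = (n_CD,shell / n_water,shell) / (n_CD,bulk / n_water,bulk) uses the
molecule's heavy-atom centre of mass to decide shell membership for
*both* species: with a minimum-atom-distance criterion a large molecule
would sit "in the shell" far more often than a water even under uniform
placement, biasing K upward. Counts are pooled over frames before the
ratio is taken — per-frame ratios are undefined whenever a frame has an
empty shell, which is the typical situation at realistic counts. Without
explicit waters the water counts are replaced by shell/bulk volumes from
seeded Monte-Carlo integration (10^4 points).

## Collective variables

* **Radius of gyration**: mass-weighted, over the protein selection.
* **α-helix content**: for every window of six consecutive residues, the
  backbone (N, CA, C) RMSD to an ideal helical template after optimal
  superposition is passed through the rational switching function
  S(x) = (1 − x^8)/(1 − x^12), x = RMSD/r0, r0 = 0.08 nm. The sum over
  windows is a continuous count in [0, n_res − 5]; there is no hard
  cutoff, so the CV is continuous in the coordinates.
* **Interface distance**: |z_COM(protein) − z0|.
* **dRMSD**: root-mean-square difference of intramolecular pairwise
  distances between a frame and a reference, restricted to atom pairs
  whose *reference* distance lies between 0.1 and 3.0 nm. The pair list
  is built from the reference only and never re-filtered on the frame;
  the backbone is taken as N, CA, C plus O when present (a documented
  superset choice — whether published dRMSD values used all backbone
  atoms or CA only is generally not stated, so the selection is
  configurable).

## Metadynamics reweighting

Well-tempered metadynamics deposits Gaussians of decaying height; the
recorded hill heights are the heights actually deposited, so
`bias_on_grid()` is a plain Gaussian sum. The Tiwary-Parrinello offset

c(t) = kT · ln [ ∫ e^{γV/((γ−1)kT)} ds / ∫ e^{V/((γ−1)kT)} ds ]

is evaluated by trapezoidal quadrature on a grid after every deposition
(grid quadrature rather than hill-by-hill analytic integration works for
any bias shape and is refinement-tested to 1e-4 kJ/mol). Frame weights
are w_t ∝ exp((V(s_t, t) − c(t))/kT), normalised to mean 1. Free-energy
surfaces are −kT ln p with the minimum at zero; empty bins are NA.

For parallel-bias runs the frames carry the *total* applied bias as
written by the production engine, so weights are computed from the COLVAR
bias column directly; per-CV biases are never recombined. Multiple
walkers are pooled after per-walker weighting, before histogramming.

### The toy validation system

A 1-D overdamped Langevin walker on U(s) = k(s² − 1)², k = 5 kJ/mol
(wells at ±1, barrier 2 kT at 300 K), is biased with the production-like
parameters bias factor γ = 15, initial height 2 kJ/mol, 1 hill/ps.
The sampler's own free parameters were fixed at design time:

* dt = 0.01 ps, mobility 0.5 nm²/(kJ/mol·ps): the Euler scheme is
  stable against the steepest curvature the walker can reach, and the
  in-well relaxation time (~0.05 ps) is far below the deposition period.
* Hill width σ = 0.2, comparable to the thermal well width
  √(kT/U'') ≈ 0.25 — the standard metadynamics rule of thumb; much
  narrower hills leave kJ-scale ripples in the reconstructed surface.
* A *reflecting boundary* at |s| = 2 plays the role of the wall
  restraints of production setups. The well-tempered offset grows
  without bound (slowly), so an unconfined walker eventually spills over
  any finite potential wall; stiff walls are Euler-unstable, while
  reflection is exact and unconditionally stable. The zero-bias
  stationary law is therefore the Boltzmann distribution of U truncated
  to [−2, 2] (`toy_boltzmann_density()`).
* Runs of 10^5 steps (1000 ps, 1000 hills) recover the analytic surface
  within ~0.3 kJ/mol at the wells across seeds; the first 20% of each
  run is discarded as the transient before the bias stabilises.

The zero-bias control is compared to the Boltzmann law with a
Kolmogorov-Smirnov test on subsamples taken every 5 ps — beyond the
measured well-hopping time — because the empirical CDF of a correlated
chain converges with the effective, not nominal, sample size; testing
all 10^5 correlated steps against the 10^5-sample critical value would
reject any finite-rate dynamics.

```{r toy-example, eval = FALSE}
run <- sample_metad_double_well(metad_params(), n_steps = 1e5, seed = 42)
out <- toyrun_fes(run)
head(out$fes)
```

## Conformational analysis

`daura_cluster()` implements the GROMOS greedy scheme: the frame with the
most neighbours (pairwise fitted RMSD over N/CA/C below 0.1 nm) becomes a
centroid, it and its neighbours are removed, and the loop repeats. Ties
on the neighbour count go to the lowest frame index — the original
algorithm leaves tie-breaking open, and a stated rule makes the result
deterministic and oracle-checkable. Clusters are formed on unweighted
RMSD geometry; metadynamics weights enter only the reported populations,
matching the usual practice of reweighting before ranking conformations.

Multiple-structure alignment machinery (STAMP-style) is deliberately
replaced by pairwise Kabsch superposition onto a designated reference:
the compared structures are the same protein, so sequence-structure
alignment adds nothing.

### The Q score

For residues i, j with |i − j| ≥ 2,

q_i = (1/N_i) Σ_j exp( −(r_ij − r'_ij)² / (2 σ_ij²) ),  σ_ij² = |i−j|^0.15,

where r and r' are CA-CA distances in the two structures, **in
Angstrom**. The width law |i−j|^0.15 is of order 1-2 and is calibrated
on Angstrom distances in the Q-score literature; on an nm reading a
0.5 nm backbone displacement would leave q ≈ 0.97 and the q < 0.5
unstable-patch rule could never fire. Internal distances make the score
superposition-invariant; the |i − j| ≥ 2 exclusion (self and adjacent
residues) and the exponent are exposed as arguments. Residues with
q < 0.5 are reported as unstable patches; `patch_frequency()` counts, per
residue, the fraction of systems flagging it (optionally stratified by
excipient), and `crossref_patches()` joins patch frequencies with
inclusion frequencies and aggregation-prone-region (APR) lists parsed
from `PHE13-CYS17`-style ranges.

```{r qres-example}
h <- make_ideal_helix(30, seed = 2)
ca <- h$frame$coords[h$topology$role == "protein_backbone_CA", ]
p <- perturb_to_rmsd(ca, 0.3, seed = 7)
summary(qres(ca, p)$q)
```

## What the synthetic generators do and do not emulate

The slab generator plants i.i.d. per-frame CD positions and
orientations, single-site waters, and a rigid helical protein. That is
enough to give every estimator a known ground truth (uniform and peaked
density laws, exact mean cos θ, exact inclusion occupancy), but it has no
dynamics: no autocorrelation, no adsorption kinetics, no capillary waves,
no solvent structure. Passing the parameter-recovery tests therefore
shows the *estimators* are correct, not that any physical claim about a
real formulation holds. The toy metadynamics system is one-dimensional by
construction; it validates the reweighting machinery, not multi-CV bias
deposition, which the package intentionally does not perform.

Problem sizes in the tests and the acceptance script (10^5-step toy
runs, 50-60-frame slabs with 30-50 CDs, 20-frame cluster sets, 60-residue
chains) were chosen as the smallest sizes at which the planted parameters
are recovered at the stated statistical tolerances.

## Numerical and degenerate-input choices

* Kabsch superposition rejects collinear selections (the rotation is
  underdetermined) and always returns a proper rotation.
* `drmsd_spec()` errors when the cutoffs exclude every pair.
* `alpha_helix_content()` skips (with a warning) windows missing
  backbone atoms; `qres()` errors on missing CA.
* The switching function is evaluated by its limit 8/12 at x = 1.
* Empty histogram bins yield NA free energies, never ±Inf.
* `estimate_ct()` refuses grids coarser than half a hill width.
* All generators are pure functions of (spec, seed); rerunning with the
  same seed reproduces byte-identical trajectories.

## Known limitations

* No intrinsic-surface (capillary-wave) correction: density profiles use
  the mean interface per frame.
* The inclusion test uses a single representative point per residue; a
  fractional-volume criterion would grade partial insertions.
* The GRO reader supports orthorhombic boxes only.
* Q-score termini have fewer contributing pairs and correspondingly
  noisier values; no end-weighting is applied.
* XTC trajectories are not readable in this stack; convert to DCD or
  multi-model PDB.
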