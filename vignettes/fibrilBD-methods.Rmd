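---
title: "Modelling glycosaminoglycan binding to amyloid fibrils with fibrilBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glycosaminoglycan binding to amyloid fibrils with fibrilBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilBD)
```

## The problem

Amyloid fibrils of the tau protein colocalize with glycosaminoglycans
(GAGs) such as heparan sulfate in neurodegenerative disease, and heparin
— the highly sulfated in-vitro analog of heparan sulfate — both seeds tau
aggregation and blocks fibril uptake by cells. A parallel in-register
amyloid fibril stacks identical monomers every ~4.8 Å, so each charged
side chain repeats along the axis as a "ladder": a lysine in the
cross-section becomes a line of positive charge along the whole fibril.
Polyanionic GAG chains are steered onto these basic ladders by long-range
electrostatics and then held by salt bridges between their anionic groups
and lysine/arginine side chains.

fibrilBD reproduces this dock-and-refine picture at desk scale:

1. **Structure generators** build an idealized fibril (a charged
   cross-section template stacked rigidly) and a linear heparin-like
   glycan of alternating glucosamine/iduronate units carrying sulfate,
   sulfamido and carboxylate charged groups (HCGs).
2. **Rigid-body Brownian dynamics (BD)** diffuses the glycan around the
   fixed fibril in a Debye–Hückel screened-Coulomb field until it either
   *reacts* (binds), *escapes*, or exhausts its step budget.
3. **Analysis** turns trajectory ensembles into per-site binding tables
   with binomial confidence intervals, orientation-filtered and
   Ward-clustered bound poses, salt-bridge contact statistics, contact
   frequency maps, an energy-per-contact regression, and sulfur density
   maps.

## The model

### Electrostatics

The field is a screened Coulomb (Yukawa) sum over formal point charges,

$$U(r) = \frac{k_e\, q_i q_j}{\varepsilon}\,\frac{e^{-\kappa r}}{r},
\qquad
\kappa^{-1} = \sqrt{\frac{\varepsilon \varepsilon_0 k_B T}{2 N_A e^2 I}},$$

with $k_e = 332.0637$ kcal·Å/(mol·e²). At the default solvent
(310.15 K, dielectric 78, ionic strength 150 mM) the Debye length is
about 8 Å. Charges are formal: +1 e on each lysine NZ and arginine
guanidinium centre, −1 e on each fibril carboxylate oxygen and on the
oxygen centroid of every glycan HCG. This replaces a nonlinear
Poisson–Boltzmann solution: linear screening preserves the qualitative
steering mechanism, is exactly testable against closed forms, and needs
no molecular surface. Desolvation, dielectric boundaries and ion
correlation are deliberately absent, so absolute energies are not
comparable to force-field/continuum estimates; only relative and
structural statements are meaningful.

Excluded volume is a soft $r^{-12}$ wall between every fibril atom and
every glycan charge centre, $E = 0.3\,(3.5/r)^{12}$ kcal/mol. The 3.5 Å
pair-contact distance (1.75 Å per bead) was chosen so that the
electrostatic pair minimum of a +1/−1 contact in $\varepsilon = 78$ lies
*inside* the 4.5 Å salt-bridge cutoff used by the contact analysis; a
harder or wider wall would make the standard salt-bridge definition
nearly unsatisfiable for a formal-charge bead model.

### Brownian dynamics

The glycan is a rigid body (no glycosidic flexibility), propagated with
the Ermak–McCammon overdamped update

$$\Delta \mathbf{r} = \frac{D_t}{k_B T}\mathbf{F}\,\Delta t +
\sqrt{2 D_t \Delta t}\,\boldsymbol{\xi}, \qquad
\Delta \boldsymbol{\phi} = \frac{D_r}{k_B T}\mathbf{T}\,\Delta t +
\sqrt{2 D_r \Delta t}\,\boldsymbol{\xi}_r ,$$

where $D_t$ and $D_r$ follow Stokes–Einstein(–Debye) from the configured
hydrodynamic radius (default 8 Å, an order-of-magnitude value for a
short GAG) and the water viscosity at the configured temperature
(Vogel–Fulcher–Tammann fit). The timestep is adaptive with the two
published extremes: 1.0 ps far from the fibril, 0.01 ps whenever any
glycan reference sulfur is within `near_shell` of a fibril reference
atom. `near_shell` defaults to 15 Å — twice the reaction distance — so
the fine timestep always engages before a reaction can trigger.

Trajectories start uniformly on the *b*-sphere with uniform random
orientation and end by one of three outcomes, in the
Northrup–Allison–McCammon accounting:

* **reacted** — at least 3 reference-atom pairs simultaneously within
  7.5 Å. Reference atoms are S2/S6 sulfurs on the glycan and NZ (Lys) or
  CZ (Arg) of solvent-exposed basic residues on the fibril. The bound
  site is the residue (pooled across layers) owning the most pairs, ties
  to the lowest residue number.
* **escaped** — centroid crosses the *q*-sphere.
* **max_steps** — step cap reached; recorded explicitly, never dropped.

The per-site binding percentage always uses the full trajectory count as
denominator. `b_radius` defaults to the fibril bounding radius plus
three Debye lengths (the force is quasi-centrosymmetric there) and
`q_radius` to $10\,b$; the bundled desk-scale configurations shrink
`q_radius` and cap steps so ensembles finish in minutes. Each trajectory
draws from a private RNG substream derived from (seed, pair, replicate),
so ensembles are reproducible and order-independent.

### Pose and contact analysis

* **Orientation filter**: the angle between the glycan chain axis
  (first→last ring centroid) and the fibril axis (third→third-from-last
  layer centroid; first→last for fibrils shorter than six layers) is
  folded into [0°, 90°]; poses with angle ≤ 45° (inclusive) are
  *aligned*.
* **Clustering**: each bound pose is described by the distance from each
  glycan sulfur to the nearest atom of the binding-site residues.
  Agglomerative Ward clustering runs on the pairwise distance-RMSD
  matrix (`sqrt(mean((f1-f2)^2))`) via the Lance–Williams update
  (`hclust` method `ward.D2`). Ward on a precomputed non-Euclidean
  dissimilarity is an accepted extension of the minimum-variance
  criterion. Default 10 clusters; the medoid (member minimizing summed
  within-cluster distance) represents each cluster and is locally
  refined by rigid-body steepest descent — a stand-in for all-atom
  refinement that tightens contacts but adds no flexibility.
* **Salt bridges**: a contact is a cationic nitrogen (Lys NZ, Arg
  NH1/NH2) within 4.5 Å — inclusive, to pin down the floating-point
  boundary — of an HCG oxygen (sulfate, sulfamido and carboxylate
  oxygens all count). Contacts are collapsed to residue × layer × HCG
  granularity: each ladder rung counts separately for the residue
  statistics (so "six K311 residues bound" is expressible on a 10-layer
  fibril), while an HCG counts once however many rungs it touches.
  Per-frame medians use the *lower* median so integer counts report as
  integers. Frequency maps pool layers: a cell is the fraction of frames
  in which that (unit, group) touched that residue at all. The
  N-sulfamido group appears as its own column by default and can be
  folded out for parity with figure conventions that show only
  OS2X/OS6X/O6X.
* **Tables**: the binomial confidence half-width is one standard error,
  $100\sqrt{p(1-p)/n}$ — the convention that reproduces printed values
  such as 24.2 ± 0.1 for 48,463/200,000 (a 1.96 multiplier does not).
  Percentages print with the same number of decimals as the half-width
  rounded to one significant figure, which is why 21,006/200,000 prints
  as 10.50 ± 0.07 but 50,771/200,000 as 25.4 ± 0.1.

## The synthetic generator: what it does and does not emulate

The cross-section template places a coarse CA trace on a line or a
C-shaped arc with charged side-chain *tips* only (NZ, CZ/NH1/NH2,
carboxylate oxygens) pointing outward. The packaged tau-like template
carries the 73-residue fibril core sequence (residues 306–378) with
K370, D314 and E372 marked buried, giving exactly the eleven
solvent-exposed basic sites K311, K317, K321, K331, K340, K343, K347,
R349, K353, K369, K375. Note that solvent exposure is *declared*, not
computed: the generator has no surface-area machinery, and an outward
side-chain heuristic is offered only for imported PDB files. Residue 372
follows the standard sequence (Glu); reports that write "D372" are read
as naming the acidic ladder at that position.

The glycan is a straight chain with an 8.7 Å disaccharide repeat (the
helical heparin repeat), odd units glucosamine and even units iduronate,
counted from unit 1 at the non-reducing end — matching the convention in
which odd-numbered units are glucosamine. Every sulfate/sulfamido/
carboxylate group carries −1 e; a fully sulfated octasaccharide has 16
HCGs and net charge −16 e. Real heparin helicity, ring pucker, glycosidic
torsions, counterion condensation and partial protonation are all out of
scope. Consequently, passing tests demonstrate the *mechanistic logic* —
steering onto basic ladders, monotonic effects of sulfation and chain
length, the arithmetic of the published tables — not quantitative
binding probabilities for real tau polymorphs, which in the source
protocol required experimentally derived structures, a Poisson–Boltzmann
field and cluster-scale sampling.

## Numerical choices

* Units: kcal/mol, Å, e, ps throughout; $k_B$ = 0.0019872 kcal/mol/K.
* Zero ionic strength switches to pure Coulomb and reports an infinite
  Debye length rather than failing.
* Deep soft-core overlaps are distance-clamped at 0.5 Å so energies stay
  finite; the BD integrator additionally aborts with a diagnostic on any
  non-finite force.
* The compiled trajectory kernel consumes R's RNG (3 translation + 3
  rotation normals per step), so a single `set.seed` reproduces a
  trajectory exactly, and the R-level `bd_step` can replay the kernel
  step for step — a property the test suite asserts.
* The rotation matrix is re-orthonormalized every 1000 steps
  (Gram–Schmidt) to contain drift.
* Cluster merge ties and site-attribution ties resolve to the lowest
  index/residue number for cross-platform determinism.
* Density voxels are half-open $[lo, hi)$; boundary points go to the
  higher index. Out-of-grid depositions are tallied in an overflow
  counter so mass conservation is checkable exactly.
* Gaussian smoothing of density maps renormalizes to conserve total
  counts despite edge truncation.

## Problem sizes

The bundled tests and the demo configuration use a two-ladder benchmark
fibril (one Lys ladder, one Glu ladder, 10 layers) with an
octasaccharide, `b_radius` 45 Å, `q_radius` 120 Å and a 20,000-step cap:
a few hundred trajectories complete in about a minute on one CPU, enough
for one-sided binomial comparisons between sulfation patterns and chain
lengths. Diffusion-law checks use 100 field-free replicas of 10,000
steps. The published scale — 20 fibril conformations × 10 glycan poses ×
1000 trajectories = 200,000 — is exercised as an ensemble-bookkeeping
contract with zero-step trajectories. A full-physics run at that scale
is a matter of compute budget, not of code: `run_ensemble` accepts it
unchanged.

## Known limitations

* Formal charges in a uniform dielectric understate short-range
  specificity; the energy-per-contact regression recovers *linearity*,
  not published kcal/mol magnitudes.
* The fibril is perfectly rigid and layers are exact copies; fibril
  conformational clustering is therefore degenerate on synthetic input
  (it is exposed for imported ensembles).
* Rigid-glycan BD cannot express the wrapped or kinked bound
  conformations that flexible-chain refinement finds; the orientation
  filter and contact statistics operate on rigid poses.
* The PDB reader assigns layers by chain or axial binning and assumes a
  single model; it is a convenience for visualization and small imports,
  not a general structure parser.
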