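---
title: "molscene: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molscene: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molscene)
```

`molscene` reimplements, as a plain R library, the computational core of
interactive molecular modeling sessions in which each molecule is driven by
a rigid 6-DOF pose. This vignette is the package's own account of the
science: the models, what their parameters mean, where the design was
genuinely open, and what the tests do and do not demonstrate.

## Poses, anchoring and the zoom factor

A pose is a unit quaternion (orthonormality enforced to 1e-9), a
translation in Å, and a positive zoom factor. A molecule is anchored
through one site, so that `apply_pose()` maps that site exactly onto the
pose translation — the molecule pivots about its anchor the way a model
pivots about the centre of the marker that carries it. Two deliberate
conventions follow:

* **Physics never sees the zoom.** Interactive front-ends scale atom sizes
  and positions to fit a screen; that is a display correction, not a change
  of physical coordinates. `assemble_scene()` therefore applies rotation and
  translation only, and every downstream computation (clashes, SAXS, PCS,
  dynamics) consumes world coordinates in Å. The zoom is honoured in exactly
  one place: `write_obj_ballstick()`, at export.
* **Pose interpolation** (`interpolate_pose()`, the primitive behind a
  predefined binding coordinate) uses linear translation interpolation and
  shortest-arc quaternion slerp, with the sign flip on negative dot product
  so the rotation never takes the long way round.

Pose trajectories are a plain-text invention of this package (one
`frame molecule qw qx qy qz tx ty tz scale` record per line): live marker
tracking has no serialized format, so an offline engine needs one.

## Coarse-graining

`coarse_grain()` gives every residue a backbone bead at its alpha carbon
and, except for glycine, a sidechain bead at the centroid of the
non-backbone heavy atoms. Open choices, and what we chose:

* **Centroid weighting.** Whether the sidechain "centre of mass" is
  mass-weighted is ambiguous at this resolution; the default is the
  unweighted centroid (`weighting = "mass"` switches). For typical sidechains
  the two differ by well under the bead radius.
* **Radii.** Bead radii are cube roots of tabulated mean residue volumes
  (a Zamyatnin-style consensus table bundled as
  `extdata/residue_volumes.tsv`, replaceable by the user). Raw cube roots
  (3.9–6.1 Å) encode *relative* size but would interpenetrate at the 3.8 Å
  alpha-carbon spacing, so the default `scale_factor = 0.5` halves them for
  display and collision work; `scale_factor = 1` recovers the raw value.
* **Backbone bead size.** Backbone beads use the glycine-volume radius —
  glycine *is* a bare backbone, and linker beads are by construction
  backbone-sized.
* **Colour classes.** Sidechains are negative (ASP, GLU), positive
  (LYS, ARG, HIS), polar uncharged (SER, THR, ASN, GLN, TYR, CYS) or
  hydrophobic (the rest); backbone and linker beads are their own classes.
  Histidine's placement in a four-class palette is not canonical; it is
  assigned positive here.
* A four-beads-per-residue variant exists in the wild for this kind of
  model; this package implements the two-bead resolution only.

## Interaction rules

All pairwise rules are evaluated per tick. Tick duration is metadata
(default 200 ms, recorded in session headers); the dynamics and the
proton chain are defined per tick, not per wall-clock second.

* **Clashes**: `center` mode flags pairs closer than 3 Å centre-to-centre
  (the atomistic rule); `radius_sum` mode flags pairs closer than the sum of
  their radii, the appropriate rule once beads have heterogeneous sizes.
* **Electrostatics**: bare Coulomb with `k_c = 332.0636` kcal·Å/(mol·e²)
  and a configurable relative dielectric (default 1; the model is a vacuum
  point-charge readout, not a solvated energy).
* **Hydrogen bond / proton transfer**: the display bond requires
  2 Å < d(donor, acceptor) < 3 Å; whether the boundaries are inclusive is
  unstated in this kind of geometric rule, and we chose *exclusive* for the
  display window and *inclusive* for the 2 Å proton–acceptor transfer
  cutoff (a proton exactly at threshold may hop).
* **Proton-transfer chain**: a two-state Markov chain over the holder
  (lysine N vs glutamate O). The forward per-tick probability defaults to
  `p_forward = 0.03`, chosen so exchanges are visible on a seconds timescale
  at 200 ms ticks; the backward rate is then fixed by detailed balance,
  `p_backward = p_forward · (0.70/0.30) = 0.07`, which makes the stationary
  occupancy exactly the 70/30 target with ratio 7/3 ≈ 2.33. This split is a
  pedagogical compression of the lysine/glutamate pKa gap — the real
  equilibrium would be shifted by orders of magnitude more.
* Charges in the bundled lysine/glutamate fixture: N carries +1 e, the two
  carboxylate oxygens share −1 e as −0.5/−0.5.

## Observables

**SAXS.** `saxs_debye()` evaluates the Debye sum at residue (bead)
granularity with the `sin(x)/x → 1` self-term limit. Default form factors
are 1 per bead — the speed-first convention for an interactive loop — with
`bead_form_factors()` providing residue electron counts as the optional
upgrade path toward parameterized coarse-grained scattering.
`fit_saxs()` names its metric explicitly: reduced chi-square with the
optimal linear scale, `c = Σ(I_c I_e/σ²)/Σ(I_c²/σ²)`,
`χ² = Σ((c·I_c − I_e)/σ)²/(N−1)`, σ defaulting to 1 when the experimental
profile carries no errors. The fit-quality metric of an interactive overlay
is not standardized; this convention is recorded in the output so users can
compare like with like.

**PCS.** `pcs_shift()` implements the standard dipolar equation in the
tensor frame, with Å→m conversion inside the function and anisotropies
supplied in the conventional 10⁻³² m³ scale. The axial test value is exact:
Δχ_ax = 2.0·10⁻³² m³, r = 10 Å, θ = 0 gives 1.061 ppm. Tensor magnitudes
and linewidths for any particular protein are inputs, not package
constants; `pcs_spectrum()` draws a unit-area Lorentzian (FWHM = linewidth)
at the shifted position.

**Contacts.** Contact predictions resolve to sidechain beads (backbone for
glycine); a contact is satisfied at ≤ 8 Å, the usual coevolution-contact
convention between sidechain centres, and line width grows linearly beyond
the cutoff (`w_min + slope·max(0, d − 8)`) so satisfied contacts stay thin.
Score-to-tier thresholds (default ≥ 0.8 high, ≥ 0.4 intermediate) are
configurable because coevolution servers scale scores differently.

## Constrained mechanics

The dynamics is position-based: predict `x += v·dt`, then project pairwise
distance constraints by Gauss–Seidel sweeps (SHAKE-like, fixed beads have
zero inverse mass), then resolve sphere overlaps between non-constrained
pairs, then recompute velocities from actual displacements.

* **Topology.** `build_molecule_constraints()` freezes 1-2 (bond) and 1-3
  (angle) distances at their input values and leaves 1-4 pairs free: bond
  lengths and angles are rigid while dihedrals rotate, which is exactly the
  degree of freedom a plastic modeling kit leaves in your hands.
* **Thermostat.** Velocities are Berendsen-style rescaled toward the target
  temperature (reduced units, k_B = m = 1, so the per-bead kinetic target is
  3T/2), applied to the *post-projection* velocities so the equipartition
  contract is measured on the state the user sees. Per-bead
  Andersen-style velocity redraws (default probability 0.1/tick) keep the
  sampling ergodic — pure rescaling of a projected velocity field can
  otherwise linger in low-dimensional orbits. Runs are deterministic for a
  fixed seed.
* **Tolerances.** Projection converges to a maximum relative violation of
  1e-3 with a sweep cap of 300. The cap is sized for the worst case we
  actually exercise: a nearly taut linker between two *fixed* anchors, where
  corrections must diffuse along the whole chain and Gauss–Seidel needs a
  few hundred sweeps. Non-convergence at the cap is flagged on the state,
  never silently dropped. Degenerate coincident pairs are nudged apart by
  1e-6 Å along x before projecting (an arbitrary but deterministic
  tie-break).
* **Linkers.** `build_linker_constraints()` chains n beads between two
  anchors with n+1 constraints at the 3.8 Å alpha-carbon spacing, starts
  from an evenly-spread (zig-zag-folded when slack) guess and projects it
  onto the constraint manifold (tolerance 1e-6) before any dynamics.
  Anchors farther apart than the contour length are an infeasibility error.

**Worm-like-chain entropy.** Interactive engines report linker entropy
without publishing a formula, so the functional form was an open choice.
We use the Gaussian-limit radial density with a finite-extensibility
denominator,
`S(r) = ln r² − 3r²/(4 p L (1 − (r/L)²))` (k_B units, additive constant
dropped), because it (i) reduces to the Gaussian chain
`ln[r² e^{−3r²/(4pL)}]` to within 2 % below 0.3 L, (ii) is monotone
decreasing beyond the modal extension, and (iii) diverges to −∞ as r → L,
so a fully taut linker is infinitely improbable rather than merely
unlikely. Persistence length defaults to 4 Å — a disordered-polypeptide
scale — and the contour is the sum of constraint targets
(7 × 3.8 = 26.6 Å for the default six-bead chain).

**Strain** is `Σ((dᵢ − d₀)/d₀)²` over consecutive links: zero exactly at
equilibrium spacing, 0.01 for a single link stretched 10 %, n(λ−1)² under
uniform stretch λ.

**Maximal extension.** The relaxed anchor-anchor maximum is the contour
length (straight chain, zero strain). With domain geometry — anchor offsets
from each domain centre in the current orientations — the centre-centre
maximum along a separation axis solves `|D·u + (o_b − o_a)| = L` in closed
form, bounded above by `L + |o_a| + |o_b|`; the package checks this against
a brute-force grid search in its tests. The "how far apart can two tethered
domains go" question for a real two-domain protein needs that protein's
coordinates; the package answers it for any loaded structure but bundles
only synthetic domains.

## The fixture generators

`generate_fixture()` builds all test inputs in code, with idealized
geometry (tetrahedral angles, 1.5 Å C–C, 3.8 Å alpha-carbon spacing,
ideal-helix parameters 2.3 Å / 1.5 Å / 100° for toy domains): the
interactive apps this engine mirrors ship with specific protein structures,
which are not redistributed here. The generators emulate *topology and
scale* — charged termini with a titratable proton, a hexaglycine linker, a
two-domain pair with anchors, a noiseless or noisy Debye target generated
at a known pose. They do not emulate real sidechain rotamer geometry,
solvent, or experimental SAXS noise correlations; a passing pose-recovery
test therefore demonstrates self-consistency and discriminability of the
engine, not performance against laboratory data.

## Problem sizes and determinism

The shipped tests run the proton chain for 10⁵ ticks (Monte-Carlo bands at
3σ with an autocorrelation correction), dynamics for 10⁴ steps on a 4-atom
chain and a 6-bead linker, Debye oracle comparisons up to 100 beads, and
angular averages over a few thousand directions — sizes chosen so the whole
suite settles in well under a minute while the stochastic bands stay
meaningful. Every stochastic path takes an explicit seed; sessions record
seed and config hash in their output headers, and identical configurations
re-run byte-identically.

## Known limitations

* No dihedral, electrostatic or solvent terms inside the dynamics: the
  constraint engine is deliberately the modeling-kit abstraction, and the
  interaction readouts are computed *on* configurations, not fed back as
  forces.
* The proton-transfer chain is a population emulator, not kinetics; its
  rates are chosen for watchability, not measured exchange rates.
* Unit form factors make the Debye profile shape-faithful but not
  electron-density-faithful; electron-count weights are one step closer,
  still without solvent-layer corrections.
* The PDB reader handles ATOM/HETATM/CONECT with altloc policies and
  insertion codes; it is not a full-dialect validator (no mmCIF).
* OBJ export writes icospheres and open cylinders with per-class flat
  materials — ball-and-stick only, no cartoons or surfaces.
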