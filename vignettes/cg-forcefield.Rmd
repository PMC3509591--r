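---
title: "The cgff coarse-grained protein force field: model, parameterization and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cgff coarse-grained protein force field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgff)
```

## The model

`cgff` implements a low-resolution protein model in which an amino acid is
one or two spherical interaction sites. Ten residue types with small side
chains (ALA, ASN, ASP, CYS, GLY, LEU, PRO, SER, THR, VAL) are a single
backbone bead `B_<res>` centered on the Cα atom. The other ten (ARG, GLN,
GLU, HIS, ILE, LYS, MET, PHE, TRP, TYR) are the uniform backbone bead
`B_GLY` at the Cα plus a side-chain bead `S_<res>` at the geometric center
of the side chain's heavy atoms. Water is a single neutral bead
representing five molecules (90 amu), matching the protein beads in mass
and volume so that solute-solvent interactions stay balanced.

The potential is

$$U = U_{bond} + U_{angle} + U_{torsion} + U_{vdw} + U_{elec}$$

with harmonic virtual bonds
$U_{bond} = \sum \tfrac12 K_{bond}(l - L_{bond})^2$, Gaussian-sum bonded
profiles
$U_{angle/torsion} = \sum_{i=1}^{N} a_i \exp[-((x - b_i)/c_i)^2]$
(coarse-grained angle and torsion profiles are too irregular for the
single-well forms of atomistic force fields), a 12-6 potential written in
terms of its zero crossing $c_{ij}$,
$U_{vdw} = \sum 4\varepsilon_{ij}(c_{ij}^{12}/r^{12} - c_{ij}^6/r^6)$,
and point-charge electrostatics
$U_{elec} = \sum Q_iQ_j/(4\pi\varepsilon_0\varepsilon_r r)$ with
$\varepsilon_r = 1$. Only four bead types carry charge: `B_ASP` and
`S_GLU` are −1, `S_ARG` and `S_LYS` +1.

Units follow the GROMACS convention throughout: nm, ps, amu, kJ/mol,
elementary charge. Angles are stored in radians internally and printed in
degrees.

## Bonded terms and where their numbers come from

Backbone-backbone bonds use the equilibrium length 0.38 nm — the
consecutive Cα–Cα distance of a trans peptide, which the mapping
reproduces for any ideal chain — with a stiff force constant of
10^5 kJ nm⁻² mol⁻¹; backbone-side-chain bonds use per-type equilibrium
lengths (0.226–0.406 nm) with a common 5·10^3 kJ nm⁻² mol⁻¹ constant.
These are adopted constants of the force field.

The angle and torsion profiles are *statistical* potentials: internal
coordinates are collected over a structure set, histogrammed (2° bins for
angles, 5° for torsions, 0.005 nm for distances), Boltzmann-inverted
($U_i = -k_BT\,\ln(n_i/n_{ref})$ at 300 K) and fitted with Gaussian sums.
Angles come in three types (B–B–B, B–B–S, S–B–B) but the two
backbone/side senses are so similar that one merged parameter set serves
both; profiles are merged by pointwise averaging with a 3-bin moving
average ("mean-value smoothing"). Dihedrals over the B–B axis come in four
types (S–B–B–S, S–B–B–B, B–B–B–S, B–B–B–B), fitted separately with
periodic wrapping.

The B–B–B profile has its two characteristic minima near 90° (α-helix)
and 120° (β-sheet). The package ships defaults fitted on a synthetic
calibration ensemble (`calibration_structures()`): helical and strand
conformers with per-residue dihedral jitter around the two
secondary-structure basins, plus coil conformers with broadly random
dihedrals. The ensemble emulates the *spread* of internal coordinates in
a fold database — it does not reproduce any particular protein, nor the
exact well depths a real database would give, so the packaged bonded
parameters are qualitatively, not quantitatively, those of a
database-derived force field. `parameterize_bonded()` re-runs the whole
pipeline on any user-supplied structure set.

### Numerical choices in the fits

* **Empty bins.** A bin never visited in the statistics is not evidence
  of zero energy — it is evidence of *high* energy. Empty bins are capped
  at 25 kJ/mol (≈10 k_BT at 300 K) and excluded from the reported
  residuals, but they *are* used as half-weight anchors in the
  Gaussian-sum fits. Without them a sum of decaying Gaussians returns to
  zero outside the sampled range, creating spurious flat regions as
  favorable as the physical wells; with them the fitted profiles have
  repulsive walls wherever the statistics say the geometry does not go.
* **Offset.** The inverted profiles are shifted to minimum zero, but a
  constant is not representable by decaying Gaussians, so the fit carries
  a free offset that is dropped afterwards (only energy differences
  matter).
* **Model selection and determinism.** The number of terms is the
  smallest N ≤ 6 whose RMS residual on the data bins falls below
  0.5 kJ/mol, else 6 (with a warning). Each N is started from a greedy
  residual-peak initialisation plus five seeded perturbations of it, so
  the fit is deterministic and robust to local optima.
* **Harmonic fits** use only the harmonic region (bins within 5 kJ/mol of
  the minimum) and reject monotone profiles.

## Non-bonded terms

The homo-pair zero crossings $c_{ii}$ are fixed from pair-distance
statistics (the packaged table: 0.40–0.65 nm for protein beads, 0.51 nm
for water). The well depths $\varepsilon_{ii}$ are fitted to homo-pair
potentials of mean force with $c$ held fixed and the fit restricted to
the long-range region $r \ge c$: the short-range part of a PMF measured
between an isolated bead pair does not transfer to beads packed inside a
protein, while the long-range attraction does. Because the PMF energy
origin is arbitrary, the fit is linear in $(\varepsilon, u_0)$.

The packaged protein well depths come from `fit_lj_depth()` run on the
synthetic homopair PMF curves under `inst/extdata/pmf_synthetic/`
(regenerated by `tools/make_params.R`). Those curves are built from
chosen "true" depths — 2.8–5 kJ/mol, deeper for hydrophobic and aromatic
side chains, all bracketed by the water bead's 6 kJ/mol — with a
short-range contact artefact and noise, emulating the *shape* of an
umbrella-sampled PMF. They are labelled synthetic and are not literature
curves; users with real PMFs feed them through the same function. The
water bead keeps the adopted $(c, \varepsilon) = (0.51\ \mathrm{nm},
6\ \mathrm{kJ/mol})$.

Hetero pairs use geometric-mean (Lorentz-Berthelot companion) mixing for
both $c$ and $\varepsilon$; the sixth/twelfth-power geometric-mean rule
for $c^6$ collapses algebraically to $c_{ij} = \sqrt{c_{ii}c_{jj}}$.

For umbrella-sampling post-processing the package implements standard
self-consistent WHAM (tolerance 10⁻⁶ kJ/mol on the window free energies),
which reduces exactly to single-histogram inversion for one unbiased
window and warns when adjacent windows do not overlap.

## Simulation engine

The engine integrates velocity Verlet with minimum-image periodic
boundaries and a Berendsen weak-coupling thermostat (τ = 1 ps by
default). The coarse resolution supports a 16 fs step — the property the
model exists for. Further numerics:

* Non-bonded interactions are cut off at 1.2 nm with both the 12-6 and
  Coulomb terms shifted to zero at the cutoff (plain cutoff, no Ewald:
  the model carries at most a handful of unit charges at
  $\varepsilon_r = 1$ and CG resolution does not warrant lattice sums).
* A Verlet pair list with a 0.3 nm skin is rebuilt whenever any bead has
  moved more than half the skin, using cell binning when the box admits
  at least three cells per dimension.
* Non-bonded exclusions cover 1-2 and 1-3 bonded neighbors; 1-4 pairs
  (dihedral ends) interact fully. The convention is stated rather than
  derived: the torsion potentials were inverted from statistics that
  include whatever 1-4 interactions real structures embody, and
  excluding 1-4 terms as well would double-count nothing either way;
  1-2/1-3 exclusion is the least surprising choice.
* Initial velocities are Maxwell-Boltzmann at the target temperature
  with the configured seed and zero total momentum; the rescaling
  thermostat preserves the zero.
* Coordinates are stored unwrapped (interactions always use minimum
  image, so energies are identical); `wrap_positions()` wraps on demand.
  Wrapped frames would split a protein across the boundary and corrupt
  RMSD analysis.
* The ensemble is NVT. Pressure coupling is not implemented: solvated
  systems are built at bulk water density (6.69 beads nm⁻³ = 1.0 g/cm³)
  and the validation questions asked here (stability, fluctuations) do
  not require a barostat, whose compressibility constant the model does
  not specify.

`solvate()` centers the protein in a box with a 1 nm clearance, fills it
with water beads on a jittered lattice at bulk density and removes waters
within 0.45 nm of a protein bead (the smallest protein bead diameter is
0.40 nm). `minimize()` is adaptive steepest descent with a monotone
non-increasing energy trace.

## Trajectory observables

RMSD uses backbone beads only — they sit on the Cα positions, so this is
the Cα RMSD — after optimal (Kabsch) superposition per frame. RMSF is
measured about the trajectory-average structure, iterating
superpose-average twice so the reference is self-consistent; the
alternative (superposing onto the initial structure) inflates
fluctuations with relaxation drift, which is why the average is used.
Crystallographic B-factors convert via
$\mathrm{RMSF} = \sqrt{3B/8\pi^2}$ for comparison with experiment.

## What the synthetic generators do and do not emulate

`ideal_chain()` builds peptides by successive internal-coordinate
placement with textbook trans-peptide geometry (N–Cα 0.146, Cα–C 0.152,
C–N 0.133 nm; angles 111°/117°/121°; ω = 180°). Side-chain heavy atoms
are placed schematically along the Cα–Cβ direction — enough to define
the centroid the mapping needs, with no rotameric realism. The helix
preset is (φ, ψ) = (−57°, −47°). The strand preset is (−120°, 115°), the
center of the β-sheet basin observed in folded proteins: under standard
backbone geometry this reproduces the ~120° Cα virtual angle
characteristic of sheets, whereas the idealised antiparallel values near
(−135°, 135°) give a visibly larger virtual angle (~130°) and do not
correspond to the sheet minimum of the statistical angle potential.

Consequences for interpreting the tests: passing parameter-recovery and
stability checks on these fixtures demonstrates that the pipeline and
engine are correct and that the force field maintains compact structures
at a 16 fs step; it does not demonstrate quantitative agreement with
experimental structures, which would require real PDB inputs and
database-scale statistics. In the same spirit, the packaged 56-residue
protein G sequence is exercised through a compact *synthetic* three-helix
fold (the experimental coordinates are not bundled), so solvated-run
checks assert bounded, plateauing backbone RMSD of the order of the
0.3–0.4 nm values typical of long CG runs, not a specific literature
number.

## Problem sizes

The test suite runs at sizes chosen for a single CPU: calibration
ensembles of tens of 20-residue conformers; bonded-ensemble samples of
2–3·10⁵ draws; WHAM with 15 windows × 4000 samples; NVE checks on a
64-bead water box; thermostat and stability checks of 10⁵ steps (1.6 ns
at 16 fs) on solvated systems of ~10²–10³ beads; one scaled-down
solvated-protein run of 3·10⁴ steps on ~900 beads. The packaged
parameters were fitted once on a larger ensemble (280 conformers of 30
residues; seed 20121108) by `tools/make_params.R`.

## Known limitations

* The bonded statistical potentials are averages over a structure set;
  loop regions are therefore restrained by average stiffness — loops with
  unusual curvature will be over- or under-restrained relative to
  reality.
* Solvent is a single neutral van der Waals bead: no hydrogen-bond
  directionality, no dielectric screening beyond the uniform
  $\varepsilon_r$, and electrostatics are cutoff-truncated.
* No pressure coupling, constraints, or enhanced sampling; the engine is
  a minimal reference implementation, not a production MD code.
* Packaged parameters are calibrated on synthetic inputs (see above);
  quantitative work should re-parameterize on a real structure database
  with `parameterize_bonded()` and real PMFs with `fit_lj_depth()`.
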