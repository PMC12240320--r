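---
title: "Characterizing conformational dynamics of a two-chain complex"
author: "complexdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing conformational dynamics of a two-chain complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexdyn)
```

## Scope and model

`complexdyn` implements the standard desk-side analysis pipeline applied to
molecular-dynamics trajectories of a two-chain protein complex — here the
motivating system is a GTPase-activating protein (GAP) domain with its
N-terminal C1 region bound to the small GTPase RhoA, but nothing in the code
is specific to that system. The pipeline characterizes a trajectory of
snapshots sharing one topology by:

1. **Conformational clustering.** Snapshots are coarsened into frames of ten
   consecutive snapshots each (a 1001-snapshot trajectory yields 101 frames:
   100 full blocks plus a final singleton), an all-versus-all
   superposition-RMSD matrix over main-chain atoms is computed, and frames
   closer than 2 Å are merged transitively into clusters. Each cluster's
   representative is the member frame with minimal mean RMSD to the other
   members.
2. **Flexibility profiling.** Per-residue Cα RMSF about the iterated mean
   structure, reported both in Å and relative to the profile mean, with
   seven ordinal flexibility classes (below 0.5, half-unit bins to 3, above
   3 on the relative scale).
3. **Interaction persistence.** Hydrogen bonds and salt bridges detected per
   snapshot (salt bridge: acidic side-chain O within 3.2 Å of a basic
   side-chain N), aggregated to residue pairs and tiered by occupancy with
   strict more-than edges at 5%, 1% and 0.1% of the trajectory — 100, 20 and
   2 ns of a 2 μs run.
4. **Dihedral ensembles.** Backbone φ/ψ series over arbitrary time windows,
   compared between ensembles through normalized Ramachandran occupancy
   grids and their Jensen–Shannon divergence.
5. **Essential dynamics.** PCA of the Cα displacement covariance after
   superposition onto the converged mean, with per-residue mode mobilities,
   and the dynamic cross-correlation matrix (DCCM).
6. **Consensus-interface mapping.** Observed contacts classified as matched,
   unmatched or unmapped against a user-supplied consensus interface
   template via a sequence-alignment map, and binding-energy tables
   summarized as percentage ratios.

All superpositions use the Kabsch algorithm (SVD of the cross-covariance
with the sign correction that forbids reflections). RMSD is unweighted — no
mass weighting — which matches common Cα/backbone practice.

## The synthetic-trajectory generator

Real μs-scale trajectories of this system are not redistributable, and no
public archive carries them, so validation rests on `sim_spec()` /
`simulate_traj()`: a generator whose every statistical property is known
exactly. A spec plants, on an idealized two-chain geometry:

* **discrete states** — per-atom displacement fields orthogonalized against
  all rigid-body motions (so superposition cannot remove them), scaled to a
  chosen RMS separation, with an explicit dwell schedule;
* **fluctuations** — per-residue isotropic Gaussian noise of standard
  deviation σ per coordinate, giving the closed-form Cα RMSF σ√3;
* **contacts** — atom pairs held at a bound distance for a prescribed duty
  cycle (random Bernoulli or one contiguous block) and an unbound distance
  otherwise, with exact distances so detection is never marginal;
* **collective modes** — mutually orthonormal 3N directions moved
  sinusoidally; a mode of amplitude A contributes a covariance eigenvalue of
  A²/2 (exactly, when the period divides the snapshot count).

`ground_truth()` returns the planted state labels, expected RMSF (noise,
mode and state-mixture contributions combined), realized contact fractions
with their tiers, and the mode vectors with expected eigenvalues; the test
suite asserts recovery against these, never against hard-coded numbers.
Defaults mirror the motivating study's sampling: 1001 snapshots at 2 ns.

What the generator does **not** emulate: physical force-field dynamics,
solvent, realistic side-chain packing (planted contact atoms are placed
geometrically, not chemically), temporally correlated noise beyond an
optional AR(1) coefficient, and anharmonic state transitions. Passing tests
therefore demonstrate that the *analysis* operations are correct and
well-calibrated, not that any biological conclusion holds for real data.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| cluster cutoff | 2 | Å | merge rule for the 2D-RMSD matrix |
| coarsening block | 10 | snapshots | noise suppression before clustering |
| salt-bridge cutoff | 3.2 | Å | acidic O–basic N distance |
| H-bond D–A cutoff | 3.0 (explicit) / 3.5 (heavy-only) | Å | VMD-style defaults; the motivating analysis cites VMD without parameters, so these are explicit assumptions |
| H-bond angle cutoff | 20 | deg from linearity | explicit-hydrogen mode only |
| persistence tiers | 5% / 1% / 0.1% | occupancy | strict "more than" comparisons |
| interface cutoffs | 6 / 5 / 4 | Å | decreasing stringency, heavy atoms, strict `<` |
| flexibility bins | 0.5 … 3.0 | relative RMSF | left-closed, right-open; open first and last bins |
| Ramachandran grid | 36 × 36 | 10° bins | scalar ensemble comparison |
| dt | 2 | ns | snapshot spacing; PDB files carry no time, so it is user input |

## Numerical and design choices

* **"Main chain" versus Cα.** The 2D-RMSD matrix uses backbone atoms
  {N, CA, C, O}; RMSF and essential dynamics use Cα only. These mirror the
  two conventions in trajectory-analysis practice.
* **Mean-structure alignment.** Frames are superposed to frame 1, the mean
  computed, frames re-superposed to the mean, iterating until the mean
  shifts less than 10⁻⁶ Å (at most 10 passes; non-convergence is an error
  reporting the final shift). Convergence is typically reached in 2–4
  passes. RMSF against the *initial* structure instead of the mean is
  available behind `reference = "initial"`, since either convention appears
  in the literature.
* **Frame structures are block means.** Each coarse frame is the per-atom
  mean of its snapshots after superposing them onto the block's first
  snapshot; means suppress noise by √(block). Whether published analyses
  compared means or medoid snapshots is rarely stated; the mean is the
  package's choice.
* **Cluster identities.** Connected components of the sub-cutoff graph,
  labelled by earliest member frame so output is deterministic; the
  "largest" cluster is the one with most member frames. Representative ties
  break to the earliest frame.
* **Remainder policy.** Coarsening takes full blocks in order and lets any
  remainder form a final smaller frame — the policy that maps 1001 snapshots
  at block 10 onto exactly 101 frames.
* **Dihedral convention.** IUPAC φ = C(i−1)–N(i)–CA(i)–C(i),
  ψ = N(i)–CA(i)–C(i)–N(i+1), right-hand sign, range (−180°, 180°] with the
  boundary mapped to +180°. Angles undefined at chain termini are `NA`,
  never 0. The implementation (atan2 on cross products) is tested against an
  independent torsion implementation to 10⁻⁶ degrees.
* **Divergence choice.** Ramachandran ensembles are compared by base-2
  Jensen–Shannon divergence, which is symmetric, bounded in [0, 1] and
  well-defined for histograms with empty bins. Published comparisons of
  such plots are usually visual; the scalar is this package's choice.
* **PCA diagonalizes the covariance**, not the correlation matrix — the
  standard essential-dynamics convention; the DCCM is provided separately
  as the normalized form. Eigenvalues are clipped at zero against
  floating-point leakage. The optional 20-ns stride subsamples snapshots
  before analysis.
* **Histidine** is excluded from the salt-bridge basic set by default
  (protonation unknown) and can be included by flag. Donor/acceptor typing
  comes from standard residue templates; non-standard residues are skipped
  with a warning.
* **Hydrogen modes.** Whether analysis structures retain MD hydrogens is
  often unknowable from deposited files, so hydrogen-bond detection has an
  explicit mode (distance + D–H⋯A angle) and a heavy-atom-only mode
  (distance only, looser cutoff). Requesting explicit mode on a
  hydrogen-free structure is an error that names the alternative.
* **Degenerate inputs.** Superposition requires ≥3 non-collinear atoms;
  empty selections are errors rather than silently analysing nothing;
  zero-variance residues get zero DCCM rows with a warning; writing
  coordinates ≥10⁴ Å (unrepresentable in PDB fixed columns) is an error.
* **Energy ratios.** `energy_ratio()` reports 100·ΔG₁/ΔG₂ rounded to one
  decimal; with both values negative this is the ratio of magnitudes, and
  mixed signs trigger a warning because the quotient then has no magnitude
  interpretation.

## Problem sizes used in validation

The bundled tests and the acceptance script exercise the pipeline at the
scale the analyses are designed for while staying desk-side: two-state
clustering on 1001 snapshots coarsened to 101 frames; RMSF and persistence
recovery on 2000-snapshot runs of 60–80 residues; essential dynamics on
2000 snapshots with two planted modes; 20 random Kabsch instances against a
15°-grid-plus-refinement rotation search. These sizes give recovery errors
well inside the asserted bands (binomial 3σ for occupancies, 5% relative
for RMSF, 10% for eigenvalue ratios) without requiring long runtimes.

## Known limitations

* The consensus-interface template is user input; the package ships only a
  small synthetic fixture for testing, not a curated reference interface.
* No detection of π-stacking, cation–π or hydrophobic contacts, and no
  energy-based contact scoring; binding free energies are consumed as
  printed tables, never computed.
* The PDB reader covers multi-model v3.3 coordinate files (ATOM/HETATM,
  altloc A-or-blank, waters skipped); binary trajectory formats (DCD/XTC)
  and mmCIF are out of scope.
* RMSF of a residue whose atoms are repositioned by a planted contact
  schedule is not covered by the generator's closed-form ground truth.
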