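---
title: "Carbohydrate topology and parameters for NMR simulated annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbohydrate topology and parameters for NMR simulated annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotop)
```

## The problem

NMR structure calculation programs in the CNS/XPLOR family build structures
by simulated annealing under a simplified geometric force field plus
experimental restraints. The chemistry is declared in two text files: a
*topology* file (residues: atoms, bonds, dihedrals, impropers; and patches
that edit residues, e.g. to form a disulfide or a glycosidic bond) and a
*parameter* file (force constants and equilibrium geometry per atom-type
tuple). The carbohydrate files shipped for crystallographic use are not
directly usable for NMR annealing, for three reasons this package makes
executable and testable:

1. **Missing parameters.** Terms declared in the topology with no entry in
   the parameter file abort the run. `check_coverage()` enumerates every
   bond/angle/dihedral/improper instance of an assembled molecule and
   reports each term with no exact or wildcard parameter. The canonical
   failure is an N-acetyl sugar's amide group whose three IMPROPER
   parameters are absent; `make_amide_fixture()` reconstructs that situation
   at fixture scale and `check_coverage()` reports exactly those three
   tuples.

2. **Force constants on the wrong scale.** Annealing applies experimental
   restraints with force constants around 50 kcal mol^-1 Å^-2; covalent
   terms weaker than that get distorted by the restraints. The bonded
   constants used by the protein/nucleic-acid files are BOND 1000.0, ANGLE
   500.0, IMPROPER 500.0 and DIHEDRAL 2.0. `harmonize_energies()` rewrites
   every force constant to those values (geometry targets untouched), and
   `check_restraint_compatibility()` asserts the resulting angle constants
   dominate the restraint scale. The dihedral constant is deliberately
   small — torsions genuinely vary between conformers — and uniform, a
   simplification rather than a fitted quantity.

3. **A chirality blind spot.** Chiral sugar carbons were pinned by an
   IMPROPER defined over the central carbon and its three *heavy*
   substituents. Such a term cannot see the hydrogen: mirror-inverting the
   hydrogen through the carbon (H -> 2C − H) leaves every heavy-atom
   improper exactly unchanged, and along the inversion line only the
   (direction-blind) bond term changes, so the flipped state is a genuine
   local minimum behind a bond-energy barrier. Annealing therefore traps a
   fraction of structures with inverted hydrogens. The fix is to define
   the chirality improper over the **four tetrahedral vertex atoms,
   hydrogen included** (the convention protein files already use): the
   four-vertex improper changes sign under the flip, giving a restoring
   gradient. `retarget_impropers()` rewrites a topology this way, and the
   annealer module demonstrates both the trap and its removal.

## The energy model

The toy annealing engine implements exactly the terms the file dialect
declares, in kcal mol^-1, with no 1/2 factors (matching the convention the
printed constants imply):

* bonds: $k(b-b_0)^2$, $k$ in kcal mol$^{-1}$Å$^{-2}$, $b_0$ in Å;
* angles: $k(\theta-\theta_0)^2$ with $\theta$ in radians internally,
  degrees in files;
* dihedrals: $k(1+\cos(n\phi-\delta))$ for periodicity $n>0$, harmonic
  $k\,\mathrm{wrap}(\phi-\phi_0)^2$ for $n=0$ (both forms appear in
  distributed files; the periodicity field selects per entry);
* impropers: harmonic in the minimal-image angular difference
  (wrap at ±180°);
* nonbonded: a purely repulsive quartic
  $k_\mathrm{rep}\,(\max(0,(s\,\sigma_{ij})^2-r^2))^2$ over atom pairs
  separated by three or more bonds, with $\sigma_{ij}$ the arithmetic mean
  of per-type radii, defaults $k_\mathrm{rep}=4.0$, $s=0.8$. NMR annealing
  conventionally uses a repel-only potential; there are no charges and no
  attractive dispersion here, and 1-4 pairs enter at full weight.

Analytic gradients are implemented for every term and verified against
central finite differences (relative error < 1e-6 in the test suite);
energies are verified against an independent literal transcription of the
formulas (< 1e-12 relative).

## Minimization and annealing

`minimize_energy()` defaults to L-BFGS (via `stats::optim`) with the
analytic gradient: the mixed 1000/500/2 force-constant scale makes the
landscape stiff, and steepest descent needs tens of thousands of
iterations to polish a minimum. A torsion angle is undefined where three
of its atoms are collinear, and a line search that grazes such a
configuration can wedge the optimizer; unconverged restarts therefore get
a tiny deterministic perturbation (0.002 Å, fixed seeds) before
continuing. A plain steepest-descent path with Armijo backtracking is kept
as `method = "sd"`; its energy is non-increasing across accepted steps and
the test suite asserts that property.

`anneal()` is a deliberately minimal Metropolis sampler: single-atom
Gaussian proposals (default 0.05 Å), geometric cooling from 50 to 0.5
kcal mol^-1 over 5000 steps, fully reproducible for a fixed seed. It is
not the production annealing protocol (no torsion dynamics, no restraint
energies, no staged cooling); it exists because *any* correct sampler over
this energy surface exhibits the hydrogen trap under heavy-atom impropers
and escapes it under four-vertex ones, which is the property worth
demonstrating. `demo_flip_trap()` packages the experiment: with
heavy-atom-only impropers the minimizer converges (gradient norm ≤ 1e-4)
while the chirality violation persists and the carbon–hydrogen line scan
shows a barrier; with four-vertex impropers the same start relaxes to zero
violations and near-zero energy. `anneal_recovery()` repeats
anneal-then-minimize across seeds; with the default schedule, 1500 steps
per replicate, 20/20 replicates recover correct chirality in the test
suite (the acceptance check requires at least 18/20).

## The synthetic pyranose

All of this is exercised on a generated fixture (`make_pyranose()`), not
on a real sugar. The fixture is a six-membered ring (O5, C1–C5) with
hydroxyls at C1–C4 and an exocyclic CH2OH at C5, built so that the chair
reference is an *exact* joint minimum of its own parameter set:

* ring bonds all 1.526 Å — including the two C–O5 ether bonds, because a
  closed six-ring with all-tetrahedral angles requires equal ring bond
  lengths (radius $L\sqrt{8}/3$, alternating height $\pm L/6$). Exocyclic
  bonds use C–O 1.420 Å, C–H 1.090 Å, O–H 0.960 Å; every angle is
  109.471°.
* substituent directions are the exact tetrahedral complements of the two
  ring bonds at each carbon, so angle terms are at equilibrium too;
* improper targets are *measured from the built geometry* rather than
  hard-coded, which guarantees self-consistency; because parameters are
  per type tuple, the generator chooses each center's hydrogen/oxygen slot
  assignment so that all centers sharing a tuple measure the same signed
  target (the magnitude is near arccos(1/3) ≈ 70.5°, modified slightly by
  the unequal substituent bond lengths);
* both improper styles are generated — heavy-atom-only quadruples
  (center + 3 heavy substituents) and four-vertex quadruples (hydrogen
  first, then substituents by descending atomic number, then name) — so
  the annealer can switch between them with one flag.

Variants: `flipped_H3` (H3 inverted through C3, the trap's starting
point), `mirror` (global reflection: every center flips), `boat` (ring
displacements taken purely from the m = 2 puckering mode, so θ = 90°
exactly), `noisy` (seeded 0.05 Å Gaussian noise). The fixture is *not* a
chemically accurate sugar — no anomeric fine structure, idealized angles,
uniform charges — and passing tests on it demonstrate the machinery's
correctness, not force-field realism on deposited glycans.

## Patches and the linkage catalogue

`generate_glycosylation_patches()` constructs the sixteen linkage patches:
A1S/A1T and B1S/B1T (α/β linkage of sugar C1 to Ser OG / Thr OG1), A1C/B1C
(to Cys SG), B13/B16 (β(1,3)/β(1,6) glycosidic bonds), and the eight
L-sugar variants (suffix L). The residue referenced `1-` is always the
sugar donating C1, `2-` the acceptor. The files this package emulates do
not list the condensation chemistry explicitly, so the generator applies
it: each patch deletes the sugar anomeric hydroxyl (O1, HO1) and the
acceptor hydroxyl/thiol hydrogen, adds the single new C1–acceptor bond,
and installs one four-vertex chirality improper at C1 (H1, linked atom,
O5, C2). α vs β and D vs L differ only in the sign of that improper's
target, recorded in the patch's `c1_sign` field; the test suite checks the
sign table against ideal constructed anomeric geometries (β = swap of
H1/linked-oxygen positions, L = mirror image). Charges of patched atoms
are left unchanged — the annealing model here is geometry-only. Whether a
glycosidic patch should also pin the acceptor carbon's chirality is left
open in the sources this emulates; the default installs only the C1
improper.

## Ensemble analyses

* **Glycosidic torsions** (`glycosidic_torsions()`): per-model φ/ψ across
  a user-specified linkage, reported as circular mean ± circular standard
  deviation ($\sqrt{-2\ln R}$). The default φ convention is the heavy-atom
  one, φ = O5–C1–Ox′–Cx′ (for O-glycosylated Thr: O5–C1–OG1–CB), with
  ψ = C1–Ox′–Cx′–C(x−1)′; a proton-based φ (H1–C1–Ox′–Cx′) is one flag
  away because published torsion tables do not always state their
  convention, and the right way to fix a default is to compare both
  against the deposited ensembles.
* **Ensemble RMSD** (`ensemble_rmsd()`): optimal Kabsch superposition on
  the selection; the default report is the mean over all model pairs,
  which is robust to how a mean structure would be defined, with an
  iterated-mean-structure mode one flag away.
* **Ring pucker** (`ring_pucker()`): Cremer–Pople (Q, θ, φ2) for the
  six-ring in O5,C1..C5 order. Classes by θ bands: chair < 45° or > 135°,
  boat family 80–100° (boat vs twist-boat by φ2 within ±15° of multiples
  of 60°), envelope/half-chair otherwise, planar when Q < 0.05 Å. The
  thresholds are the standard coarse banding; they are classification
  conveniences, not fitted values.
* **Restraint counting** (`parse_distance_restraints()`,
  `count_between()`): XPLOR-style `assign (sel) (sel) d dminus dplus`
  statements, possibly spanning lines, with flat and/or selections over
  segid/resid/resname/name. Restraints are parsed for counting and
  inspection only — they carry no energy here.

## Numerical choices and edge cases

* Angles are degrees in files and user-facing tables, radians inside the
  energy/gradient kernels; angular differences always wrap to (−180°, 180°].
* The torsion sign convention is IUPAC (positive clockwise looking down
  the axis); torsions are invariant under full reversal of the atom order
  and flip sign under reflection — both property-tested.
* Chiral centers are detected as tetravalent carbons whose four
  substituents differ under a Morgan-style breadth-first environment
  signature; a ring-only switch restricts to ring carbons. Centers
  without a bonded hydrogen are an error for retargeting (the four-vertex
  definition requires it).
* Duplicate parameter entries with identical type tuples: the last one
  wins, with a warning — distributed files contain such duplicates and a
  hard error would make round-tripping them impossible.
* Parameter lookup is symmetric (bond pair order, angle/torsion reversal)
  and exact-before-wildcard; both properties are tested against a
  brute-force matcher.
* The topology/parameter dialect is a subset: RESIdue/PRESidue, ATOM
  (TYPE=, CHARge=, optional MASS=), BOND/ANGLe/DIHEdral/IMPRoper,
  DELETE/ADD/MODIfy, GROUp, MASS, AUTOgenerate, `!` comments,
  case-insensitive 4-character keywords, and statement continuation by a
  trailing `-`. Everything else is preserved verbatim and re-emitted, so
  a read/modify/write cycle does not corrupt foreign content. Full
  statement grammar (DONOr/ACCEptor, hydrogen-bond parameters) and other
  force-field formats are out of scope.

## Problem sizes used by the checks

The bundled checks run on the 24-atom fixture: flip-trap demonstrations
with up to 4000 optimizer iterations, annealing recovery over 20 seeds at
1500 Metropolis steps each, torsion recovery over 20 constructed models,
and oracle comparisons over a few hundred random conformations. These
sizes were chosen as the smallest that exercise every code path with
comfortable margins.

## Known limitations

* The annealer is a fixture-scale Metropolis sampler, not the production
  simulated-annealing protocol; nothing here recalculates deposited
  ensembles under experimental restraints, and the package makes no claim
  about reproducing recalculated structures.
* The fixture sugar is idealized; conclusions about real glycan energetics
  require the real files and the real protocol.
* PDB ingestion handles standard multi-model files (altloc A preferred,
  HETATM retained); mmCIF is not supported. Linkages are user-specified,
  never auto-detected from coordinates.
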