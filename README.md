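# glycotop

Carbohydrate topology and parameter files for NMR structure calculation
by simulated annealing — as an executable, testable R package.

NMR structure programs of the CNS/XPLOR family declare chemistry in text
topology (`.top`) and parameter (`.param`) files. The carbohydrate files
distributed for crystallographic use break down under the standard NMR
annealing protocol in three specific ways, and this package implements
both the diagnostics and the fixes:

* **Parameter coverage.** A topology term with no parameter entry aborts
  the run. `check_coverage()` enumerates every bond/angle/dihedral/improper
  instance of an assembled molecule and reports each one with no exact or
  wildcard parameter — e.g. the three missing amide IMPROPER parameters of
  an N-acetyl sugar group.
* **Force-constant harmonization.** `harmonize_energies()` sets every
  BOND/ANGLE/IMPROPER/DIHEDRAL force constant to the values used by the
  protein/nucleic-acid annealing files (1000.0 / 500.0 / 500.0 / 2.0
  kcal·mol⁻¹ per Å² or rad² as appropriate), leaving all geometry targets
  untouched, so covalent terms are never overpowered by experimental
  restraints (typical restraint constants ≈ 50).
* **Four-vertex chirality impropers.** An improper defined over a chiral
  carbon plus its three *heavy* substituents cannot see a hydrogen
  mirror-flipped through the carbon: the flipped state is a local minimum
  behind a bond-energy barrier, and annealing traps it. Redefining the
  improper over the four tetrahedral vertices — hydrogen included —
  (`retarget_impropers()`) makes the flip change the improper's sign and
  restores the correct geometry. A small Cartesian energy model,
  L-BFGS/steepest-descent minimizer and Metropolis annealer demonstrate
  the trap and its removal quantitatively (`demo_flip_trap()`,
  `scan_flip_line()`, `anneal_recovery()`).

The package also generates the sixteen O-/S-glycosylation and glycosidic
linkage patches (A1S, A1T, B1S, B1T, A1C, B1C, B13, B16 and their eight
L-sugar variants; `generate_glycosylation_patches()`), and provides the
ensemble analyses used to validate carbohydrate structures: glycosidic
φ/ψ torsion statistics with circular means (`glycosidic_torsions()`),
sugar heavy-atom ensemble RMSD after Kabsch superposition
(`ensemble_rmsd()`), Cremer–Pople ring pucker classification
(`ring_pucker()`), and XPLOR-style distance-restraint counting
(`parse_distance_restraints()`, `count_between()`).

## Worked example

```r
library(glycotop)

## the self-consistent pyranose fixture: exact chair, zero energy
b <- make_pyranose()
terms <- pyranose_terms(b, "four_vertex")
ff_energy(b$conf, terms)
#> energy (kcal/mol): total 2.88427e-27 [bond 1.109e-27 | angle 1.381e-27 | ...]

## the flip trap: heavy-atom impropers leave the flipped hydrogen stuck
demo_flip_trap("heavy_only")
#> flip-trap demo [heavy_only]: violations 1 -> 1; E 693 -> 412 kcal/mol;
#>   line-scan barrier 1.71e+03

## four-vertex impropers drive it home
demo_flip_trap("four_vertex")
#> flip-trap demo [four_vertex]: violations 1 -> 0; E 2.44e+03 -> 2.33e-14 ...

## torsion machinery recovers constructed angles exactly
e <- make_torsion_ensemble(c(60, 70), c(-30, -40))
glycosidic_torsions(e, glycosidic_linkage(1, 2, "O4", "C4", "C3"))
#> 1->2(O4) [heavy]: phi 65.0 +/- 5.0, psi -35.0 +/- 5.0 (n=2)

## ring pucker classification
ring_pucker(b$conf)$class            # "chair"  (theta 180)
ring_pucker(b$variants$boat)$class   # "boat"   (theta 90)
```

The first number to read in `demo_flip_trap()` output is the violation
count before and after minimization: `1 -> 1` under heavy-atom impropers
(converged yet still wrong — the trap), `1 -> 0` under the four-vertex
definition. The line-scan barrier is the energy wall (kcal/mol) between
the flipped and correct hydrogen wells along the C–H line.

## Command line

A thin launcher is installed at `exec/glycotop` inside the package
directory (run it via `Rscript <path>/glycotop ...` or call
`glycotop_main()` directly):

```sh
glycotop emit --param carbohydrate.param --harmonize --out carbohydrate-nmr.param
glycotop patch --top carbohydrate.top --out carbohydrate-nmr.top
glycotop check-top --top FILE.top --param FILE.param
glycotop validate-pdb --pdb ensemble.pdb          # exit 1 on violations
glycotop torsions --pdb ensemble.pdb --linkage 1,2,O4,C4,C3
glycotop rmsd --pdb ensemble.pdb --select sugar
glycotop pucker --pdb ensemble.pdb --resid 1
glycotop restraints --table noe.tbl --resid 166
glycotop demo-flip --mode heavy_only --seed 7
glycotop fixtures --out fixtures/
```

Exit codes: 0 success, 1 validation findings, 2 usage/parse errors. TSV
to stdout, diagnostics to stderr.

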