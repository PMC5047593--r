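---
title: "Quantifying structural perturbation of missense mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structural perturbation of missense mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idspert)
```

## The measurement model

`idspert` measures how far a missense mutation deforms a protein model,
using iduronate 2-sulfatase (IDS) — the lysosomal enzyme deficient in
mucopolysaccharidosis type II — as its motivating system. The pipeline
consumes an already-built pair of coordinate models (wild type and
mutant); it does not perform homology modelling or energy minimisation
itself. The analysis is a fixed sequence:

1. atoms are paired on the identity key (chain, residue number, atom
   name). Atoms without a counterpart — typically the chemically
   renamed side-chain atoms of the substituted residue, e.g. OD2/ND2 in
   an Asp-to-Asn exchange — are excluded from everything downstream and
   only their count is reported. Pairing is by residue number; no
   sequence alignment is attempted, so the two models must share a
   numbering scheme;
2. the mutant is superposed on the wild type by least squares over the
   paired C-alpha atoms only (Kabsch/SVD with reflection correction).
   All paired C-alpha atoms enter the fit, including the mutated
   residue's own; there is no outlier trimming, matching the idea of a
   single global reference frame;
3. per-atom displacements are Euclidean distances in the fixed
   wild-type frame. An atom is *affected* when its displacement
   strictly exceeds the cutoff; the default 0.15 Å is the conventional
   threshold below which displacements of minimised homology models are
   indistinguishable from noise. A displacement of exactly the cutoff
   is not affected;
4. affected atoms are tallied by backbone/side-chain class and by
   membership of the active-site residue set (IDS default: D45, D46,
   C84, K135, D334 — C84 being the residue converted to formylglycine
   in the mature enzyme). The active-site count includes affected atoms
   of either class in those residues;
5. the all-atom RMSD `sqrt(mean(d^2))` over paired atoms summarises the
   total deformation.

The backbone is operationalised as the atom-name set N, CA, C, O, OXT
plus the amide/alpha hydrogens (H, H1–H3, HA, HA2, HA3); every other
name, including non-standard ones, is side chain. This is the one place
where "backbone hydrogens" needed a concrete decision: amide and alpha
hydrogens ride on main-chain heavy atoms, all other hydrogens on
side-chain ones. The pipeline counts whatever atoms both models contain
— with hydrogens present in both, hydrogens are counted; with
heavy-atom-only models, they are not.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 0.15 Å | strict displacement threshold for "affected" |
| `active_site` | 45, 46, 84, 135, 334 | residue numbers counted as active site |
| `probe_radius` | 1.4 Å | solvent probe (water) for ASA |
| `n_sphere_points` | 960 | test points per atom in Shrake–Rupley |
| bin edges | 0.15/0.30/0.45/0.60/0.75 Å | colour classes cyan/green/yellow/orange/red |

The colour bins are left-closed and right-open, with everything below
0.15 Å uncoloured and everything from 0.75 Å up red; displacements are
exported in the PDB B-factor column so any viewer can render them
(unpaired atoms are flagged with −1.00).

## Accessible surface area

Per-residue ASA uses the Shrake–Rupley construction: each heavy atom's
sphere is expanded by the probe radius, sampled with a deterministic
golden-spiral point set, and the exposed fraction scaled to the sphere
area. Radii are C 1.70, N 1.55, O 1.52, S 1.80 Å; hydrogens are
ignored. Two numerical choices matter:

* the point lattice is oriented along the principal axes of the
  heavy-atom cloud (signs fixed by the third moment, right-handed
  completion), which makes the computed areas exactly covariant with —
  hence invariant under — rigid motion of the input, rather than
  invariant only up to lattice discretisation. For pathologically
  symmetric point sets the sign tie-break falls back to the largest
  eigenvector component; such inputs do not arise for real chains;
* 960 points per atom keep the isolated-sphere error at the rounding
  level and total-ASA changes under point doubling below 0.5 % on the
  synthetic chains used in the tests.

The packaged catalogue's ASA column describes the wild-type residue
environment of each mutation site as published; the engine here is a
clean-room Shrake–Rupley implementation, and since the underlying IDS
model coordinates were never deposited, numerical agreement between the
engine and the catalogue column is neither expected nor asserted. The
catalogue is data; the engine is verified against closed forms and a
Monte-Carlo surface oracle instead.

## The mutation catalogue

`ids_mutations()` ships 131 IDS missense mutations with phenotype
labels (severe/attenuated) compiled from the case-report literature,
together with the published per-mutation metrics (affected main-chain,
side-chain and active-site atom counts, all-atom RMSD, wild-type
residue ASA) and the originating reference for each phenotype call. As
packaged, the catalogue holds 68 severe and 63 attenuated records; all
group-level aggregates reproduce from these rows at printed precision
(the accompanying prose of the source literature quotes a 67/64 split,
which is inconsistent with its own table — the row-level data are
authoritative here). Loading validates notation, phenotype labels,
non-negativity and uniqueness on every row.

Group statistics use the sample (n − 1) standard deviation, quartiles
by linear interpolation, and two-sided Welch t-tests at α = 0.05 with
Welch–Satterthwaite degrees of freedom; no multiple-testing correction
is applied, and the main-chain and side-chain counts are tested
separately. Active-site involvement is binarised as "any active-site
atom affected".

## What the synthetic generators emulate

`generate_chain()` builds poly-alanine-like chains (N, CA, C, O, CB per
residue) as an extended zig-zag with the canonical 3.8 Å C-alpha
spacing or an ideal alpha-helix (2.3 Å radius, 1.5 Å rise, 100° twist).
A sub-0.002 Å seeded jitter makes every chain generic (no exact
collinearity of the C-alpha set) without disturbing the idealised
distances.

`perturb_structure()` turns a chain into a "mutant" by displacing
selected atoms by known magnitudes along seeded directions, and returns
the expected perturbation report by direct bookkeeping on the final
coordinates — the central end-to-end oracle. When displaced C-alpha
atoms leave a net rigid component, the generator removes the best-fit
rigid motion of the C-alpha set so that the analysis' own superposition
is the identity; when the C-alpha set is untouched, intended magnitudes
are realised exactly, which is how strict-cutoff behaviour is testable
at the exact boundary value. These synthetic mutants are displacement
fields, not physically minimised structures: they validate the
measurement pipeline, not the realism of any modelling chain. Passing
tests therefore certify the geometry and statistics, and say nothing
about the fidelity of homology models built elsewhere.

`simulate_mutation_table()` draws catalogues whose columns mimic the
statistical shape of the packaged data: rounded lognormal affected-atom
counts (non-negative and right-skewed — in both observed groups the SD
exceeds the mean), side-chain counts proportional to main-chain counts,
RMSD increasing with total count, ASA independent of phenotype. The
baseline `meanlog = 3.74`, `sdlog = 0.9` matches the attenuated group's
observed mean (63) and coefficient of variation (~1.2); the default
effect shift `log(106/63)` reproduces the observed severe/attenuated
mean ratio. With `effect_shift = 0` the generator provides null tables
on which the Welch test's type-I error is calibrated (0.05 ± 0.02 over
1000 seeds in the acceptance suite).

## Degenerate inputs and numerical conventions

* superposition requires at least three non-collinear C-alpha pairs
  (collinearity detected via the second singular value of the centred
  C-alpha matrix, threshold 1e−8 relative);
* models with zero shared atoms, empty displacement sets, zero-variance
  groups in the Welch test, and absent residues in ASA lookups raise
  typed validation errors (the CLI maps them to exit code 2,
  other computation failures to 3);
* PDB output quantises coordinates to 0.001 Å and B-factors to 0.01;
  round-trip tests operate on pre-quantised models. Coordinates with
  magnitude ≥ 10 000 Å do not fit the fixed-width format and are
  rejected;
* alternate locations other than blank/"A" are skipped on parsing, and
  only the first model of a multi-MODEL file is read — single-conformer
  homology models are the intended input class;
* problem sizes in the test and acceptance suites (chains of 15–140
  residues, 100 end-to-end perturbation specs, 1000 random-transform
  optimality trials, 1000 null-table seeds, 10^6-point Monte-Carlo ASA
  oracle) were chosen to exercise every guarantee at tight tolerances
  while keeping the default suite fast on a single CPU.

## Known limitations

* No mmCIF input, no ligand/heteroatom handling, and chain identifiers
  pass through verbatim; multi-chain assemblies work only insofar as
  numbering matches across models.
* The affected-atom measure treats all displacements equally; it is not
  an energy or contact score, and per-residue aggregation beyond the
  main/side/active-site split is out of scope.
* The published per-mutation geometry cannot be recomputed because the
  underlying mutant models are not publicly available; the package's
  reproducible layer is the catalogue statistics plus the synthetic
  ground-truth guarantees.
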