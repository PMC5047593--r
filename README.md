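# idspert

Structural perturbation analysis of missense mutations, built around the
iduronate 2-sulfatase (IDS) enzyme whose deficiency causes
mucopolysaccharidosis type II (MPS II, Hunter syndrome). Missense
mutations in the *IDS* gene produce phenotypes ranging from severe to
attenuated, and the structural damage a substitution inflicts on the
modelled enzyme tracks that clinical severity. `idspert` provides the
measurement pipeline for quantifying that damage from wild-type/mutant
coordinate pairs, plus the 131-mutation IDS catalogue and the
phenotype-group statistics computed from it.

## What it computes

Given a wild-type model and a mutant model of the same protein in PDB
format:

1. **Superposition.** Atoms are matched on `(chain, residue number, atom
   name)`; the mutant is superposed on the wild type by least squares
   over the C-alpha atoms using the closed-form Kabsch/SVD solution
   (rotation `R` with `det(R) = +1`, translation `t` minimising
   `sum_i |R q_i + t - p_i|^2` over C-alpha pairs).
2. **Affected atoms.** An atom is *affected* when its displacement in the
   wild-type frame exceeds the cutoff distance (default 0.15 Å,
   strictly). Affected atoms are tallied for the main chain (backbone:
   N, Cα, C, O and their amide/alpha hydrogens), the side chain, and the
   active site (residues D45, D46, C84, K135, D334 by default).
3. **RMSD.** The all-atom root-mean-square distance
   `sqrt(mean(d_i^2))` over all paired atoms.
4. **ASA.** Solvent-accessible surface area per residue by the
   Shrake–Rupley method (probe 1.4 Å, 960 deterministic golden-spiral
   points per atom).
5. **Colouring.** Displacements binned into the five colour classes
   0.15 ≤ cyan < 0.30 ≤ green < 0.45 ≤ yellow < 0.60 ≤ orange < 0.75 ≤ red
   (Å) and written into the PDB B-factor column for any viewer to render.
6. **Group statistics.** For a mutation catalogue with severe/attenuated
   labels: per-group means, SDs and five-number summaries, threshold
   proportions, active-site involvement, and two-sided Welch t-tests
   (significance at p < 0.05).

Because the mutant 3D models behind the published catalogue are not
deposited anywhere, the packaged per-mutation metrics are data, not
recomputation targets; the geometry engine is verified on synthetic
structure pairs with known ground truth (`generate_chain()`,
`perturb_structure()`).

## Worked example

```r
library(idspert)

# a synthetic 60-residue helix and a "mutant" with residues 45-46 displaced
wt  <- generate_chain(60, "helix", seed = 42)
mut <- perturb_structure(wt,
         data.frame(residue_number = c(45, 46),
                    atom_class = "any", magnitude = 0.35),
         seed = 42)$model

perturbation(wt, mut)
#> Structural perturbation (synthetic-helix-60 vs synthetic-helix-60-perturbed)
#>   paired atoms: 300 (0 unpaired, excluded)
#>   affected atoms (> 0.15 Angstrom): main chain 8, side chain 2, active site 10
#>   all-atom RMSD: 0.0643 Angstrom
```

Residues 45 and 46 belong to the default active site, so all ten
displaced atoms (eight backbone, two side chain) are counted there as
well; the rigid component of the perturbation was removed by the
generator, and the 0.35 Å displacements spread over 300 atoms give the
0.064 Å all-atom RMSD.

The packaged catalogue reproduces the published group-level contrasts:

```r
phenotype_comparison(ids_mutations())
#> Phenotype-group comparison: 68 severe vs 63 attenuated
#>   main_chain severe  106.147 (+/- 113.194)  attenuated   62.651 (+/-  77.711)  Welch p = 0.0111   *
#>   side_chain severe  123.956 (+/- 124.901)  attenuated   70.778 (+/-  83.517)  Welch p = 0.00468  *
#>   rmsd       severe    0.074 (+/-   0.050)  attenuated    0.056 (+/-   0.043)  Welch p = 0.0284   *
#>   asa        severe   25.221 (+/-  40.760)  attenuated   27.948 (+/-  38.712)  Welch p = 0.695
#>   severe with >= 50 main-chain atoms affected: 42/68 (62%)
#>   attenuated with <= 49: 39/63 (62%)
#>   active site involved: severe 31/68 (46%), attenuated 17/63 (27%)
```

Severe mutations damage more of the structure (larger affected-atom
counts and RMSD, both significant by Welch's t-test), while the surface
exposure (ASA) of the mutated residue does not differ between groups —
severe and attenuated substitutions are spread over the whole molecule.

A thin command-line wrapper ships in `inst/cli/idspert.R` with
subcommands `compare`, `stats`, `asa` and `simulate`.

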