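# focuslib

Reaction-based focused virtual screening around the pyrazinyl-sulfonamide
scaffold, as used to search for intracellular allosteric ligands of the
chemokine receptors CCR2/CCR5, packaged as a reusable R toolkit.

Intracellular allosteric GPCR pockets are small and conserved, and the
chemistry that decorates the pyrazinyl-sulfonamide chemotype is a single
step: N-sulfonylation of a primary amino-azine with an aryl sulfonyl
chloride,

    Ar–SO2–Cl + H2N–Az  →  Ar–SO2–NH–Az + HCl

which makes an enumerate-then-dock campaign both synthetically honest and
cheap. `focuslib` implements that campaign end to end:

1. **Building blocks** — load SMILES/SDF vendor files, canonicalise
   (salt stripping, charge neutralisation), classify into
   `amino_heteroarene` / `sulfonyl_chloride` roles by substructure
   pattern, and retro-decompose any sulfonamide back into its block pair.
2. **Enumeration** — exhaustive virtual N-sulfonylation over the
   amine × sulfonyl-chloride Cartesian product, canonically deduplicated,
   every product keeping all contributing block pairs and a stable
   SHA-256-derived `product_id`.
3. **State expansion** — tautomers (1,3 heteroatom proton shifts) and
   pH-window protonation states (rule table with representative pKa
   values; window 6.0–7.2, precision 1.0, ≤128 variants per molecule).
4. **Docking** — one deterministic distance-geometry conformer per
   species, PDBQT preparation via OpenBabel, and a pluggable engine:
   AutoDock-Vina-compatible external backend (exhaustiveness 8, seed 42
   by default) or an exact mock scorer
   `score = −0.1·C + 1.0·K` (C = ligand heavy atoms with a receptor
   heavy atom within 4 Å, K = pairs closer than 2 Å) for fully
   reproducible tests. Only the lowest-scoring pose flows to triage.
5. **Interaction profiling** — PLIP-style geometric detection of
   hydrogen bonds, hydrophobic contacts, halogen bonds, π-stacking and
   salt bridges, with a 5 Å pocket shell and optional
   Ballesteros–Weinstein residue labels (e.g. Glu302^8.48).
6. **Triage** — score ranking, required-contact filters (e.g. hydrogen
   bonds to ≥2 of the conserved Glu/Lys/Phe motif), motif frequency among
   top hits, and novelty as the maximum Tanimoto similarity on
   radius-2/1024-bit circular fingerprints against a reference set.
7. **Assay math** — percent displacement/inhibition, four-parameter
   logistic (4PL) fitting, `ECf = EC50·(f/(1−f))^(1/hill)`, and
   Cheng–Prusoff `Ki = IC50 / (1 + [L]/KD)`.

A synthetic-fixture module (`gen_blocks()`, `gen_pocket()`,
`gen_curves()`) generates block sets with provably distinct products, toy
pockets with analytically known contact geometry, and seeded
dose–response curves, so the whole pipeline is testable offline.

## Worked example

```r
library(focuslib)

fx  <- gen_blocks(3, 4, dir = tempdir())          # 3 amines x 4 sulfonyl chlorides
am  <- load_blocks(fx$amine_file,    role_hint = "amino_heteroarene")
su  <- load_blocks(fx$sulfonyl_file, role_hint = "sulfonyl_chloride")
lib <- enumerate_library(am, su)
nrow(lib)
#> [1] 12
sp  <- expand_library(lib)
table(sp$kind)
#>   parent tautomer
#>       12       11

pocket <- gen_pocket()
cfg    <- dock_config(c(0, 0, 0), c(20, 20, 20), engine = "mock", seed = 42)
ranked <- rank_hits(screen(sp, pocket$receptor, cfg))
head(ranked$best_score, 3)
#> [1] -1.4 -1.4 -1.3

prof <- profile_pose(pocket$receptor, pocket$ligand)
prof
#> <fl_profile> 5 contacts (halogen_bond:1, hbond:2, hydrophobic:1, pi_stack:1), shell of 5 residues

cheng_prusoff_ki(1000e-9, 6e-9, 6.3e-9)$ki * 1e9   # Ki (nM) of a 1000 nM IC50
#> [1] 512.1951
ic50_to_pic50(10.79e-6)                            # 10.79 uM -> pIC50
#> [1] 4.966979
```

The 12 products are every pairing of the 3 amines with the 4 sulfonyl
chlorides; expansion adds a sulfonamide↔ring-imine tautomer for all but one
product (whose shifted form canonicalises onto another state); the mock screen scores each species by its geometric pocket
contact count; the profiler recovers exactly the five contacts the toy
pocket was built to contain; and the assay helpers reproduce the
Cheng–Prusoff and pIC50 arithmetic used when evaluating synthesized
ligands.

A thin command-line interface is installed at `inst/cli/focuslib`
(subcommands `run`, `dock`, `profile`, `assay-fit`, `assay-ki`).

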