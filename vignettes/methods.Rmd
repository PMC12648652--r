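---
title: "Methods: reaction-based focused screening with focuslib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction-based focused screening with focuslib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`focuslib` implements a focused, reaction-based virtual screening
workflow: a single coupling chemistry (amine N-sulfonylation) applied
exhaustively to classified building blocks, followed by
protonation/tautomer expansion, seeded docking, geometric interaction
profiling and triage, plus the assay mathematics used downstream of
synthesis. This vignette records the models, the tunable parameters, and
the design choices made where the design was genuinely open.

## The virtual reaction and its inverse

The coupling is modeled as a graph edit, not a text substitution: a
reactive amine nitrogen (neutral, two hydrogens, single heavy neighbour =
an aromatic carbon of a six-membered azine ring) is bonded to a reactive
sulfur (S bearing one Cl, two S=O and one aryl carbon) while the chlorine
leaves. Each distinct reactive-site pair yields one product; canonical
SMILES (OpenBabel) deduplicate symmetric sites. Retro-decomposition is
the exact inverse: every sulfonamide N–S bond in scaffold context is cut,
the amine N–H restored and the sulfur capped with Cl. The round trip
`retro(couple(a, s)) = {a, s}` is asserted by tests over all fixture
products.

Role classification is pattern-based. The amine pattern
`[NX3;H2][c;R;$(c1naaaa1),$(c1anaaa1),$(c1aanaa1)]` restricts to primary
amines on six-membered azines — the only chemistry the coupling
implements — so aliphatic amines and plain anilines classify `unknown`.
Blocks matching both role patterns are flagged `ambiguous` and excluded
from enumeration rather than guessed.

### Scaffold query semantics

The product scaffold query is `[c;R]S(O)(O)Nc1cnccn1`. Read as strict
SMARTS this cannot match a sulfonamide: the bonds to the sulfonyl oxygens
are written without a bond symbol, which in SMARTS means
"single-or-aromatic", while the targets have S=O double bonds. The query
originates from a database substructure search, where such queries are
matched permissively. `match_scaffold()` therefore compiles the scaffold
pattern with any-bond-order semantics for implicit bonds (`~`), which
restores the intended behaviour: every enumeration product matches, plain
pyrazine does not. The rewrite applies only to the scaffold query; role
patterns are used verbatim.

## State expansion

Protonation uses a rule-table approach: ionisable sites are found by
substructure rules on the molecular graph, each with a representative
literature pKa (`pka_rules()`: carboxylic acid 4.21, arylsulfonamide N–H
10.10, phenol 9.84, imidazole-type ring N 6.99, azine ring N 0.60,
pyridine ring N 5.23, morpholine 8.36, cyclic aliphatic amine 11.10,
aliphatic amine 10.68, aniline 4.60). A site whose window
pKa ± `pka_precision` (default 1.0) intersects the pH range
(default 6.0–7.2) contributes both forms; otherwise only the dominant
form. Defaults — window, precision, and the 128-variant cap with
lexicographic truncation — are the screening protocol's conditions.
The table is deliberately small and versioned inside the package so that
species counts are stable across installations; it does not attempt
conformer-dependent or continuum pKa prediction.

Tautomers come from one conservative rule family: 1,3 proton shifts
between heteroatoms across a carbon (D–H⋯C=A ↔ D=C⋯A–H, D,A ∈ {N,O}).
This covers lactam/lactim (2-pyridone ↔ 2-hydroxypyridine), amide/imidic
acid and amidine-type shifts, including the sulfonamide↔ring-imine
tautomer of the products; carbon-acid (keto–enol) shifts are outside the
rule set, so acetone is a singleton. Tautomers are enumerated first, then
each tautomer is protonated, then the union is deduplicated — the
ordering and the rule-set identifier (`heteroatom-1,3-shift/v1`) are
recorded in the expansion manifest. Because this rule set is more
conservative than exhaustive toolkit enumerators, absolute species counts
are smaller than those a campaign using such tools would report; all
per-species invariants (single parent, idempotence, pH-window
monotonicity) are rule-set-independent and tested.

## Conformer embedding

The docking contract requires exactly one conformer per species and
bit-identical coordinates for a fixed (structure, seed). The embedder is
classical distance geometry, written for reproducibility rather than
force-field quality: exact distances for bonds (covalent-radius table),
geminal pairs (ideal angles by hybridisation: sp 180°, sp2 120°,
sp3 109.47°) and aromatic rings (planar polygon); Floyd–Warshall-smoothed
upper bounds and steric lower bounds elsewhere; a seeded uniform sample
of the distance matrix; metric-matrix (classical MDS) embedding into 3D;
then deterministic pairwise bound-correction sweeps (200 sweeps, damped
step, fixed pair order). Coordinates are rounded to 10^-4 Å so that
serialisation is byte-stable. Stereocentres are not assigned (none are
created by this chemistry); chirality-aware embedding is a known
limitation.

## Docking engines

`external_vina` drives an AutoDock-Vina-compatible binary with the
configured box, exhaustiveness (default 8), seed (default 42) and pose
count (default 9), parsing `REMARK VINA RESULT` scores; only the
lowest-scoring pose is used downstream, with ties broken by engine rank.
The docking box defaults to the bounding box of a named pocket residue
selection plus a 5 Å margin, overridable by explicit centre/size.

The `mock` engine exists so that the full pipeline contract — embedding,
preparation, scoring, ranking, reporting — can be exercised exactly and
offline: the conformer is translated (unrotated) to the box centre and
scored `−0.1·C + 1.0·K` with C the ligand heavy atoms having any receptor
heavy atom within 4.0 Å and K the ligand–receptor heavy-atom pairs below
2.0 Å. The score is recomputable by brute force in a few lines, which is
how the tests verify it.

## Interaction profiling

Detection is purely geometric, with all thresholds exposed in
`profiler_config()` and defaulting to the published defaults of
rule-based profilers: hydrogen bonds at donor–acceptor ≤ 4.1 Å and
≥ 100° at the donor hydrogen; hydrophobic carbon–carbon ≤ 4.0 Å between
apolar carbons; halogen bonds at X⋯A ≤ 4.0 Å with C–X⋯A within 165 ± 30°
and Y–A⋯X within 120 ± 30°; ring-centroid π-stacking ≤ 5.5 Å with
parallel or perpendicular normals within 30°; charged-group centroids
≤ 5.5 Å for salt bridges; and a 5.0 Å heavy-atom pocket shell. Distance
thresholds are closed intervals (equality detects), asserted at machine
precision on constructed fixtures.

Typing tables are vendored: ligand donors are N/O/S bearing hydrogen,
ligand acceptors are oxygens and lone-pair nitrogens; receptor donors and
acceptors are per-residue atom-name lists (backbone N donates, backbone O
accepts), aromatic rings are the PHE/TYR/TRP/HIS name sets, and charged
groups are ASP/GLU carboxylates versus LYS/ARG heads (HIS is not assumed
protonated). When the receptor lacks explicit hydrogens the hydrogen-bond
angle test degrades to a donor-geometry proxy (angle at the donor between
its heavy neighbour and the acceptor ≥ 90°); the mode used is recorded in
each profile. Water bridges, metal coordination and solvent accessibility
are out of scope.

The shell list is defined as residues with any heavy atom within the
shell radius, extended by contact residues, so the invariant "every
contact's residue is in the shell" holds structurally even for
centroid-based contacts.

## Triage

Ranking is ascending by best score with a canonical-structure tie-break
(stable and permutation-invariant). Contact filters are arbitrary
predicates over profiles; `pred_contacts_to()` expresses the common
"hydrogen bonds to ≥ k of a residue set" form used for the conserved
Glu/Lys/Phe intracellular motif. Novelty is the maximum Tanimoto
similarity to a reference set on hashed circular fingerprints (radius 2,
folded to 1024 bits, computed by OpenBabel's ECFP4); the mean is reported
alongside, and the maximum is used as the conservative criterion.
Availability/price are pass-through metadata, never scraped.

## Assay mathematics

Displacement and inhibition are window-normalised percentages (0% at
total binding / full stimulation, 100% at non-specific binding / basal);
both are affine-invariant in the raw counts and error on degenerate
windows. The 4PL model is
`y = bottom + (top − bottom) / (1 + 10^((log10 EC50 − log10 c)·hill))`,
fitted by Levenberg–Marquardt least squares (minpack.lm) with
deterministic initialisation: plateaus from the data extremes, midpoint
from the concentration nearest half-maximal response, Hill ±1 by
direction. If the optimiser returns an inverted orientation the plateaus
are swapped and the Hill slope negated (an algebraically identical
curve), so `bottom ≤ top` always holds. Cheng–Prusoff and the EC-fraction
identity are closed forms; the study constants ([L] ≈ 6 nM, KD 6.3 nM,
EC80 of the agonist 5.15 nM) are available as defaults but the
Cheng–Prusoff parameters must always be passed explicitly. One recorded
inconsistency in the source tables — a footnote pEC80 of 7.9
(≈ 12.6 nM) versus the stated 5.15 nM challenge concentration — is left
as data; the package resolves nothing.

## Synthetic fixtures and what they show

`gen_blocks()` writes substituted 2-aminopyrazines and para-substituted
benzenesulfonyl chlorides with pairwise-distinct inert substituents
(halogens, CF3, OMe, then alkyl/alkoxy/chloroalkyl series), so the
enumerated library has exactly `n_amines × n_sulfonyls` products — count
assertions are exact, and the 200-block fixture uses the 60/140 split,
the unique positive split consistent with 200 blocks and 8,400 products.
`gen_pocket()` places five residues at stated distances/angles from a
posed ligand and returns the implied golden contact list, so profiler
correctness is checked against construction, not against itself.
`gen_curves()` produces seeded 4PL data with embedded truth for recovery
tests.

What passing these tests does *not* show: fixture blocks are cleaner than
vendor files (no salts, no exotic elements, single reactive sites except
where constructed); the toy pocket has no conformational ambiguity, no
waters and few atoms; the mock engine is not a physical scoring function.
Results on real campaign data depend on the external docking engine and
on receptor preparation quality, neither of which the fixtures emulate.

## Problem sizes and reproducibility

Default test and acceptance sizes are chosen to keep full runs in
minutes on one core: the study-scale enumeration (200 blocks → 8,400
products) runs once; docking-dependent checks use the 12-product toy
library; 4PL recovery uses 100 curves per condition. All randomness
derives from a single root seed fanned out per stage; pipeline manifests
record counts, config snapshots and file digests but no wall-clock
timestamps, so identical configurations reproduce byte-identical output
trees (timing goes to the log stream instead).
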