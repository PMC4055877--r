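---
title: "Predicting active positions by virtual fragment growing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting active positions by virtual fragment growing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In fragment-based drug development, a weakly binding seed fragment is
elaborated into a lead by attaching chemical groups at specific positions.
The expensive question is *where*: which hydrogen (or fluorine) of the seed
should be replaced so that the modification increases affinity? `fraggrow`
answers it computationally. Every H/F position of the seed is replaced, one
by one, by each member of a library of small hydrocarbon side chains; the
resulting virtual compounds are energy-minimized and docked into the target
pocket; and the modified position of the best-scoring virtual compound is
reported as the predicted *active position*. No attempt is made to propose
the actual substituent — practising medicinal chemists pick reagents by
availability; the method only points at the position worth modifying.

## Pipeline and assumptions

1. **Preparation** (`load_molecule`, `prepare_protonation`,
   `assign_gasteiger_charges`): inputs are SDF/MOL2/PDB/SMILES. Molecules
   are set to their dominant ionization state at pH 7 by a small fixed rule
   table (carboxylic acids deprotonated; aliphatic amines and
   amidines/guanidines protonated). This is deliberately rule-based, not a
   pKa predictor. Partial charges are Gasteiger (PEOE, via OpenBabel).
   SMILES inputs receive a deterministic 3D embedding: an OpenBabel 2D
   layout, a seed-derived out-of-plane displacement, then force-field
   minimization. (OpenBabel's native 3D generator is not deterministic
   across runs, which would break reproducibility.)

2. **Side-chain sets** (`build_set`): three nested hydrocarbon template
   sets, A (78), B (38) and C (25), with exactly one attachment point each,
   no heteroatoms, and at most two aromatic rings. All sets share the
   direct-attachment derivatives of nine base scaffolds; the aromatic
   scaffolds additionally spawn linker variants: set C adds `-CH2-`, set B
   also `-CH2-CH2-`, and set A also trans `-CH=CH-` (the alkene linker
   mimics the geometry of amide/ester linkages). The published counts
   (78/38/25) cannot be produced by linker variants alone — the pairwise
   set-size differences (40 and 13) are unequal, while each linker type
   adds the same number of templates — so the shipped scaffold table also
   records, per derivative, the smallest set that lists it. The table is
   data, not code: users who possess the original template structures can
   substitute their own file and keep the whole pipeline.

3. **Growth** (`attach_sidechain`, `enumerate_virtual_library`): the site's
   H or F is removed; the template is bonded to the anchor atom along the
   former bond vector with a covalent-radius bond length; the side-chain
   torsion about the new bond is scanned in 30-degree steps and the rotamer
   with the fewest clash contacts kept. If the best rotamer still has a
   contact below 0.7 (heavy) or 0.6 (with-H) times the summed van der Waals
   radii, the compound is rejected — bookkeeping guarantees
   accepted + rejected = sites x templates. Clashes are screened before
   minimization (cheap) on the grounds that minimization cannot rescue a
   torsion scan that fails at every rotamer. Because the numeric clash
   thresholds are a package choice, per-target virtual-compound counts from
   any particular study are not expected to be reproduced.

4. **Minimization** (`minimize_molecule`): an internal small-molecule force
   field — harmonic bonds and angles, cosine torsions, Lennard-Jones 12-6,
   and Coulomb electrostatics with the distance-dependent dielectric
   eps = 4R — minimized by L-BFGS-B with analytic gradients. Energies are
   kcal/mol. The returned energy never exceeds the starting energy, and a
   divergent (non-finite) energy is an error, not a silent fallback.

5. **Docking** (`prepare_receptor`, `build_score_grid`, `dock_compound`):
   the receptor is rigid; the pocket box is the reference ligand's bounding
   box plus a margin. Three channels are precomputed on a 120^3 lattice:
   a buried-surface reward (negative Gaussian shell at contact distance,
   vdW + 1.4 A probe, width 0.45 A), the receptor Coulomb potential under
   eps = 4R, and a soft-core repulsion inside the vdW envelope. The
   buried-surface value is saturated at 10 per grid point: a patch of
   surface can only be buried once, and without the cap penetration into an
   atom-dense wall would be rewarded without bound. Ligand flexibility
   comes solely from pre-generated conformers (systematic torsion driving,
   0.5 A RMSD deduplication, `max_conformers` 100 by default); the pose
   search is an exhaustive, fully deterministic scan over the 60 rotations
   of the icosahedral group times an anchored translation lattice
   (default step 1 A), with a branch-and-bound cutoff that never changes
   the optimum. Default weights w_surf = 1, w_elec = 0.3, w_rep = 1
   reflect that surface burial, not electrostatics, carries most of the
   signal in hydrophobic fragment growth; repulsion heights are set so that
   penetration cannot be bought back by contact reward (rep_k = 15 with
   the saturated surface reward). Scores are dimensionless; lower = better.
   `import_external_scores()` substitutes any external docking engine for
   the built-in scorer without touching the evaluation machinery.

6. **Ranking and evaluation** (`rank_compounds`,
   `predict_active_position`, `merge_ensemble`, `spike_true_leads`,
   `success_rate`, `random_baseline`, `lead_baseline`): compounds are
   sorted by score with deterministic tie-breaking by generation index
   (ties are not discussed in the source protocol; stability makes reruns
   identical). The top-k prediction collects *distinct* site labels from
   the top of the table. Ensembles of receptor structures are merged by
   concatenating all (compound, receptor, score) rows and re-ranking
   globally. The random baseline pools counts across targets
   (sum of active positions / sum of H/F sites); pooling, not per-target
   averaging, is what the published benchmark reports (26.32% = 45/171,
   where averaging would give 26.78%). The top-2 baseline is
   1 - (1 - p)^2, two independent draws with replacement — the only simple
   form consistent with the published 45.71%; it is reverse-derived and
   flagged as such here.

## The embedded benchmark

`load_benchmark_tables()` returns transcriptions of a published 15-target
FBDD benchmark: per target the number of H/F sites of the seed, the number
of true active positions, and — per side-chain set — the library size and
the rank of the first virtual compound modified at a true active position;
plus 6 multi-structure ensemble records and 15 true-lead spiking records.
The loader enforces an integrity manifest (15/6/15 records; site/active
column sums 171/45). From these records the package recomputes every
summary statistic: top-1 success 60.00% for set A against a 26.32% pooled
random baseline; top-2 success 66.67% (A) and 46.67% (B and C) against
45.71%; ensemble merged rank-1 rate 66.67% (4 of 6); lead-spiking rank-1
rate 60.00% against a 2.80% random-selection baseline. One display note:
the ensemble table's average is the exact fraction 4/6 = 66.67%, which some
summaries truncate to "66%"; the package always computes the exact fraction
and formats separately.

## The synthetic pocket

Real benchmark targets cannot be shipped, so the package generates a
deterministic toy system (`make_toy_receptor`, `make_toy_seed`) that
isolates the single geometric claim the method rests on: growth into a
complementary subpocket scores best. The receptor is a shell of uncharged
carbon pseudo-atoms on a jittered cubic lattice (hydrophobic pocket; an
optional charge pattern exercises the electrostatic channel), carved so the
cavity is snugly complementary to a posed seed — clearance 2.8 A around
heavy atoms, 2.2 A around hydrogens, just outside the scorer's repulsion
range — plus one tube-shaped subpocket adjoining exactly one replaceable
site. The default seed is m-xylene-like ("branched"): its unique ring H
between the two methyls faces the tube, so the compound grown there (a
1,2,3-trisubstituted ring) is the only positional isomer whose shape
matches cavity + tube simultaneously; a symmetric benzene seed would make
every grown compound the same molecule and site recovery would only test
tie-breaking. The recovery test (`predict_active_position`, k = 1) returns
the tube-facing site for all three side-chain sets.

What the toy does *not* emulate: real protein chemistry (heteroatom
contacts, hydrogen bonds, charged residues), receptor flexibility, water,
and realistic pocket shapes. Passing the recovery test shows the pipeline's
machinery — growth, minimization, conformers, grid scoring, ranking — is
wired correctly and that the buried-surface term discriminates geometry as
designed; it says nothing about prediction accuracy on real targets, which
is what the embedded benchmark records quantify.

## Numerical choices and scale

* Atom indices are 1-based everywhere (R convention); site labels such as
  `H8@C3` use the same numbering.
* Rotamer/conformer/pose enumeration orders are fixed, and all tie-breaks
  go to the earlier candidate, so identical inputs give bit-identical
  outputs; the only RNG uses are the SMILES-embedding jitter, the toy
  lattice jitter, and conformer subsampling, all driven by explicit seeds.
* The bundled recovery runs use a 0.5 A translation step, 3 conformers per
  compound, and 200 minimizer iterations — the cavity's clearance leaves
  about 0.3 A of slack, so the pose lattice must be finer than that;
  coarser steps (the 1 A default) are fine for real, roomier pockets.
* Degenerate inputs: a seed without H/F sites yields an empty library plus
  a warning; a compound that fits no pose inside the box is an error from
  `dock_compound` and ranks last (score NA) in `dock_library`.

## Known limitations

The built-in scorer is a documented geometric surrogate, not a calibrated
affinity function; its absolute values are meaningless across receptors.
The force field has no dedicated aromaticity terms (kekulized bonds plus
planarizing torsions keep rings near-planar, slightly alternating bond
lengths). Protonation rules cover the common basic/acidic groups only.
Stereocenters are not enumerated, and ring-fusing or scaffold-replacing
growth (fragment merging/linking) is out of scope by design.
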