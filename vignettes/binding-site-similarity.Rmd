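---
title: "Quantifying physico-chemical similarity between protein-protein binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying physico-chemical similarity between protein-protein binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the method

When two homologous proteins A and A′ (same family) are each crystallized in
complex with unrelated partners B and C that occupy equivalent binding
sites, one can ask whether B and C achieve recognition with similar
chemistry: do their interfaces present the same kinds of atoms at the same
places? `sitesim` answers this by superposing the homologous domains,
overlaying the four binding sites in one frame, and counting, for each site,
how many of its interface elements have a like-typed partner element nearby.

The procedure for one pair of complexes AB / A′C:

1. **Interface detection.** An atom is interfacial if some heavy atom of the
   partner chain lies strictly within 5 Å; a residue belongs to the binding
   site if it owns at least one interfacial atom. Hydrogens never
   participate.
2. **Superposition.** The sequences of A and A′ are aligned globally
   (BLOSUM62, affine gaps, open 11 / extend 1) and a least-squares rigid
   transform (Kabsch, proper rotation enforced) is fitted on the matched
   Cα pairs of the whole domains, then applied to every atom of A′ and C.
   The fit is whole-domain, not interface-restricted, mirroring how general
   structural alignment is used for this task.
3. **Representation.** Each binding site becomes a set of typed points at
   three levels: every interfacial heavy atom (five atom classes); a
   coarse-grained reduction with a Cα bead plus one or two side-chain
   pseudo-atoms per residue (glycine: Cα only); or one point per residue at
   its Cα (five residue classes).
4. **Counting.** An element is *superimposed* if any element of the facing
   site lies strictly within the match cutoff — 3 Å for atoms, 4 Å for the
   reduced representations — and *similar* if some within-cutoff element
   carries the same class. This is an existence test, not a one-to-one
   matching: one partner point may match several elements. The
   *similarity ratio* of a site is n_similar / n_superimposed.
5. **Significance.** For each of the four sites in turn, the class labels of
   its overlapping (superimposed) elements are permuted uniformly at random
   while the partner's labels stay fixed; 500 replicates give
   p = #{N_rand ≥ N_obs} / 500. Geometry is untouched, so the sizes of the
   compared objects are preserved by construction.

A binary-label variant replaces the five classes by conserved/unconserved
(normalized conservation score < −1; chains without scores are entirely
unconserved) and asks whether conserved residues co-localize across the
superposed sites. Sites with no superimposed conserved residue are flagged
`excluded` — with sparse conservation data this prunes a substantial part of
a cohort, which is inherent to the analysis, not an implementation artifact.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `contact_cutoff` | 5.0 | Å | heavy-atom interface definition |
| `match_cutoff_atom` | 3.0 | Å | similar/superimposed test, all-atom |
| `match_cutoff_cg`, `match_cutoff_ca` | 4.0 | Å | reduced representations describe a residue with fewer points, so a larger tolerance is used |
| `n_bootstrap` | 500 | replicates | resolves p-values on a 1/500 grid |
| conservation threshold | −1.0 | normalized score | conserved ⇔ score strictly below |
| gap penalties | 11 / 1 | score | standard affine protein-alignment setting |

All cutoffs are strict inequalities (`< cutoff`). Boundary ties are
measure-zero on real coordinates but the convention is fixed and tested.

The p-value estimator is the plain proportion, without +1 smoothing, so a
site with zero observed similar elements reports p = 1 exactly: the shuffled
null cannot produce a count below zero, and this degenerate case is treated
as maximally insignificant rather than undefined.

## Numerical and policy choices

- **Alternate locations**: per atom name within a residue, the
  highest-occupancy conformer is kept; ties prefer altloc "A", then file
  order. Single-conformer geometry is required by the distance computations.
- **Non-standard residues**: selenomethionine is remapped to MET (SE → SD);
  anything else non-standard is dropped with a warning, since the class
  tables cover the 20 standard residues.
- **Residue identity** is author chain + author number + insertion code;
  nothing is renumbered, so conservation tables and manifests can reference
  author numbering directly.
- **Multi-model files**: only one model (the first, by default) is used.
- **Degenerate superposition**: near-collinear Cα sets trigger a warning
  (the rotation about the axis is ill-determined); reflections are never
  returned (determinant correction in the SVD).
- **Coarse-grain beads** are placed at the centroid of their member heavy
  atoms present in the file; a bead whose members are all absent is skipped
  with a warning. Bead classes are derived from the atom table by majority
  vote with ties resolved toward the more polar class (charged > polar >
  nonpolar > hydrophobic).
- **Bootstrap seeding**: every site's replicate stream is seeded by
  `run_seed + role_index * 100003 (mod 2^31 − 1)`, and in a cohort run each
  pair additionally offsets the run seed by `65537 * pair_index`. Identical
  configs are bit-identical; the caller's RNG state is never disturbed.
- **Shuffle mode**: permutation of the observed labels (composition
  preserved) is the default; an i.i.d.-redraw mode (`shuffle = "redraw"`) is
  available for sensitivity analysis. Labels are shuffled one site at a
  time, the partner fixed, because the analysis reports four per-site
  p-values.

### Where the design was genuinely open

- The published analyses of this kind used an external structural-alignment
  binary for the superposition step. `sitesim` replaces it with
  sequence-guided Kabsch superposition: within-family homologs share >30%
  identity, where sequence correspondence is reliable, and this removes an
  opaque dependency. On structurally divergent pairs (alternate interface
  conformations, insertions, poor global similarity) the superposition — and
  therefore downstream counts — can differ from what a structure-based
  aligner would give. This is the main caveat when comparing against
  published per-pair numbers.
- The exact published five-class atom partition and the residue/bead tables
  are not recoverable from accessible text. The shipped tables implement the
  partition's stated logic — positively charged (Lys NZ/CE, Arg and His
  groups), negatively charged (carboxylates, OXT), polar (backbone N/O,
  side-chain O/N/S), nonpolar (Cα, C, carbons adjacent to functional
  groups), hydrophobic (remaining aliphatic/aromatic carbons) — and live in
  editable TSVs (`inst/extdata`), so a recovered original table can be
  substituted via `representation_tables()` without touching code.
- "Missing atomic coordinates at the binding site" (a validation rule with
  no published numeric definition) is operationalized as: any interfacial
  residue lacking its Cα or more than 50% of its canonical heavy atoms. The
  threshold is a `run_config` argument and every rejection is logged with
  its reason.
- The minimum-overlap filter uses exactly zero superimposed Cα elements on
  the B or C side as the exclusion rule, the only threshold stated for it.

## The synthetic generator

`generate_pair()` builds two facing extended strands (3.8 Å Cα spacing,
4.5 Å apart — inside the contact cutoff by construction, with a 0.7 Å
zig-zag so the Cα trace is never collinear), with side chains marching into
the interface so that all three representation levels receive informative
elements. Classes are controlled through residue identity (one
representative residue per class: LYS/ASP/SER/ALA/LEU), so labels emerge
from the shipped tables exactly as for real files. Complex 2 copies the
scaffold with Gaussian coordinate noise, relabels A′ with probability
`similarity_AA` of copying A, shifts the C strand along the interface to set
the overlap fraction, relabels C with probability `similarity_BC` of copying
B in the overlap, and applies a planted rigid transform. The ground truth
(planted transform, per-position classes, cross-side agreement counts,
conserved residues) is stored alongside.

Defaults are 40/28 residues, overlap 0.75, `similarity_AA` 0.9 (homologs),
`similarity_BC` 0 (the null condition for the partner side), uniform class
frequencies, 0.3 Å noise, a 30° + ~11 Å planted displacement and 30%
conserved residues.

What the generator does **not** emulate: real protein geometry (rotamers,
secondary-structure packing, sterics), non-uniform class composition of real
interfaces, correlated conservation patterns, or the superposition
difficulty of structurally divergent homologs. Passing the calibration and
power checks therefore demonstrates the statistical machinery is correct
and well-calibrated under controlled geometry; it does not certify accuracy
of the superposition step on hard real pairs.

## Verification strategy and problem sizes

The test-suite checks run at sizes chosen to keep the whole suite fast while
exercising every code path: interface detection is compared against a
brute-force all-pairs scan on complexes of a few hundred atoms; the
superposition is cross-checked against an independent quaternion-based
fit; bootstrap p-values are compared with exhaustive permutation
enumeration on overlaps of ≤ 8 elements (50 instances), calibrated against
the exact null on 200 synthetic pairs, and power-checked on cohorts of
20–25 pairs per planted-similarity level, all with 500 replicates.

## Known limitations

- Sequence-guided superposition can diverge from structure-based alignment
  on low-identity or conformationally variable homolog pairs.
- The all-atom null model ignores the spatial clustering of same-class
  atoms within a residue, which inflates random similar counts (and hence
  p-values) at that level; the reduced representations are the recommended
  basis for inference, and the per-residue level the most interpretable.
- The analysis sees only the overlapping portion of the binding sites;
  determinants outside the overlap are invisible to it, and shape
  complementarity is not represented at all.
- mmCIF input, assembly generation and domain-boundary assignment are out
  of scope; inputs are single-model PDB files with author numbering.
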