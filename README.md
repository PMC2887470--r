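# sitesim

Do unrelated proteins that bind the same (or homologous) partner use
similar chemistry at the interface? `sitesim` is an R package for
structural bioinformaticians that quantifies physico-chemical similarity
between protein–protein binding sites in pairs of complexes **AB / A′C**,
where A and A′ are homologous domains (same family) and B, C are unrelated
partners occupying equivalent binding sites.

## Method in brief

For each pair of complexes:

- **Interfaces** — an atom is interfacial if a heavy atom of the partner
  chain lies strictly within 5 Å; a residue is part of the binding site if
  it has ≥ 1 interfacial atom.
- **Superposition** — the homologous domains are superposed by global
  sequence alignment (BLOSUM62, gap open 11 / extend 1) followed by
  least-squares (Kabsch) fitting on matched Cα; the transform carries A′
  and C into the frame of A and B.
- **Representations** — each binding site becomes a set of typed points at
  three levels: all interfacial heavy atoms (five physico-chemical atom
  classes), a coarse-grained model (Cα bead plus 1–2 side-chain
  pseudo-atoms per residue, glycine Cα-only), or one Cα point per residue
  (five residue classes).
- **Counting** — an element is *superimposed* if any facing-site element
  lies strictly within the match cutoff (3 Å atoms, 4 Å coarse-grain/Cα)
  and *similar* if a within-cutoff element has the same class. The
  similarity ratio of a site is `n_similar / n_superimposed`.
- **Significance** — per site, class labels are shuffled among the
  overlapping elements (partner fixed; 500 replicates) and
  `p = #{N_rand ≥ N_obs} / 500`. A site with zero observed similar
  elements reports p = 1 exactly. Four p-values per pair: A, A′, B, C.

A conservation variant labels interface residues conserved/unconserved
(normalized score < −1) and tests co-localization of conserved residues
across the superposed sites with the same bootstrap.

## Worked example

Synthetic pairs with known ground truth are generated by the package
itself, so the pipeline can be exercised end to end without any downloads
(planted homolog-side similarity 0.9, label-independent partner sides):

```r
library(sitesim)
dir <- tempfile()
generate_cohort(3, synthetic_pair_spec(similarity_AA = 0.9,
                                       similarity_BC = 0, seed = 1),
                seed = 1, dir = dir)
cfg <- run_config(file.path(dir, "manifest.tsv"), dir,
                  output_dir = file.path(dir, "out"),
                  conservation = file.path(dir, "conservation.tsv"),
                  levels = c("CG", "CA"), seed = 1)
res <- run_pipeline(cfg)
subset(res$results, pair_id == "syn0001")
```

```
   site level n_elements n_superimposed n_similar similarity_ratio p_value
      A    CG         65             52        51        0.9807692   0.000
 Aprime    CG         67             54        52        0.9629630   0.000
      B    CG         58             45        35        0.7777778   0.458
      C    CG         64             45        37        0.8222222   0.060
      A    CA         29             24        22        0.9166667   0.000
 Aprime    CA         30             23        20        0.8695652   0.000
      B    CA         28             22         5        0.2272727   0.978
      C    CA         28             21         4        0.1904762   0.986
```

Reading the Cα rows of this pair: 24 of A's 29 interface residues have an
A′ residue within 4 Å after superposition, and 22 of those also agree in
class — far more than label shuffling can produce, hence p = 0.000. On the
partner side only 5 of B's 22 superimposed residues find a like-classed C
residue, which is entirely compatible with chance (p = 0.978): the two
unrelated partners bind the same site with different chemistry, exactly the
condition that was planted.

Cohort summaries mirror this (`res$summary$means` reports mean similar
counts per side and their ratio, here ≈ 3 at the residue level;
`res$summary$significant_fraction` shows all homolog-side and no
partner-side p-values below 0.05 at Cα level).

For real structures, point `run_config()` at a manifest TSV
(`pair_id  pdb1  chainA  chainB  pdb2  chainAprime  chainC  category`) and
a directory of PDB files, or use `compare_pair()` for a single pair. A thin
command-line wrapper with `run` / `simulate` / `pair` / `tables`
subcommands is installed at `inst/scripts/sitesim.R`.

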