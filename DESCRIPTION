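Package: sitesim
Title: Physico-Chemical Similarity of Protein-Protein Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the physico-chemical similarity between protein-protein
    binding sites in pairs of complexes AB and A'C that share homologous
    partners (A and A') bound by unrelated proteins (B and C). Interfaces are
    detected with a heavy-atom distance cutoff, binding sites are compared at
    three levels of representation (all-atom with five atom classes, a
    coarse-grained pseudo-atom model, and one point per residue at the C-alpha)
    after rigid superposition of the homologous domains, and the significance
    of the observed similarity is assessed with a label-shuffling bootstrap.
    Includes a variant that tests whether evolutionarily conserved residues
    co-localize across superposed binding sites, and a seeded synthetic-pair
    generator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
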