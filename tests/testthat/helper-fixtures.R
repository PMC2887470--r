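# Small in-code fixtures: hand-written PDB records and typed-element frames.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1.00, bfac = 0.00, altloc = " ", ins = " ",
                          record = "ATOM", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, altloc, resn, chain, resno, ins,
          x, y, z, occ, bfac, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a typed-element frame in the shape produced by build_representation()
make_elements <- function(coords, classes, level = "CA") {
  coords <- matrix(coords, ncol = 3)
  data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
             class = classes, level = level,
             res_key = paste0("X:", seq_len(nrow(coords))),
             source = "CA", stringsAsFactors = FALSE)
}

# random typed-element pair in a small box so that overlaps are common
random_element_pair <- function(n1, n2, box = 6, cutoff = 4,
                                classes = ALL_CLASSES) {
  e1 <- make_elements(cbind(runif(n1, 0, box), runif(n1, 0, box),
                            runif(n1, 0, box)),
                      sample(classes, n1, replace = TRUE))
  e2 <- make_elements(cbind(runif(n2, 0, box), runif(n2, 0, box),
                            runif(n2, 0, box)),
                      sample(classes, n2, replace = TRUE))
  list(e1 = e1, e2 = e2)
}

# two-chain fixture: chain A has 2 residues (GLY, ALA), chain B has 2 (SER,
# GLY), backbone-complete, chains ~4.5 A apart
two_chain_fixture <- function() {
  lines <- c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0.0, 0.5, 0.0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.0, 0.0, 0.0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 2.0, 0.5, 0.0),
    pdb_atom_line(4, "O", "GLY", "A", 1, 2.0, 1.7, 0.0),
    pdb_atom_line(5, "N", "ALA", "A", 2, 3.5, 0.5, 0.0),
    pdb_atom_line(6, "CA", "ALA", "A", 2, 4.5, 0.0, 0.0),
    pdb_atom_line(7, "C", "ALA", "A", 2, 5.5, 0.5, 0.0),
    pdb_atom_line(8, "O", "ALA", "A", 2, 5.5, 1.7, 0.0),
    pdb_atom_line(9, "CB", "ALA", "A", 2, 4.5, -1.0, -1.0),
    pdb_atom_line(10, "N", "SER", "B", 1, 0.0, 0.5, 4.5),
    pdb_atom_line(11, "CA", "SER", "B", 1, 1.0, 0.0, 4.5),
    pdb_atom_line(12, "C", "SER", "B", 1, 2.0, 0.5, 4.5),
    pdb_atom_line(13, "O", "SER", "B", 1, 2.0, 1.7, 4.5),
    pdb_atom_line(14, "CB", "SER", "B", 1, 1.0, -1.0, 5.5),
    pdb_atom_line(15, "OG", "SER", "B", 1, 1.0, -2.0, 6.5),
    pdb_atom_line(16, "N", "GLY", "B", 2, 3.5, 0.5, 4.5),
    pdb_atom_line(17, "CA", "GLY", "B", 2, 4.5, 0.0, 4.5),
    pdb_atom_line(18, "C", "GLY", "B", 2, 5.5, 0.5, 4.5),
    pdb_atom_line(19, "O", "GLY", "B", 2, 5.5, 1.7, 4.5)
  )
  write_pdb_fixture(lines)
}

# poly-peptide chain builder for alignment tests: one CA per residue
ca_chain <- function(aa3_vec, chain = "A", z = 0) {
  n <- length(aa3_vec)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain, resno = i, ins = "", resid = aa3_vec[i],
               elety = "CA", elesy = "C",
               x = 3.8 * i, y = 0.7 * (i %% 2), z = z, o = 1,
               is_heavy = TRUE, res_key = paste0(chain, ":", i),
               stringsAsFactors = FALSE)
  }))
}

as_domain <- function(atoms, chain = atoms$chain[1], structure_id = "fix") {
  attr(atoms, "structure_id") <- structure_id
  attr(atoms, "chain_id") <- chain
  class(atoms) <- c("sitesim_domain", "data.frame")
  atoms
}

# standard three-letter codes indexed by one-letter code
AA123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
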