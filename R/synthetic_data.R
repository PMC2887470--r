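# Seeded generator of synthetic AB / A'C pairs with known ground truth.
#
# Scaffold: two parallel extended strands with 3.8 A Calpha spacing, 4.5 A
# apart (inside the 5 A contact cutoff), side chains placed by idealized
# internal coordinates pointing into the interface so that side-chain atoms
# participate in the contact. Physico-chemical classes are controlled through
# residue identity (one representative residue per class), so labels emerge
# from the shipped representation tables exactly as for real structures.
# Complex 2 copies the scaffold of complex 1 with optional coordinate noise,
# re-labelled classes (similarity_AA / similarity_BC) and a partner strand
# shifted along the strand axis to control the overlap fraction, then is
# displaced by a planted rigid transform.

CLASS_REPRESENTATIVE <- c(POSITIVE = "LYS", NEGATIVE = "ASP", POLAR = "SER",
                          NONPOLAR = "ALA", HYDROPHOBIC = "LEU")

#' Specification of one synthetic pair
#'
#' @param n_residues_A Residues in the homologous domains A and A' (default
#'   40; must cover the shifted partner strand).
#' @param n_residues_B Residues in the partner domains B and C (default 28).
#' @param overlap_fraction Fraction of each binding site inside the shared
#'   region after superposition (default 0.75).
#' @param similarity_AA Probability that an A' residue keeps the class of its
#'   A counterpart (default 0.9; homologs are highly similar).
#' @param similarity_BC Probability that a C residue in the overlap copies
#'   the class of the B residue at the same position (default 0: partner
#'   labels independent, the null condition).
#' @param class_frequencies Length-5 probability vector over POSITIVE,
#'   NEGATIVE, POLAR, NONPOLAR, HYDROPHOBIC (default uniform).
#' @param class_frequencies_B,class_frequencies_C Optional per-side
#'   overrides; default to `class_frequencies`.
#' @param coordinate_noise_sigma Gaussian noise (A) added to every atom of
#'   complex 2 before the planted transform (default 0.3).
#' @param planted_transform `rigid_transform` applied to complex 2 (default:
#'   30 degrees about z plus a 10 A translation).
#' @param conserved_fraction Fraction of residues marked conserved in the
#'   emitted conservation table (default 0.3).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return List of class `synthetic_pair_spec`.
#' @export
synthetic_pair_spec <- function(n_residues_A = 40L, n_residues_B = 28L,
                                overlap_fraction = 0.75,
                                similarity_AA = 0.9, similarity_BC = 0,
                                class_frequencies = rep(0.2, 5),
                                class_frequencies_B = NULL,
                                class_frequencies_C = NULL,
                                coordinate_noise_sigma = 0.3,
                                planted_transform = rigid_transform(
                                  rotation_about_axis(c(0, 0, 1), pi / 6),
                                  c(10, 4, -3)),
                                conserved_fraction = 0.3,
                                seed = 1L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            similarity_AA >= 0, similarity_AA <= 1,
            similarity_BC >= 0, similarity_BC <= 1,
            conserved_fraction >= 0, conserved_fraction <= 1,
            length(class_frequencies) == 5,
            abs(sum(class_frequencies) - 1) < 1e-9,
            coordinate_noise_sigma >= 0,
            inherits(planted_transform, "rigid_transform"))
  if (!is.null(class_frequencies_B)) {
    stopifnot(length(class_frequencies_B) == 5,
              abs(sum(class_frequencies_B) - 1) < 1e-9)
  }
  if (!is.null(class_frequencies_C)) {
    stopifnot(length(class_frequencies_C) == 5,
              abs(sum(class_frequencies_C) - 1) < 1e-9)
  }
  structure(list(
    n_residues_A = as.integer(n_residues_A),
    n_residues_B = as.integer(n_residues_B),
    overlap_fraction = overlap_fraction,
    similarity_AA = similarity_AA, similarity_BC = similarity_BC,
    class_frequencies = class_frequencies,
    class_frequencies_B = class_frequencies_B %||% class_frequencies,
    class_frequencies_C = class_frequencies_C %||% class_frequencies,
    coordinate_noise_sigma = coordinate_noise_sigma,
    planted_transform = planted_transform,
    conserved_fraction = conserved_fraction,
    seed = as.integer(seed)), class = "synthetic_pair_spec")
}

CA_SPACING <- 3.8
STRAND_SEPARATION <- 4.5

# idealized atoms of one residue: backbone in the strand plane, side chain
# marching along `side_dir` with small deterministic lateral offsets; the
# strand zig-zags in y so the Calpha trace is never collinear (a collinear
# trace would leave the superposition rotation ill-determined)
residue_atoms <- function(aa3, pos_index, z_chain, side_dir) {
  x0 <- CA_SPACING * pos_index
  y0 <- 0.7 * (pos_index %% 2)
  bb <- rbind(
    N  = c(x0 - 1.45, y0 + 0.5, z_chain),
    CA = c(x0, y0, z_chain),
    C  = c(x0 + 1.45, y0 + 0.5, z_chain),
    O  = c(x0 + 1.45, y0 + 1.73, z_chain))
  side <- setdiff(canonical_heavy_atoms()[[aa3]], rownames(bb))
  sc <- NULL
  if (length(side)) {
    sc <- t(vapply(seq_along(side), function(j) {
      c(x0 + 0.35 * sin(2.1 * j), y0 + 0.35 * cos(2.1 * j),
        z_chain + side_dir * 1.5 * j)
    }, numeric(3)))
    rownames(sc) <- side
  }
  coords <- rbind(bb, sc)
  data.frame(elety = rownames(coords), x = unname(coords[, 1]),
             y = unname(coords[, 2]), z = unname(coords[, 3]),
             row.names = NULL, stringsAsFactors = FALSE)
}

build_chain <- function(chain_id, aa3_vec, positions, z_chain, side_dir) {
  aa3_vec <- unname(aa3_vec)
  rows <- lapply(seq_along(aa3_vec), function(i) {
    at <- residue_atoms(aa3_vec[i], positions[i], z_chain, side_dir)
    data.frame(chain = chain_id, resno = positions[i], ins = "",
               resid = aa3_vec[i], elety = at$elety,
               elesy = substr(at$elety, 1, 1),
               x = at$x, y = at$y, z = at$z, o = 1,
               is_heavy = TRUE,
               res_key = paste0(chain_id, ":", positions[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

draw_classes <- function(n, freqs) {
  sample(ELEMENT_CLASSES, n, replace = TRUE, prob = freqs)
}

#' Generate one synthetic AB / A'C pair
#'
#' @param spec A `synthetic_pair_spec`.
#' @param pair_id Identifier used in file and structure names.
#' @param dir Optional directory; when given, the two complexes are written
#'   as `<pair_id>_1.pdb` / `<pair_id>_2.pdb` and a conservation TSV row set
#'   is returned alongside.
#' @return List with `structure1`, `structure2` (`sitesim_structure`
#'   objects), `manifest_entry` (one-row data.frame), `truth` (planted
#'   transform, per-position classes, cross-side agreement counts, conserved
#'   residue keys), `conservation` (data.frame) and, when `dir` is given,
#'   `files`.
#' @export
generate_pair <- function(spec, pair_id = "pair1", dir = NULL) {
  stopifnot(inherits(spec, "synthetic_pair_spec"))
  nA <- spec$n_residues_A
  nB <- spec$n_residues_B
  shift <- as.integer(round((1 - spec$overlap_fraction) * nB))
  if (nB + shift > nA) {
    stop("infeasible geometry: n_residues_A must be at least ",
         nB + shift, " to host the shifted partner strand")
  }

  out <- with_local_rng(spec$seed, {
    class_A <- draw_classes(nA, spec$class_frequencies)
    class_B <- draw_classes(nB, spec$class_frequencies_B)
    copy_a <- stats::runif(nA) < spec$similarity_AA
    class_Ap <- ifelse(copy_a, class_A,
                       draw_classes(nA, spec$class_frequencies))
    pos_C <- seq_len(nB) + shift
    in_overlap <- pos_C <= nB
    copy_c <- stats::runif(nB) < spec$similarity_BC
    class_C <- draw_classes(nB, spec$class_frequencies_C)
    class_C[in_overlap & copy_c] <- class_B[pos_C[in_overlap & copy_c]]

    chainA <- build_chain("A", CLASS_REPRESENTATIVE[class_A], seq_len(nA),
                          0, +1)
    chainB <- build_chain("B", CLASS_REPRESENTATIVE[class_B], seq_len(nB),
                          STRAND_SEPARATION, -1)
    chainAp <- build_chain("A", CLASS_REPRESENTATIVE[class_Ap], seq_len(nA),
                           0, +1)
    chainC <- build_chain("C", CLASS_REPRESENTATIVE[class_C], pos_C,
                          STRAND_SEPARATION, -1)

    atoms2 <- rbind(chainAp, chainC)
    if (spec$coordinate_noise_sigma > 0) {
      n2 <- nrow(atoms2)
      atoms2$x <- atoms2$x + stats::rnorm(n2, 0, spec$coordinate_noise_sigma)
      atoms2$y <- atoms2$y + stats::rnorm(n2, 0, spec$coordinate_noise_sigma)
      atoms2$z <- atoms2$z + stats::rnorm(n2, 0, spec$coordinate_noise_sigma)
    }
    xyz <- apply_transform(as.matrix(atoms2[, c("x", "y", "z")]),
                           spec$planted_transform)
    atoms2$x <- xyz[, 1]; atoms2$y <- xyz[, 2]; atoms2$z <- xyz[, 3]

    all_keys <- c(paste0("1:", unique(chainA$res_key)),
                  paste0("1:", unique(chainB$res_key)),
                  paste0("2:", unique(chainAp$res_key)),
                  paste0("2:", unique(chainC$res_key)))
    conserved <- all_keys[stats::runif(length(all_keys)) <
                            spec$conserved_fraction]
    list(class_A = class_A, class_Ap = class_Ap, class_B = class_B,
         class_C = class_C, pos_C = pos_C, atoms2 = atoms2,
         chainA = chainA, chainB = chainB, conserved = conserved)
  })

  id1 <- paste0(pair_id, "_1")
  id2 <- paste0(pair_id, "_2")
  structure1 <- structure(list(atoms = rbind(out$chainA, out$chainB),
                               id = id1, path = NA_character_),
                          class = "sitesim_structure")
  structure2 <- structure(list(atoms = out$atoms2, id = id2,
                               path = NA_character_),
                          class = "sitesim_structure")
  rownames(structure1$atoms) <- rownames(structure2$atoms) <- NULL

  manifest_entry <- data.frame(
    pair_id = pair_id, pdb1 = paste0(id1, ".pdb"), chainA = "A",
    chainB = "B", pdb2 = paste0(id2, ".pdb"), chainAprime = "A",
    chainC = "C", category = "O", stringsAsFactors = FALSE)

  # ground truth: agreements over the shared (overlap) positions
  shift_pos <- out$pos_C[1] - 1L
  ov_pos <- seq(shift_pos + 1L, spec$n_residues_B)  # scaffold positions
  truth <- list(
    planted_transform = spec$planted_transform,
    shift = shift_pos,
    class_A = out$class_A, class_Aprime = out$class_Ap,
    class_B = out$class_B, class_C = out$class_C, pos_C = out$pos_C,
    overlap_positions = ov_pos,
    n_agree_AA = sum(out$class_A[ov_pos] == out$class_Ap[ov_pos]),
    n_agree_BC = sum(out$class_B[ov_pos] ==
                       out$class_C[match(ov_pos, out$pos_C)]),
    conserved_keys = out$conserved)

  conservation <- synthetic_conservation(structure1, structure2,
                                         out$conserved)

  result <- list(structure1 = structure1, structure2 = structure2,
                 manifest_entry = manifest_entry, truth = truth,
                 conservation = conservation)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(dir, paste0(id1, ".pdb"))
    f2 <- file.path(dir, paste0(id2, ".pdb"))
    write_structure(structure1, f1)
    write_structure(structure2, f2)
    result$files <- c(f1, f2)
  }
  result
}

synthetic_conservation <- function(structure1, structure2, conserved_keys) {
  per_structure <- function(s, tag) {
    res <- s$atoms[!duplicated(s$atoms$res_key), , drop = FALSE]
    key <- paste0(tag, ":", res$res_key)
    data.frame(structure_id = s$id, chain_id = res$chain,
               seq_id = paste0(res$resno, res$ins),
               normalized_score = ifelse(key %in% conserved_keys, -1.5, 0.0),
               stringsAsFactors = FALSE)
  }
  rbind(per_structure(structure1, "1"), per_structure(structure2, "2"))
}

#' Generate a cohort of synthetic pairs
#'
#' @param n_pairs Number of pairs.
#' @param spec Base `synthetic_pair_spec`; each pair gets a derived seed.
#' @param seed Cohort seed.
#' @param dir Directory to write PDB files, `manifest.tsv`,
#'   `conservation.tsv` and `truth.tsv` into; NULL keeps everything in
#'   memory.
#' @return List with `manifest`, `pairs` (list of [generate_pair()] results),
#'   `conservation` and `truth_table`.
#' @export
generate_cohort <- function(n_pairs, spec = synthetic_pair_spec(),
                            seed = spec$seed, dir = NULL) {
  stopifnot(n_pairs >= 0)
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    spec_i <- spec
    spec_i$seed <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    pairs[[i]] <- generate_pair(spec_i, pair_id = sprintf("syn%04d", i),
                                dir = dir)
  }
  manifest <- if (n_pairs > 0) {
    do.call(rbind, lapply(pairs, `[[`, "manifest_entry"))
  } else {
    data.frame(pair_id = character(), pdb1 = character(),
               chainA = character(), chainB = character(),
               pdb2 = character(), chainAprime = character(),
               chainC = character(), category = character())
  }
  conservation <- if (n_pairs > 0) {
    do.call(rbind, lapply(pairs, `[[`, "conservation"))
  } else NULL
  truth_table <- if (n_pairs > 0) {
    do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      t <- pairs[[i]]$truth
      data.frame(pair_id = pairs[[i]]$manifest_entry$pair_id,
                 n_overlap = length(t$overlap_positions),
                 n_agree_AA = t$n_agree_AA, n_agree_BC = t$n_agree_BC,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (!is.null(dir) && n_pairs > 0) {
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(conservation, file.path(dir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_table, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(manifest = manifest, pairs = pairs, conservation = conservation,
       truth_table = truth_table)
}
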