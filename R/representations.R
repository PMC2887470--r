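# Three levels of binding-site representation:
#   ATOM - one typed element per interfacial heavy atom, five atom classes
#   CG   - Zacharias-style reduction: Calpha bead plus one or two side-chain
#          pseudo-atoms per residue (GLY: Calpha only), five classes
#   CA   - one element per interfacial residue at its Calpha, five residue
#          classes
#
# Class tables are loaded from editable TSV data files so the partition can be
# substituted without touching code. Coarse-grain bead classes are derived at
# load time from the atom table: majority class of the member atoms, ties
# resolved toward the more polar class (POSITIVE > NEGATIVE > POLAR >
# NONPOLAR > HYDROPHOBIC priority).

ELEMENT_CLASSES <- c("POSITIVE", "NEGATIVE", "POLAR", "NONPOLAR",
                     "HYDROPHOBIC")
REPRESENTATION_LEVELS <- c("ATOM", "CG", "CA")

#' Canonical heavy atoms of the 20 standard residues
#'
#' @return Named list mapping three-letter residue codes to the PDB names of
#'   their canonical heavy atoms (excluding the terminal OXT).
#' @export
canonical_heavy_atoms <- function() {
  list(
    ALA = c("N","CA","C","O","CB"),
    ARG = c("N","CA","C","O","CB","CG","CD","NE","CZ","NH1","NH2"),
    ASN = c("N","CA","C","O","CB","CG","OD1","ND2"),
    ASP = c("N","CA","C","O","CB","CG","OD1","OD2"),
    CYS = c("N","CA","C","O","CB","SG"),
    GLN = c("N","CA","C","O","CB","CG","CD","OE1","NE2"),
    GLU = c("N","CA","C","O","CB","CG","CD","OE1","OE2"),
    GLY = c("N","CA","C","O"),
    HIS = c("N","CA","C","O","CB","CG","ND1","CD2","CE1","NE2"),
    ILE = c("N","CA","C","O","CB","CG1","CG2","CD1"),
    LEU = c("N","CA","C","O","CB","CG","CD1","CD2"),
    LYS = c("N","CA","C","O","CB","CG","CD","CE","NZ"),
    MET = c("N","CA","C","O","CB","CG","SD","CE"),
    PHE = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ"),
    PRO = c("N","CA","C","O","CB","CG","CD"),
    SER = c("N","CA","C","O","CB","OG"),
    THR = c("N","CA","C","O","CB","OG1","CG2"),
    TRP = c("N","CA","C","O","CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2",
            "CZ3","CH2"),
    TYR = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
    VAL = c("N","CA","C","O","CB","CG1","CG2")
  )
}

#' Load the representation class tables
#'
#' @param atom_table,residue_table,bead_table Optional paths to TSV overrides
#'   with the same columns as the shipped defaults under
#'   `system.file("extdata", package = "sitesim")`: atom_classes.tsv
#'   (aa3, atom_name, class), residue_classes.tsv (aa3, class), cg_beads.tsv
#'   (aa3, bead_index, member_atoms comma-separated).
#' @return A list of class `representation_tables` with components
#'   `atom_class` (named lookup vector keyed "AA3 NAME"), `residue_class`
#'   (named vector keyed by aa3) and `cg_beads` (data.frame with a derived
#'   `class` column).
#' @export
representation_tables <- function(atom_table = NULL, residue_table = NULL,
                                  bead_table = NULL) {
  pkg_file <- function(f) system.file("extdata", f, package = "sitesim",
                                      mustWork = TRUE)
  at <- utils::read.delim(atom_table %||% pkg_file("atom_classes.tsv"),
                          stringsAsFactors = FALSE)
  rt <- utils::read.delim(residue_table %||% pkg_file("residue_classes.tsv"),
                          stringsAsFactors = FALSE)
  bt <- utils::read.delim(bead_table %||% pkg_file("cg_beads.tsv"),
                          stringsAsFactors = FALSE)
  stopifnot(all(at$class %in% ELEMENT_CLASSES),
            all(rt$class %in% ELEMENT_CLASSES))

  atom_class <- at$class
  names(atom_class) <- paste(at$aa3, at$atom_name)
  residue_class <- rt$class
  names(residue_class) <- rt$aa3

  bt$class <- vapply(seq_len(nrow(bt)), function(i) {
    members <- strsplit(bt$member_atoms[i], ",", fixed = TRUE)[[1]]
    cls <- atom_class[paste(bt$aa3[i], members)]
    if (anyNA(cls)) {
      stop("bead table references unknown atoms for ", bt$aa3[i])
    }
    counts <- table(factor(cls, levels = ELEMENT_CLASSES))
    # majority; ties resolved by polarity priority = order of ELEMENT_CLASSES
    ELEMENT_CLASSES[which.max(counts)]
  }, character(1))

  structure(list(atom_class = atom_class, residue_class = residue_class,
                 cg_beads = bt),
            class = "representation_tables")
}

tables_cache <- new.env(parent = emptyenv())

#' Default representation tables (cached)
#' @return The `representation_tables` built from the shipped TSVs.
#' @export
default_tables <- function() {
  if (is.null(tables_cache$tables)) {
    tables_cache$tables <- representation_tables()
  }
  tables_cache$tables
}

#' Classify one heavy atom into the five-class scheme
#'
#' @param aa3 Three-letter residue code.
#' @param atom_name PDB atom name (e.g. "NZ").
#' @param tables A `representation_tables` object.
#' @return One of POSITIVE, NEGATIVE, POLAR, NONPOLAR, HYDROPHOBIC.
#' @export
classify_atom <- function(aa3, atom_name, tables = default_tables()) {
  cls <- unname(tables$atom_class[paste(aa3, atom_name)])
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1]
    stop("no atom class for residue ", aa3[min(bad, length(aa3))],
         ", atom ", atom_name[bad])
  }
  cls
}

#' Classify a residue into the five-class scheme
#' @inheritParams classify_atom
#' @export
classify_residue <- function(aa3, tables = default_tables()) {
  cls <- unname(tables$residue_class[aa3])
  if (anyNA(cls)) stop("no residue class for ", aa3[which(is.na(cls))[1]])
  cls
}

#' Build the typed-element representation of a binding site
#'
#' ATOM level emits one element per interfacial heavy atom; CA level one
#' element per interfacial residue at its Calpha; CG level, per interfacial
#' residue, the Calpha bead plus side-chain pseudo-atoms at the centroid of
#' each bead's member heavy atoms present in the file. Residues missing their
#' Calpha (CA/CG level) and beads with no member atom present are skipped
#' with a warning.
#'
#' @param site A `binding_site`.
#' @param level "ATOM", "CG" or "CA".
#' @param tables A `representation_tables` object.
#' @return data.frame of typed elements: x, y, z, class, level, res_key,
#'   source.
#' @export
build_representation <- function(site, level = c("ATOM", "CG", "CA"),
                                 tables = default_tables()) {
  level <- match.arg(level)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      class = character(), level = character(),
                      res_key = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (length(site$residues) == 0) return(empty)
  a <- site$atoms

  if (level == "ATOM") {
    sel <- a[a$interfacial & a$is_heavy, , drop = FALSE]
    if (nrow(sel) == 0) return(empty)
    return(data.frame(
      x = sel$x, y = sel$y, z = sel$z,
      class = classify_atom(sel$resid, sel$elety, tables),
      level = level, res_key = sel$res_key, source = sel$elety,
      stringsAsFactors = FALSE))
  }

  out <- vector("list", length(site$residues))
  for (i in seq_along(site$residues)) {
    key <- site$residues[i]
    ra <- a[a$res_key == key & a$is_heavy, , drop = FALSE]
    aa3 <- ra$resid[1]
    ca <- ra[ra$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) {
      warning("residue ", key, " (", aa3, ") has no Calpha; skipped at ",
              level, " level")
      next
    }
    if (level == "CA") {
      out[[i]] <- data.frame(
        x = ca$x[1], y = ca$y[1], z = ca$z[1],
        class = classify_residue(aa3, tables),
        level = level, res_key = key, source = "CA",
        stringsAsFactors = FALSE)
    } else {
      beads <- tables$cg_beads[tables$cg_beads$aa3 == aa3, , drop = FALSE]
      if (nrow(beads) == 0) {
        warning("no coarse-grain bead definition for ", aa3, "; residue ",
                key, " skipped")
        next
      }
      rows <- vector("list", nrow(beads))
      for (b in seq_len(nrow(beads))) {
        members <- strsplit(beads$member_atoms[b], ",", fixed = TRUE)[[1]]
        mem <- ra[ra$elety %in% members, , drop = FALSE]
        if (nrow(mem) == 0) {
          warning("bead ", beads$bead_index[b], " of residue ", key, " (",
                  aa3, ") has no member atoms in the file; skipped")
          next
        }
        rows[[b]] <- data.frame(
          x = mean(mem$x), y = mean(mem$y), z = mean(mem$z),
          class = beads$class[b], level = level, res_key = key,
          source = paste0("bead", beads$bead_index[b]),
          stringsAsFactors = FALSE)
      }
      out[[i]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
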