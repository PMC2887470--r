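# Structure parsing and domain selection.
#
# Structures are held as a flat atom table (one row per atom) in the style of
# bio3d's `pdb$atom`, with a per-atom residue key "<chain>:<resno><ins>" that
# follows author numbering throughout (conservation tables and pair manifests
# reference author numbering, so residues are never renumbered).

STANDARD_AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                  "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into a flat atom table. Water and non-amino-acid
#' ligands are excluded; selenomethionine (MSE) is remapped to MET (SE -> SD);
#' other non-standard residues are dropped with a warning. Alternate locations
#' are resolved by keeping, per atom name within a residue, the highest
#' occupancy conformer (ties broken in favour of altloc "A", then file order).
#' Hydrogens are retained but flagged (`is_heavy = FALSE`); all distance-based
#' computations downstream use heavy atoms only.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param model_index 1-based model to read from multi-model files; only a
#'   single model is ever used (crystallographic single-conformation analysis).
#' @param structure_id Label for the structure; defaults to the file base name.
#' @return An object of class `sitesim_structure`: a list with elements
#'   `atoms` (data.frame with columns chain, resno, ins, resid, elety, elesy,
#'   x, y, z, o, is_heavy, res_key), `id` and `path`.
#' @export
read_structure <- function(path, model_index = 1L, structure_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read structure: file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_index > 1L,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (model_index > 1L) {
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || model_index > nmod) {
      stop("model_index ", model_index, " not present in '", path, "'")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # drop water, remap MSE, drop other non-amino-acid / non-standard residues
  at <- at[!(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  is_mse <- at$resid == "MSE"
  if (any(is_mse)) {
    at$resid[is_mse] <- "MET"
    at$elety[is_mse & at$elety == "SE"] <- "SD"
    at$elesy[is_mse & at$elesy == "SE"] <- "S"
  }
  nonstd <- !(at$resid %in% STANDARD_AA3)
  if (any(nonstd)) {
    dropped <- unique(at$resid[nonstd])
    warning("dropping non-standard residues: ", paste(dropped, collapse = ", "))
    at <- at[!nonstd, , drop = FALSE]
  }
  if (nrow(at) == 0) {
    stop("no amino-acid atoms found in '", path, "'")
  }

  # element symbol: prefer the PDB element column, fall back to atom-name
  elesy <- toupper(trimws(as.character(at$elesy)))
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) {
    elesy[miss] <- vapply(at$elety[miss], guess_element, character(1))
  }
  at$elesy <- elesy
  at$is_heavy <- !(elesy %in% c("H", "D"))

  # altloc resolution: per (residue, atom name), keep max occupancy;
  # ties prefer altloc "A", then first encountered
  res_key <- paste0(at$chain, ":", at$resno, at$insert)
  sel_key <- paste(res_key, at$elety)
  if (any(duplicated(sel_key))) {
    at$.file_order <- seq_len(nrow(at))
    ord <- order(sel_key, -at$o, at$alt != "A", at$.file_order)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(sel_key[ord]), , drop = FALSE]
    at <- at[order(at$.file_order), , drop = FALSE]
    res_key <- paste0(at$chain, ":", at$resno, at$insert)
  }

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, ins = at$insert, resid = at$resid,
    elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z, o = at$o,
    is_heavy = at$is_heavy, res_key = res_key,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL

  structure(
    list(atoms = atoms,
         id = if (is.null(structure_id)) sub("\\.pdb$", "", basename(path))
              else structure_id,
         path = path),
    class = "sitesim_structure"
  )
}

guess_element <- function(elety) {
  s <- gsub("[0-9']", "", toupper(trimws(elety)))
  if (nchar(s) == 0) return("")
  # two-letter elements occurring in standard residues + MSE
  if (substr(s, 1, 2) %in% c("SE", "FE", "ZN", "MG")) return(substr(s, 1, 2))
  substr(s, 1, 1)
}

#' @export
print.sitesim_structure <- function(x, ...) {
  cat("sitesim_structure '", x$id, "': ", nrow(x$atoms), " atoms, chains: ",
      paste(unique(x$atoms$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Select one domain (chain) from a parsed structure
#'
#' @param structure A `sitesim_structure`.
#' @param chain_id One-character chain identifier.
#' @return A data.frame of atoms (class `sitesim_domain`) in file order, which
#'   preserves author sequence order including insertion codes.
#' @export
select_domain <- function(structure, chain_id) {
  stopifnot(inherits(structure, "sitesim_structure"))
  avail <- unique(structure$atoms$chain)
  if (!chain_id %in% avail) {
    stop("chain '", chain_id, "' not found in structure '", structure$id,
         "'; available chains: ", paste(avail, collapse = ", "))
  }
  dom <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  rownames(dom) <- NULL
  attr(dom, "structure_id") <- structure$id
  attr(dom, "chain_id") <- chain_id
  class(dom) <- c("sitesim_domain", "data.frame")
  dom
}

#' Residue-level view of a domain
#'
#' @param domain A `sitesim_domain` atom table.
#' @return data.frame with one row per residue (res_key, chain, resno, ins,
#'   resid) in author order.
#' @export
domain_residues <- function(domain) {
  keep <- !duplicated(domain$res_key)
  out <- domain[keep, c("res_key", "chain", "resno", "ins", "resid"),
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a domain or structure back to a PDB file
#'
#' @param x A `sitesim_structure` or `sitesim_domain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  at <- if (inherits(x, "sitesim_structure")) x$atoms else x
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno,
    resid = at$resid,
    insert = ifelse(at$ins == "", "", at$ins),
    chain = at$chain,
    elety = at$elety,
    elesy = at$elesy,
    o = at$o,
    b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Read a pair manifest
#'
#' The manifest is a TSV with columns pair_id, pdb1, chainA, chainB, pdb2,
#' chainAprime, chainC and optionally category (one of O, M, E, I, S or
#' unknown). The category is carried as metadata only; it stratifies summary
#' tables and is never computed by the pipeline.
#'
#' @param path Path to the manifest TSV.
#' @return data.frame with one row per pair.
#' @export
read_pair_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("pair_id", "pdb1", "chainA", "chainB", "pdb2", "chainAprime",
            "chainC")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("pair manifest '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"category" %in% names(m)) m$category <- "unknown"
  m$category[!m$category %in% c("O", "M", "E", "I", "S")] <- "unknown"
  m
}

#' Read per-residue conservation scores
#'
#' Expects a TSV with columns structure_id, chain_id, seq_id (author residue
#' number plus any insertion code) and normalized_score. Chains absent from
#' the table are treated downstream as having no conserved residues.
#'
#' @param path Path to the conservation TSV.
#' @return data.frame of scores.
#' @export
read_conservation <- function(path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "chain_id", "seq_id", "normalized_score")
  missing_cols <- setdiff(need, names(sc))
  if (length(missing_cols)) {
    stop("conservation table '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sc$seq_id <- as.character(sc$seq_id)
  sc$normalized_score <- as.numeric(sc$normalized_score)
  sc
}
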