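# Interface detection: heavy atoms of one chain strictly within the contact
# cutoff (default 5 A) of any heavy atom of the partner chain. A residue is
# part of the binding site if it has at least one interfacial atom.

#' Interface detection parameters
#'
#' @param contact_cutoff Heavy-atom contact distance in Angstrom; an atom is
#'   interfacial when some heavy atom of the partner lies strictly closer than
#'   this. Default 5.0.
#' @return A list of class `interface_params`.
#' @export
interface_params <- function(contact_cutoff = 5.0) {
  stopifnot(is.numeric(contact_cutoff), length(contact_cutoff) == 1,
            contact_cutoff > 0)
  structure(list(contact_cutoff = contact_cutoff), class = "interface_params")
}

# squared-distance matrix between n x 3 and m x 3 coordinate matrices
dist2_matrix <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Detect the binding sites of two interacting domains
#'
#' An atom of one domain is interfacial iff some heavy atom of the other
#' domain lies at Euclidean distance strictly below `contact_cutoff`.
#' Hydrogens never participate. The result is symmetric in the two domains.
#'
#' @param domain1,domain2 `sitesim_domain` atom tables (different chains).
#' @param params An `interface_params` object.
#' @param role1,role2 Optional role labels ("A", "Aprime", "B", "C") carried
#'   on the returned sites.
#' @return List with elements `site1` and `site2`, each a `binding_site`:
#'   a list with `atoms` (all atoms of interfacial residues, with a logical
#'   `interfacial` column), `residues` (res_keys of the site), `owner_role`,
#'   `chain_id` and `n_interfacial_atoms`. Sites may be empty.
#' @export
detect_interface <- function(domain1, domain2, params = interface_params(),
                             role1 = NA_character_, role2 = NA_character_) {
  if (nrow(domain1) == 0 || nrow(domain2) == 0) {
    stop("detect_interface: both domains must contain atoms")
  }
  h1 <- which(domain1$is_heavy)
  h2 <- which(domain2$is_heavy)
  c1 <- as.matrix(domain1[h1, c("x", "y", "z")])
  c2 <- as.matrix(domain2[h2, c("x", "y", "z")])
  cut2 <- params$contact_cutoff^2

  # block over the larger side to bound memory on big chains
  int1 <- logical(length(h1))
  int2 <- logical(length(h2))
  block <- 2000L
  for (start in seq(1L, length(h1), by = block)) {
    idx <- start:min(start + block - 1L, length(h1))
    d2 <- dist2_matrix(c1[idx, , drop = FALSE], c2)
    hit <- d2 < cut2
    int1[idx] <- int1[idx] | (rowSums(hit) > 0)
    int2 <- int2 | (colSums(hit) > 0)
  }

  list(
    site1 = make_binding_site(domain1, h1[int1], role1),
    site2 = make_binding_site(domain2, h2[int2], role2)
  )
}

make_binding_site <- function(domain, interfacial_idx, role) {
  int_keys <- unique(domain$res_key[interfacial_idx])
  flag <- logical(nrow(domain))
  flag[interfacial_idx] <- TRUE
  keep <- domain$res_key %in% int_keys
  atoms <- domain[keep, , drop = FALSE]
  atoms$interfacial <- flag[keep]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms,
         residues = int_keys,
         owner_role = role,
         chain_id = attr(domain, "chain_id"),
         structure_id = attr(domain, "structure_id"),
         n_interfacial_atoms = length(interfacial_idx)),
    class = "binding_site"
  )
}

#' @export
print.binding_site <- function(x, ...) {
  cat("binding_site (role ", x$owner_role, ", chain ", x$chain_id, "): ",
      x$n_interfacial_atoms, " interfacial atoms in ",
      length(x$residues), " residues\n", sep = "")
  invisible(x)
}

#' Export binding-site residues as a table
#'
#' @param site A `binding_site`.
#' @return data.frame with structure_id, chain, seq_id, aa3 and the number of
#'   interfacial atoms per residue.
#' @export
binding_site_table <- function(site) {
  if (length(site$residues) == 0) {
    return(data.frame(structure_id = character(), chain = character(),
                      seq_id = character(), aa3 = character(),
                      n_interfacial_atoms = integer()))
  }
  a <- site$atoms
  per <- tapply(a$interfacial, a$res_key, sum)
  first <- a[!duplicated(a$res_key), , drop = FALSE]
  data.frame(
    structure_id = site$structure_id %||% NA_character_,
    chain = first$chain,
    seq_id = paste0(first$resno, first$ins),
    aa3 = first$resid,
    n_interfacial_atoms = as.integer(per[first$res_key]),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
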