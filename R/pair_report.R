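# Single-pair convenience wrapper: load two complexes, superpose the
# homologous domains, and report counts and p-values at the requested levels.

#' Compare one AB / A'C pair of complexes
#'
#' Convenience wrapper around [read_structure()], [superpose_pair()] and
#' [compute_similarity()] for a single pair, e.g. for a deep report on one
#' case of interest.
#'
#' @param pdb1,pdb2 Paths to the two PDB files.
#' @param chainA,chainB Chains of the homologous (A) and partner (B) domains
#'   in complex 1.
#' @param chainAprime,chainC Chains of A' and C in complex 2.
#' @param levels Representation levels to compute.
#' @param params,iface_params,tables See [compute_similarity()].
#' @return List with `results` (rows per level x site), `alignment` (rmsd,
#'   irmsd, matched pair count) and the `superposed_pair`.
#' @export
compare_pair <- function(pdb1, chainA, chainB, pdb2, chainAprime, chainC,
                         levels = c("ATOM", "CG", "CA"),
                         params = match_params(),
                         iface_params = interface_params(),
                         tables = default_tables()) {
  s1 <- read_structure(pdb1)
  s2 <- read_structure(pdb2)
  sp <- superpose_pair(select_domain(s1, chainA), select_domain(s1, chainB),
                       select_domain(s2, chainAprime),
                       select_domain(s2, chainC),
                       iface_params = iface_params)
  rows <- lapply(levels, function(level) {
    compute_similarity(sp, level, params, iface_params, tables)
  })
  list(results = do.call(rbind, rows), alignment = sp$alignment,
       superposed = sp)
}
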