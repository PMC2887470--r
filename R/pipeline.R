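# End-to-end orchestration: validate manifest pairs, superpose, compare at
# the requested representation levels, bootstrap, summarize, and write a run
# report. Per-pair failures are logged and skipped; they never abort a run.

#' Pipeline run configuration
#'
#' @param manifest Path to the pair manifest TSV (see
#'   [read_pair_manifest()]).
#' @param structure_dir Directory containing the PDB files named in the
#'   manifest.
#' @param output_dir Directory for result tables and the run report.
#' @param conservation Optional path to a conservation TSV.
#' @param levels Representation levels to run (subset of ATOM, CG, CA).
#' @param iface_params,params Interface and match/bootstrap parameters.
#' @param tables Representation tables (overridable).
#' @param max_missing_heavy_fraction An interfacial residue missing more than
#'   this fraction of its canonical heavy atoms (or its Calpha) marks the
#'   pair as having missing coordinates at the binding site (default 0.5).
#' @param seed Run seed; overrides `params$rng_seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(manifest, structure_dir, output_dir,
                       conservation = NULL,
                       levels = c("ATOM", "CG", "CA"),
                       iface_params = interface_params(),
                       params = match_params(),
                       tables = NULL,
                       max_missing_heavy_fraction = 0.5,
                       seed = NULL) {
  stopifnot(file.exists(manifest), dir.exists(structure_dir),
            all(levels %in% REPRESENTATION_LEVELS))
  if (!is.null(seed)) params$rng_seed <- as.integer(seed)
  structure(list(manifest = manifest, structure_dir = structure_dir,
                 output_dir = output_dir, conservation = conservation,
                 levels = levels, iface_params = iface_params,
                 params = params, tables = tables,
                 max_missing_heavy_fraction = max_missing_heavy_fraction),
            class = "run_config")
}

# missing-coordinates proxy: any interfacial residue lacking its Calpha or
# more than `max_missing` of its canonical heavy atoms
missing_atoms_at_site <- function(site, max_missing = 0.5) {
  canon <- canonical_heavy_atoms()
  bad <- character(0)
  for (key in site$residues) {
    ra <- site$atoms[site$atoms$res_key == key & site$atoms$is_heavy, ,
                     drop = FALSE]
    aa3 <- ra$resid[1]
    expected <- canon[[aa3]]
    if (is.null(expected)) next
    if (!"CA" %in% ra$elety ||
        mean(!(expected %in% ra$elety)) > max_missing) {
      bad <- c(bad, key)
    }
  }
  bad
}

#' Validate one manifest pair
#'
#' Rejects pairs whose partners share a chain (intra-chain interaction),
#' whose structures cannot be loaded or aligned, whose binding sites contain
#' residues with missing coordinates (no Calpha or more than half of the
#' canonical heavy atoms absent), or whose B/C overlap is empty (zero
#' superimposed Calpha elements on B or C after superposition).
#'
#' @param entry One-row data.frame from the manifest.
#' @param structures Named list with `s1`, `s2` (`sitesim_structure`), or
#'   NULL to load from `structure_dir`.
#' @param config A `run_config`.
#' @return List with `ok` (logical), `reason` (string, when rejected) and,
#'   when accepted, the `superposed_pair` ready for comparison.
#' @export
validate_pair <- function(entry, structures = NULL, config) {
  rej <- function(reason) list(ok = FALSE, reason = reason)
  if (entry$chainA == entry$chainB) {
    return(rej("intra-chain interaction in complex 1"))
  }
  if (entry$chainAprime == entry$chainC) {
    return(rej("intra-chain interaction in complex 2"))
  }
  if (is.null(structures)) {
    structures <- tryCatch(
      list(s1 = read_structure(file.path(config$structure_dir, entry$pdb1)),
           s2 = read_structure(file.path(config$structure_dir, entry$pdb2))),
      error = function(e) e)
    if (inherits(structures, "error")) {
      return(rej(paste("unloadable structure:",
                       conditionMessage(structures))))
    }
  }
  doms <- tryCatch(list(
    A = select_domain(structures$s1, entry$chainA),
    B = select_domain(structures$s1, entry$chainB),
    Ap = select_domain(structures$s2, entry$chainAprime),
    C = select_domain(structures$s2, entry$chainC)),
    error = function(e) e)
  if (inherits(doms, "error")) {
    return(rej(paste("missing chain:", conditionMessage(doms))))
  }
  sp <- tryCatch(
    superpose_pair(doms$A, doms$B, doms$Ap, doms$C,
                   iface_params = config$iface_params),
    error = function(e) e)
  if (inherits(sp, "error")) {
    return(rej(paste("superposition failed:", conditionMessage(sp))))
  }
  sites <- pair_binding_sites(sp, config$iface_params)
  for (role in names(sites)) {
    if (length(sites[[role]]$residues) == 0) {
      return(rej(paste0("empty binding site on ", role)))
    }
    bad <- missing_atoms_at_site(sites[[role]],
                                 config$max_missing_heavy_fraction)
    if (length(bad)) {
      return(rej(paste0("missing atomic coordinates at the binding site of ",
                        role, " (", length(bad), " residues)")))
    }
  }
  # minimum-overlap rule: superimposed Calpha elements on the B/C side
  repB <- build_representation(sites$B, "CA", config$tables %||%
                                 default_tables())
  repC <- build_representation(sites$C, "CA", config$tables %||%
                                 default_tables())
  cm <- count_matches(repB, repC, config$params$match_cutoff_ca)
  if (cm$n_superimposed_1 == 0 || cm$n_superimposed_2 == 0) {
    return(rej("no superimposed elements on the B/C side"))
  }
  list(ok = TRUE, reason = NA_character_, superposed = sp)
}

#' Run the full binding-site similarity pipeline
#'
#' @param config A `run_config`.
#' @return List with `results` (per pair x level x site rows), `rejections`,
#'   `conservation_results` (when a conservation table was given), `summary`
#'   and the paths of the written files. Re-running with an identical config
#'   produces identical outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- read_pair_manifest(config$manifest)
  conservation <- if (!is.null(config$conservation)) {
    read_conservation(config$conservation)
  } else NULL
  tables <- config$tables %||% default_tables()

  results <- list()
  cons_results <- list()
  rejections <- list()
  report <- c(
    paste0("sitesim run report (version ",
           as.character(utils::packageVersion("sitesim")), ")"),
    paste0("manifest: ", config$manifest),
    paste0("structure_dir: ", config$structure_dir),
    paste0("levels: ", paste(config$levels, collapse = ",")),
    paste0("contact_cutoff: ", config$iface_params$contact_cutoff),
    paste0("match_cutoffs (ATOM/CG/CA): ",
           config$params$match_cutoff_atom, "/",
           config$params$match_cutoff_cg, "/",
           config$params$match_cutoff_ca),
    paste0("n_bootstrap: ", config$params$n_bootstrap),
    paste0("shuffle: ", config$params$shuffle),
    paste0("rng_seed: ", config$params$rng_seed),
    "")

  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, , drop = FALSE]
    params_i <- config$params
    # per-pair seed stream derived from the run seed and the pair index
    params_i$rng_seed <- as.integer(
      (as.numeric(config$params$rng_seed) + 65537 * i) %% 2147483647)
    v <- tryCatch(validate_pair(entry, structures = NULL, config = config),
                  error = function(e) list(ok = FALSE,
                                           reason = conditionMessage(e)))
    if (!v$ok) {
      rejections[[length(rejections) + 1]] <-
        data.frame(pair_id = entry$pair_id, reason = v$reason,
                   stringsAsFactors = FALSE)
      report <- c(report, paste0("REJECT ", entry$pair_id, ": ", v$reason))
      next
    }
    tfm <- v$superposed$transform
    report <- c(report,
                paste0("ACCEPT ", entry$pair_id,
                       " rmsd=", format(v$superposed$alignment$rmsd,
                                        digits = 4),
                       " irmsd=", format(v$superposed$alignment$irmsd,
                                         digits = 4),
                       " transform=",
                       paste(format(cbind(tfm$rotation, tfm$translation),
                                    digits = 4), collapse = " ")))
    for (level in config$levels) {
      res <- compute_similarity(v$superposed, level, params_i,
                                config$iface_params, tables)
      res$pair_id <- entry$pair_id
      res$category <- entry$category
      results[[length(results) + 1]] <- res
    }
    if (!is.null(conservation)) {
      ids <- c(A = sub("\\.pdb$", "", entry$pdb1),
               Aprime = sub("\\.pdb$", "", entry$pdb2),
               B = sub("\\.pdb$", "", entry$pdb1),
               C = sub("\\.pdb$", "", entry$pdb2))
      cr <- conservation_colocalization(v$superposed, conservation,
                                        params_i, config$iface_params,
                                        structure_ids = ids)
      cr$pair_id <- entry$pair_id
      cr$category <- entry$category
      cons_results[[length(cons_results) + 1]] <- cr
    }
  }

  if (length(results) == 0) {
    stop("run_pipeline: no pair passed validation")
  }
  results <- do.call(rbind, results)
  rejections <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(pair_id = character(), reason = character())
  cons_results <- if (length(cons_results)) do.call(rbind, cons_results) else
    NULL
  summary <- if (length(unique(results$pair_id)) >= 2) {
    summarize_similarity(results)
  } else NULL

  out <- list(results = results, rejections = rejections,
              conservation_results = cons_results, summary = summary,
              report = report)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wpath <- function(f) file.path(config$output_dir, f)
    utils::write.table(results, wpath("similarity_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rejections, wpath("rejections.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(cons_results)) {
      utils::write.table(cons_results, wpath("conservation_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(summary)) {
      utils::write.table(summary$means, wpath("summary_means.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summary$correlations,
                         wpath("summary_correlations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    writeLines(report, wpath("run_report.txt"))
    out$files <- wpath(c("similarity_results.tsv", "rejections.tsv",
                         "run_report.txt"))
  }
  out
}
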