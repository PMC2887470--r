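# Counting superimposed and similar elements between superposed binding
# sites, and assessing significance with a label-shuffling bootstrap.
#
# An element of one site is "superimposed" if ANY element of the partner site
# lies strictly within the match cutoff (an existence test, not a one-to-one
# matching: several elements can be matched by the same partner point), and
# "similar" if some within-cutoff partner element carries the same class.
# The null model permutes the class labels among the overlapping (i.e.
# superimposed) elements of one site while the partner's labels stay fixed;
# geometry, and therefore the number of superimposed elements, is unchanged
# by construction. The p-value is the plain proportion of replicates whose
# similar count reaches the observed one, so an observed count of zero gives
# p = 1 exactly.

#' Match-counting and bootstrap parameters
#'
#' @param match_cutoff_atom Distance cutoff in Angstrom for similar/
#'   superimposed elements at the all-atom level (default 3).
#' @param match_cutoff_cg,match_cutoff_ca Cutoffs for the coarse-grain and
#'   Calpha levels (default 4; the reduced representations describe residues
#'   with fewer points, so a larger tolerance is used).
#' @param n_bootstrap Number of bootstrap replicates (default 500).
#' @param rng_seed Integer seed for the bootstrap streams.
#' @param shuffle Either "permute" (permute the observed labels, preserving
#'   the class composition; the default) or "redraw" (i.i.d. redraw from the
#'   observed label frequencies; for sensitivity analysis).
#' @return List of class `match_params`.
#' @export
match_params <- function(match_cutoff_atom = 3.0, match_cutoff_cg = 4.0,
                         match_cutoff_ca = 4.0, n_bootstrap = 500L,
                         rng_seed = 1L, shuffle = c("permute", "redraw")) {
  shuffle <- match.arg(shuffle)
  stopifnot(match_cutoff_atom > 0, match_cutoff_cg > 0, match_cutoff_ca > 0,
            n_bootstrap >= 1)
  structure(list(match_cutoff_atom = match_cutoff_atom,
                 match_cutoff_cg = match_cutoff_cg,
                 match_cutoff_ca = match_cutoff_ca,
                 n_bootstrap = as.integer(n_bootstrap),
                 rng_seed = as.integer(rng_seed),
                 shuffle = shuffle),
            class = "match_params")
}

level_cutoff <- function(params, level) {
  switch(level,
         ATOM = params$match_cutoff_atom,
         CG = params$match_cutoff_cg,
         CA = params$match_cutoff_ca,
         stop("unknown level: ", level))
}

# For each element of `self`, which partner elements lie strictly within the
# cutoff, and which classes do they carry? Returns:
#   superimposed: logical per self element
#   near_class: n_self x 5 logical matrix (classes present within cutoff)
match_geometry <- function(self, other, cutoff) {
  n <- nrow(self)
  near_class <- matrix(FALSE, n, length(ELEMENT_CLASSES),
                       dimnames = list(NULL, ELEMENT_CLASSES))
  if (n == 0 || nrow(other) == 0) {
    return(list(superimposed = logical(n), near_class = near_class))
  }
  d2 <- dist2_matrix(as.matrix(self[, c("x", "y", "z")]),
                     as.matrix(other[, c("x", "y", "z")]))
  within <- d2 < cutoff^2
  sup <- rowSums(within) > 0
  other_cls <- factor(other$class, levels = ELEMENT_CLASSES)
  for (k in seq_along(ELEMENT_CLASSES)) {
    cols <- which(other_cls == ELEMENT_CLASSES[k])
    if (length(cols)) {
      near_class[, k] <- rowSums(within[, cols, drop = FALSE]) > 0
    }
  }
  list(superimposed = sup, near_class = near_class)
}

#' Count superimposed and similar elements between two superposed sites
#'
#' @param site1,site2 Typed-element data.frames (from
#'   [build_representation()]) in a common frame.
#' @param cutoff Match cutoff in Angstrom (strict inequality).
#' @return Named list: n_superimposed_1, n_similar_1, n_superimposed_2,
#'   n_similar_2.
#' @export
count_matches <- function(site1, site2, cutoff) {
  g1 <- match_geometry(site1, site2, cutoff)
  g2 <- match_geometry(site2, site1, cutoff)
  sim1 <- similar_count(site1$class, g1$near_class)
  sim2 <- similar_count(site2$class, g2$near_class)
  list(n_superimposed_1 = sum(g1$superimposed), n_similar_1 = sim1,
       n_superimposed_2 = sum(g2$superimposed), n_similar_2 = sim2)
}

similar_count <- function(labels, near_class) {
  if (length(labels) == 0) return(0L)
  idx <- match(labels, ELEMENT_CLASSES)
  sum(near_class[cbind(seq_along(labels), idx)])
}

#' Bootstrap p-value for the similarity of one binding site
#'
#' Restricts the tested site to its overlapping elements (those superimposed
#' with respect to the partner site), then repeatedly shuffles the class
#' labels among those positions (partner labels fixed) and recomputes the
#' similar count. p = #\{replicates with N_rand >= N_obs\} / n_reps.
#'
#' @param site_self Typed elements of the tested site.
#' @param site_other Typed elements of the partner site (labels held fixed).
#' @param cutoff Match cutoff in Angstrom.
#' @param n_reps Number of replicates.
#' @param seed Integer seed (local RNG stream; the global RNG state is not
#'   touched).
#' @param shuffle "permute" or "redraw" (see [match_params()]).
#' @return Numeric p-value in \[0, 1\] with attributes `n_obs`,
#'   `n_superimposed`.
#' @export
bootstrap_pvalue <- function(site_self, site_other, cutoff, n_reps = 500L,
                             seed = 1L, shuffle = "permute") {
  g <- match_geometry(site_self, site_other, cutoff)
  n_sup <- sum(g$superimposed)
  if (n_sup == 0) {
    return(structure(1, n_obs = 0L, n_superimposed = 0L))
  }
  labels <- site_self$class[g$superimposed]
  near <- g$near_class[g$superimposed, , drop = FALSE]
  n_obs <- similar_count(labels, near)
  if (n_obs == 0) {
    # the null cannot produce a similar count below zero
    return(structure(1, n_obs = 0L, n_superimposed = n_sup))
  }
  idx0 <- match(labels, ELEMENT_CLASSES)
  n_rand <- integer(n_reps)
  with_local_rng(seed, {
    for (r in seq_len(n_reps)) {
      idx <- if (shuffle == "permute") {
        idx0[sample.int(length(idx0))]
      } else {
        sample(idx0, length(idx0), replace = TRUE)
      }
      n_rand[r] <- sum(near[cbind(seq_along(idx), idx)])
    }
  })
  structure(mean(n_rand >= n_obs), n_obs = n_obs, n_superimposed = n_sup)
}

# evaluate `expr` under a locally seeded RNG, restoring the caller's state
with_local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# per-site seed derivation: run seed plus a fixed large odd multiplier per
# role, folded into the 32-bit signed range
site_seed <- function(rng_seed, role) {
  role_index <- match(role, c("A", "Aprime", "B", "C"))
  as.integer((as.numeric(rng_seed) + role_index * 100003) %% 2147483647)
}

#' Compare the four binding sites of a superposed pair at one level
#'
#' Builds the typed-element representations of the A, A', B and C binding
#' sites, counts superimposed/similar elements for A vs A' and B vs C, and
#' computes one bootstrap p-value per site (each site's labels shuffled in
#' turn while the partner's are held fixed).
#'
#' @param sp A `superposed_pair`.
#' @param level "ATOM", "CG" or "CA".
#' @param params A `match_params`.
#' @param iface_params An `interface_params` for binding-site detection.
#' @param tables Representation tables.
#' @return data.frame of class `similarity_result`: one row per site (A,
#'   Aprime, B, C) with n_elements, n_superimposed, n_similar,
#'   similarity_ratio (NA when n_superimposed = 0) and p_value.
#' @export
compute_similarity <- function(sp, level = c("ATOM", "CG", "CA"),
                               params = match_params(),
                               iface_params = interface_params(),
                               tables = default_tables()) {
  level <- match.arg(level)
  stopifnot(inherits(sp, "superposed_pair"))
  sites <- pair_binding_sites(sp, iface_params)
  reps <- lapply(sites, build_representation, level = level, tables = tables)
  cutoff <- level_cutoff(params, level)

  cm_a <- count_matches(reps$A, reps$Aprime, cutoff)
  cm_b <- count_matches(reps$B, reps$C, cutoff)

  partner <- c(A = "Aprime", Aprime = "A", B = "C", C = "B")
  rows <- lapply(c("A", "Aprime", "B", "C"), function(role) {
    self <- reps[[role]]
    other <- reps[[partner[[role]]]]
    p <- bootstrap_pvalue(self, other, cutoff, n_reps = params$n_bootstrap,
                          seed = site_seed(params$rng_seed, role),
                          shuffle = params$shuffle)
    n_sup <- attr(p, "n_superimposed")
    n_sim <- attr(p, "n_obs")
    data.frame(site = role, level = level,
               n_elements = nrow(self),
               n_superimposed = n_sup,
               n_similar = n_sim,
               similarity_ratio = if (n_sup > 0) n_sim / n_sup else NA_real_,
               p_value = as.numeric(p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # cross-check against the joint count (existence-test symmetry)
  stopifnot(res$n_superimposed[1] == cm_a$n_superimposed_1,
            res$n_similar[1] == cm_a$n_similar_1,
            res$n_superimposed[3] == cm_b$n_superimposed_1,
            res$n_similar[3] == cm_b$n_similar_1)
  class(res) <- c("similarity_result", "data.frame")
  res
}

pair_binding_sites <- function(sp, iface_params = interface_params()) {
  s1 <- detect_interface(sp$domA, sp$domB, iface_params,
                         role1 = "A", role2 = "B")
  s2 <- detect_interface(sp$domAprime, sp$domC, iface_params,
                         role1 = "Aprime", role2 = "C")
  list(A = s1$site1, B = s1$site2, Aprime = s2$site1, C = s2$site2)
}

#' Conservation co-localization analysis of a superposed pair
#'
#' Calpha-level variant with binary labels: interface residues are labelled
#' conserved (normalized conservation score strictly below `threshold`) or
#' unconserved; residues of chains without scores are all unconserved. Only
#' conserved residues are candidates: a conserved residue co-localizes iff a
#' conserved residue of the partner site lies strictly within the Calpha
#' match cutoff. The bootstrap shuffles the conservation labels over the
#' overlapping interface positions. Sites with zero superimposed conserved
#' residues are flagged excluded (p = 1).
#'
#' @param sp A `superposed_pair`.
#' @param conservation data.frame from [read_conservation()], or NULL (all
#'   residues unconserved).
#' @param params A `match_params` (the Calpha cutoff is used).
#' @param iface_params An `interface_params`.
#' @param threshold Conservation threshold (default -1; scores below it mark
#'   conserved residues).
#' @param structure_ids Named character vector mapping roles A, Aprime, B, C
#'   to the structure_id values used in the conservation table.
#' @return data.frame: one row per site with n_elements (interface residues),
#'   n_conserved, n_superimposed_conserved, n_colocalized, p_value, excluded.
#' @export
conservation_colocalization <- function(sp, conservation = NULL,
                                        params = match_params(),
                                        iface_params = interface_params(),
                                        threshold = -1.0,
                                        structure_ids = NULL) {
  stopifnot(inherits(sp, "superposed_pair"))
  sites <- pair_binding_sites(sp, iface_params)
  reps <- lapply(sites, build_representation, level = "CA")
  cutoff <- params$match_cutoff_ca

  lab <- lapply(c("A", "Aprime", "B", "C"), function(role) {
    conserved_labels(reps[[role]], sites[[role]], conservation, threshold,
                     if (!is.null(structure_ids)) structure_ids[[role]]
                     else sites[[role]]$structure_id)
  })
  names(lab) <- c("A", "Aprime", "B", "C")

  partner <- c(A = "Aprime", Aprime = "A", B = "C", C = "B")
  rows <- lapply(c("A", "Aprime", "B", "C"), function(role) {
    r <- colocalization_pvalue(
      reps[[role]], lab[[role]], reps[[partner[[role]]]],
      lab[[partner[[role]]]], cutoff, n_reps = params$n_bootstrap,
      seed = site_seed(params$rng_seed, role))
    data.frame(site = role, level = "CA_CONSERVATION",
               n_elements = nrow(reps[[role]]),
               n_conserved = sum(lab[[role]]),
               n_superimposed_conserved = r$n_superimposed_conserved,
               n_colocalized = r$n_obs,
               p_value = r$p,
               excluded = r$excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

conserved_labels <- function(rep_ca, site, conservation, threshold,
                             structure_id) {
  if (nrow(rep_ca) == 0) return(logical(0))
  if (is.null(conservation)) return(rep(FALSE, nrow(rep_ca)))
  a <- site$atoms[!duplicated(site$atoms$res_key), , drop = FALSE]
  seq_ids <- paste0(a$resno, a$ins)[match(rep_ca$res_key, a$res_key)]
  sub <- conservation[conservation$structure_id == structure_id &
                        conservation$chain_id == site$chain_id, ,
                      drop = FALSE]
  if (nrow(sub) == 0) return(rep(FALSE, nrow(rep_ca)))
  scores <- sub$normalized_score[match(seq_ids, sub$seq_id)]
  out <- !is.na(scores) & scores < threshold
  out
}

colocalization_pvalue <- function(rep_self, lab_self, rep_other, lab_other,
                                  cutoff, n_reps = 500L, seed = 1L) {
  g <- match_geometry(rep_self, rep_other, cutoff)
  if (nrow(rep_other) > 0 && length(lab_other) > 0) {
    d2 <- dist2_matrix(as.matrix(rep_self[, c("x", "y", "z")]),
                       as.matrix(rep_other[, c("x", "y", "z")]))
    near_cons <- rowSums(d2[, lab_other, drop = FALSE] < cutoff^2) > 0
  } else {
    near_cons <- logical(nrow(rep_self))
  }
  sup <- g$superimposed
  n_sup_cons <- sum(sup & lab_self)
  if (n_sup_cons == 0) {
    return(list(p = 1, n_obs = 0L, n_superimposed_conserved = 0L,
                excluded = TRUE))
  }
  lab_ov <- lab_self[sup]
  near_ov <- near_cons[sup]
  n_obs <- sum(lab_ov & near_ov)
  if (n_obs == 0) {
    return(list(p = 1, n_obs = 0L, n_superimposed_conserved = n_sup_cons,
                excluded = FALSE))
  }
  n_rand <- integer(n_reps)
  with_local_rng(seed, {
    for (r in seq_len(n_reps)) {
      perm <- lab_ov[sample.int(length(lab_ov))]
      n_rand[r] <- sum(perm & near_ov)
    }
  })
  list(p = mean(n_rand >= n_obs), n_obs = n_obs,
       n_superimposed_conserved = n_sup_cons, excluded = FALSE)
}

#' Summarize similarity results over a cohort
#'
#' @param results data.frame of per-site rows (rbind of
#'   [compute_similarity()] outputs) with added `pair_id` and optionally
#'   `category` columns.
#' @param alpha Significance threshold for the p-value fractions (default
#'   0.05).
#' @return List with `means` (per category x level: mean similar counts on
#'   the homologous and non-homologous sides and their ratio), `correlations`
#'   (per level: Pearson r between homologous- and non-homologous-side
#'   counts, between ratios, and between overlap fraction and similar
#'   fraction) and `significant_fraction` (per level and side: fraction of
#'   p-values below `alpha`).
#' @export
summarize_similarity <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) >= 2,
            all(c("pair_id", "site", "level", "n_superimposed", "n_similar",
                  "p_value") %in% names(results)))
  if (!"category" %in% names(results)) results$category <- "unknown"
  results$side <- ifelse(results$site %in% c("A", "Aprime"), "homolog",
                         "partner")

  # per pair x level: mean similar count per side (two complexes per pair,
  # i.e. A and Aprime rows, B and C rows)
  agg <- stats::aggregate(
    cbind(n_similar, n_superimposed, n_elements) ~
      pair_id + category + level + side,
    data = results, FUN = mean)
  wide <- merge(
    agg[agg$side == "homolog",
        c("pair_id", "category", "level", "n_similar", "n_superimposed",
          "n_elements")],
    agg[agg$side == "partner",
        c("pair_id", "level", "n_similar", "n_superimposed", "n_elements")],
    by = c("pair_id", "level"), suffixes = c("_h", "_p"))

  mean_block <- function(d) {
    data.frame(n_pairs = nrow(d),
               mean_similar_homolog = mean(d$n_similar_h),
               mean_similar_partner = mean(d$n_similar_p),
               ratio = if (mean(d$n_similar_p) > 0)
                 mean(d$n_similar_h) / mean(d$n_similar_p) else NA_real_)
  }
  means <- do.call(rbind, lapply(
    split(wide, list(wide$category, wide$level), drop = TRUE),
    function(d) cbind(category = d$category[1], level = d$level[1],
                      mean_block(d))))
  overall <- do.call(rbind, lapply(split(wide, wide$level), function(d)
    cbind(category = "Total", level = d$level[1], mean_block(d))))
  means <- rbind(means, overall)
  rownames(means) <- NULL

  safe_cor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])
  }
  correlations <- do.call(rbind, lapply(split(wide, wide$level), function(d) {
    ratio_h <- ifelse(d$n_superimposed_h > 0,
                      d$n_similar_h / d$n_superimposed_h, NA)
    ratio_p <- ifelse(d$n_superimposed_p > 0,
                      d$n_similar_p / d$n_superimposed_p, NA)
    # overlap fraction vs similar fraction, pooled over sides
    ov <- c(d$n_superimposed_h / pmax(d$n_elements_h, 1),
            d$n_superimposed_p / pmax(d$n_elements_p, 1))
    sf <- c(d$n_similar_h / pmax(d$n_elements_h, 1),
            d$n_similar_p / pmax(d$n_elements_p, 1))
    data.frame(level = d$level[1],
               cor_similar_counts = safe_cor(d$n_similar_h, d$n_similar_p),
               cor_similarity_ratios = safe_cor(ratio_h, ratio_p),
               cor_overlap_vs_similar_fraction = safe_cor(ov, sf))
  }))
  rownames(correlations) <- NULL

  sig <- stats::aggregate(p_value ~ level + side, data = results,
                          FUN = function(p) mean(p < alpha))
  names(sig)[names(sig) == "p_value"] <- "fraction_significant"

  list(means = means, correlations = correlations,
       significant_fraction = sig)
}
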