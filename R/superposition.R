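# Rigid superposition of the homologous domains A and A'. Residue
# correspondence comes from a global sequence alignment (homologs within one
# family share >30% identity, where sequence-guided correspondence is
# reliable); the least-squares transform is fitted on matched Calpha pairs of
# the whole domains and then applied to every atom of A' and of its partner C.

#' Global sequence alignment of two domains
#'
#' Aligns the amino-acid sequences of the two domains globally (affine gaps,
#' standard substitution matrix) and returns the matched residue pairs,
#' excluding gap positions.
#'
#' @param domA,domAprime `sitesim_domain` atom tables.
#' @param substitution_matrix Name of the substitution matrix (default
#'   "BLOSUM62").
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1; a gap
#'   of length L costs gap_open + L * gap_extend).
#' @return data.frame with columns key_a, key_aprime (residue keys) and
#'   pos_a, pos_aprime (1-based residue indices).
#' @export
align_sequences <- function(domA, domAprime,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  resA <- domain_residues(domA)
  resB <- domain_residues(domAprime)
  if (nrow(resA) < 3 || nrow(resB) < 3) {
    stop("align_sequences: both domains need at least 3 residues")
  }
  seqA <- paste(bio3d::aa321(resA$resid), collapse = "")
  seqB <- paste(bio3d::aa321(resB$resid), collapse = "")
  mat <- get(data(list = substitution_matrix,
                  package = "Biostrings", envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  alnA <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  alnB <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- ib <- 0L
  pos_a <- pos_b <- integer(0)
  for (k in seq_along(alnA)) {
    if (alnA[k] != "-") ia <- ia + 1L
    if (alnB[k] != "-") ib <- ib + 1L
    if (alnA[k] != "-" && alnB[k] != "-") {
      pos_a <- c(pos_a, ia)
      pos_b <- c(pos_b, ib)
    }
  }
  if (length(pos_a) < 3) {
    stop("align_sequences: fewer than 3 matched residue pairs; cannot ",
         "superimpose")
  }
  data.frame(key_a = resA$res_key[pos_a], key_aprime = resB$res_key[pos_b],
             pos_a = pos_a, pos_aprime = pos_b, stringsAsFactors = FALSE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R %*% y + t` onto `x` over corresponding points.
#'
#' @param coords_target n x 3 matrix of reference points (domain A).
#' @param coords_mobile n x 3 matrix of points to move (domain A'), in
#'   correspondence order with `coords_target`.
#' @return List of class `rigid_transform` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` after fitting.
#' @export
fit_transform <- function(coords_target, coords_mobile) {
  x <- as.matrix(coords_target)
  y <- as.matrix(coords_mobile)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y))
  n <- nrow(x)
  if (n < 3) stop("fit_transform: need at least 3 point pairs")
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  sv <- svd(crossprod(yc, xc))   # 3x3 covariance t(yc) %*% xc
  if (sv$d[2] < 1e-10) {
    warning("fit_transform: near-degenerate (collinear) point set; ",
            "rotation may be ill-determined")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # maps mobile -> target frame
  trans <- as.numeric(cx - rot %*% cy)
  moved <- tcrossprod(yc, rot)  # rotated centered mobile
  rmsd <- sqrt(mean(rowSums((sweep(x, 2, cx) - moved)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' Build a rigid transform from a rotation and translation
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 numeric vector.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            det(rotation) > 0, length(translation) == 3)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = NA_real_),
            class = "rigid_transform")
}

#' Rotation about an axis by an angle
#' @param axis Length-3 axis (normalized internally).
#' @param angle Angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ca * diag(3) + sa * ux + (1 - ca) * tcrossprod(u)
}

#' Apply a rigid transform to coordinates or a domain
#'
#' A domain is marked as transformed; transforming it a second time is an
#' error (guard against accidental double application).
#'
#' @param x An n x 3 coordinate matrix or a `sitesim_domain`.
#' @param transform A `rigid_transform`.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "sitesim_domain") || is.data.frame(x)) {
    if (isTRUE(attr(x, "transformed"))) {
      stop("apply_transform: domain has already been transformed")
    }
    xyz <- as.matrix(x[, c("x", "y", "z")])
    moved <- sweep(tcrossprod(xyz, transform$rotation), 2,
                   transform$translation, "+")
    x$x <- moved[, 1]; x$y <- moved[, 2]; x$z <- moved[, 3]
    attr(x, "transformed") <- TRUE
    return(x)
  }
  xyz <- as.matrix(x)
  sweep(tcrossprod(xyz, transform$rotation), 2, transform$translation, "+")
}

domain_ca_coords <- function(domain, keys) {
  ca <- domain[domain$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$res_key), , drop = FALSE]
  idx <- match(keys, ca$res_key)
  found <- !is.na(idx)
  list(coords = as.matrix(ca[idx[found], c("x", "y", "z")]), found = found)
}

#' Superimpose the homologous domains of an AB / A'C pair
#'
#' Aligns the sequences of A and A', fits the least-squares transform on the
#' matched Calpha pairs of the whole domains, and applies it to every atom of
#' A' and of C (A and B stay fixed). Also reports the interface RMSD (irmsd)
#' over matched pairs whose A-side residue is interfacial with respect to B.
#'
#' @param domA,domB Domains of complex 1 (fixed).
#' @param domAprime,domC Domains of complex 2 (moved into the frame of A).
#' @param iface_params `interface_params` used for the irmsd restriction.
#' @param ... Passed to [align_sequences()].
#' @return List of class `superposed_pair` with the four domains (Aprime and
#'   C transformed), the `transform`, and `alignment` (matched_pairs, rmsd,
#'   irmsd, n_matched).
#' @export
superpose_pair <- function(domA, domB, domAprime, domC,
                           iface_params = interface_params(), ...) {
  aln <- align_sequences(domA, domAprime, ...)
  caA <- domain_ca_coords(domA, aln$key_a)
  caP <- domain_ca_coords(domAprime, aln$key_aprime)
  ok <- caA$found & caP$found
  if (sum(ok) < 3) stop("superpose_pair: fewer than 3 matched Calpha pairs")
  xa <- domain_ca_coords(domA, aln$key_a[ok])$coords
  xp <- domain_ca_coords(domAprime, aln$key_aprime[ok])$coords
  tf <- fit_transform(xa, xp)

  domAprime_t <- apply_transform(domAprime, tf)
  domC_t <- apply_transform(domC, tf)

  # irmsd: matched pairs whose A-side residue is interfacial w.r.t. B
  siteA <- detect_interface(domA, domB, iface_params)$site1
  int_ok <- ok & (aln$key_a %in% siteA$residues)
  irmsd <- NA_real_
  if (sum(int_ok) > 0) {
    ya <- domain_ca_coords(domA, aln$key_a[int_ok])$coords
    yp <- domain_ca_coords(domAprime_t, aln$key_aprime[int_ok])$coords
    irmsd <- sqrt(mean(rowSums((ya - yp)^2)))
  }

  structure(
    list(domA = domA, domB = domB, domAprime = domAprime_t, domC = domC_t,
         transform = tf,
         alignment = list(matched_pairs = aln[ok, c("key_a", "key_aprime")],
                          rmsd = tf$rmsd, irmsd = irmsd,
                          n_matched = sum(ok))),
    class = "superposed_pair"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (rmsd ",
      ifelse(is.na(x$rmsd), "NA", format(x$rmsd, digits = 4)), " A)\n",
      sep = "")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(NULL, c("r1", "r2", "r3", "t"))
  print(round(m, 6))
  invisible(x)
}
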