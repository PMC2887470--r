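# Independent reference implementations used as oracles. These deliberately
# use naive algorithms (double loops, full enumeration) and share no code
# with the package internals.

ALL_CLASSES <- c("POSITIVE", "NEGATIVE", "POLAR", "NONPOLAR", "HYDROPHOBIC")

# brute-force interfacial atom scan: O(n*m) double loop, heavy atoms only
brute_interfacial <- function(dom1, dom2, cutoff = 5.0) {
  h1 <- dom1[dom1$is_heavy, , drop = FALSE]
  h2 <- dom2[dom2$is_heavy, , drop = FALSE]
  int1 <- rep(FALSE, nrow(h1))
  int2 <- rep(FALSE, nrow(h2))
  for (i in seq_len(nrow(h1))) {
    for (j in seq_len(nrow(h2))) {
      d <- sqrt((h1$x[i] - h2$x[j])^2 + (h1$y[i] - h2$y[j])^2 +
                  (h1$z[i] - h2$z[j])^2)
      if (d < cutoff) {
        int1[i] <- TRUE
        int2[j] <- TRUE
      }
    }
  }
  list(keys1 = paste(h1$res_key, h1$elety)[int1],
       keys2 = paste(h2$res_key, h2$elety)[int2])
}

# brute-force superimposed/similar counts (existence test, strict cutoff)
brute_count <- function(site1, site2, cutoff) {
  count_one <- function(a, b) {
    n_sup <- 0L; n_sim <- 0L
    for (i in seq_len(nrow(a))) {
      sup <- FALSE; sim <- FALSE
      for (j in seq_len(nrow(b))) {
        d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                    (a$z[i] - b$z[j])^2)
        if (d < cutoff) {
          sup <- TRUE
          if (a$class[i] == b$class[j]) sim <- TRUE
        }
      }
      n_sup <- n_sup + sup; n_sim <- n_sim + sim
    }
    c(n_sup, n_sim)
  }
  c1 <- count_one(site1, site2)
  c2 <- count_one(site2, site1)
  list(n_superimposed_1 = c1[1], n_similar_1 = c1[2],
       n_superimposed_2 = c2[1], n_similar_2 = c2[2])
}

# Gotoh global alignment with affine gaps (a gap of length L costs
# open + L * ext, terminal gaps penalized), matching the package's scoring
# convention. Returns the optimal score; matched sets are asserted on cases
# whose optimum is structurally forced.
gotoh_score <- function(seq_a, seq_b, mat, open = 11, ext = 1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score an alignment given as two gapped strings, same convention
score_alignment <- function(aln_a, aln_b, mat, open = 11, ext = 1) {
  ca <- strsplit(aln_a, "")[[1]]
  cb <- strsplit(aln_b, "")[[1]]
  sc <- 0
  in_gap <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") {
      if (!in_gap) sc <- sc - open
      sc <- sc - ext
      in_gap <- TRUE
    } else {
      sc <- sc + mat[ca[k], cb[k]]
      in_gap <- FALSE
    }
  }
  sc
}

# Horn's quaternion-based absolute orientation: rotation + translation
# minimizing RMSD of y onto x; algorithmically distinct from the SVD route.
quaternion_fit <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  S <- crossprod(yc, xc)  # sum over points of y_i x_i^T
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  R <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  moved <- tcrossprod(yc, R)
  rmsd <- sqrt(mean(rowSums((xc - moved)^2)))
  list(rotation = R, translation = as.numeric(cx - R %*% cy), rmsd = rmsd)
}

# classes of partner elements strictly within `cutoff` of each self element,
# via a double loop (independent of the package's matrix route)
brute_near_classes <- function(self, other, cutoff) {
  lapply(seq_len(nrow(self)), function(i) {
    cls <- character(0)
    for (j in seq_len(nrow(other))) {
      d <- sqrt((self$x[i] - other$x[j])^2 + (self$y[i] - other$y[j])^2 +
                  (self$z[i] - other$z[j])^2)
      if (d < cutoff) cls <- c(cls, other$class[j])
    }
    unique(cls)
  })
}

# exact permutation p-value by exhaustive enumeration of the distinct
# arrangements of the label multiset over the overlapping positions
exact_perm_pvalue <- function(self, other, cutoff) {
  near <- brute_near_classes(self, other, cutoff)
  sup <- vapply(near, function(cl) length(cl) > 0, logical(1))
  if (!any(sup)) return(1)
  labels <- self$class[sup]
  near <- near[sup]
  n_obs <- sum(vapply(seq_along(labels),
                      function(i) labels[i] %in% near[[i]], logical(1)))
  if (n_obs == 0) return(1)
  n <- length(labels)
  counts <- table(labels)
  hits <- 0; total <- 0
  rec <- function(pos, counts, n_sim) {
    if (pos > n) {
      total <<- total + 1
      if (n_sim >= n_obs) hits <<- hits + 1
      return(invisible())
    }
    for (lab in names(counts)[counts > 0]) {
      counts2 <- counts
      counts2[lab] <- counts2[lab] - 1
      rec(pos + 1, counts2, n_sim + (lab %in% near[[pos]]))
    }
  }
  rec(1, counts, 0)
  hits / total
}
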