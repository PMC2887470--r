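test_that("identical sequences match at every position", {
  set.seed(1)
  aas <- names(canonical_heavy_atoms())
  seqs <- sample(aas, 25, replace = TRUE)
  dA <- as_domain(ca_chain(seqs, "A"))
  dB <- as_domain(ca_chain(seqs, "B"))
  aln <- align_sequences(dA, dB)
  expect_equal(nrow(aln), 25)
  expect_equal(aln$pos_a, aln$pos_aprime)
})

test_that("an internal deletion reduces matches by the deletion length", {
  set.seed(2)
  aas <- names(canonical_heavy_atoms())
  seqs <- sample(aas, 30, replace = TRUE)
  k <- 5
  dA <- as_domain(ca_chain(seqs, "A"))
  dB <- as_domain(ca_chain(seqs[-(10:(10 + k - 1))], "B"))
  aln <- align_sequences(dA, dB)
  expect_equal(nrow(aln), 30 - k)
})

test_that("alignment of a 30% divergent homolog is optimal per an independent DP", {
  set.seed(3)
  one <- names(AA123)
  s1 <- sample(one, 40, replace = TRUE)
  s2 <- s1
  mut <- sample(40, 12)                    # 30% substitutions
  s2[mut] <- sample(one, 12, replace = TRUE)
  s2 <- s2[-c(15, 16, 17)]                 # plus one internal deletion
  dA <- as_domain(ca_chain(AA123[s1], "A"))
  dB <- as_domain(ca_chain(AA123[s2], "B"))
  aln <- align_sequences(dA, dB)

  mat <- get(data("BLOSUM62", package = "Biostrings",
                  envir = environment()))
  oracle <- gotoh_score(paste(s1, collapse = ""), paste(s2, collapse = ""),
                        mat, open = 11, ext = 1)
  # reconstruct the gapped strings from the matched pairs and score them
  aln_str <- function(pos_a, pos_b, s1, s2) {
    ia <- 1; ib <- 1; ca <- character(0); cb <- character(0)
    for (k in seq_along(pos_a)) {
      while (ia < pos_a[k]) { ca <- c(ca, s1[ia]); cb <- c(cb, "-"); ia <- ia + 1 }
      while (ib < pos_b[k]) { ca <- c(ca, "-"); cb <- c(cb, s2[ib]); ib <- ib + 1 }
      ca <- c(ca, s1[ia]); cb <- c(cb, s2[ib]); ia <- ia + 1; ib <- ib + 1
    }
    while (ia <= length(s1)) { ca <- c(ca, s1[ia]); cb <- c(cb, "-"); ia <- ia + 1 }
    while (ib <= length(s2)) { ca <- c(ca, "-"); cb <- c(cb, s2[ib]); ib <- ib + 1 }
    c(paste(ca, collapse = ""), paste(cb, collapse = ""))
  }
  g <- aln_str(aln$pos_a, aln$pos_aprime, s1, s2)
  expect_equal(score_alignment(g[1], g[2], mat, 11, 1), oracle)
})

test_that("fit_transform is exact on identity and on known rigid motions", {
  set.seed(4)
  x <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  tf0 <- fit_transform(x, x)
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(tf0$translation)), 1e-10)
  expect_lt(tf0$rmsd, 1e-10)

  R <- rotation_about_axis(c(1, 2, 3), 0.8)
  t <- c(4, -2, 7)
  y <- sweep(tcrossprod(x, R), 2, t, "+")   # y = R x + t
  tf <- fit_transform(x, y)                  # recovers the inverse motion
  expect_lt(tf$rmsd, 1e-8)
  expect_lt(max(abs(tf$rotation %*% R - diag(3))), 1e-8)
  back <- apply_transform(y, tf)
  expect_lt(max(abs(back - x)), 1e-8)
})

test_that("noisy superposition agrees with an independent quaternion fit", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 3, sd = 6), ncol = 3)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, pi))
    y <- sweep(tcrossprod(x, R), 2, rnorm(3, sd = 5), "+") +
      matrix(rnorm(40 * 3, sd = 0.5), ncol = 3)
    tf <- fit_transform(x, y)
    q <- quaternion_fit(x, y)
    expect_lt(abs(tf$rmsd - q$rmsd), 1e-6)
    expect_lt(max(abs(tf$rotation - q$rotation)), 1e-6)
  }
})

test_that("fit rmsd is invariant to a common rigid motion and never worse than identity", {
  set.seed(6)
  x <- matrix(rnorm(25 * 3, sd = 5), ncol = 3)
  y <- x + matrix(rnorm(25 * 3, sd = 1), ncol = 3)
  base <- fit_transform(x, y)$rmsd
  R <- rotation_about_axis(c(0, 1, 1), 1.1)
  common <- function(m) sweep(tcrossprod(m, R), 2, c(3, 3, 3), "+")
  moved <- fit_transform(common(x), common(y))$rmsd
  expect_lt(abs(base - moved), 1e-8)
  expect_lte(base, sqrt(mean(rowSums((x - y)^2))))
})

test_that("a rigidly moved copy superposes back to machine precision", {
  spec <- synthetic_pair_spec(seed = 30, coordinate_noise_sigma = 0,
                              similarity_AA = 1,
                              planted_transform = rigid_transform(
                                rotation_about_axis(c(0, 0, 1), pi / 6),
                                c(10, 0, 0)))
  p <- generate_pair(spec, "rigid")
  sp <- superpose_pair(select_domain(p$structure1, "A"),
                       select_domain(p$structure1, "B"),
                       select_domain(p$structure2, "A"),
                       select_domain(p$structure2, "C"))
  expect_lt(sp$alignment$rmsd, 1e-6)
  # all-atom deviation of A' from A after superposition
  a <- select_domain(p$structure1, "A")
  ap <- sp$domAprime
  m <- merge(as.data.frame(a), as.data.frame(ap), by = c("res_key", "elety"))
  expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y), abs(m$z.x - m$z.y)),
            1e-6)
})

test_that("irmsd is computed over interfacial matched residues only", {
  spec <- synthetic_pair_spec(seed = 31, coordinate_noise_sigma = 0,
                              similarity_AA = 1)
  p <- generate_pair(spec, "ir")
  dA <- select_domain(p$structure1, "A")
  dB <- select_domain(p$structure1, "B")
  sp <- superpose_pair(dA, dB, select_domain(p$structure2, "A"),
                       select_domain(p$structure2, "C"))
  expect_lt(sp$alignment$irmsd, 1e-6)
  siteA <- detect_interface(dA, dB)$site1
  expect_true(all(sp$alignment$matched_pairs$key_a %in% dA$res_key))
  expect_lte(sum(sp$alignment$matched_pairs$key_a %in% siteA$residues),
             sp$alignment$n_matched)
})

test_that("a domain cannot be transformed twice", {
  p <- generate_pair(synthetic_pair_spec(seed = 32), "dbl")
  d <- select_domain(p$structure2, "A")
  tf <- rigid_transform(diag(3), c(1, 0, 0))
  d2 <- apply_transform(d, tf)
  expect_error(apply_transform(d2, tf), "already been transformed")
})
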