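test_that("single-element pairs follow the strict cutoff and class rules", {
  a <- make_elements(c(0, 0, 0), "POLAR")
  b_same <- make_elements(c(2.9, 0, 0), "POLAR")
  b_diff <- make_elements(c(2.9, 0, 0), "POSITIVE")
  expect_equal(count_matches(a, b_same, 3.0),
               list(n_superimposed_1 = 1L, n_similar_1 = 1L,
                    n_superimposed_2 = 1L, n_similar_2 = 1L))
  expect_equal(count_matches(a, b_diff, 3.0),
               list(n_superimposed_1 = 1L, n_similar_1 = 0L,
                    n_superimposed_2 = 1L, n_similar_2 = 0L))
  b_far <- make_elements(c(3.0, 0, 0), "POLAR")
  expect_equal(count_matches(a, b_far, 3.0)$n_superimposed_1, 0L)
})

test_that("one partner element can match several elements (existence test)", {
  s1 <- make_elements(rbind(c(0, 0, 0), c(1, 0, 0)),
                      c("POLAR", "POLAR"))
  s2 <- make_elements(c(0.5, 0, 0), "POLAR")
  cm <- count_matches(s1, s2, 3.0)
  expect_equal(cm$n_superimposed_1, 2L)
  expect_equal(cm$n_similar_1, 2L)
  expect_equal(cm$n_superimposed_2, 1L)
})

test_that("counts on random 50-element sites equal the brute-force scan", {
  for (seed in c(7, 23, 91)) {
    set.seed(seed)
    pr <- random_element_pair(50, 50, box = 8, cutoff = 4)
    cm <- count_matches(pr$e1, pr$e2, 4.0)
    oracle <- brute_count(pr$e1, pr$e2, 4.0)
    expect_equal(cm$n_superimposed_1, as.integer(oracle$n_superimposed_1))
    expect_equal(cm$n_similar_1, as.integer(oracle$n_similar_1))
    expect_equal(cm$n_superimposed_2, as.integer(oracle$n_superimposed_2))
    expect_equal(cm$n_similar_2, as.integer(oracle$n_similar_2))
  }
})

test_that("bootstrap p-value is 1 when nothing matches or labels are uniform", {
  # zero observed similar elements
  s1 <- make_elements(rbind(c(0, 0, 0), c(1, 0, 0)),
                      c("POSITIVE", "POSITIVE"))
  s2 <- make_elements(rbind(c(0.5, 0, 0), c(1.5, 0, 0)),
                      c("NEGATIVE", "NEGATIVE"))
  expect_equal(as.numeric(bootstrap_pvalue(s1, s2, 3, 500, seed = 1)), 1)

  # no superimposed elements at all
  far <- make_elements(c(50, 50, 50), "POSITIVE")
  p0 <- bootstrap_pvalue(s1, far, 3, 500, seed = 1)
  expect_equal(as.numeric(p0), 1)
  expect_equal(attr(p0, "n_superimposed"), 0L)

  # single-class labels: every permutation reproduces the observed count
  u1 <- make_elements(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      rep("POLAR", 3))
  u2 <- make_elements(rbind(c(0.3, 0, 0), c(1.3, 0, 0)), rep("POLAR", 2))
  expect_equal(as.numeric(bootstrap_pvalue(u1, u2, 3, 200, seed = 5)), 1)
})

test_that("bootstrap p matches exhaustive enumeration on small overlaps", {
  n_reps <- 500
  set.seed(101)
  n_checked <- 0
  while (n_checked < 20) {
    pr <- random_element_pair(sample(4:8, 1), sample(4:8, 1), box = 5)
    g_exact <- exact_perm_pvalue(pr$e1, pr$e2, 4.0)
    pb <- bootstrap_pvalue(pr$e1, pr$e2, 4.0, n_reps,
                           seed = 1000 + n_checked)
    se <- sqrt(g_exact * (1 - g_exact) / n_reps)
    expect_lte(abs(as.numeric(pb) - g_exact), 3 * se + 1e-12)
    n_checked <- n_checked + 1
  }
})

test_that("bootstrap p-values are deterministic given the seed", {
  set.seed(55)
  pr <- random_element_pair(20, 20)
  p1 <- bootstrap_pvalue(pr$e1, pr$e2, 4, 300, seed = 77)
  p2 <- bootstrap_pvalue(pr$e1, pr$e2, 4, 300, seed = 77)
  p3 <- bootstrap_pvalue(pr$e1, pr$e2, 4, 300, seed = 78)
  expect_identical(as.numeric(p1), as.numeric(p2))
  # a different seed may move the estimate but stays on the k/n grid
  expect_true(as.numeric(p3) * 300 == round(as.numeric(p3) * 300))
})

test_that("the bootstrap does not disturb the caller's RNG stream", {
  set.seed(123)
  draw_a <- runif(3)
  set.seed(123)
  pr <- within_rng <- random_element_pair(5, 5)
  set.seed(123)
  invisible(runif(10))  # advance, then snapshot
  snap <- .Random.seed
  bootstrap_pvalue(pr$e1, pr$e2, 4, 50, seed = 9)
  expect_identical(snap, .Random.seed)
})

test_that("self-comparison gives ratio 1 and minimal p-values at every level", {
  spec <- synthetic_pair_spec(seed = 61, coordinate_noise_sigma = 0,
                              similarity_AA = 1, similarity_BC = 1,
                              overlap_fraction = 1,
                              planted_transform = rigid_transform())
  p <- generate_pair(spec, "self")
  sp <- superpose_pair(select_domain(p$structure1, "A"),
                       select_domain(p$structure1, "B"),
                       select_domain(p$structure2, "A"),
                       select_domain(p$structure2, "C"))
  for (level in c("ATOM", "CG", "CA")) {
    r <- compute_similarity(sp, level, match_params(rng_seed = 3))
    expect_true(all(r$similarity_ratio == 1), info = level)
    expect_true(all(r$n_similar <= r$n_superimposed))
    expect_true(all(r$n_superimposed <= r$n_elements))
  }
  # CA level with mixed classes in a 20+ element overlap: p at the floor
  r_ca <- compute_similarity(sp, "CA", match_params(rng_seed = 3))
  expect_true(all(r_ca$p_value <= 1 / 500))
})

test_that("count sanity holds across levels and seeds", {
  for (seed in c(71, 72)) {
    p <- generate_pair(synthetic_pair_spec(seed = seed), "sane")
    sp <- superpose_pair(select_domain(p$structure1, "A"),
                         select_domain(p$structure1, "B"),
                         select_domain(p$structure2, "A"),
                         select_domain(p$structure2, "C"))
    for (level in c("ATOM", "CG", "CA")) {
      r <- compute_similarity(sp, level, match_params(rng_seed = seed))
      expect_true(all(r$n_similar <= r$n_superimposed))
      expect_true(all(r$n_superimposed <= r$n_elements))
      expect_true(all(r$p_value >= 0 & r$p_value <= 1))
      expect_true(all(is.na(r$similarity_ratio) | r$similarity_ratio <= 1))
    }
  }
})

test_that("conservation co-localization handles absent and planted labels", {
  spec <- synthetic_pair_spec(seed = 81, coordinate_noise_sigma = 0,
                              similarity_AA = 1, similarity_BC = 1,
                              overlap_fraction = 1,
                              planted_transform = rigid_transform(),
                              conserved_fraction = 0.5)
  p <- generate_pair(spec, "cons")
  sp <- superpose_pair(select_domain(p$structure1, "A"),
                       select_domain(p$structure1, "B"),
                       select_domain(p$structure2, "A"),
                       select_domain(p$structure2, "C"))

  # no conservation data: everything unconserved, excluded, p = 1
  r0 <- conservation_colocalization(sp, conservation = NULL,
                                    match_params(rng_seed = 1))
  expect_true(all(r0$excluded))
  expect_true(all(r0$p_value == 1))
  expect_true(all(r0$n_conserved == 0))

  # identical complexes with identical conservation labels on A and A':
  # every superimposed conserved residue co-localizes
  cons <- p$conservation
  cons2 <- cons[cons$structure_id == "cons_1", ]
  cons2$structure_id <- "cons_2"
  cons_sym <- rbind(cons[cons$structure_id == "cons_1", ], cons2)
  ids <- c(A = "cons_1", Aprime = "cons_2", B = "cons_1", C = "cons_2")
  r1 <- conservation_colocalization(sp, cons_sym, match_params(rng_seed = 1),
                                    structure_ids = ids)
  a_row <- r1[r1$site == "A", ]
  expect_equal(a_row$n_colocalized, a_row$n_superimposed_conserved)
})

test_that("conservation bootstrap p matches exact enumeration of placements", {
  # 12-residue overlap, 5 conserved: enumerate all placements of the
  # conserved labels over the overlapping positions
  set.seed(202)
  coords1 <- cbind(seq(0, 22, by = 2), 0, 0)
  coords2 <- cbind(seq(0, 22, by = 2) + 0.5, 0, 0)
  e1 <- make_elements(coords1, rep("POLAR", 12))
  e2 <- make_elements(coords2, rep("POLAR", 12))
  lab1 <- rep(FALSE, 12); lab1[c(1, 3, 5, 8, 11)] <- TRUE
  lab2 <- rep(FALSE, 12); lab2[c(1, 2, 9, 12)] <- TRUE
  r <- sitesim:::colocalization_pvalue(e1, lab1, e2, lab2, 4.0,
                                       n_reps = 2000, seed = 5)
  # exact: which positions have a conserved partner within 4 A
  near <- vapply(seq_len(12), function(i) {
    any(sqrt(rowSums(sweep(coords2[lab2, , drop = FALSE], 2,
                           coords1[i, ])^2)) < 4)
  }, logical(1))
  n_obs <- sum(lab1 & near)
  combos <- utils::combn(12, sum(lab1))
  hits <- apply(combos, 2, function(idx) sum(near[idx]) >= n_obs)
  p_exact <- mean(hits)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lte(abs(r$p - p_exact), 3 * se + 1e-12)
})

test_that("cohort summaries reproduce hand arithmetic and planted structure", {
  # three hand-built result row sets
  mk <- function(pair, nsA, nsB, pA, pB) {
    data.frame(pair_id = pair, category = "O",
               site = c("A", "Aprime", "B", "C"), level = "CA",
               n_elements = 20, n_superimposed = c(15, 15, 10, 10),
               n_similar = c(nsA, nsA, nsB, nsB),
               similarity_ratio = c(nsA / 15, nsA / 15, nsB / 10, nsB / 10),
               p_value = c(pA, pA, pB, pB), stringsAsFactors = FALSE)
  }
  res <- rbind(mk("p1", 12, 4, 0.002, 0.5), mk("p2", 9, 3, 0.002, 0.9),
               mk("p3", 6, 2, 0.04, 0.2))
  s <- summarize_similarity(res)
  tot <- s$means[s$means$category == "Total", ]
  expect_equal(tot$mean_similar_homolog, mean(c(12, 9, 6)))
  expect_equal(tot$mean_similar_partner, mean(c(4, 3, 2)))
  expect_equal(tot$ratio, 9 / 3)
  sig <- s$significant_fraction
  expect_equal(sig$fraction_significant[sig$side == "homolog"], 1)
  expect_equal(sig$fraction_significant[sig$side == "partner"], 0)

  # degenerate identical results: correlations flagged as NA
  res2 <- rbind(mk("q1", 8, 4, 0.1, 0.1), mk("q2", 8, 4, 0.1, 0.1))
  s2 <- summarize_similarity(res2)
  expect_true(is.na(s2$correlations$cor_similar_counts))
})
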