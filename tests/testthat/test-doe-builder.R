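test_that("candidate sets have the expected composition and no duplicates", {
  c1 <- generate_candidates(space3, c(-1, 1),
                            include = c("vertex", "edge_midpoint", "centroid"))
  expect_equal(nrow(c1), 14) # (3 + 3 + 1) x 2
  c2 <- generate_candidates(component_space(2), 0, include = "vertex")
  expect_equal(nrow(c2), 2)
  c3 <- generate_candidates(space5, c(-1, 0, 1))
  expect_equal(nrow(c3), 63) # (5 + 10 + 1 + 5) x 3
  key <- apply(round(as.matrix(c3[, c(space5$names, "amount_coded")]), 9), 1,
               paste, collapse = "|")
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(abs(rowSums(c3[, space5$names]) - 1) < 1e-9))
})

test_that("D-optimal exchange picks vertices for linear blending", {
  sp2 <- component_space(2)
  tt <- enumerate_terms(sp2, 1, 0)
  cand <- generate_candidates(sp2, 0, include = c("vertex", "edge_midpoint"))
  d <- select_d_optimal(cand, tt, 2, seed = 1)
  expect_equal(sort(d$x1), c(0, 1))
  tt3 <- enumerate_terms(space3, 1, 0)
  cand3 <- generate_candidates(space3, 0, include = c("vertex", "centroid"))
  d3 <- select_d_optimal(cand3, tt3, 3, seed = 1)
  expect_equal(unname(sort(colSums(d3[, c("A", "B", "C")]))), c(1, 1, 1))
})

test_that("exchange matches the exhaustive oracle on small instances", {
  set.seed(99)
  for (k in 1:8) {
    q <- sample(2:3, 1)
    sp <- component_space(q)
    tt <- enumerate_terms(sp, sample(1:2, 1), 0)
    cand <- generate_candidates(sp, if (k %% 2) 0 else c(-1, 1),
                                include = c("vertex", "edge_midpoint", "centroid"))
    cand <- cand[seq_len(min(nrow(cand), 10)), ]
    n <- min(nrow(tt) + sample(0:2, 1), nrow(cand))
    Xc <- build_model_matrix(cand, tt)
    opt <- brute_force_logdet(Xc, n)
    if (!is.finite(opt)) next
    d <- select_d_optimal(cand, tt, n, seed = k, n_starts = 10)
    expect_equal(attr(d, "logdet"), opt, tolerance = 1e-8)
  }
})

test_that("exchange beats random subsets of the same size", {
  set.seed(5)
  for (k in 1:5) {
    sp <- component_space(3)
    tt <- enumerate_terms(sp, 2, 0)
    cand <- generate_candidates(sp, c(-1, 1))
    Xc <- build_model_matrix(cand, tt)
    n <- nrow(tt) + 2
    d <- select_d_optimal(cand, tt, n, seed = k)
    best_rand <- max(vapply(1:1000, function(i) {
      M <- crossprod(Xc[sample(nrow(Xc), n), , drop = FALSE])
      ld <- determinant(M, logarithm = TRUE)
      if (ld$sign > 0) as.numeric(ld$modulus) else -Inf
    }, numeric(1)))
    expect_gte(attr(d, "logdet"), best_rand - 1e-8)
  }
})

test_that("lack-of-fit augmentation is maximin and rejects exhaustion", {
  tt <- enumerate_terms(space3, 1, 0)
  cand <- generate_candidates(space3, 0,
                              include = c("vertex", "edge_midpoint", "centroid"))
  d <- select_d_optimal(cand, tt, 3, seed = 1) # the three vertices
  d1 <- augment_lack_of_fit(d, cand, 1, seed = 1)
  # centroid is farther from all vertices than any edge midpoint
  added <- d1[d1$role == "lack_of_fit", c("A", "B", "C")]
  expect_equal(unname(unlist(added)), rep(1 / 3, 3), tolerance = 1e-9)
  expect_identical(nrow(augment_lack_of_fit(d, cand, 0)), nrow(d))
  expect_error(augment_lack_of_fit(d, cand, 99, seed = 1), "distinct candidates")
})

test_that("replicates duplicate existing points and preserve distinctness", {
  d <- small_design(q = 3, n_rep = 0, n_blocks = 1)
  n_dist <- length(unique(mixamount:::distinct_point_id(d)))
  d2 <- augment_replicates(d, 3, seed = 2)
  expect_equal(nrow(d2), nrow(d) + 3)
  expect_equal(length(unique(mixamount:::distinct_point_id(d2))), n_dist)
  # every replicate matches some non-replicate point exactly
  sp <- mixamount:::design_space(d2)
  coords <- as.matrix(d2[, c(sp$names, "amount_coded")])
  reps <- which(d2$role == "replicate")
  base <- which(d2$role != "replicate")
  for (r in reps) {
    expect_true(any(colSums(abs(t(coords[base, ]) - coords[r, ])) < 1e-9))
  }
})

test_that("center points sit at the centroid and mid amount", {
  # centroid-free candidate pool so the center point is a fresh distinct point
  sp <- component_space(5)
  af <- amount_factor(10, 30)
  tt <- enumerate_terms(sp, 2, 1)
  cand <- generate_candidates(sp, c(-1, 0, 1),
                              include = c("vertex", "edge_midpoint", "axial"),
                              amount_factor = af)
  d <- select_d_optimal(cand, tt, nrow(tt), seed = 1, n_starts = 4)
  n_dist <- length(unique(mixamount:::distinct_point_id(d)))
  d2 <- add_center_points(d, 5)
  ctr <- d2[d2$role == "center", ]
  expect_equal(nrow(ctr), 5)
  expect_true(all(abs(as.matrix(ctr[, 4:8]) - 0.2) < 1e-12))
  expect_equal(ctr$amount, rep(20, 5)) # midpoint of (10, 30)
  expect_equal(length(unique(mixamount:::distinct_point_id(d2))), n_dist + 1)
  expect_identical(add_center_points(d, 0), d)
})

test_that("block assignment balances sizes and spreads replicate copies", {
  d <- small_design(q = 3, n_rep = 6, n_blocks = 3, seed = 3)
  sizes <- table(d$block)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(assign_blocks(d, nrow(d) + 1), "between 1")
  # 7 runs in 3 blocks -> sizes {3,2,2}
  d7 <- d[1:7, ]
  d7 <- mixamount:::new_design(d7, mixamount:::design_space(d),
                               mixamount:::design_amount(d),
                               attr(d, "terms"))
  s7 <- sort(as.integer(table(assign_blocks(d7, 3, seed = 1)$block)))
  expect_equal(s7, c(2, 2, 3))
})

test_that("df partition reproduces the canonical 100-run accounting", {
  d <- build_study_design(space5, af_ref, seed = 1)
  expect_equal(nrow(d), 100)
  expect_equal(length(unique(mixamount:::distinct_point_id(d))), 51)
  part <- df_partition(d)
  expect_equal(part$block_df, 4)
  expect_equal(part$model_df, 44)
  expect_equal(part$lack_of_fit_df, 6)
  expect_equal(part$pure_error_df, 45)
  expect_equal(part$total_df, 99)
})

test_that("df partition components always sum to N - 1", {
  set.seed(11)
  for (k in 1:6) {
    d <- small_design(q = sample(3:4, 1), n_rep = sample(0:6, 1),
                      n_blocks = sample(1:3, 1), seed = k)
    part <- df_partition(d)
    expect_equal(part$block_df + part$model_df + part$lack_of_fit_df +
                   part$pure_error_df, nrow(d) - 1)
    expect_true(all(part >= 0))
  }
})

test_that("saturated unreplicated one-block designs have zero LOF and PE df", {
  sp <- component_space(3)
  tt <- enumerate_terms(sp, 2, 0)
  cand <- generate_candidates(sp, 0)
  d <- select_d_optimal(cand, tt, nrow(tt), seed = 1)
  part <- df_partition(d)
  expect_equal(unlist(part[, 1:4], use.names = FALSE),
               c(0, nrow(tt) - 1, 0, 0))
})
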