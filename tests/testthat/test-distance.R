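test_that("PhiST is 1 for fixed distinct haplotypes and 0 for mirrored populations", {
  a <- make_pop("a", rep(list(c(16093L, 16189L)), 3))
  b <- make_pop("b", rep(list(integer(0)), 3))
  expect_equal(phi_st(a, b), 1)

  # identical haplotype multisets split symmetrically: no among-group
  # variation, so the raw AMOVA estimate is non-positive and the
  # linearized distance is exactly 0
  x <- make_pop("x", list(c(16093L), c(16189L)))
  y <- make_pop("y", list(c(16093L), c(16189L)))
  expect_lte(phi_st(x, y), 0)
  expect_equal(slatkin_linearize(phi_st(x, y)), 0)

  expect_error(phi_st(make_pop("z", list(16093L)), a), "at least 2")
  # symmetry and within-population order invariance
  p <- altai_populations()
  expect_equal(phi_st(p$bronze, p$iron), phi_st(p$iron, p$bronze))
  shuffled <- population_dataset("s", rev(p$iron$records))
  expect_equal(phi_st(p$bronze, shuffled), phi_st(p$bronze, p$iron))
})

test_that("PhiST agrees with a literal sums-of-squares AMOVA oracle on random datasets", {
  ref <- hvr1_reference()
  set.seed(91)
  for (k in 1:200) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- make_pop("a", random_pos_list(na, max_k = 4, n_haplotypes = 3))
    b <- make_pop("b", random_pos_list(nb, max_k = 4, n_haplotypes = 3))
    expect_equal(phi_st(a, b), oracle_phi_for_pops(a, b, ref),
                 tolerance = 1e-12)
  }
})

test_that("random splits of one population give near-zero PhiST on average", {
  set.seed(92)
  pool <- random_pos_list(12, n_haplotypes = 5)
  phis <- replicate(50, {
    idx <- sample(12, 6)
    phi_st(make_pop("a", pool[idx]), make_pop("b", pool[-idx]))
  })
  expect_lt(abs(mean(phis)), 0.05)
})

test_that("permutation p-values behave at the null and at complete fixation", {
  # complete fixation: only a permutation reproducing the exact split can
  # tie the observed maximum, so p sits at the floor 1/(n_perm + 1)
  a <- make_pop("a", rep(list(c(16093L, 16189L)), 8))
  b <- make_pop("b", rep(list(integer(0)), 8))
  res <- phi_st_permutation_test(a, b, n_perm = 199, seed = 4)
  expect_equal(res$p, 1 / 200)

  set.seed(95)
  pool <- random_pos_list(10, n_haplotypes = 4)
  x <- make_pop("x", pool[1:5]); y <- make_pop("y", pool[6:10])
  res0 <- phi_st_permutation_test(x, y, n_perm = 199, seed = 5)
  expect_gt(res0$p, 0.05)

  expect_error(phi_st_permutation_test(a, b, n_perm = 0, seed = 1), ">= 100")
  expect_error(phi_st_permutation_test(a, b, n_perm = 199), "seed")
})

test_that("Slatkin linearization obeys its closed form, truncation and infinity rules", {
  expect_equal(slatkin_linearize(0), 0)
  expect_equal(slatkin_linearize(0.5), 1)
  expect_equal(slatkin_linearize(-0.02), 0)
  expect_equal(slatkin_linearize(0.25), 1 / 3)
  expect_warning(lin <- slatkin_linearize(1), "infinite")
  expect_identical(lin, Inf)
  m <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_identical(dim(slatkin_linearize(m)), c(2L, 2L))
})

test_that("classical MDS reproduces low-rank distance matrices to 1e-9", {
  # collinear configuration
  pts <- cbind(c(0, 1, 3), c(0, 0, 0))
  d <- as.matrix(dist(pts))
  ord <- classical_mds(d)
  expect_lt(max(abs(as.matrix(dist(ord$points)) - d)), 1e-9)
  expect_lt(ord$stress, 1e-9)

  # equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- classical_mds(d3)
  emb <- as.matrix(dist(ord3$points))
  expect_true(all(abs(emb[upper.tri(emb)] - 1) < 1e-9))

  # two populations: single axis, stress 0
  d2 <- matrix(c(0, 2.5, 2.5, 0), 2)
  ord2 <- classical_mds(d2)
  expect_equal(unname(dist(ord2$points)[1]), 2.5)
  expect_equal(ord2$stress, 0)
  expect_gte(ord2$points[1, 1], 0)

  # random planar configurations are exactly rank 2
  set.seed(93)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), n)
    d <- as.matrix(dist(pts))
    ord <- classical_mds(d)
    expect_lt(max(abs(as.matrix(dist(ord$points)) - d)), 1e-9)
  }

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("the distance matrix bundle is symmetric with linearized entries and zero diagonal", {
  p <- altai_populations()
  sets <- list(p$bronze, p$iron,
               make_pop("m", random_pos_list(5, n_haplotypes = 3)))
  dm <- phi_st_matrix(sets)
  expect_identical(diag(dm$fst), c(AMGBR = 0, PAZMG1 = 0, m = 0))
  expect_identical(dm$fst, t(dm$fst))
  expect_equal(dm$linearized[1, 2],
               max(dm$fst[1, 2], 0) / (1 - max(dm$fst[1, 2], 0)))
})
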