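test_that("Gower centering of a star tree matches the closed form", {
  d <- patristic_distances(star_tree(4))   # all off-diagonal distances 2
  g <- gower_center(d)
  C <- diag(4) - matrix(1 / 4, 4, 4)
  expect_equal(unname(g), 2 * C, tolerance = 1e-12)    # (d^2/2) * C
  ev <- eigen(g, symmetric = TRUE)$values
  expect_equal(ev, c(2, 2, 2, 0), tolerance = 1e-10)
})

test_that("Gower centering zeroes every row and column sum", {
  for (seed in 1:4) {
    d <- patristic_distances(simulate_yule_tree(10, 1, seed = seed))
    g <- gower_center(d)
    expect_lt(max(abs(rowSums(g))), 1e-10)
    expect_lt(max(abs(colSums(g))), 1e-10)
    expect_equal(g, t(g), tolerance = 1e-12)
  }
})

test_that("two-tip case reproduces the hand eigenvalues", {
  d <- seedforage:::new_phylo_weights(
    matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))),
    "patristic_distance")
  g <- gower_center(d)
  expect_equal(eigen(g)$values, c(2, 0), tolerance = 1e-12)
})

test_that("asymmetric input to Gower centering is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(gower_center(m), "symmetric")
})

test_that("extracted eigenvectors are orthonormal and drop null space", {
  d <- patristic_distances(simulate_yule_tree(12, 1, seed = 2))
  b <- extract_eigenvectors(gower_center(d))
  expect_lte(length(b$values), 11)          # centering kills >= 1 dimension
  expect_equal(crossprod(b$vectors), diag(length(b$values)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(b$values) <= 1e-12)) # descending
  # eigen-decomposition oracle: same leading eigenvalue
  expect_equal(b$values[1], eigen(gower_center(d))$values[1],
               tolerance = 1e-10)
})

test_that("the leading eigenvector of a balanced 4-tip tree separates the cherries", {
  b <- extract_eigenvectors(gower_center(patristic_distances(balanced4())))
  v1 <- b$vectors[, 1]
  expect_equal(v1[["A"]], v1[["B"]], tolerance = 1e-10)
  expect_equal(v1[["C"]], v1[["D"]], tolerance = 1e-10)
  expect_equal(v1[["A"]], -v1[["C"]], tolerance = 1e-10)
})

test_that("a response equal to an eigenvector selects exactly that vector", {
  tr <- simulate_yule_tree(15, 1, seed = 8)
  b <- extract_eigenvectors(gower_center(patristic_distances(tr)))
  w <- normalize_weights(abouheif_proximity(tr), "row_normalized")
  y <- stats::setNames(b$vectors[, 1], tr$tip.label)
  sel <- select_eigenvectors(y, b, w, alpha = 0.05, B = 199, seed = 3)
  expect_equal(as.integer(sel), 1L)
})

test_that("selection is deterministic under a fixed seed and rarely fires on noise", {
  tr <- simulate_yule_tree(20, 1, seed = 9)
  b <- extract_eigenvectors(gower_center(patristic_distances(tr)))
  w <- normalize_weights(abouheif_proximity(tr), "row_normalized")
  set.seed(30)
  sizes <- replicate(40, {
    y <- iid_traits(tr)
    length(select_eigenvectors(y, b, w, alpha = 0.05, B = 199,
                               seed = sample.int(1e6, 1)))
  })
  expect_gte(mean(sizes <= 1), 0.8)
  y <- iid_traits(tr)
  s1 <- select_eigenvectors(y, b, w, B = 199, seed = 4)
  s2 <- select_eigenvectors(y, b, w, B = 199, seed = 4)
  expect_identical(as.integer(s1), as.integer(s2))
})

test_that("variance partition reproduces closed-form decompositions", {
  tr <- simulate_yule_tree(12, 1, seed = 5)
  b <- extract_eigenvectors(gower_center(patristic_distances(tr)))
  v1 <- b$vectors[, 1]
  # y = v1, traits = v1: everything is shared
  vp <- partition_variance(v1, cbind(t1 = v1), cbind(v1), "shared_all")
  expect_equal(vp$traits_alone, 0, tolerance = 1e-9)
  expect_equal(vp$shared, 1, tolerance = 1e-9)
  expect_equal(vp$phylo_alone, 0, tolerance = 1e-9)
  expect_equal(vp$unexplained, 0, tolerance = 1e-9)
  # y = t + v with t orthogonal to v, equal variances, no noise
  v <- b$vectors[, 1]
  t_ <- b$vectors[, 2]
  y <- t_ + v
  vp2 <- partition_variance(y, cbind(t = t_), cbind(v), "orthogonal")
  expect_equal(vp2$traits_alone, 0.5, tolerance = 1e-9)
  expect_equal(vp2$shared, 0, tolerance = 1e-9)
  expect_equal(vp2$phylo_alone, 0.5, tolerance = 1e-9)
  expect_equal(vp2$unexplained, 0, tolerance = 1e-9)
})

test_that("the four fractions always sum to one and match an independent lm oracle", {
  set.seed(77)
  tr <- simulate_yule_tree(18, 1, seed = 6)
  b <- extract_eigenvectors(gower_center(patristic_distances(tr)))
  for (rep in 1:5) {
    y <- rnorm(18)
    Xt <- matrix(rnorm(18 * 3), 18, dimnames = list(NULL, paste0("t", 1:3)))
    Xp <- b$vectors[, 1:2]
    vp <- suppressWarnings(partition_variance(y, Xt, Xp))
    expect_equal(vp$traits_alone + vp$shared + vp$phylo_alone + vp$unexplained,
                 1, tolerance = 1e-9)
    # oracle: three independent lm fits
    r2 <- function(X) summary(stats::lm(y ~ X))$r.squared
    expect_equal(vp$traits_alone, r2(cbind(Xt, Xp)) - r2(Xp), tolerance = 1e-9)
    expect_equal(vp$phylo_alone, r2(cbind(Xt, Xp)) - r2(Xt), tolerance = 1e-9)
    expect_equal(vp$unexplained, 1 - r2(cbind(Xt, Xp)), tolerance = 1e-9)
  }
})

test_that("saturated partitions are rejected", {
  y <- rnorm(6)
  expect_error(partition_variance(y, matrix(rnorm(18), 6), matrix(rnorm(12), 6)),
               "Saturated")
})

test_that("phylogeny-free traits produce near-zero mean shared fraction", {
  set.seed(123)
  shared <- replicate(40, {
    tr <- simulate_yule_tree(20, 1, seed = sample.int(1e6, 1))
    b <- extract_eigenvectors(gower_center(patristic_distances(tr)))
    y <- rnorm(20)
    Xt <- matrix(rnorm(20 * 2), 20)
    suppressWarnings(partition_variance(y, Xt, b$vectors[, 1:2])$shared)
  })
  expect_lt(abs(mean(shared)), 0.08)
})

test_that("pvr_partition returns one labelled row per behavior", {
  sim <- simulate_paperlike(seed = 21)
  design <- build_design_matrix(
    suppressMessages(apply_floors(sim$traits, "tannin_pct_tae", 0.35)))
  beh <- sim$behaviors[c("species", "time_consume", "dist_cache")]
  vp <- pvr_partition(beh, design, sim$tree, B = 199, seed = 5)
  expect_equal(vp$response, c("time_consume", "dist_cache"))
  expect_true(all(abs(rowSums(vp[, c("traits_alone", "shared",
                                     "phylo_alone", "unexplained")]) - 1) < 1e-9))
  expect_s3_class(autoplot(vp), "ggplot")
})
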