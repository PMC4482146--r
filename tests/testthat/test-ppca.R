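ppca_fixture <- function(n = 20, p = 5, seed = 1, lambda = 1) {
  tr <- simulate_yule_tree(n, 1, seed = seed)
  X <- simulate_traits(tr, p = p, lambda = lambda, seed = seed + 1000)
  list(tree = tr, X = standardize(X),
       w = normalize_weights(abouheif_proximity(tr),
                             "symmetrized_row_normalized"))
}

test_that("pPCA with identity weights is ordinary PCA of the correlation matrix", {
  fx <- ppca_fixture()
  n <- nrow(fx$X)
  W <- diag(n)
  dimnames(W) <- list(rownames(fx$X), rownames(fx$X))
  fit <- fit_ppca(fx$X, W)
  # oracle: eigen-decomposition of the divisor-n covariance of standardized
  # traits = correlation matrix
  ev_oracle <- eigen(crossprod(fx$X) / n, symmetric = TRUE)
  expect_equal(unname(fit$eigenvalues), ev_oracle$values, tolerance = 1e-9)
  expect_equal(abs(unname(fit$loadings)), abs(ev_oracle$vectors),
               tolerance = 1e-9)
  expect_true(all(fit$eigenvalues >= 0))  # no local axes without a phylogeny
  # and against prcomp's sdev (divisor n-1, rescaled)
  pc <- stats::prcomp(fx$X, center = FALSE, scale. = FALSE)
  expect_equal(unname(fit$eigenvalues), pc$sdev^2 * (n - 1) / n,
               tolerance = 1e-9)
})

test_that("a single trait gives the scalar eigenvalue var_n(x) * I(x)", {
  fx <- ppca_fixture(p = 1)
  fit <- fit_ppca(fx$X, fx$w)
  x <- fx$X[, 1]
  expect_equal(unname(fit$eigenvalues),
               (sum(x^2) / length(x)) * morans_i(x, fx$w),
               tolerance = 1e-10)
})

test_that("perfectly collinear traits yield one non-null axis", {
  tr <- simulate_yule_tree(15, 1, seed = 3)
  x <- simulate_traits(tr, p = 1, seed = 4)[, 1]
  X <- standardize(cbind(a = x, b = 2 * x + 1))
  fit <- fit_ppca(X, normalize_weights(abouheif_proximity(tr),
                                       "symmetrized_row_normalized"))
  expect_equal(min(abs(unname(fit$eigenvalues))), 0, tolerance = 1e-10)
})

test_that("unstandardized traits and label mismatches are rejected", {
  fx <- ppca_fixture()
  expect_error(fit_ppca(fx$X * 2, fx$w), "standardized")
  Xbad <- fx$X
  rownames(Xbad) <- paste0("x", seq_len(nrow(Xbad)))
  expect_error(fit_ppca(Xbad, fx$w), "labels")
})

test_that("per-axis eigenvalue identity and trace identity hold on every fit", {
  for (seed in c(2, 5, 9)) {
    fx <- ppca_fixture(n = 18, p = 6, seed = seed)
    fit <- fit_ppca(fx$X, fx$w)
    n <- fit$n
    for (j in seq_along(fit$eigenvalues)) {
      s <- fit$scores[, j]
      expect_equal(unname(fit$eigenvalues[j]),
                   (sum((s - mean(s))^2) / n) * morans_i(s, fx$w),
                   tolerance = 1e-8)
    }
    expect_equal(sum(fit$eigenvalues),
                 sum(diag(crossprod(fx$X, unclass(fx$w) %*% fx$X))) / n,
                 tolerance = 1e-9)
    expect_equal(crossprod(fit$loadings),
                 diag(ncol(fit$loadings)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(fit$scores, fx$X %*% fit$loadings, ignore_attr = TRUE)
  }
})

test_that("axes are ordered and labelled by sign groups", {
  fx <- ppca_fixture(n = 22, p = 7, seed = 11)
  fit <- fit_ppca(fx$X, fx$w)
  glob <- fit$eigenvalues[startsWith(names(fit$eigenvalues), "global")]
  loc <- fit$eigenvalues[startsWith(names(fit$eigenvalues), "local")]
  expect_true(all(diff(glob) <= 1e-12))   # descending positives
  expect_true(all(diff(loc) >= -1e-12))   # most negative first
  expect_true(all(glob >= 0) && all(loc < 0))
  expect_equal(sum(fit$variance_share), 1, tolerance = 1e-12)
})

test_that("label_axes retains the requested axes and errors when impossible", {
  fx <- ppca_fixture(n = 22, p = 7, seed = 11)
  fit <- fit_ppca(fx$X, fx$w)
  n_loc <- sum(fit$eigenvalues < 0)
  lab <- label_axes(fit, k_global = 2, k_local = 1)
  expect_length(lab$retained, 3)
  expect_equal(lab$axis_labels[lab$retained][1:2], c("global_1", "global_2"))
  expect_equal(lab$retained_share,
               sum(lab$variance_share[lab$retained]))
  expect_error(label_axes(fit, k_local = n_loc + 1), "negative eigenvalues")
  expect_error(label_axes(fit, k_global = 50), "positive eigenvalues")
  # identity weights: no local axes exist, but all-global retention works
  W <- diag(fit$n)
  dimnames(W) <- list(rownames(fx$X), rownames(fx$X))
  fit_id <- fit_ppca(fx$X, W)
  lab_id <- label_axes(fit_id, k_global = 3, k_local = 0)
  expect_true(all(startsWith(lab_id$axis_labels[lab_id$retained], "global")))
})

test_that("score signal tests use the sign-appropriate tails and fixed seeds", {
  fx <- ppca_fixture(n = 20, p = 6, seed = 7)
  fit <- label_axes(fit_ppca(fx$X, fx$w), 2, 1)
  s1 <- score_signal(fit, fx$tree, B = 199, seed = 5)
  s2 <- score_signal(fit, fx$tree, B = 199, seed = 5)
  expect_identical(s1$p.value, s2$p.value)
  expect_equal(s1$tail, c("upper", "upper", "lower"))
  expect_equal(s1$axis, c("global_1", "global_2", "local_1"))
})

test_that("collapsed-clade (polytomized) trees run and keep sign-labelled axes", {
  fx <- ppca_fixture(n = 20, p = 6, seed = 13)
  fit <- fit_ppca(fx$X, fx$w)
  coll <- ape::di2multi(fx$tree, tol = 0.2)  # collapse short internal edges
  expect_gt(length(fx$tree$tip.label) - 1, coll$Nnode)  # polytomies created
  w2 <- normalize_weights(abouheif_proximity(coll),
                          "symmetrized_row_normalized")
  fit2 <- fit_ppca(fx$X, w2)
  expect_equal(length(fit2$eigenvalues), length(fit$eigenvalues))
  expect_true(all(c("global_1", "local_1") %in% fit2$axis_labels))
})

test_that("tidy and autoplot expose loadings, scores and the dominant flag", {
  fx <- ppca_fixture(n = 16, p = 8, seed = 4)
  fit <- label_axes(fit_ppca(fx$X, fx$w), 2, 1)
  ld <- tidy(fit, "loadings")
  expect_named(ld, c("trait", "axis", "loading", "dominant"))
  # 75th-percentile rule: 2 of 8 loadings flagged per axis
  per_axis <- dplyr::count(dplyr::filter(ld, dominant), axis)
  expect_true(all(per_axis$n == 2))
  sc <- tidy(fit, "scores")
  expect_equal(nrow(sc), 16 * length(fit$eigenvalues))
  ev <- tidy(fit, "eigenvalues")
  expect_equal(sum(ev$retained), 3)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(glance(fit), "tbl_df")
})
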