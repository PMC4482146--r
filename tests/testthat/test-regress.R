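test_that("OLS recovers exact linear relations and matches the normal equations", {
  x <- seq(0, 5, length.out = 12)
  fit <- suppressWarnings(fit_ols(2 + 3 * x, cbind(x = x)))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-12)

  set.seed(6)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(n)
    expect_equal(unname(fit_ols(y, X)$coefficients),
                 unname(oracle_ols_coef(y, X)), tolerance = 1e-9)
  }
})

test_that("slopes vanish when the response is orthogonal to centered predictors", {
  set.seed(8)
  X <- scale(matrix(rnorm(40), 20, 2), scale = FALSE)
  q <- qr.Q(qr(cbind(1, X)))
  y0 <- rnorm(20)
  y <- y0 - q %*% crossprod(q, y0)  # orthogonal to intercept and X
  fit <- fit_ols(drop(y), X)
  expect_lt(max(abs(fit$coefficients)), 1e-10)
})

test_that("rank-deficient designs are rejected", {
  x <- rnorm(10)
  expect_error(fit_ols(rnorm(10), cbind(a = x, b = 2 * x)), "rank deficient")
})

test_that("permutation regression p-values hit the add-one floor for perfect fits", {
  set.seed(10)
  x <- rnorm(20)
  y <- 1 + 2 * x   # noiseless; no permutation can match the observed |t|
  res <- suppressWarnings(permutation_inference(y, cbind(x = x), B = 999, seed = 3))
  expect_equal(unname(res$perm_p["x"]), 0.001)
  expect_equal(tidy(res)$term, c("(Intercept)", "x"))
  expect_equal(glance(res)$r.squared, 1, tolerance = 1e-12)
})

test_that("permutation p-values are seed-deterministic and affine-invariant", {
  set.seed(11)
  X <- matrix(rnorm(23 * 3), 23, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(23) + X[, 1]
  r1 <- permutation_inference(y, X, B = 499, seed = 12)
  r2 <- permutation_inference(y, X, B = 499, seed = 12)
  expect_identical(r1$perm_p, r2$perm_p)
  # affine rescaling of y leaves t statistics and perm p untouched
  r3 <- permutation_inference(10 + 5 * y, X, B = 499, seed = 12)
  expect_equal(unname(r3$perm_p[-1]), unname(r1$perm_p[-1]), tolerance = 1e-12)
  expect_equal(unname(r3$t_statistics[-1]), unname(r1$t_statistics[-1]),
               tolerance = 1e-9)
})

test_that("permuted-fit t statistics match per-permutation lm refits", {
  set.seed(13)
  n <- 15
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  y <- rnorm(n)
  res <- permutation_inference(y, X, B = 99, seed = 44)
  # rebuild the same permutations and fit each with lm
  perm_idx <- seedforage:::with_seed(44, replicate(99, sample.int(n)))
  for (b in c(1, 50, 99)) {
    sm <- summary(stats::lm(y[perm_idx[, b]] ~ X))
    expect_equal(unname(res$null_t[, b]), unname(stats::coef(sm)[, 3]),
                 tolerance = 1e-9)
  }
})

test_that("intercept-only Poisson MLE is the log mean", {
  fit <- fit_poisson(c(1, 2, 3), matrix(numeric(0), 3, 0))
  expect_equal(unname(fit$coefficients), log(2), tolerance = 1e-8)
})

test_that("Poisson regression agrees with a direct likelihood maximization", {
  set.seed(14)
  n <- 30
  X <- matrix(rnorm(n), n, dimnames = list(NULL, "x"))
  counts <- rpois(n, exp(0.5 + 0.7 * X[, 1]))
  fit <- fit_poisson(counts, X)
  nll <- function(b) -sum(stats::dpois(counts, exp(b[1] + b[2] * X[, 1]),
                                       log = TRUE))
  opt <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
})

test_that("degenerate Poisson inputs are rejected", {
  expect_error(fit_poisson(c(0, 0, 0), matrix(numeric(0), 3, 0)),
               "diverges")
  expect_error(fit_poisson(c(1.5, 2, 1), matrix(numeric(0), 3, 0)),
               "integers")
  expect_error(fit_poisson(c(-1, 2, 1), matrix(numeric(0), 3, 0)),
               "integers|non-negative")
})

test_that("paired t reproduces the hand-computed example", {
  a <- c(2, 1, 3, 5)
  b <- c(1, 2, 3, 3)    # differences (1, -1, 0, 2): mean 0.5, sd 1.29099
  res <- paired_t(a, b)
  expect_equal(res$t, 0.5 / (sqrt(5 / 3) / 2), tolerance = 1e-9)
  expect_equal(round(res$t, 4), 0.7746)
  expect_equal(res$df, 3)
  # swapping the arguments flips the sign of t
  res2 <- paired_t(b, a)
  expect_equal(res2$t, -res$t, tolerance = 1e-12)
  expect_equal(res2$p.value, res$p.value, tolerance = 1e-12)
})

test_that("constant-difference pairs are an error", {
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("behavior regressions return the table shape with one fit per response", {
  sim <- simulate_paperlike(seed = 31)
  design <- build_design_matrix(
    suppressMessages(apply_floors(sim$traits, "tannin_pct_tae", 0.35)))
  w <- normalize_weights(abouheif_proximity(sim$tree),
                         "symmetrized_row_normalized")
  fit <- label_axes(fit_ppca(standardize(design), w), 2, 1)
  tab <- behavior_regressions(sim$behaviors[c("species", "time_consume",
                                              "time_cache")],
                              fit, B = 199, seed = 7)
  expect_equal(unique(tab$response), c("time_consume", "time_cache"))
  expect_equal(nrow(tab), 2 * 4)  # intercept + 3 axes per response
  expect_true(all(tab$p.value > 0 & tab$p.value <= 1))
})
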