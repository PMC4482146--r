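#' Ordinary least squares with classical t statistics
#'
#' Plain multiple linear regression (via [stats::lm()]) returning the pieces
#' the permutation machinery needs: coefficients, classical t statistics and
#' the ordinary (non-adjusted) R-squared.
#'
#' @param y Response vector.
#' @param X Predictor matrix or data frame (no intercept column; one is
#'   added).
#' @return List: `coefficients`, `t_statistics` (both named, intercept
#'   first), `R2`, and the underlying `lm` fit as `fit`.
#' @export
fit_ols <- function(y, X) {
  X <- as_species_matrix(X)
  n <- length(y)
  abort_if(nrow(X) != n, "Row mismatch between `y` and `X`.")
  abort_if(n <= ncol(X) + 1L, "Need n > p + 1 observations.")
  abort_if(qr(cbind(1, X))$rank < ncol(X) + 1L,
           "Design matrix is rank deficient.")
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(coefficients = stats::setNames(co[, 1], rownames(co)),
       t_statistics = stats::setNames(co[, 3], rownames(co)),
       R2 = sm$r.squared,
       fit = fit)
}

#' Permutation inference for regression coefficients
#'
#' Fits `y ~ X` by OLS, then permutes the response vector `B` times,
#' refitting each time, and reports for every coefficient the two-sided
#' permutation p-value `(1 + #{|t*| >= |t|}) / (B + 1)`. The observed fit is
#' untouched; only the inference is permutation-based (appropriate when
#' residual diagnostics contraindicate normal-theory p-values).
#'
#' @inheritParams fit_ols
#' @inheritParams signal_test
#' @return A `perm_lm` object; `tidy()` gives term/estimate/t/p rows and
#'   `glance()` the fit-level summary.
#' @export
permutation_inference <- function(y, X, B = 999L, seed = 1L) {
  abort_if(B < 99L, "Use at least 99 permutations.")
  X <- as_species_matrix(X)
  obs <- fit_ols(y, X)
  n <- length(y)
  Xm <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xm)
  XtX_inv <- chol2inv(chol(crossprod(Xm)))
  M <- XtX_inv %*% t(Xm)        # p x n: maps y to coefficients
  dvar <- diag(XtX_inv)
  perm_t <- with_seed(seed, {
    idx <- replicate(B, sample.int(n))
    Yp <- matrix(y[idx], nrow = n)
    Bmat <- M %*% Yp                       # p x B coefficients
    R <- Yp - Xm %*% Bmat
    sigma2 <- colSums(R^2) / (n - p)
    Bmat / sqrt(outer(dvar, sigma2))       # p x B t statistics
  })
  t_obs <- obs$t_statistics
  perm_p <- vapply(seq_len(p), function(j)
    (1 + sum(abs(perm_t[j, ]) >= abs(t_obs[j]))) / (B + 1), numeric(1))
  structure(list(coefficients = obs$coefficients,
                 t_statistics = t_obs,
                 perm_p = stats::setNames(perm_p, names(t_obs)),
                 R2 = obs$R2,
                 B = as.integer(B), seed = as.integer(seed),
                 null_t = perm_t,
                 response = deparse(substitute(y))[1]),
            class = "perm_lm")
}

#' @export
print.perm_lm <- function(x, ...) {
  cat(sprintf("Permutation-inference regression (B = %d, seed = %d), R2 = %.3f\n",
              x$B, x$seed, x$R2))
  print(data.frame(estimate = round(x$coefficients, 4),
                   t = round(x$t_statistics, 3),
                   p.perm = round(x$perm_p, 4)))
  invisible(x)
}

#' @describeIn permutation_inference Term-level tibble (slope, t,
#'   permutation p).
#' @param x A `perm_lm` object.
#' @method tidy perm_lm
#' @export
tidy.perm_lm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 statistic = unname(x$t_statistics),
                 p.value = unname(x$perm_p))
}

#' @method glance perm_lm
#' @export
glance.perm_lm <- function(x, ...) {
  tibble::tibble(r.squared = x$R2, B = x$B, seed = x$seed)
}

#' Regress each behavior on retained pPCA axes with permutation inference
#'
#' One multiple regression per behavior column against the retained axis
#' scores, each with response-permutation p-values — the shape of the
#' study's behavior-by-axis regression table.
#'
#' @param behaviors Data frame with `species` and numeric behavior columns.
#' @param result A `ppca` fit after [label_axes()].
#' @inheritParams signal_test
#' @return Tibble: `response`, `term`, `estimate`, `statistic`, `p.value`,
#'   `r.squared`; the `perm_lm` objects are in attribute `"fits"`.
#' @export
behavior_regressions <- function(behaviors, result, B = 999L, seed = 1L) {
  abort_if(is.null(result$retained), "Run label_axes() first.")
  S <- result$scores[, result$retained, drop = FALSE]
  bm <- as_species_matrix(behaviors)
  abort_if(!setequal(rownames(bm), rownames(S)),
           "Behavior species do not match the pPCA scores.")
  bm <- bm[rownames(S), , drop = FALSE]
  fits <- lapply(colnames(bm), function(resp)
    permutation_inference(bm[, resp], S, B = B,
                          seed = stage_seed(seed, resp)))
  names(fits) <- colnames(bm)
  out <- purrr::map_dfr(colnames(bm), function(resp) {
    dplyr::mutate(tidy(fits[[resp]]), response = resp,
                  r.squared = fits[[resp]]$R2, .before = 1)
  })
  attr(out, "fits") <- fits
  out
}

#' Poisson regression for interference counts
#'
#' Log-link Poisson regression (IRLS, via [stats::glm()] with a tight
#' convergence tolerance). Counts must be non-negative integers; an
#' all-zero response is rejected (its intercept MLE lies at minus infinity).
#'
#' @param counts Non-negative integer response vector.
#' @param X Predictor matrix or data frame.
#' @return List: `coefficients`, `se`, `z`, `p.value` (Wald), `deviance`,
#'   and the `glm` fit as `fit`.
#' @export
fit_poisson <- function(counts, X) {
  abort_if(any(counts < 0) || any(abs(counts - round(counts)) > 1e-8),
           "`counts` must be non-negative integers.")
  abort_if(all(counts == 0),
           "All counts are zero: the Poisson MLE diverges (log-mean at -Inf).")
  X <- as_species_matrix(X)
  abort_if(length(counts) <= ncol(X) + 1L, "Need n > p + 1 observations.")
  df <- data.frame(counts = counts, X)
  fit <- stats::glm(counts ~ ., data = df, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  abort_if(!fit$converged,
           sprintf("Poisson IRLS did not converge in %d iterations.", fit$iter))
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(coefficients = stats::setNames(co[, 1], rownames(co)),
       se = stats::setNames(co[, 2], rownames(co)),
       z = stats::setNames(co[, 3], rownames(co)),
       p.value = stats::setNames(co[, 4], rownames(co)),
       deviance = fit$deviance,
       fit = fit)
}

#' Paired t test
#'
#' Classical paired t on the differences `a - b`, two-sided p from the t
#' distribution on `n - 1` df. Zero-variance differences are an error
#' rather than `NaN`.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return List: `t`, `df`, `p.value`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  abort_if(length(a) != length(b), "`a` and `b` must have equal length.")
  abort_if(length(a) < 2L, "Need at least 2 pairs.")
  d <- a - b
  abort_if(stats::var(d) <= 0, "Differences have zero variance.")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mean_difference = unname(ht$estimate))
}
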