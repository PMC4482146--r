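#' Moran's I phylogenetic autocorrelation coefficient
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z = x - mean(x)` and
#' `S0 = sum(W)`. With a row-normalized weight matrix `S0 = n` and the
#' leading factor drops out. Expectation under random tip labelling is
#' `-1/(n-1)`.
#'
#' @param x Numeric vector of tip values. If named, it is aligned to the row
#'   labels of `w`; otherwise it is assumed already aligned.
#' @param w Square weight matrix (`phylo_weights` or plain), same size as `x`.
#' @return The Moran's I statistic (scalar).
#' @export
morans_i <- function(x, w) {
  m <- unclass(w)
  n <- length(x)
  abort_if(n < 3L, "Moran's I needs at least 3 observations.")
  abort_if(nrow(m) != n || ncol(m) != n,
           "Weight matrix dimensions do not match the data vector.")
  x <- align_to_weights(x, m)
  z <- x - mean(x)
  ztz <- sum(z^2)
  abort_if(ztz <= 0, "Moran's I is undefined for a constant vector.")
  (n / sum(m)) * drop(crossprod(z, m %*% z)) / ztz
}

align_to_weights <- function(x, m) {
  if (!is.null(names(x)) && !is.null(rownames(m))) {
    abort_if(!setequal(names(x), rownames(m)),
             "Labels of `x` do not match the weight matrix labels.")
    x <- x[rownames(m)]
  }
  unname(x)
}

new_perm_test <- function(statistic, null_values, tail, B, seed,
                          method = "morans_i", extra = list()) {
  p <- perm_p_value(statistic, null_values, tail)
  structure(c(list(statistic = statistic, null_values = null_values,
                   p_value = p, tail = tail, B = B, seed = seed,
                   method = method), extra),
            class = "perm_test")
}

# Add-one permutation p-value: never zero, at most 1.
perm_p_value <- function(stat, null, tail) {
  B <- length(null)
  up <- (1 + sum(null >= stat)) / (B + 1)
  lo <- (1 + sum(null <= stat)) / (B + 1)
  switch(tail,
         upper = up,
         lower = lo,
         two_sided = min(1, 2 * min(up, lo)),
         stop("Unknown tail: ", tail, call. = FALSE))
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s): statistic = %.4f, p = %.4g (%s tail, B = %d, seed = %d)\n",
              x$method, x$statistic, x$p_value, x$tail, x$B, x$seed))
  invisible(x)
}

#' @describeIn signal_test Tidy one-row summary of a permutation test.
#' @param x A `perm_test` object.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p_value, tail = x$tail, B = x$B, seed = x$seed)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x)

#' Permutation test of phylogenetic signal via Moran's I
#'
#' The observed Moran's I is compared against a null distribution obtained by
#' permuting the trait values across the tips `B` times.
#'
#' @inheritParams morans_i
#' @param B Number of permutations (>= 99). The study convention is 1000.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param tail `"upper"` (positive autocorrelation, the default for trait
#'   signal), `"lower"`, or `"two_sided"`. P-values use the add-one rule
#'   `(1 + #exceedances) / (B + 1)` and are never zero.
#' @param ... Unused.
#' @return A `perm_test` object: `statistic`, `null_values`, `p_value`,
#'   `tail`, `B`, `seed`.
#' @export
signal_test <- function(x, w, B = 999L, seed = 1L,
                        tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  abort_if(B < 99L, "Use at least 99 permutations.")
  m <- unclass(w)
  x <- align_to_weights(x, m)
  stat <- morans_i(x, m)
  null <- with_seed(seed, morans_i_null(x, m, B))
  new_perm_test(stat, null, tail, as.integer(B), as.integer(seed),
                extra = list(matrix_kind = attr(w, "kind") %||% "unknown"))
}

# Vectorized Moran's I over B random tip permutations (RNG state is the
# caller's responsibility).
morans_i_null <- function(x, m, B) {
  n <- length(x)
  z <- x - mean(x)
  ztz <- sum(z^2)
  idx <- replicate(B, sample.int(n))
  Z <- matrix(z[idx], nrow = n)
  (n / sum(m)) * colSums((m %*% Z) * Z) / ztz
}

#' Abouheif's test of phylogenetic signal
#'
#' [signal_test()] run against the row-normalized Abouheif proximity matrix
#' of the tree. Upper tail detects positive autocorrelation (trait values
#' clumped within clades), lower tail negative autocorrelation (divergence
#' between close relatives).
#'
#' @inheritParams signal_test
#' @param tree An [ape::phylo] object whose tip labels match `names(x)`.
#' @return A `perm_test` object.
#' @export
abouheif_test <- function(x, tree, B = 999L, seed = 1L,
                          tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  w <- normalize_weights(abouheif_proximity(tree), "row_normalized")
  out <- signal_test(x, w, B = B, seed = seed, tail = tail)
  out$method <- "abouheif_moran"
  out
}

#' Per-trait phylogenetic signal table
#'
#' Runs [abouheif_test()] on every numeric column of a trait table and
#' returns the tidy per-trait signal summary (Moran's I and permutation p).
#'
#' @param traits Data frame with a `species` column and numeric trait
#'   columns, or a numeric matrix with species rownames.
#' @inheritParams abouheif_test
#' @return A tibble with columns `trait`, `moran_i`, `p.value`, `tail`, `B`.
#' @export
trait_signal <- function(traits, tree, B = 999L, seed = 1L, tail = "upper") {
  m <- as_species_matrix(traits)
  purrr::map_dfr(colnames(m), function(tr) {
    res <- abouheif_test(stats::setNames(m[, tr], rownames(m)), tree,
                         B = B, seed = stage_seed(seed, tr), tail = tail)
    tibble::tibble(trait = tr, moran_i = res$statistic,
                   p.value = res$p_value, tail = res$tail, B = res$B)
  })
}

#' Kendall's W concordance of distance matrices
#'
#' Generic congruence test for two or more distance matrices over the same
#' species: the upper triangles are midranked and Kendall's coefficient of
#' concordance W (with the standard tie correction) is computed across the
#' matrices. The null distribution permutes the species labels of every
#' matrix except the first, independently, `B` times; the test is
#' upper-tailed (large W = congruent).
#'
#' @param matrices List of >= 2 square distance matrices with identical
#'   species labels (order may differ; matrices are aligned to the first).
#' @inheritParams signal_test
#' @return A `perm_test` object with `method = "kendall_w"`.
#' @export
cadm_concordance <- function(matrices, B = 999L, seed = 1L) {
  abort_if(!is.list(matrices) || length(matrices) < 2L,
           "Provide a list of at least 2 distance matrices.")
  lab <- rownames(matrices[[1]])
  n <- nrow(matrices[[1]])
  abort_if(n < 4L, "Concordance needs at least 4 species.")
  mats <- lapply(matrices, function(m) {
    m <- unclass(m)
    abort_if(nrow(m) != n || ncol(m) != n, "Matrices differ in size.")
    if (!is.null(lab) && !is.null(rownames(m))) {
      abort_if(!setequal(rownames(m), lab),
               "Matrices have different species labels.")
      m <- m[lab, lab]
    }
    m
  })
  ut <- upper.tri(matrix(0, n, n))
  stat <- kendall_w(lapply(mats, function(m) m[ut]))
  null <- with_seed(seed, vapply(seq_len(B), function(b) {
    vecs <- c(list(mats[[1]][ut]), lapply(mats[-1], function(m) {
      p <- sample.int(n)
      m[p, p][ut]
    }))
    kendall_w(vecs)
  }, numeric(1)))
  new_perm_test(stat, null, "upper", as.integer(B), as.integer(seed),
                method = "kendall_w", extra = list(m = length(mats), n = n))
}

# Kendall's W over m numeric vectors of common length k, midranks + tie
# correction: W = 12 S / (m^2 (k^3 - k) - m sum(T_i)).
kendall_w <- function(vecs) {
  m <- length(vecs)
  k <- length(vecs[[1]])
  R <- vapply(vecs, rank, numeric(k))        # k x m midranks
  Rj <- rowSums(R)
  S <- sum((Rj - mean(Rj))^2)
  Tcorr <- sum(vapply(seq_len(m), function(i) {
    t <- table(R[, i])
    sum(t^3 - t)
  }, numeric(1)))
  denom <- m^2 * (k^3 - k) - m * Tcorr
  abort_if(denom <= 0, "Degenerate ranking: all values tied in every matrix.")
  12 * S / denom
}
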