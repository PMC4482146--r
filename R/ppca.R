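#' Phylogenetic principal component analysis (global/local axes)
#'
#' Eigen-decomposition of `H = (1/n) X' W X` where `X` is the standardized
#' (mean 0, variance 1, divisor n) trait matrix and `W` a symmetrized
#' row-normalized phylogenetic proximity matrix. Each axis maximizes the
#' product of trait variance and phylogenetic autocorrelation of its scores:
#' the defining identity is `eigenvalue = var_n(score) * I(score)` under `W`.
#' Positive eigenvalues ("global" axes) capture clade-level trait structure;
#' negative eigenvalues ("local" axes) capture divergence between close
#' relatives. Axes are ordered positive-descending first, then negative with
#' the most negative first; each axis's sign is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param traits_std Standardized trait matrix or data frame (`species`
#'   column allowed). Columns must have mean 0 and divisor-n variance 1
#'   (tolerance 1e-6); see [standardize()].
#' @param w Weight matrix. Use
#'   `normalize_weights(abouheif_proximity(tree), "symmetrized_row_normalized")`
#'   for the Abouheif analysis; the identity matrix recovers ordinary PCA.
#' @return A `ppca` object: `eigenvalues` (signed), `loadings` (trait x
#'   axis, unit columns), `scores` (species x axis), `axis_labels`
#'   (`global_1`, ..., `local_1`, ...), `variance_share`
#'   (`|eigenvalue| / sum |eigenvalue|`), `retained` (set by
#'   [label_axes()]).
#' @export
fit_ppca <- function(traits_std, w) {
  X <- as_species_matrix(traits_std)
  n <- nrow(X)
  mu <- colMeans(X)
  v <- colSums(sweep(X, 2, mu)^2) / n
  abort_if(any(abs(mu) > 1e-6) || any(abs(v - 1) > 1e-6),
           "Traits must be standardized (mean 0, variance 1, divisor n); see standardize().")
  m <- unclass(w)
  abort_if(nrow(m) != n, "Weight matrix size does not match the trait table.")
  if (!is.null(rownames(X)) && !is.null(rownames(m))) {
    abort_if(!setequal(rownames(X), rownames(m)),
             "Species labels of traits and weights do not match.")
    X <- X[rownames(m), , drop = FALSE]
  }
  H <- crossprod(X, m %*% X) / n
  H <- (H + t(H)) / 2
  eig <- eigen(H, symmetric = TRUE)
  vals <- eig$values
  ord <- c(which(vals >= 0)[order(vals[vals >= 0], decreasing = TRUE)],
           which(vals < 0)[order(vals[vals < 0])])
  vals <- vals[ord]
  L <- eig$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  n_glob <- sum(vals >= 0)
  labels <- c(if (n_glob > 0) paste0("global_", seq_len(n_glob)),
              if (n_glob < length(vals))
                paste0("local_", seq_len(length(vals) - n_glob)))
  rownames(L) <- colnames(X)
  colnames(L) <- labels
  S <- X %*% L
  structure(list(eigenvalues = stats::setNames(vals, labels),
                 loadings = L,
                 scores = S,
                 axis_labels = labels,
                 variance_share = stats::setNames(abs(vals) / sum(abs(vals)),
                                                  labels),
                 weight_kind = attr(w, "kind") %||% "unknown",
                 weight_normalization = attr(w, "normalization") %||% "raw",
                 n = n,
                 retained = NULL),
            class = "ppca")
}

#' @export
print.ppca <- function(x, ...) {
  cat(sprintf("<ppca> %d species x %d traits, weights: %s (%s)\n",
              x$n, nrow(x$loadings), x$weight_kind, x$weight_normalization))
  df <- data.frame(axis = x$axis_labels,
                   eigenvalue = round(x$eigenvalues, 4),
                   variance_share = round(x$variance_share, 4),
                   row.names = NULL)
  print(utils::head(df, 8))
  if (!is.null(x$retained))
    cat("retained:", paste(x$axis_labels[x$retained], collapse = ", "), "\n")
  invisible(x)
}

#' Retain global and local axes
#'
#' Keeps the `k_global` largest-positive and `k_local` most-negative axes
#' (the study design is 2 global + 1 local) and records the variance share
#' of the retained set.
#'
#' @param result A `ppca` fit.
#' @param k_global,k_local Number of axes of each sign to retain.
#' @return The `ppca` object with `retained` (axis indices) and
#'   `retained_share` set.
#' @export
label_axes <- function(result, k_global = 2L, k_local = 1L) {
  n_glob <- sum(result$eigenvalues >= 0)
  n_loc <- length(result$eigenvalues) - n_glob
  abort_if(k_global > n_glob,
           sprintf("Requested %d global axes but only %d have positive eigenvalues.",
                   k_global, n_glob))
  abort_if(k_local > n_loc,
           sprintf("Requested %d local axes but only %d have negative eigenvalues.",
                   k_local, n_loc))
  idx <- c(seq_len(k_global),
           if (k_local > 0) n_glob + seq_len(k_local))
  result$retained <- idx
  result$retained_share <- sum(result$variance_share[idx])
  result
}

#' Phylogenetic signal of retained pPCA axis scores
#'
#' Abouheif permutation test per retained axis: upper-tailed for global axes
#' (positive autocorrelation expected), lower-tailed for local axes.
#'
#' @param result A `ppca` fit after [label_axes()].
#' @param tree The phylogeny the weights came from.
#' @inheritParams signal_test
#' @return Tibble with `axis`, `moran_i`, `p.value`, `tail`; the full
#'   `perm_test` objects are in attribute `"tests"`.
#' @export
score_signal <- function(result, tree, B = 999L, seed = 1L) {
  abort_if(is.null(result$retained), "Run label_axes() first.")
  tests <- lapply(result$retained, function(i) {
    lab <- result$axis_labels[i]
    tail <- if (startsWith(lab, "global")) "upper" else "lower"
    abouheif_test(stats::setNames(result$scores[, i],
                                  rownames(result$scores)),
                  tree, B = B, seed = stage_seed(seed, lab), tail = tail)
  })
  out <- tibble::tibble(
    axis = result$axis_labels[result$retained],
    moran_i = vapply(tests, `[[`, numeric(1), "statistic"),
    p.value = vapply(tests, `[[`, numeric(1), "p_value"),
    tail = vapply(tests, `[[`, character(1), "tail"),
    B = as.integer(B))
  attr(out, "tests") <- tests
  out
}

#' @describeIn fit_ppca Tidy pPCA components: `"eigenvalues"` (axis,
#'   eigenvalue, variance share, sign), `"loadings"` (long, with the
#'   dominant flag marking loadings above the 75th percentile of absolute
#'   loadings per axis), or `"scores"` (long).
#' @param x A `ppca` object.
#' @param matrix Which component to tidy.
#' @param ... Unused.
#' @method tidy ppca
#' @export
tidy.ppca <- function(x, matrix = c("eigenvalues", "loadings", "scores"),
                      ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(axis = x$axis_labels,
                          eigenvalue = unname(x$eigenvalues),
                          variance_share = unname(x$variance_share),
                          sign = ifelse(x$eigenvalues >= 0, "global", "local"),
                          retained = seq_along(x$axis_labels) %in%
                            (x$retained %||% integer(0))))
  }
  if (matrix == "loadings") {
    long <- tibble::as_tibble(as.data.frame.table(x$loadings,
                                                  stringsAsFactors = FALSE))
    names(long) <- c("trait", "axis", "loading")
    long <- dplyr::group_by(long, .data$axis)
    long <- dplyr::mutate(long,
                          dominant = abs(.data$loading) >
                            stats::quantile(abs(.data$loading), 0.75))
    return(dplyr::ungroup(long))
  }
  long <- tibble::as_tibble(as.data.frame.table(x$scores,
                                                stringsAsFactors = FALSE))
  names(long) <- c("species", "axis", "score")
  long
}

#' @method glance ppca
#' @export
glance.ppca <- function(x, ...) {
  tibble::tibble(n_species = x$n,
                 n_traits = nrow(x$loadings),
                 n_global = sum(x$eigenvalues >= 0),
                 n_local = sum(x$eigenvalues < 0),
                 retained_share = x$retained_share %||% NA_real_)
}
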