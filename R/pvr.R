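#' Gower double-centering of a distance matrix
#'
#' `G = -1/2 * C %*% D2 %*% C` with `C = I - 11'/n` and `D2` the elementwise
#' squared distances (the classical principal-coordinates convention).
#' Centering the raw (unsquared) distances instead is available for
#' sensitivity analysis.
#'
#' @param d Symmetric distance matrix with zero diagonal (a `phylo_weights`
#'   of kind `patristic_distance`, typically).
#' @param squared Square the distances before centering (default `TRUE`).
#' @return Symmetric matrix `G` whose rows and columns sum to zero.
#' @export
gower_center <- function(d, squared = TRUE) {
  m <- unclass(d)
  abort_if(!is.matrix(m) || nrow(m) != ncol(m), "`d` must be square.")
  abort_if(max(abs(m - t(m))) > 1e-8, "`d` must be symmetric.")
  n <- nrow(m)
  d2 <- if (squared) m^2 else m
  C <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * C %*% d2 %*% C
  g <- (g + t(g)) / 2
  dimnames(g) <- dimnames(m)
  g
}

#' Extract the phylogenetic eigenvector basis
#'
#' Eigen-decomposition of a Gower-centered distance matrix. Eigenpairs are
#' sorted by descending eigenvalue; only eigenvalues above `tol * max`
#' are retained (the centering always produces at least one ~zero value).
#' Each eigenvector's sign is fixed by making its first non-zero loading
#' positive. Leading vectors contrast deep clades; later ones structure
#' near the tips.
#'
#' @param g Symmetric matrix from [gower_center()].
#' @param tol Relative eigenvalue cutoff (default `1e-8`).
#' @return An `eigenbasis`: list with `labels`, `values` (descending),
#'   `vectors` (orthonormal columns, one per retained eigenvalue).
#' @export
extract_eigenvectors <- function(g, tol = 1e-8) {
  abort_if(max(abs(g - t(g))) > 1e-8, "`g` must be symmetric.")
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- eig$values > tol * max(abs(eig$values))
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, j]) > 1e-10)[1]
    if (!is.na(nz) && vecs[nz, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- rownames(g)
  colnames(vecs) <- paste0("pev", seq_len(ncol(vecs)))
  structure(list(labels = rownames(g), values = vals, vectors = vecs),
            class = "eigenbasis")
}

#' @export
print.eigenbasis <- function(x, ...) {
  cat(sprintf("<eigenbasis> %d species, %d retained eigenvectors\n",
              length(x$labels), length(x$values)))
  cat("eigenvalues:", paste(signif(utils::head(x$values, 6), 4),
                            collapse = ", "),
      if (length(x$values) > 6) "..." else "", "\n")
  invisible(x)
}

#' Select phylogenetic eigenvectors by residual-autocorrelation minimization
#'
#' Greedy forward selection: starting from the empty set, regress the
#' response on the current selection, test the residuals for phylogenetic
#' signal (two-sided permutation Moran's I against `w`), and, while the
#' residual signal is significant at `alpha`, add the candidate eigenvector
#' whose inclusion most reduces the absolute residual Moran's I. Ties go to
#' the lower eigenvector index (coarser phylogenetic scale first). Selection
#' stops when the residual test is non-significant, when no candidate
#' reduces `|I|`, or when `n - 3` vectors are in the model.
#'
#' @param y Response vector aligned to `basis$labels` (names are aligned if
#'   present).
#' @param basis An `eigenbasis` from [extract_eigenvectors()].
#' @param w Weight matrix for the residual Moran's I (e.g. row-normalized
#'   inverse patristic distances or Abouheif proximity).
#' @param alpha Stopping significance level (default 0.05).
#' @inheritParams signal_test
#' @return Integer vector of selected eigenvector indices (possibly empty),
#'   with the `|I|` trace as attribute `"i_trace"`.
#' @export
select_eigenvectors <- function(y, basis, w, alpha = 0.05, B = 999L,
                                seed = 1L) {
  V <- basis$vectors
  n <- nrow(V)
  y <- align_to_weights(y, unclass(w))
  abort_if(length(y) != n, "`y` length does not match the basis.")
  selected <- integer(0)
  resid <- y - mean(y)
  i_trace <- abs(morans_i(resid, w))
  step <- 0L
  repeat {
    if (stats::var(resid) < 1e-12) break  # perfect fit, nothing left to explain
    test <- signal_test(resid, w, B = B,
                        seed = stage_seed(seed, paste0("select", step)),
                        tail = "two_sided")
    if (test$p_value > alpha) break
    if (length(selected) >= n - 3L) break
    cand <- setdiff(seq_len(ncol(V)), selected)
    if (length(cand) == 0L) break
    cur <- abs(morans_i(resid, w))
    abs_i <- vapply(cand, function(k) {
      fit <- stats::lm.fit(cbind(1, V[, c(selected, k), drop = FALSE]), y)
      abort_if(any(is.na(fit$coefficients)),
               "Collinear eigenvector selection (degenerate regression).")
      r <- fit$residuals
      if (stats::var(r) < 1e-12) -Inf else abs(morans_i(r, w))
    }, numeric(1))
    best <- cand[which.min(abs_i)]  # which.min takes the first = lowest index
    if (min(abs_i) >= cur) break
    selected <- c(selected, best)
    resid <- stats::lm.fit(cbind(1, V[, selected, drop = FALSE]), y)$residuals
    i_trace <- c(i_trace, if (stats::var(resid) < 1e-12) 0 else
      abs(morans_i(resid, w)))
    step <- step + 1L
  }
  structure(selected, i_trace = i_trace)
}

#' Partial-regression variance partitioning
#'
#' Decomposes the variance of a response into four fractions from three
#' ordinary least-squares R-squared values — `R2_T` (traits only), `R2_P`
#' (selected phylogenetic eigenvectors only) and `R2_TP` (both):
#' traits alone `= R2_TP - R2_P`, phylogeny alone `= R2_TP - R2_T`, shared
#' `= R2_T + R2_P - R2_TP`, unexplained `= 1 - R2_TP`. The four fractions
#' sum to one by construction; the shared fraction may be slightly negative
#' (suppression), in which case it is flagged.
#'
#' @param y Response vector.
#' @param X_traits Numeric matrix / data frame of trait predictors.
#' @param basis_selected Matrix of selected eigenvectors (0 columns allowed,
#'   giving `R2_P = 0`).
#' @param response Name recorded in the output row.
#' @return A one-row tibble of class `variance_partition`: `response`,
#'   `traits_alone`, `shared`, `phylo_alone`, `unexplained`, `n_eigenvectors`.
#' @export
partition_variance <- function(y, X_traits, basis_selected,
                               response = "response") {
  Xt <- as_species_matrix(X_traits)
  Xp <- if (is.null(basis_selected)) matrix(numeric(0), length(y), 0)
        else as.matrix(basis_selected)
  n <- length(y)
  abort_if(nrow(Xt) != n || nrow(Xp) != n, "Row mismatch in predictors.")
  abort_if(ncol(Xt) + ncol(Xp) + 1L >= n,
           "Saturated model: combined predictor count must be < n.")
  r2 <- function(X) {
    if (ncol(X) == 0L) return(0)
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  R2_T <- r2(Xt); R2_P <- r2(Xp); R2_TP <- r2(cbind(Xt, Xp))
  shared <- R2_T + R2_P - R2_TP
  if (shared < -1e-6)
    warning(sprintf("Negative shared fraction (%.4g) for '%s' (suppression).",
                    shared, response), call. = FALSE)
  out <- tibble::tibble(response = response,
                        traits_alone = R2_TP - R2_P,
                        shared = shared,
                        phylo_alone = R2_TP - R2_T,
                        unexplained = 1 - R2_TP,
                        n_eigenvectors = ncol(Xp))
  class(out) <- c("variance_partition", class(out))
  out
}

#' Full PVR variance partitioning of behavior responses
#'
#' For each behavior column: extract the eigenvector basis of the
#' Gower-centered (squared) patristic distances, run the greedy
#' residual-autocorrelation eigenvector selection, and partition the
#' behavior's variance between the trait matrix and the selected
#' eigenvectors.
#'
#' @param behaviors Data frame with `species` plus numeric behavior columns.
#' @param traits_design Data frame / matrix of trait predictors (`species`
#'   column allowed), e.g. from [build_design_matrix()].
#' @param tree An [ape::phylo] object covering the same species.
#' @param residual_weights Weight matrix for residual Moran's I:
#'   `"inv_patristic"` (row-normalized `1/d`, default) or `"abouheif"`.
#' @param squared Passed to [gower_center()].
#' @inheritParams select_eigenvectors
#' @return A `variance_partition` tibble, one row per behavior.
#' @export
pvr_partition <- function(behaviors, traits_design, tree,
                          residual_weights = c("inv_patristic", "abouheif"),
                          alpha = 0.05, B = 999L, seed = 1L, squared = TRUE) {
  residual_weights <- match.arg(residual_weights)
  d <- patristic_distances(tree)
  basis <- extract_eigenvectors(gower_center(d, squared = squared))
  w <- switch(residual_weights,
              inv_patristic = {
                m <- unclass(d)
                inv <- 1 / m
                diag(inv) <- 0
                normalize_weights(
                  new_phylo_weights(inv, "inv_patristic"), "row_normalized")
              },
              abouheif = normalize_weights(abouheif_proximity(tree),
                                           "row_normalized"))
  bm <- as_species_matrix(behaviors)
  ord <- tree$tip.label
  abort_if(!setequal(rownames(bm), ord), "Behavior species do not match tree tips.")
  bm <- bm[ord, , drop = FALSE]
  Xt <- as_species_matrix(traits_design)
  abort_if(!setequal(rownames(Xt), ord), "Trait species do not match tree tips.")
  Xt <- Xt[ord, , drop = FALSE]
  rows <- purrr::map_dfr(colnames(bm), function(resp) {
    y <- bm[, resp]
    sel <- select_eigenvectors(stats::setNames(y, ord), basis, w,
                               alpha = alpha, B = B,
                               seed = stage_seed(seed, resp))
    max_k <- length(y) - ncol(Xt) - 2L
    if (length(sel) > max_k) {
      warning(sprintf("Truncating eigenvector selection for '%s' to %d to keep the combined model unsaturated.",
                      resp, max_k), call. = FALSE)
      sel <- sel[seq_len(max(max_k, 0L))]
    }
    partition_variance(y, Xt, basis$vectors[, sel, drop = FALSE],
                       response = resp)
  })
  class(rows) <- c("variance_partition", class(tibble::tibble()))
  rows
}
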