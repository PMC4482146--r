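#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation with exponential waiting times: starting from two
#' lineages, the next speciation event arrives after `Exp(k * birth_rate)`
#' time with `k` lineages extant and splits a uniformly chosen lineage;
#' after the `n`-th lineage appears the process runs for one further
#' `Exp(n * birth_rate)` interval and all pending branches are cut at the
#' present, making the tree exactly ultrametric.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @return An [ape::phylo] object with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  abort_if(n_tips < 2L, "Need at least 2 tips.")
  abort_if(birth_rate <= 0, "`birth_rate` must be > 0.")
  sim <- with_seed(seed, {
    kids <- vector("list", 2L * n_tips)
    start <- numeric(2L * n_tips)
    split_at <- rep(NA_real_, 2L * n_tips)
    kids[[1L]] <- c(2L, 3L)   # id 1 = root, splits at time 0
    split_at[1L] <- 0
    active <- c(2L, 3L)
    next_id <- 4L
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + stats::rexp(1L, rate = k * birth_rate)
      i <- sample.int(k, 1L)
      L <- active[i]
      split_at[L] <- t
      kids[[L]] <- c(next_id, next_id + 1L)
      start[next_id + 0:1] <- t
      active <- c(active[-i], next_id, next_id + 1L)
      next_id <- next_id + 2L
    }
    list(kids = kids, start = start, split_at = split_at,
         t_end = t + stats::rexp(1L, rate = n_tips * birth_rate))
  })
  lineage_to_phylo(sim, n_tips)
}

# Convert the lineage bookkeeping of simulate_yule_tree into an ape phylo.
lineage_to_phylo <- function(sim, n_tips) {
  n_node <- n_tips - 1L
  edge <- matrix(0L, 2L * n_tips - 2L, 2L)
  elen <- numeric(2L * n_tips - 2L)
  env <- new.env()
  env$tip <- 0L; env$node <- n_tips; env$row <- 0L
  dfs <- function(id) {
    if (is.null(sim$kids[[id]])) {
      env$tip <- env$tip + 1L
      return(env$tip)
    }
    env$node <- env$node + 1L
    my <- env$node
    for (child in sim$kids[[id]]) {
      r <- env$row + 1L; env$row <- r
      edge[r, 1L] <<- my
      end <- if (is.null(sim$kids[[child]])) sim$t_end else sim$split_at[child]
      elen[r] <<- end - sim$start[child]
      edge[r, 2L] <<- dfs(child)
    }
    my
  }
  dfs(1L)
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = paste0("t", seq_len(n_tips)),
                         Nnode = n_node),
                    class = "phylo", order = "cladewise")
  validate_phylogeny(tree)
}

#' Simulate traits on a tree with tunable phylogenetic signal
#'
#' Each trait is a multivariate-normal draw with covariance
#' `sigma2 * V(lambda)`, where `V(1)` is the Brownian-motion covariance
#' (shared root-to-MRCA path length) and `V(lambda)` attenuates the
#' off-diagonal entries by `lambda` while keeping the diagonal — Pagel's
#' lambda construction. `lambda = 1` is pure Brownian motion; `lambda = 0`
#' gives i.i.d. tip values (no signal). Traits are mutually independent.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param p Number of traits.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Signal attenuation in `[0, 1]`.
#' @param seed Integer seed.
#' @return `n x p` numeric matrix, rownames = tip labels, columns
#'   `trait_1 ... trait_p`.
#' @export
simulate_traits <- function(tree, p = 1L, sigma2 = 1, lambda = 1,
                            seed = 1L) {
  validate_phylogeny(tree)
  abort_if(sigma2 <= 0, "`sigma2` must be > 0.")
  abort_if(lambda < 0 || lambda > 1, "`lambda` must be in [0, 1].")
  V <- ape::vcv(tree)
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Sigma <- sigma2 * Vl
  U <- tryCatch(chol(Sigma), error = function(e) {
    warning("Covariance numerically non-positive-definite; jittering by 1e-10.",
            call. = FALSE)
    chol(Sigma + diag(1e-10, nrow(Sigma)))
  })
  n <- nrow(Sigma)
  X <- with_seed(seed, t(U) %*% matrix(stats::rnorm(n * p), n, p))
  dimnames(X) <- list(rownames(V), paste0("trait_", seq_len(p)))
  X
}

#' Simulate behavioral responses from latent axis scores
#'
#' Each behavior is a linear function of the axis scores plus Gaussian
#' noise: `y = intercept + scores %*% beta + N(0, noise_sd)`. Per-species
#' interference counts are Poisson with mean `interference_rate`,
#' independent of the axes (the null the post-hoc Poisson regression sits
#' on).
#'
#' @param axis_scores `n x k` matrix of axis scores (rownames = species).
#' @param beta `k x q` matrix of effect sizes (columns = behaviors; a
#'   vector is treated as a single behavior called `behavior`).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param interference_rate Poisson mean of the interference counts (>= 0).
#' @param intercepts Optional length-`q` baseline added per behavior.
#' @param seed Integer seed.
#' @return Tibble: `species`, one column per behavior, and integer
#'   `interference`.
#' @export
simulate_behaviors <- function(axis_scores, beta, noise_sd = 1,
                               interference_rate = 0.5, intercepts = NULL,
                               seed = 1L) {
  S <- as.matrix(axis_scores)
  abort_if(any(!is.finite(S)), "Axis scores must be finite.")
  abort_if(noise_sd < 0 || interference_rate < 0,
           "`noise_sd` and `interference_rate` must be >= 0.")
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1,
                                         dimnames = list(NULL, "behavior"))
  abort_if(nrow(beta) != ncol(S),
           "`beta` rows must match the number of score axes.")
  q <- ncol(beta)
  if (is.null(intercepts)) intercepts <- rep(0, q)
  n <- nrow(S)
  out <- with_seed(seed, {
    Y <- S %*% beta +
      matrix(intercepts, n, q, byrow = TRUE) +
      matrix(stats::rnorm(n * q, sd = noise_sd), n, q)
    list(Y = Y, counts = stats::rpois(n, interference_rate))
  })
  res <- tibble::as_tibble(as.data.frame(out$Y))
  names(res) <- colnames(beta) %||% paste0("behavior_", seq_len(q))
  dplyr::bind_cols(tibble::tibble(species = rownames(S) %||%
                                    paste0("s", seq_len(n))),
                   res,
                   tibble::tibble(interference = as.integer(out$counts)))
}

# Rescale an ultrametric tree to a target root-to-tip depth.
rescale_depth <- function(tree, depth) {
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / cur
  tree
}

#' Study-design-like synthetic dataset
#'
#' Emulates the structure of the foraging study: an ultrametric 23-tip tree
#' with three nested clades (8, 10 and 5 tips, standing in for
#' family/genus structure), 10 raw seed traits generated in blocks of
#' mixed phylogenetic signal (two Brownian blocks with `lambda = 1`, one
#' signal-free block with `lambda = 0`) and mapped monotonically onto
#' natural trait scales (percentages, masses, etc.; the three smallest
#' tannin values are zeroed so the detection floor is exercised), and four
#' behavioral responses generated as linear functions of the fitted pPCA
#' axis scores (`global_1`, `global_2`, `local_1`) plus noise. Because the
#' behaviors are built from the same processed design matrix the analysis
#' pipeline reconstructs, effect recovery is exact at zero noise.
#'
#' @param seed Integer seed.
#' @param noise_sd Residual SD of the behaviors (default 0.5; axis scores
#'   have SD of roughly 1-3).
#' @param beta `3 x 4` effect matrix on (global_1, global_2, local_1);
#'   default: every behavior loads `-3` on global_1 and `+3` on local_1,
#'   `0` on global_2.
#' @param interference_rate Poisson mean of interference counts
#'   (default 0.6, matching a low-rate post-hoc count design).
#' @return List: `tree`, `traits` (raw-scale tibble), `behaviors` (tibble
#'   with interference counts), `scores` (the generating axis scores) and
#'   `truth` (effect sizes, block structure, seed).
#' @export
simulate_paperlike <- function(seed = 1L, noise_sd = 0.5, beta = NULL,
                               interference_rate = 0.6) {
  sizes <- c(8L, 10L, 5L)
  subs <- lapply(seq_along(sizes), function(i) {
    rescale_depth(simulate_yule_tree(sizes[i], birth_rate = 1,
                                     seed = stage_seed(seed, paste0("clade", i))),
                  0.5)
  })
  offs <- c(0L, cumsum(sizes))
  nwk <- vapply(seq_along(subs), function(i) {
    tr <- subs[[i]]
    tr$tip.label <- sprintf("sp%02d", offs[i] + seq_len(sizes[i]))
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  # clades 1 and 2 are sisters (split at depth 0.75); clade 3 is the outgroup
  tree <- read_newick(text = sprintf("((%s:0.25,%s:0.25):0.25,%s:0.5);",
                                     nwk[1], nwk[2], nwk[3]))
  n <- sum(sizes)
  blocks <- list(brownian_a = 4L, brownian_b = 4L, free = 2L)
  lambdas <- c(brownian_a = 1, brownian_b = 1, free = 0)
  Z <- do.call(cbind, lapply(names(blocks), function(b) {
    simulate_traits(tree, p = blocks[[b]], sigma2 = 1, lambda = lambdas[[b]],
                    seed = stage_seed(seed, b))
  }))
  Z <- Z[tree$tip.label, ]
  zstd <- apply(Z, 2, function(v) (v - mean(v)) / stats::sd(v))
  tannin <- exp(0.6 * zstd[, 8])
  tannin[order(tannin)[1:3]] <- 0   # below the assay detection limit
  traits <- tibble::tibble(
    species = tree$tip.label,
    lipid_pct = 100 * stats::plogis(0.8 * zstd[, 1]),
    carb_pct = 100 * stats::plogis(-0.8 * zstd[, 1] + 0.3 * zstd[, 2]),
    thickness_um = 400 * exp(0.9 * zstd[, 3]),
    shell_mass_g = 1.5 * exp(0.8 * zstd[, 4]),
    protein_pct = 100 * stats::plogis(0.6 * zstd[, 5] - 1),
    dormancy_days = 60 * exp(0.5 * zstd[, 6]),
    hardness_kg = 25 * exp(0.7 * zstd[, 7]),
    tannin_pct_tae = tannin,
    kernel_mass_g = 2 * exp(0.9 * zstd[, 9]),
    energy_cal_g = 5000 * exp(0.12 * zstd[, 10]),
    moisture_pct = 100 * stats::plogis(
      with_seed(stage_seed(seed, "moisture"), stats::rnorm(n, -1, 0.2))))
  design <- build_design_matrix(
    suppressMessages(apply_floors(traits, "tannin_pct_tae", 0.35)))
  std <- standardize(design)
  w <- normalize_weights(abouheif_proximity(tree),
                         "symmetrized_row_normalized")
  fit <- label_axes(fit_ppca(std, w), k_global = 2L, k_local = 1L)
  S <- fit$scores[, fit$retained, drop = FALSE]
  if (is.null(beta))
    beta <- matrix(c(-3, 0, 3), 3, 4,
                   dimnames = list(colnames(S),
                                   c("time_consume", "dist_consume",
                                     "time_cache", "dist_cache")))
  behaviors <- simulate_behaviors(S, beta, noise_sd = noise_sd,
                                  interference_rate = interference_rate,
                                  intercepts = c(10, 6, 3, 25),
                                  seed = stage_seed(seed, "behaviors"))
  list(tree = tree, traits = traits, behaviors = behaviors, scores = S,
       truth = list(beta = beta, lambda_blocks = lambdas,
                    block_sizes = unlist(blocks), noise_sd = noise_sd,
                    interference_rate = interference_rate, seed = seed))
}
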