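# Independent brute-force oracles used to check the package's kernels.

# Moran's I via an explicit double loop.
oracle_moran <- function(x, m) {
  n <- length(x)
  z <- x - mean(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + m[i, j] * z[i] * z[j]
  (n / sum(m)) * s / sum(z^2)
}

# Abouheif proximity via ape's node paths: product of direct-descendant
# counts of the internal nodes on the tip-to-tip path.
oracle_abouheif <- function(tree) {
  n <- length(tree$tip.label)
  ddf <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  a <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      path <- ape::nodepath(tree, i, j)
      internal <- path[path > n]
      a[i, j] <- a[j, i] <- 1 / prod(ddf[internal])
    }
  }
  a
}

# Spearman as rank-then-Pearson.
oracle_spearman <- function(m) stats::cor(apply(m, 2, rank))

# OLS coefficients from the normal equations.
oracle_ols_coef <- function(y, X) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# A small fixed balanced ultrametric tree used across tests.
balanced4 <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 4) {
  labs <- LETTERS[seq_len(n)]
  read_newick(text = paste0("(", paste0(labs, ":1", collapse = ","), ");"))
}

# i.i.d. standard normal tip values named for a tree.
iid_traits <- function(tree) {
  stats::setNames(stats::rnorm(length(tree$tip.label)), tree$tip.label)
}

# All n! permutations of 1..n (rows), for exhaustive null enumeration.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Kendall's W statistic of a list of distance matrices (package kernel).
kendall_w_stat <- function(mats) {
  ut <- upper.tri(mats[[1]])
  seedforage:::kendall_w(lapply(mats, function(m) m[ut]))
}

# Drop phylo_weights metadata, keeping only dim/dimnames (for oracle
# comparisons).
strip_w <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
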