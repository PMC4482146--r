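#' Read and validate a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream comparative analyses rely on: unique tip labels, every internal
#' node with at least two children (polytomies are fine, singletons are not),
#' and non-negative branch lengths. Trees without branch lengths are accepted;
#' operations that need distances fall back to unit lengths with a warning.
#'
#' @param path Path to a Newick file. A raw Newick string is also accepted
#'   via `text`.
#' @param text Optional Newick string, used instead of `path`.
#' @return A validated [ape::phylo] object.
#' @export
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' tr$tip.label
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    abort_if(is.null(path) || !file.exists(path),
             sprintf("Newick file not found: '%s'", path %||% "<NULL>"))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  abort_if(is.null(tree) || !inherits(tree, "phylo"),
           "Malformed Newick string: parser returned no tree.")
  validate_phylogeny(tree)
  tree
}

# Cheap structural pre-check so malformed input fails with a character offset
# instead of an opaque parser error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      abort_if(depth < 0L,
               sprintf("Malformed Newick: unmatched ')' at offset %d.", i))
    }
  }
  abort_if(depth != 0L,
           sprintf("Malformed Newick: %d unclosed '(' at end of string.", depth))
  abort_if(!grepl(";\\s*$", text),
           sprintf("Malformed Newick: missing terminal ';' (string length %d).",
                   nchar(text)))
  invisible(TRUE)
}

#' Validate the invariants of a phylogeny
#'
#' @param tree An [ape::phylo] object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  abort_if(!inherits(tree, "phylo"), "`tree` must be an ape 'phylo' object.")
  abort_if(length(tree$tip.label) < 1L, "Tree has no tips.")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  abort_if(length(dup) > 0L,
           sprintf("Duplicate tip labels: %s.", paste(dup, collapse = ", ")))
  if (!is.null(tree$edge.length))
    abort_if(any(tree$edge.length < 0),
             "Negative branch lengths are not allowed.")
  # a lone tip is represented by a root with a single child; allow it
  if (length(tree$tip.label) > 1L && !is.null(tree$edge) &&
      nrow(tree$edge) > 0L) {
    kids <- tabulate(tree$edge[, 1L])
    internal <- sort(unique(tree$edge[, 1L]))
    abort_if(any(kids[internal] < 2L),
             "Every internal node must have at least 2 children (singleton node found).")
  }
  invisible(tree)
}

new_phylo_weights <- function(values, kind, normalization = "raw") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values,
            kind = kind,
            normalization = normalization,
            class = c("phylo_weights", class(values)))
}

#' @export
print.phylo_weights <- function(x, ...) {
  cat(sprintf("<phylo_weights> %d x %d, kind = %s, normalization = %s\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "normalization")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips. Trees
#' without branch lengths get unit lengths (with a warning), which turns the
#' result into a node-count distance.
#'
#' @param tree An [ape::phylo] object.
#' @return A `phylo_weights` matrix, `kind = "patristic_distance"`, with tip
#'   labels as dimnames, zero diagonal, symmetric.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  if (is.null(tree$edge.length)) {
    warning("Tree has no branch lengths; assuming unit lengths.", call. = FALSE)
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  n <- length(tree$tip.label)
  if (n == 1L) {
    d <- matrix(0, 1L, 1L, dimnames = list(tree$tip.label, tree$tip.label))
    return(new_phylo_weights(d, "patristic_distance"))
  }
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  new_phylo_weights(d, "patristic_distance")
}

#' Abouheif phylogenetic proximity matrix
#'
#' Topology-only closeness between tips: `a_ij` is the reciprocal of the
#' product of the numbers of direct descendants of every internal node on the
#' path from tip `i` to tip `j` (both the MRCA and intermediate nodes count).
#' Branch lengths are ignored; the diagonal is zero. This is the proximity
#' that makes Abouheif's test a Moran's I statistic.
#'
#' @param tree An [ape::phylo] object.
#' @return A `phylo_weights` matrix, `kind = "abouheif_proximity"`.
#' @export
#' @examples
#' tr <- read_newick(text = "((A,B),(C,D));")
#' abouheif_proximity(tr)["A", c("B", "C")]  # 1/2 and 1/8
abouheif_proximity <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  a <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  if (n >= 2L) {
    edge <- tree$edge
    parent_of <- integer(max(edge))
    parent_of[edge[, 2L]] <- edge[, 1L]
    ddf <- tabulate(edge[, 1L], nbins = max(edge))  # direct-descendant counts
    root <- setdiff(edge[, 1L], edge[, 2L])[1L]
    # ancestor chains, tip -> root (excluding the tip itself)
    chains <- lapply(seq_len(n), function(tip) {
      ch <- integer(0)
      node <- tip
      while (node != root) {
        node <- parent_of[node]
        ch <- c(ch, node)
      }
      ch
    })
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ci <- chains[[i]]; cj <- chains[[j]]
        mrca <- ci[match(TRUE, ci %in% cj)]
        path_nodes <- c(ci[seq_len(match(mrca, ci))],
                        cj[seq_len(match(mrca, cj) - 1L)])
        a[i, j] <- a[j, i] <- 1 / prod(ddf[path_nodes])
      }
    }
  }
  new_phylo_weights(a, "abouheif_proximity")
}

#' Normalize a species weight matrix
#'
#' @param w A `phylo_weights` matrix (or plain square matrix).
#' @param mode `"row_normalized"` divides each row by its sum;
#'   `"symmetrized_row_normalized"` additionally symmetrizes the result as
#'   `(W + t(W)) / 2`. Both keep the total weight equal to the number of
#'   species, so Moran's I scaling constants stay exact.
#' @return A `phylo_weights` matrix with the requested `normalization`.
#' @export
normalize_weights <- function(w,
                              mode = c("row_normalized",
                                       "symmetrized_row_normalized")) {
  mode <- match.arg(mode)
  kind <- attr(w, "kind") %||% "unknown"
  m <- unclass(w)
  rs <- rowSums(m)
  bad <- rownames(m)[rs <= 0] %||% which(rs <= 0)
  abort_if(any(rs <= 0),
           sprintf("Zero (or negative) row sum for species: %s.",
                   paste(bad, collapse = ", ")))
  m <- m / rs
  if (mode == "symmetrized_row_normalized") m <- (m + t(m)) / 2
  new_phylo_weights(m, kind, mode)
}

#' Write / read a labelled species matrix as CSV
#'
#' Round-trips `phylo_weights` (or any labelled square matrix) through a CSV
#' file with species labels as the first column and the header row.
#'
#' @param w Matrix to write.
#' @param path File path.
#' @rdname weights_csv
#' @return `write_weights()` returns `path` invisibly; `read_weights()` a
#'   `phylo_weights` matrix (kind/normalization restored from an attribute
#'   comment line when present).
#' @export
write_weights <- function(w, path) {
  df <- data.frame(species = rownames(w), unclass(w), check.names = FALSE)
  header <- sprintf("# kind=%s normalization=%s",
                    attr(w, "kind") %||% "unknown",
                    attr(w, "normalization") %||% "raw")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname weights_csv
#' @export
read_weights <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- c(kind = "unknown", normalization = "raw")
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    kv <- regmatches(first, gregexpr("\\w+=[\\w_]+", first, perl = TRUE))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=")[[1]]
      meta[parts[1]] <- parts[2]
    }
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  new_phylo_weights(m, meta[["kind"]], meta[["normalization"]])
}
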