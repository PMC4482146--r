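# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage sub-seed from the run seed: stable in the stage name, so
# adding a stage never perturbs another stage's draws. Kept below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 10007 * h) %% 2147483647)
}

# Coerce a data frame (species column allowed) or matrix to a plain numeric
# matrix with species rownames.
as_species_matrix <- function(x, species_col = "species") {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  if (species_col %in% names(x)) {
    rn <- as.character(x[[species_col]])
    x <- x[setdiff(names(x), species_col)]
  } else {
    rn <- rownames(x)
  }
  keep <- vapply(x, is.numeric, logical(1))
  m <- as.matrix(x[keep])
  storage.mode(m) <- "double"
  if (!is.null(rn)) rownames(m) <- rn
  m
}

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
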