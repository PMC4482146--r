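#' Configuration for a full pipeline run
#'
#' Bundles and validates the inputs and tuning parameters of
#' [run_pipeline()]. Defaults follow the study design: 1000 permutations,
#' alpha 0.05, 2 global + 1 local pPCA axes.
#'
#' @param tree_path Newick file of the rooted phylogeny.
#' @param traits_path CSV of raw seed traits (`species` + the columns of
#'   `raw` trait names; see [build_design_matrix()]).
#' @param behaviors_path CSV with `species`, behavior columns, and
#'   optionally an integer `interference` column.
#' @param out_dir Output directory (created if absent).
#' @param B Permutations for every permutation test (>= 99).
#' @param alpha Significance level for eigenvector selection stopping.
#' @param seed Single run seed; every stage derives its own substream from
#'   it by stable hashing of the stage name.
#' @param k_global,k_local Retained pPCA axes.
#' @param tannin_floor Detection floor applied to zero tannin values before
#'   the log transform (default 0.35% TAE).
#' @param residual_weights,squared Passed to [pvr_partition()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(tree_path, traits_path, behaviors_path, out_dir,
                            B = 1000L, alpha = 0.05, seed = 1L,
                            k_global = 2L, k_local = 1L,
                            tannin_floor = 0.35,
                            residual_weights = "inv_patristic",
                            squared = TRUE) {
  for (p in c(tree_path, traits_path, behaviors_path))
    abort_if(!file.exists(p), sprintf("Input file not found: '%s'.", p))
  abort_if(B < 99L, "B must be >= 99.")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1).")
  structure(list(tree_path = tree_path, traits_path = traits_path,
                 behaviors_path = behaviors_path, out_dir = out_dir,
                 B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 k_global = as.integer(k_global),
                 k_local = as.integer(k_local),
                 tannin_floor = tannin_floor,
                 residual_weights = residual_weights,
                 squared = squared),
            class = "pipeline_config")
}

#' Run the full comparative analysis pipeline
#'
#' Orchestrates every stage on file inputs: trait preparation (tannin
#' floor, transforms, standardization), per-trait phylogenetic signal
#' table, Spearman screen of behaviors against traits, PVR variance
#' partitioning, pPCA with retained-axis signal tests, permutation
#' regressions of behaviors on the retained axes, and (when an
#' `interference` column is present) the post-hoc Poisson regression.
#' Results are returned and also written to `out_dir` as CSV/JSON with a
#' manifest; a rerun with the same config is byte-identical except for the
#' manifest timestamp.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list of tibbles/objects, invisibly:
#'   `signal_table`, `spearman`, `partition`, `ppca`, `score_signal`,
#'   `regressions`, `poisson` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "pipeline_config"),
           "`config` must come from pipeline_config().")
  tree <- read_newick(config$tree_path)
  traits <- tibble::as_tibble(utils::read.csv(config$traits_path,
                                              check.names = FALSE))
  behaviors <- tibble::as_tibble(utils::read.csv(config$behaviors_path,
                                                 check.names = FALSE))
  check_species_match(tree$tip.label, traits[["species"]], "trait table")
  check_species_match(tree$tip.label, behaviors[["species"]], "behavior table")
  ord <- tree$tip.label  # canonical species order everywhere
  traits <- traits[match(ord, traits$species), ]
  behaviors <- behaviors[match(ord, behaviors$species), ]

  # -- trait prep ------------------------------------------------------
  floored <- suppressMessages(
    apply_floors(traits, "tannin_pct_tae", config$tannin_floor))
  design <- build_design_matrix(floored)
  std <- standardize(design)

  # -- per-trait signal + correlation screen ---------------------------
  signal_table <- trait_signal(design, tree, B = config$B,
                               seed = stage_seed(config$seed, "signal"))
  beh_cols <- setdiff(names(behaviors),
                      c("species", "interference"))
  screen_df <- dplyr::bind_cols(behaviors[beh_cols],
                                design[setdiff(names(design), "species")])
  spearman <- spearman_matrix(screen_df)

  # -- PVR variance partitioning ---------------------------------------
  partition <- pvr_partition(behaviors[c("species", beh_cols)], design, tree,
                             residual_weights = config$residual_weights,
                             alpha = config$alpha, B = config$B,
                             seed = stage_seed(config$seed, "pvr"),
                             squared = config$squared)

  # -- pPCA + axis signal ----------------------------------------------
  w <- normalize_weights(abouheif_proximity(tree),
                         "symmetrized_row_normalized")
  fit <- label_axes(fit_ppca(std, w),
                    k_global = config$k_global, k_local = config$k_local)
  axis_signal <- score_signal(fit, tree, B = config$B,
                              seed = stage_seed(config$seed, "ppca"))

  # -- regressions ------------------------------------------------------
  regressions <- behavior_regressions(behaviors[c("species", beh_cols)], fit,
                                      B = config$B,
                                      seed = stage_seed(config$seed, "regress"))
  poisson_fit <- NULL
  if ("interference" %in% names(behaviors)) {
    poisson_fit <- fit_poisson(behaviors$interference,
                               fit$scores[, fit$retained, drop = FALSE])
  }

  result <- structure(list(signal_table = signal_table,
                           spearman = spearman,
                           partition = partition,
                           ppca = fit,
                           score_signal = axis_signal,
                           regressions = regressions,
                           poisson = poisson_fit,
                           design = design,
                           config = config),
                      class = "pipeline_result")
  write_pipeline_outputs(result)
  invisible(result)
}

check_species_match <- function(tips, species, what) {
  abort_if(is.null(species), sprintf("The %s has no 'species' column.", what))
  only_tree <- setdiff(tips, species)
  only_tab <- setdiff(species, tips)
  abort_if(length(only_tree) > 0 || length(only_tab) > 0,
           sprintf("Species mismatch with %s. Only in tree: [%s]; only in table: [%s].",
                   what, paste(only_tree, collapse = ", "),
                   paste(only_tab, collapse = ", ")))
  invisible(TRUE)
}

write_pipeline_outputs <- function(result) {
  out <- result$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  wcsv(result$signal_table, "signal_table.csv")
  # correlation screen in the compact matrix layout: rho above the
  # diagonal, p-values below
  rho <- result$spearman$rho
  comb <- rho
  comb[lower.tri(comb)] <- result$spearman$p[lower.tri(comb)]
  diag(comb) <- 1
  utils::write.csv(data.frame(variable = rownames(comb),
                              round(comb, 4), check.names = FALSE),
                   file.path(out, "spearman_matrix.csv"), row.names = FALSE)
  wcsv(result$partition, "partition_table.csv")
  L <- result$ppca$loadings
  wcsv(data.frame(trait = rownames(L), L, check.names = FALSE),
       "ppca_loadings.csv")
  S <- result$ppca$scores
  wcsv(data.frame(species = rownames(S), S, check.names = FALSE),
       "ppca_scores.csv")
  jsonlite::write_json(
    list(eigenvalues = as.list(result$ppca$eigenvalues),
         variance_share = as.list(result$ppca$variance_share),
         retained = result$ppca$axis_labels[result$ppca$retained],
         retained_share = result$ppca$retained_share),
    file.path(out, "ppca_eigenvalues.json"), auto_unbox = TRUE, digits = NA)
  wcsv(result$score_signal, "score_signal.csv")
  wcsv(result$regressions, "regression_table.csv")
  if (!is.null(result$poisson))
    wcsv(data.frame(term = names(result$poisson$coefficients),
                    estimate = result$poisson$coefficients,
                    se = result$poisson$se,
                    z = result$poisson$z,
                    p.value = result$poisson$p.value),
         "interference_poisson.csv")
  cfg <- result$config
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "seedforage",
    version = as.character(utils::packageVersion("seedforage")),
    seed = cfg$seed, B = cfg$B,
    config = unclass(cfg),
    config_hash = sprintf("%08x",
                          sum(utf8ToInt(cfg_json) *
                                (seq_len(nchar(cfg_json)) %% 251 + 1)) %%
                            .Machine$integer.max),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d species, %d behaviors, B = %d, seed = %d\n",
              x$ppca$n, nrow(x$partition), x$config$B, x$config$seed))
  cat("  variance partition:\n")
  print(as.data.frame(x$partition), digits = 3)
  invisible(x)
}
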