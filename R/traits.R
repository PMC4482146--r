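#' Column names of the analysis-ready seed-trait design matrix
#'
#' Eleven traits, in the fixed analysis order: percent lipids, percent
#' carbohydrates, percent proteins, caloric concentration (cal/g), dormancy
#' period (cold stratification days), log hardness (kg), log shell thickness
#' (um), log of the hardness x thickness interaction, log kernel mass (g),
#' log shell mass (g), and log tannin concentration (% TAE). Moisture is
#' measured but excluded. Logs are natural logs.
#'
#' @format Character vector of length 11.
#' @export
design_trait_names <- c(
  "lipid_pct", "carb_pct", "protein_pct", "energy_cal_g", "dormancy_days",
  "log_hardness", "log_thickness", "log_hardness_x_thickness",
  "log_kernel_mass", "log_shell_mass", "log_tannin")

# Raw input columns the design matrix is built from.
raw_trait_names <- c(
  "lipid_pct", "carb_pct", "protein_pct", "energy_cal_g", "dormancy_days",
  "hardness_kg", "thickness_um", "kernel_mass_g", "shell_mass_g",
  "tannin_pct_tae")

#' Replace zeros in a trait column by a small positive floor
#'
#' Detection floor for assay columns that must be log-transformed: zeros are
#' replaced by `floor` (for the tannin assay the study convention is
#' 0.35% TAE). Negative values are an error; the number of replacements is
#' reported as a message.
#'
#' @param traits Data frame of traits.
#' @param column Column name to floor.
#' @param floor Positive replacement value for zeros.
#' @return The trait table with zeros in `column` replaced, as a tibble.
#' @export
#' @examples
#' apply_floors(tibble::tibble(tannin_pct_tae = c(0, 0.5, 0)),
#'              "tannin_pct_tae", 0.35)
apply_floors <- function(traits, column, floor = 0.35) {
  abort_if(!column %in% names(traits),
           sprintf("Column '%s' not found.", column))
  abort_if(!is.numeric(floor) || floor <= 0, "`floor` must be > 0.")
  v <- traits[[column]]
  abort_if(any(v < 0, na.rm = TRUE),
           sprintf("Column '%s' contains negative values; floors apply to zeros only.",
                   column))
  nz <- sum(v == 0, na.rm = TRUE)
  if (nz > 0) {
    message(sprintf("apply_floors: %d zero value(s) in '%s' set to %g.",
                    nz, column, floor))
    v[v == 0] <- floor
  }
  traits[[column]] <- v
  tibble::as_tibble(traits)
}

#' Build the 11-column analysis design matrix from raw seed traits
#'
#' Applies the fixed transform scheme: percentages, caloric concentration and
#' dormancy enter untransformed; hardness, shell thickness, their product,
#' kernel mass, shell mass and tannin enter as natural logs. Moisture (and
#' any other extra column) is dropped. Floors (e.g. [apply_floors()] on
#' tannin) must already have been applied: a non-positive value in any log
#' column is an error naming the offending cell.
#'
#' @param traits Data frame with a `species` column and the raw trait columns
#'   `lipid_pct`, `carb_pct`, `protein_pct`, `energy_cal_g`, `dormancy_days`,
#'   `hardness_kg`, `thickness_um`, `kernel_mass_g`, `shell_mass_g`,
#'   `tannin_pct_tae`.
#' @return A tibble: `species` plus the 11 columns of [design_trait_names],
#'   in that order.
#' @export
build_design_matrix <- function(traits) {
  missing <- setdiff(c("species", raw_trait_names), names(traits))
  abort_if(length(missing) > 0,
           sprintf("Missing trait columns: %s.", paste(missing, collapse = ", ")))
  log_src <- c("hardness_kg", "thickness_um", "kernel_mass_g",
               "shell_mass_g", "tannin_pct_tae")
  for (cn in log_src) {
    bad <- which(traits[[cn]] <= 0)
    abort_if(length(bad) > 0,
             sprintf("Non-positive value in log column '%s' for species %s.",
                     cn, paste(traits$species[bad], collapse = ", ")))
  }
  pct <- c("lipid_pct", "carb_pct", "protein_pct")
  for (cn in pct)
    abort_if(any(traits[[cn]] < 0 | traits[[cn]] > 100),
             sprintf("Percentage column '%s' outside [0, 100].", cn))
  tibble::tibble(
    species = traits$species,
    lipid_pct = traits$lipid_pct,
    carb_pct = traits$carb_pct,
    protein_pct = traits$protein_pct,
    energy_cal_g = traits$energy_cal_g,
    dormancy_days = traits$dormancy_days,
    log_hardness = log(traits$hardness_kg),
    log_thickness = log(traits$thickness_um),
    log_hardness_x_thickness = log(traits$hardness_kg * traits$thickness_um),
    log_kernel_mass = log(traits$kernel_mass_g),
    log_shell_mass = log(traits$shell_mass_g),
    log_tannin = log(traits$tannin_pct_tae))
}

#' Pairwise Spearman rank-correlation screen
#'
#' Spearman's rho for every pair of numeric columns, with two-sided p-values
#' from the large-sample t approximation on midranked data,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df. Constant columns
#' yield `NA` correlations and are flagged with a warning rather than
#' silently reported as zero.
#'
#' @param data Data frame (a `species` column is ignored) or numeric matrix;
#'   at least 4 rows.
#' @return A `spearman_screen` object holding the `rho` and `p` matrices;
#'   `tidy()` gives the long pair-by-pair tibble.
#' @export
spearman_matrix <- function(data) {
  m <- as_species_matrix(data)
  abort_if(nrow(m) < 4L, "Need at least 4 rows for the correlation screen.")
  const <- colnames(m)[apply(m, 2, function(v) stats::var(v) == 0)]
  if (length(const) > 0)
    warning(sprintf("Constant column(s), correlations undefined: %s.",
                    paste(const, collapse = ", ")), call. = FALSE)
  p <- ncol(m)
  n <- nrow(m)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (length(const) > 0) rho[const, ] <- rho[, const] <- NA_real_
  diag(rho) <- ifelse(colnames(m) %in% const, NA_real_, 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(pval) <- NA_real_
  structure(list(rho = rho, p = pval, n = n, constant = const),
            class = "spearman_screen")
}

#' @export
print.spearman_screen <- function(x, ...) {
  cat(sprintf("<spearman_screen> %d variables, n = %d\n", ncol(x$rho), x$n))
  print(round(x$rho, 3))
  invisible(x)
}

#' @describeIn spearman_matrix Long tibble of unique pairs (rho, p).
#' @param x A `spearman_screen` object.
#' @param ... Unused.
#' @method tidy spearman_screen
#' @export
tidy.spearman_screen <- function(x, ...) {
  nm <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(var1 = nm[idx[, 1]], var2 = nm[idx[, 2]],
                 rho = x$rho[idx], p.value = x$p[idx])
}

#' Standardize columns to mean 0, variance 1 (divisor n)
#'
#' Uses the population (divisor-`n`) variance so that downstream pPCA
#' eigenvalues decompose exactly the trait variance entering the score
#' identities. Constant columns are an error.
#'
#' @param data Data frame (optionally with a `species` column, preserved) or
#'   numeric matrix.
#' @return Same shape as the input (tibble in, tibble out), standardized.
#' @export
standardize <- function(data) {
  is_df <- is.data.frame(data)
  m <- as_species_matrix(data)
  const <- colnames(m)[apply(m, 2, function(v) stats::var(v) == 0)]
  abort_if(length(const) > 0,
           sprintf("Cannot standardize constant column(s): %s.",
                   paste(const, collapse = ", ")))
  n <- nrow(m)
  ctr <- sweep(m, 2, colMeans(m))
  sds <- sqrt(colSums(ctr^2) / n)
  out <- sweep(ctr, 2, sds, "/")
  if (is_df) {
    res <- tibble::as_tibble(as.data.frame(out))
    if ("species" %in% names(data))
      res <- dplyr::bind_cols(tibble::tibble(species = data$species), res)
    res
  } else out
}
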