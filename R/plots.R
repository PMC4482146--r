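#' Plot a permutation null distribution
#'
#' Histogram of the permutation null with the observed statistic marked.
#'
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("%s under tip permutation", object$method),
      y = "count",
      title = sprintf("observed = %.3f, p = %.4g (%s tail, B = %d)",
                      object$statistic, object$p_value, object$tail,
                      object$B)) +
    ggplot2::theme_minimal()
}

#' Biplot of a phylogenetic PCA
#'
#' Species scores on two retained axes with loading arrows for the dominant
#' traits (|loading| above the per-axis 75th percentile).
#'
#' @param object A `ppca` fit (after [label_axes()] if you want the
#'   retained set; otherwise the first two axes are shown).
#' @param axes Length-2 integer vector of axis indices to plot.
#' @param arrow_scale Multiplier applied to the loading arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppca
#' @export
autoplot.ppca <- function(object, axes = NULL,
                          arrow_scale = NULL, ...) {
  axes <- axes %||% (object$retained %||% c(1L, 2L))[1:2]
  ax <- object$axis_labels[axes]
  sc <- tibble::tibble(species = rownames(object$scores),
                       x = object$scores[, axes[1]],
                       y = object$scores[, axes[2]])
  ld <- tidy.ppca(object, "loadings")
  dom <- unique(ld$trait[ld$dominant & ld$axis %in% ax])
  arrow_scale <- arrow_scale %||%
    (0.7 * max(abs(c(sc$x, sc$y))) /
       max(abs(object$loadings[, axes])))
  ar <- tibble::tibble(trait = rownames(object$loadings),
                       x = object$loadings[, axes[1]] * arrow_scale,
                       y = object$loadings[, axes[2]] * arrow_scale)
  ar <- ar[ar$trait %in% dom, ]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$species),
                       size = 2.6, vjust = -0.8, colour = "grey40") +
    ggplot2::geom_segment(data = ar,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          arrow = ggplot2::arrow(length = grid::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = ar,
                       ggplot2::aes(label = .data$trait),
                       colour = "firebrick", size = 3, vjust = 1.4) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], 100 * object$variance_share[axes[1]]),
      y = sprintf("%s (%.1f%%)", ax[2], 100 * object$variance_share[axes[2]])) +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of variance partition fractions
#'
#' One bar per response, split into the four fractions (traits alone,
#' shared, phylogeny alone, unexplained).
#'
#' @param object A `variance_partition` tibble from [partition_variance()]
#'   or [pvr_partition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variance_partition
#' @export
autoplot.variance_partition <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("traits_alone", "shared",
                                       "phylo_alone", "unexplained"),
                              names_to = "fraction", values_to = "value")
  long$fraction <- factor(long$fraction,
                          levels = c("unexplained", "phylo_alone",
                                     "shared", "traits_alone"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$response, y = .data$value,
                                     fill = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "PuOr") +
    ggplot2::labs(x = NULL, y = "proportion of variance") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
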