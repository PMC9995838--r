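#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination plot
#'
#' @param object a [pcoa_ordination()] result.
#' @param colour optional vector (length = samples) mapped to point colour,
#'   e.g. a group label.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, colour = NULL, ...) {
  df <- object$points
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PCo2 (%.1f%%)",
                  100 * ifelse(length(object$var_explained) > 1,
                               object$var_explained[2], 0))) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
}

#' Variance-explained curve plot
#'
#' Mean held-out variance explained (clipped at 0 for display) against the
#' selection threshold, with +/- 1 sd ribbon.
#'
#' @param object a [variance_explained_cv()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ve_curve
#' @export
autoplot.ve_curve <- function(object, ...) {
  df <- as.data.frame(object)
  df$shown <- pmax(df$mean_ve, 0)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$threshold), .data$shown)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$shown - .data$sd_ve, 0),
      ymax = .data$shown + .data$sd_ve), width = 0.2) +
    ggplot2::labs(x = "significance threshold",
                  y = "held-out variance explained") +
    ggplot2::theme_minimal()
}

#' Signed-Z plot of a two-part scan
#'
#' Features ordered by signed Z of the winning component; positive bars are
#' positive microbe-phenotype associations.
#'
#' @param object a [two_part_scan()] result.
#' @param q_cutoff features with `q_bh` below this are shown (default 0.05;
#'   use 1 for all).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot two_part_scan
#' @export
autoplot.two_part_scan <- function(object, q_cutoff = 0.05, ...) {
  df <- dplyr::filter(as.data.frame(object), .data$q_bh <= q_cutoff)
  if (nrow(df) == 0) df <- as.data.frame(object)
  df <- dplyr::arrange(df, .data$z_signed)
  df$feature_id <- factor(df$feature_id, levels = df$feature_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$z_signed, .data$feature_id,
                                   fill = .data$z_signed > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "signed Z (winning component)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Alpha-diversity comparison plot
#'
#' Boxplots of one or more indices split by a grouping column of the
#' [alpha_diversity()] tibble.
#'
#' @param profile an [alpha_diversity()] tibble.
#' @param group name of the grouping column (default `"group"`).
#' @param indices index columns to show.
#' @return a ggplot.
#' @export
plot_alpha_diversity <- function(profile, group = "group",
                                 indices = c("shannon", "simpson", "chao1", "ace")) {
  indices <- intersect(indices, names(profile))
  df <- tidyr::pivot_longer(profile, dplyr::all_of(indices),
                            names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data[[group]], .data$value,
                                   fill = .data[[group]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
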