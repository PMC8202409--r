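# ggplot2 figures for the main result types.

#' Stacked-bar figure of domain composition per sample
#'
#' @param props Output of [domain_proportions()] (facetted by dataset when
#'   the column is present).
#' @return A ggplot object.
#' @export
plot_domain_proportions <- function(props) {
  p <- ggplot2::ggplot(props, ggplot2::aes(
    x = .data$sample_id, y = .data$proportion, fill = .data$domain)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x,
                                name = "proportion of microbial reads (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample")
  if ("dataset" %in% names(props)) {
    p <- p + ggplot2::facet_grid(~dataset, scales = "free_x",
                                 space = "free_x")
  }
  p
}

#' Stacked-bar figure of top taxa relative abundances
#'
#' @param collapsed Output of [top_n_collapse()] (any taxonomic level).
#' @param metadata Optional metadata tibble for dataset facets.
#' @return A ggplot object.
#' @export
plot_top_taxa <- function(collapsed, metadata = NULL) {
  level <- names(collapsed)[1]
  long <- tidyr::pivot_longer(collapsed, -1, names_to = "sample_id",
                              values_to = "abundance")
  if (!is.null(metadata)) {
    long <- dplyr::left_join(
      long, dplyr::select(metadata, "sample_id", "dataset"), by = "sample_id")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample_id, y = .data$abundance, fill = .data[[level]])) +
    ggplot2::geom_col(width = 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample", y = "relative abundance", fill = level)
  if ("dataset" %in% names(long)) {
    p <- p + ggplot2::facet_grid(~dataset, scales = "free_x",
                                 space = "free_x")
  }
  p
}

#' @method autoplot accumulation_curve
#' @export
autoplot.accumulation_curve <- function(object, fit = NULL, ...) {
  s <- object$summary
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$n_samples, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "number of samples",
                  y = "cumulative number of genera")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fit$fitted, ggplot2::aes(x = .data$n, y = .data$fitted),
      colour = "blue") +
      ggplot2::labs(subtitle = sprintf(
        "P(n) = %.1f n^%.3f   R² = %.4f",
        fit$kappa, fit$gamma, fit$r_squared))
  }
  p
}

#' @method autoplot heaps_fit
#' @export
autoplot.heaps_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "grey50", size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "blue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "number of samples",
                  y = "cumulative number of genera",
                  subtitle = sprintf("P(n) = %.1f n^%.3f   R² = %.4f",
                                     object$kappa, object$gamma,
                                     object$r_squared))
}

#' @method autoplot permanova_test
#' @export
autoplot.permanova_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(f = object$f_perm),
                  ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$pseudo_f, colour = "red") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "permutation pseudo-F", y = "count",
                  subtitle = sprintf("observed F = %.3f, p = %.4g",
                                     object$pseudo_f, object$p_value))
}

#' @method autoplot divergence_result
#' @export
autoplot.divergence_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group,
                                       y = .data$divergence)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "divergence to group median profile")
}

#' Diverging bar chart of separating coefficients
#'
#' Blue bars mark taxa more abundant in the reference group, red bars taxa
#' more abundant in the other group.
#'
#' @param coefs Output of [separating_coefficients()] (or
#'   [top_coefficients()]).
#' @return A ggplot object.
#' @export
plot_coefficients <- function(coefs) {
  ref <- attr(coefs, "reference")
  other <- attr(coefs, "other")
  dat <- dplyr::mutate(coefs, direction = ifelse(
    .data$coefficient >= 0,
    paste0("higher in ", ref), paste0("higher in ", other)))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$genus, abs(.data$coefficient)),
    y = .data$coefficient, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = stats::setNames(
      c("#2166ac", "#b2182b"),
      c(paste0("higher in ", ref), paste0("higher in ", other)))) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "difference of group mean relative abundance")
}
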