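# ggplot2 views of the result objects.

#' Plot a mutational landscape as a 2-D height map
#'
#' Each gene or domain occupies one grid cell; fill encodes the
#' length-normalized mutation frequency and significant peaks are outlined.
#'
#' @param object A `landscape` object.
#' @param grid_seed Seed for the [layout_landscape()] shuffle.
#' @param cap Optional height cap (see [layout_landscape()]).
#' @param label_top Label the `label_top` highest peaks (default 5; 0 for
#'   none).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot landscape
#' @export
autoplot.landscape <- function(object, grid_seed = 1, cap = NULL,
                               label_top = 5, ...) {
  lay <- layout_landscape(object, grid_seed = grid_seed, cap = cap)
  sig <- significant_regions(object)
  lay$significant <- lay$region_id %in% sig
  p <- ggplot2::ggplot(lay, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$height,
                                    colour = .data$significant),
                       linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(name = "k / L") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste(object$cohort_name, object$kind,
                                "mutational landscape"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    top <- utils::head(lay[order(-lay$height), ], label_top)
    p <- p + ggplot2::geom_text(data = top,
                                ggplot2::aes(label = .data$region_id),
                                size = 2.5, vjust = -0.4)
  }
  p
}

#' Plot an lfdr fit: score histogram, fitted marginal, and scaled null
#'
#' @param object An `lfdr_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfdr_fit
#' @export
autoplot.lfdr_fit <- function(object, ...) {
  bins <- object$bins
  grid <- tibble::tibble(z = seq(min(object$z), max(object$z),
                                 length.out = 400))
  grid$f0 <- object$n * object$bin_width * object$pi0 *
    dnorm(grid$z, object$null_mean, object$null_sd)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$center)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70",
                      width = object$bin_width) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$z, y = .data$f0),
                       colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "z", y = "count",
                  title = sprintf("lfdr fit (%s null, pi0 = %.3f)",
                                  object$null_type, object$pi0)) +
    ggplot2::theme_minimal()
}

#' Plot the Venn counts of a landscape comparison
#'
#' @param object A `landscape_comparison` object.
#' @param ... Unused.
#' @return A ggplot object (bar chart of the three Venn compartments).
#' @method autoplot landscape_comparison
#' @export
autoplot.landscape_comparison <- function(object, ...) {
  d <- tidy(object)
  d$compartment <- factor(d$compartment,
                          levels = c("exclusive_a", "shared", "exclusive_b"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(title = sprintf("Shared %s peaks: %s vs %s", object$kind,
                                  object$name_a, object$name_b),
                  x = NULL, y = "significant regions") +
    ggplot2::theme_minimal()
}
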