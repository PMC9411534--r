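# ggplot2 views of the main result types.

#' Plot a Monte-Carlo null distribution
#'
#' Histogram of the sampled random-square \%FL values with the
#' significance threshold marked.
#'
#' @param object A `flip_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flip_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent_loss)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "%FL per random square (fraction)", y = "squares",
      title = sprintf("Null %%FL, channel %s", object$channel),
      subtitle = sprintf("threshold %.3f at %.0f%% confidence",
                         object$threshold, 100 * object$confidence)) +
    ggplot2::theme_minimal()
}

#' Plot compartment concentration traces
#'
#' One line per node and species over acquisition time.
#'
#' @param object A `concentration_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concentration_series <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                   y = .data$concentration,
                                   colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a compartment map
#'
#' Tile view of the pairwise relations, annotated with the merged block
#' of each zone.
#'
#' @param object A `compartment_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.compartment_map <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, zone_a = "zone_b", zone_b = "zone_a",
                  block_a = "block_b", block_b = "block_a")
  )
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$zone_a, y = .data$zone_b,
                                    fill = .data$relation)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      connected = "#2c7fb8", barrier = "#d95f0e", dynamic = "#756bb1",
      untested = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise compartment relations") +
    ggplot2::theme_minimal()
}

#' Plot clone statistics
#'
#' Clone-size distribution coloured by the number of colours per clone.
#'
#' @param object A `cg_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_stats <- function(object, ...) {
  df <- object$clones
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_nuclei,
                                   fill = factor(.data$n_colours))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "nuclei per clone", y = "clones",
                  fill = "colours",
                  title = sprintf("Clones at induction %g h ALH",
                                  object$induction$time)) +
    ggplot2::theme_minimal()
}
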