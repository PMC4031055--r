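# ggplot2 views of the result objects.

#' @export
#' @method autoplot hm_rate_map
autoplot.hm_rate_map <- function(object, ...) {
  bins <- object$bins
  df <- tidyr::expand_grid(y = seq_len(bins), x = seq_len(bins))
  df$rate <- as.vector(object$rate)   # column-major: x fast
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hz") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot hm_pv
autoplot.hm_pv <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "PV r",
                  subtitle = sprintf("mean %.2f", object$mean)) +
    ggplot2::theme_minimal()
}

#' Morphing metric curves, by region and recurrence setting
#'
#' @param x An `hm_morph` experiment or a [morph_metrics()] tibble.
#' @param metric Which metric to draw.
#' @return A ggplot.
#' @export
plot_morph_curves <- function(x, metric = "pv") {
  m <- if (inherits(x, "hm_morph")) morph_metrics(x) else x
  m <- dplyr::filter(m, .data$metric == !!metric, !is.na(.data$cond))
  m$setting <- paste0(m$region, ifelse(m$recurrence, " (rec on)", " (rec off)"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$cond, y = .data$value,
                                  colour = .data$setting)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = "Morph condition (1 = square, 7 = circle)",
                  y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot hm_learning_curve
autoplot.hm_learning_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("pv_11p", "pv_12"),
                            names_to = "comparison", values_to = "pv")
  df$comparison <- ifelse(df$comparison == "pv_11p", "1 vs 1'", "1 vs 2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l_rate, y = .data$pv,
                                   colour = .data$comparison)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Learning rate", y = "Mean PV correlation",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a session spike table to CSV
#'
#' @param session An `hm_session` simulated with `record_spikes = TRUE`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(session, path) {
  if (is.null(session$spikes)) {
    abort("Session has no spike table; simulate with record_spikes = TRUE.",
          class = "hippomorph_state_error")
  }
  readr::write_csv(session$spikes, path)
  invisible(path)
}
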