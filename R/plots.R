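#' Plot a GAW trace
#'
#' Total area versus time, with the half waveforms overlaid when present.
#'
#' @param object A `gaw_record`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gaw_record
#' @export
autoplot.gaw_record <- function(object, ...) {
  d <- as_tibble(object)
  long <- tidyr::pivot_longer(
    d, dplyr::any_of(c("total_area", "left_area", "right_area")),
    names_to = "trace", values_to = "area"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$area,
                                     colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "glottal area (px)",
      title = sprintf("GAW @ %g fps", gaw_fs(object)), colour = NULL
    )
}

#' Plot a stability report
#'
#' One row per parameter, one tile per frame rate; tiles are filled by the
#' stable interval they belong to (alternating shades; gray bridges hatched
#' darker) and each row is annotated with its stability group.
#'
#' @param object A `gaw_stability_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gaw_stability_report
#' @export
autoplot.gaw_stability_report <- function(object, ...) {
  rows <- purrr::map_dfr(object$parameters, function(e) {
    iv <- e$intervals
    iv$interval_id <- seq_len(nrow(iv))
    purrr::pmap_dfr(iv, function(start_rate, end_rate, n_rates, gray,
                                 mean_min, mean_max, interval_id) {
      tibble(
        fps = object$rates[object$rates >= start_rate &
                             object$rates <= end_rate],
        parameter = e$parameter, interval_id = interval_id, gray = gray,
        group = e$group
      )
    })
  })
  rows$parameter <- factor(rows$parameter, levels = rev(unique(rows$parameter)))
  rows$fill <- ifelse(rows$gray, "bridge",
                      ifelse(rows$interval_id %% 2 == 1, "a", "b"))
  labs <- rows |>
    dplyr::distinct(.data$parameter, .data$group)
  ggplot2::ggplot(rows, ggplot2::aes(.data$fps / 1000, .data$parameter,
                                     fill = .data$fill)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.3,
                       show.legend = FALSE) +
    ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = max(rows$fps) / 1000 + 1, y = .data$parameter,
                   label = paste0("G", .data$group)),
      inherit.aes = FALSE, size = 3
    ) +
    ggplot2::scale_fill_manual(values = c(a = "#4e79a7", b = "#a0cbe8",
                                          bridge = "#6b6b6b")) +
    ggplot2::labs(x = "recording rate (kfps)", y = NULL,
                  title = "Frame-rate stability: merged stable intervals")
}

#' Mean and spread of each parameter across the rate sweep
#'
#' Per-rate mean and standard deviation of every parameter in a long sweep
#' table, faceted by parameter with free y scales.
#'
#' @param table Long sweep table from [sweep_parameters()].
#' @param parameters Optional subset of parameter names.
#' @return A ggplot.
#' @export
plot_parameter_sweep <- function(table, parameters = NULL) {
  d <- table
  if (!is.null(parameters)) d <- d[d$parameter %in% parameters, ]
  s <- d |>
    dplyr::group_by(.data$parameter, .data$fps) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(.data$fps / 1000, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "recording rate (kfps)", y = "parameter mean ± sd")
}
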