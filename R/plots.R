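#' Plot a condition-by-phase foci summary
#'
#' Bar chart of mean foci per cell with SEM error bars, faceted by phase —
#' the standard presentation of stratified foci counts.
#'
#' @param object A `foci_summary` tibble from [summarize_foci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.foci_summary <- function(object, ...) {
  xvar <- if ("line_id" %in% names(object)) "line_id" else names(object)[1]
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xvar]], y = .data$mean_foci)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_foci - .data$sem,
                                        ymax = .data$mean_foci + .data$sem),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "foci per cell (mean ± SEM)") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(object))
    p <- p + ggplot2::facet_wrap(~phase)
  p
}

#' Plot repair kinetics after irradiation
#'
#' Mean foci per cell at 0, 0.5, 2 and 6 h post-irradiation, one line per
#' (line, marker, phase) series; a steeper decline from the 0.5 h peak
#' indicates faster DSB repair.
#'
#' @param tc A tibble from [repair_time_course()].
#' @return A ggplot object.
#' @export
plot_time_course <- function(tc) {
  long <- tc %>%
    select("line_id", "marker", "phase", "mean_0h", "mean_0.5h",
           "mean_2h", "mean_6h") %>%
    tidyr::pivot_longer(dplyr::starts_with("mean_"), names_to = "time_h",
                        values_to = "mean_foci") %>%
    mutate(time_h = as.numeric(sub("h$", "", sub("^mean_", "", .data$time_h))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$mean_foci,
                                     colour = .data$line_id,
                                     linetype = .data$phase)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = "hours after irradiation", y = "foci per cell") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of a channel
#'
#' Quick-look rendering of a stack channel as a 2D max projection, with
#' optional nucleus outlines from a segmentation.
#'
#' @param stack A `channel_stack`.
#' @param channel `"nuclear"`, `"foci"` or `"edu"`.
#' @param nuclei Optional `labeled_nuclei` to overlay centroids.
#' @return A ggplot object.
#' @export
plot_projection <- function(stack, channel = c("nuclear", "foci", "edu"),
                            nuclei = NULL) {
  channel <- match.arg(channel)
  v <- stack[[channel]]
  proj <- apply(v, c(2, 3), max)
  df <- tibble(y = rep(seq_len(nrow(proj)) - 1, ncol(proj)),
               x = rep(seq_len(ncol(proj)) - 1, each = nrow(proj)),
               intensity = as.vector(proj))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(channel, "channel, max projection")) +
    ggplot2::theme_void()
  if (!is.null(nuclei) && nrow(nuclei$nuclei) > 0)
    p <- p + ggplot2::geom_point(
      data = nuclei$nuclei,
      ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
      inherit.aes = FALSE, colour = "yellow", shape = 3)
  p
}
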