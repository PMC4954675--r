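# ggplot2 views of tracks, segments and fits.

role_palette <- c(clothing_noise = "#b2182b", participant = "#2166ac",
                  other = "#66bd63", silence = "grey80")

#' Plot a diarized segment timeline
#'
#' @param segments Segment tibble; a `conversation_id` column facets rows.
#' @return A ggplot object.
#' @export
plot_segments <- function(segments) {
  stopifnot_cols(segments, c("start_s", "end_s", "role"), "segments")
  if (!"conversation_id" %in% names(segments)) {
    segments$conversation_id <- "conversation"
  }
  ggplot2::ggplot(segments,
                  ggplot2::aes(xmin = .data$start_s / 60,
                               xmax = .data$end_s / 60,
                               ymin = 0, ymax = 1, fill = .data$role)) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~conversation_id, ncol = 1) +
    ggplot2::scale_fill_manual(values = role_palette) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = "role") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @method autoplot diarization
#' @export
autoplot.diarization <- function(object, ...) {
  plot_segments(object$segments)
}

#' Plot a frame track
#'
#' Volume trace over time, coloured by ground-truth role when present, with
#' the pitch track in a second panel when available.
#'
#' @param track Frame-track tibble.
#' @return A ggplot object.
#' @export
plot_frame_track <- function(track) {
  stopifnot_cols(track, c("t_s", "volume_db"), "frame track")
  long <- tidyr::pivot_longer(
    track[, intersect(c("t_s", "volume_db", "pitch_hz", "role"),
                      names(track))],
    cols = dplyr::any_of(c("volume_db", "pitch_hz")),
    names_to = "measure", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value))
  p <- if ("role" %in% names(long)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$role), size = 0.3) +
      ggplot2::scale_colour_manual(values = role_palette)
  } else {
    p + ggplot2::geom_point(size = 0.3)
  }
  p + ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot enjoyment against percentage of speaking time
#'
#' One point per conversation with a pooled linear trend; a quick visual of
#' the headline association between talking less and enjoying more.
#'
#' @param data Table with `pct_speaking` and `rating`.
#' @return A ggplot object.
#' @export
plot_enjoyment <- function(data) {
  stopifnot_cols(data, c("pct_speaking", "rating"), "feature table")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$pct_speaking,
                                     y = .data$rating)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "% of time speaking", y = "enjoyment (1-7)") +
    ggplot2::theme_minimal()
}
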