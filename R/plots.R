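#' Plot state timelines
#'
#' Raster of every grab and peg-contact channel over frames; useful to
#' compare raw and debounced states.
#'
#' @param object A `peg_timelines`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peg_timelines
#' @export
autoplot.peg_timelines <- function(object, ...) {
  d <- tidy(object)
  d$channel <- factor(d$channel, levels = rev(unique(d$channel)))
  ggplot2::ggplot(d[d$state, ],
                  ggplot2::aes(x = .data$frame, y = .data$channel,
                               fill = .data$channel_group)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(grab = "#D55E00",
                                          contact = "#0072B2"),
                               guide = "none") +
    ggplot2::labs(x = "frame", y = NULL,
                  title = "State timelines (true frames)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluated exercise
#'
#' Session holder intervals per ring with pitfall markers.
#'
#' @param object A `peg_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peg_result
#' @export
autoplot.peg_result <- function(object, ...) {
  ss <- object$sessions
  if (nrow(ss) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No sessions detected") +
             ggplot2::theme_minimal())
  }
  hold <- purrr::map_dfr(seq_len(nrow(ss)), function(j) {
    dplyr::mutate(ss$holders[[j]], ring_id = ss$ring_id[j])
  })
  p <- ggplot2::ggplot(hold) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$ring_id,
                   yend = .data$ring_id, colour = .data$instrument),
      linewidth = 3) +
    ggplot2::labs(
      x = "frame", y = "ring",
      title = sprintf("%s: %s in %.2f s", object$video_id,
                      toupper(object$verdict), object$duration_s),
      colour = "instrument") +
    ggplot2::theme_minimal()
  if (nrow(object$pitfalls) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$pitfalls,
      ggplot2::aes(x = .data$frame, y = .data$ring_id, shape = .data$kind),
      size = 3, colour = "black")
  }
  p
}
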