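#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a motility result
#'
#' One row per consecutive-frame interval, with the elapsed time of the
#' interval midpoint in seconds.
#'
#' @param x A `motility_result` from [motility_index()].
#' @param ... Unused.
#' @return A tibble with columns `t`, `time_s` and the per-interval
#'   measures (`R`, `A_t`, `A_t1`, `M1`, `M2`, `N` as available).
#' @export
tidy.motility_result <- function(x, ...) {
  dplyr::mutate(x$intervals,
                time_s = (.data$t - 0.5) * x$frame_interval,
                .after = "t")
}

#' Summarize a motility result in one row
#'
#' @param x A `motility_result`.
#' @param ... Unused.
#' @return One-row tibble with `n_intervals`, `frame_interval_s`,
#'   `area_mean`, `m1_mean`, `m2_mean`, `boxcar_w`.
#' @export
glance.motility_result <- function(x, ...) {
  tibble::tibble(
    n_intervals = nrow(x$intervals),
    frame_interval_s = x$frame_interval,
    area_mean = x$area_mean,
    m1_mean = x$m1_mean,
    m2_mean = x$m2_mean,
    boxcar_w = x$w
  )
}

#' Plot per-interval motility indices
#'
#' @param object A `motility_result`.
#' @param ... Unused.
#' @return A ggplot of the available indices against elapsed time.
#' @export
autoplot.motility_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df,
                              cols = dplyr::any_of(c("M1", "M2")),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s / 60, .data$value,
                                     colour = .data$index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "motility index", colour = NULL)
}

#' Plot a boxcar-width sweep
#'
#' @param object A `boxcar_sweep` tibble from [boxcar_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean index against window width.
#' @export
autoplot.boxcar_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$w, .data$m2_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "boxcar width w (px)",
                  y = "mean boxcar-weighted index")
}

#' Plot a temporal-frequency classification map
#'
#' Dominant per-pixel frequency with rejected pixels highlighted.
#'
#' @param object A `frequency_mask` from [classify_pixels()].
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.frequency_mask <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$dominant_freq)),
                           col = seq_len(ncol(object$dominant_freq)))
  df$frequency <- as.vector(object$dominant_freq)
  df$status <- ifelse(as.vector(object$accepted) == 1L, "accepted",
                      "rejected")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$frequency)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~status) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "dominant\nfreq (Hz)")
}
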