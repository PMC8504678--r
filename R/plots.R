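#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   geom_text geom_tile labs theme_minimal scale_fill_gradient2 coord_fixed
#'   autoplot facet_wrap
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a montage flat-projected onto the page
#'
#' Azimuthal-equidistant projection (vertex at the origin, nose up).
#'
#' @param montage An `ow_montage`.
#' @param adjacency Optional `ow_adjacency`; edges are drawn when given.
#' @return A ggplot.
#' @export
plot_montage <- function(montage, adjacency = NULL) {
  pr <- montage_projection(montage)
  p <- ggplot(pr, aes(x = .data$px, y = .data$py))
  if (!is.null(adjacency)) {
    ed <- adjacency_edges(adjacency)
    ed <- dplyr::left_join(ed, pr[, c("label", "px", "py")],
                           by = c(a = "label"))
    ed <- dplyr::left_join(ed, pr[, c("label", "px", "py")],
                           by = c(b = "label"), suffix = c("", "_b"))
    p <- p + ggplot2::geom_segment(
      data = ed, aes(x = .data$px, y = .data$py,
                     xend = .data$px_b, yend = .data$py_b),
      colour = "grey70")
  }
  p + geom_point(size = 2) +
    geom_text(aes(label = .data$label), vjust = -0.9, size = 3) +
    coord_fixed() + theme_minimal() +
    labs(x = NULL, y = NULL, title = "Montage (vertex projection, nose up)")
}

montage_projection <- function(montage) {
  r <- attr(montage, "radius_cm")
  incl <- acos(pmin(1, pmax(-1, montage$z / r)))
  az <- atan2(montage$x, montage$y)
  tibble(label = montage$label,
         px = incl * sin(az), py = incl * cos(az))
}

#' @export
#' @method autoplot ow_wave
autoplot.ow_wave <- function(object, electrodes = NULL, ...) {
  chans <- electrodes %||% object$channels
  ci <- match(chans, object$channels)
  df <- tidyr::expand_grid(electrode = chans, i = 1) |>
    dplyr::mutate(data = purrr::map(.data$electrode, function(ch) {
      tibble(time = object$times,
             amplitude = object$wave[match(ch, object$channels), ])
    })) |>
    tidyr::unnest("data")
  ggplot(df, aes(x = .data$time, y = .data$amplitude)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70", linetype = 2) +
    geom_line() +
    facet_wrap(~electrode) +
    theme_minimal() +
    labs(x = "time (ms)", y = "amplitude (µV)",
         title = sprintf("Difference wave #%s", object$index),
         subtitle = object$formula)
}

#' @export
#' @method autoplot ow_erp
autoplot.ow_erp <- function(object, electrodes = NULL, ...) {
  w <- new_wave(object$wave, object$times, object$channels,
                formula = sprintf("%s (%d trials)",
                                  object$meta$role %||% "average",
                                  object$n_trials))
  autoplot.ow_wave(w, electrodes = electrodes, ...)
}

#' Topography of a wave at one time point
#'
#' @param wave An `ow_wave` or `ow_erp`.
#' @param montage The `ow_montage` giving positions.
#' @param time_ms Time at which to show the scalp distribution (nearest
#'   sample is used).
#' @return A ggplot (projected electrode positions coloured by amplitude).
#' @export
plot_topography <- function(wave, montage, time_ms) {
  ti <- which.min(abs(wave$times - time_ms))
  pr <- montage_projection(montage)
  pr <- pr[match(wave$channels, pr$label), ]
  pr$amplitude <- wave$wave[, ti]
  ggplot(pr, aes(x = .data$px, y = .data$py, colour = .data$amplitude)) +
    geom_point(size = 6) +
    geom_text(aes(label = .data$label), colour = "black", vjust = -1.2,
              size = 2.6) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red") +
    coord_fixed() + theme_minimal() +
    labs(title = sprintf("Topography at %g ms", wave$times[ti]),
         colour = "µV", x = NULL, y = NULL)
}

#' @export
#' @method autoplot ow_clusters
autoplot.ow_clusters <- function(object, ...) {
  df <- tidyr::expand_grid(ci = seq_len(nrow(object$t_map)),
                           ti = seq_len(ncol(object$t_map)))
  df$t <- object$t_map[cbind(df$ci, df$ti)]
  df$channel <- factor(object$channels[df$ci], levels = rev(object$channels))
  df$time <- object$times[df$ti]
  p <- ggplot(df, aes(x = .data$time, y = .data$channel, fill = .data$t)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    theme_minimal() +
    labs(x = "time (ms)", y = NULL, fill = "t",
         title = sprintf("Cluster test %g..%g ms (%s)",
                         object$window[1], object$window[2], object$tail))
  sig <- which(object$clusters$p_value < object$alpha)
  if (length(sig)) {
    mem <- dplyr::bind_rows(object$members[sig])
    mem$channel <- factor(mem$channel, levels = rev(object$channels))
    p <- p + geom_point(data = mem,
                        aes(x = .data$time, y = .data$channel),
                        inherit.aes = FALSE, size = 0.4)
  }
  p
}

#' @export
#' @method autoplot ow_inference
autoplot.ow_inference <- function(object, ...) {
  ggplot(object$effects, aes(x = .data$term, y = .data$estimate)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_point(size = 3) +
    theme_minimal() +
    labs(x = NULL, y = sprintf("effect on %s", object$value),
         title = sprintf("2x2 effects (%s)", object$method))
}
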