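#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot a peakogram
#'
#' Resolution (1/d) against log10 peak intensity with bin counts on a log
#' colour scale — the picture from which salt-filter thresholds are chosen.
#'
#' @param object A [peakogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peakogram
#' @export
autoplot.peakogram <- function(object, ...) {
  d <- object$data
  ggplot(d, aes(x = .data$invd, y = .data$logi)) +
    ggplot2::geom_bin2d(bins = c(nrow(object$counts), ncol(object$counts))) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = expression(1 / d ~ (ring(A)^-1)),
                  y = expression(log[10] ~ "peak intensity"),
                  fill = "reflections")
}

#' Plot a powder fingerprint
#'
#' Ring positions as sticks (height = multiplicity) with an optional
#' Gaussian-rendered curve.
#'
#' @param object A [enumerate_rings()] fingerprint.
#' @param peak_width If not `NULL`, overlay [simulate_curve()] with this
#'   width (nm^-1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot powder_fingerprint
#' @export
autoplot.powder_fingerprint <- function(object, peak_width = NULL, ...) {
  p <- ggplot(object, aes(x = .data$s_nm_inv)) +
    ggplot2::geom_segment(aes(xend = .data$s_nm_inv, y = 0,
                              yend = .data$multiplicity)) +
    ggplot2::labs(x = expression(s ~ (nm^-1)), y = "multiplicity")
  if (!is.null(peak_width)) {
    curve <- simulate_curve(object, peak_width = peak_width)
    sc <- max(object$multiplicity) / max(curve$intensity)
    p <- p + ggplot2::geom_line(
      data = curve, aes(x = .data$s_nm_inv, y = .data$intensity * sc),
      colour = "steelblue")
  }
  p
}

#' Plot a spot-count series with detected wedges
#'
#' @param object A [frame_series()].
#' @param wedges Optional wedge tibble from [find_wedges()], drawn as
#'   shaded frame ranges.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot frame_series
#' @export
autoplot.frame_series <- function(object, wedges = NULL, ...) {
  d <- tibble(frame = seq_along(object$spot_counts) - 1L,
              spots = object$spot_counts)
  p <- ggplot(d, aes(x = .data$frame, y = .data$spots)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "spot count")
  if (!is.null(wedges) && nrow(wedges)) {
    p <- p + ggplot2::geom_rect(
      data = wedges, inherit.aes = FALSE,
      aes(xmin = .data$start_frame - 0.5, xmax = .data$end_frame + 0.5,
          ymin = -Inf, ymax = Inf), alpha = 0.2, fill = "tomato") +
      ggplot2::geom_point(
        data = wedges, inherit.aes = FALSE,
        aes(x = .data$center_frame, y = 0), shape = 17)
  }
  p
}

#' Plot per-shell figures of merit
#'
#' Rsplit and CC1/2 against shell resolution.
#'
#' @param object A `shell_table` from [shell_stats()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shell_table
#' @export
autoplot.shell_table <- function(object, ...) {
  d <- tidy(object)
  d$invd <- 1 / ((d$d_max + d$d_min) / 2)
  long <- tidyr::pivot_longer(
    d[c("invd", "rsplit", "cc_half", "completeness_pct")],
    -"invd", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$invd, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(1 / d ~ (ring(A)^-1)), y = NULL)
}

#' Plot a titer plate's dose-response
#'
#' Positive-well proportion against log10 dilution, the curve the TCID50
#' endpoint is read from.
#'
#' @param object A [titer_plate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot titer_plate
#' @export
autoplot.titer_plate <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$dilution_log10, y = .data$proportion)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = expression(log[10] ~ "dilution"),
                  y = "fraction of positive wells")
}
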