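#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_col geom_point
#'   geom_tile labs theme_minimal autoplot scale_fill_viridis_c facet_wrap
#' @export
ggplot2::autoplot

#' Plot a trace with its fitted stepwise model
#'
#' @param object A `step_model`.
#' @param ... Unused.
#' @return A ggplot: raw intensity with the piecewise-constant fit overlaid.
#' @method autoplot step_model
#' @export
autoplot.step_model <- function(object, ...) {
  tr <- object$trace
  lv <- object$levels
  fitted <- tibble(time_s = c(lv$start_s, max(lv$end_s)),
                   intensity = c(lv$mean, lv$mean[nrow(lv)]))
  ggplot(tr, aes(.data$time_s, .data$intensity)) +
    geom_line(color = "grey55", linewidth = 0.3) +
    geom_step(data = fitted, color = "firebrick", linewidth = 0.7) +
    labs(x = "time (s)", y = "ROI intensity (ADU)",
         title = sprintf("spot %s: %d steps", object$spot_id,
                         nrow(object$steps))) +
    theme_minimal()
}

#' Plot a shifted cross-correlation matrix
#'
#' @param object A `cc_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map of the 9x9 shift grid.
#' @method autoplot cc_matrix
#' @export
autoplot.cc_matrix <- function(object, ...) {
  ggplot(object$grid, aes(.data$dcol, .data$drow, fill = .data$cc)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "column shift (px)", y = "row shift (px)", fill = "CC",
         title = sprintf("peak CC = %.3f at (%d, %d)", object$peak_cc,
                         object$peak_shift[1], object$peak_shift[2])) +
    theme_minimal()
}

#' Plot an occupancy distribution with its fit
#'
#' @param object An `occupancy_fit`.
#' @param ... Unused.
#' @return A ggplot: observed histogram with fitted expected counts.
#' @method autoplot occupancy_fit
#' @export
autoplot.occupancy_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(.data$n_cam, .data$count)) +
    geom_col(fill = "grey70") +
    geom_point(aes(y = .data$expected), color = "firebrick") +
    geom_line(aes(y = .data$expected), color = "firebrick") +
    labs(x = expression(N[CAM]), y = "spots",
         title = sprintf("%s fit (n = %d)", object$model, object$n)) +
    theme_minimal()
}

#' Plot a residence-time histogram with the exponential fit
#'
#' @param object A `tau_fit`.
#' @param ... Unused.
#' @return A ggplot of binned `|tau|` counts and the fitted decay.
#' @method autoplot tau_fit
#' @export
autoplot.tau_fit <- function(object, ...) {
  h <- object$histogram
  comp <- object$components
  fitcurve <- tibble(
    mid_s = seq(min(h$mid_s), max(h$mid_s), length.out = 200))
  fitcurve$count <- rowSums(vapply(seq_len(nrow(comp)), function(i)
    comp$amplitude[i] * exp(-comp$rate[i] * fitcurve$mid_s),
    numeric(nrow(fitcurve))))
  ggplot(h, aes(.data$mid_s, .data$count)) +
    geom_col(fill = "grey70") +
    geom_line(data = fitcurve, color = "firebrick") +
    labs(x = expression("|" * tau * "| (s)"), y = expression(N[tau]),
         title = sprintf("%s exponential, k = %.3g s^-1", object$model,
                         object$k_tau)) +
    theme_minimal()
}
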