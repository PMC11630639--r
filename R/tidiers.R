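#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted step model
#'
#' @param x A `step_model`.
#' @param ... Unused.
#' @return The accepted steps as a tibble (`frame`, `time_s`, `delta_i`,
#'   `sign`, `multiplicity`, `p_value`) with the `spot_id` prepended.
#' @method tidy step_model
#' @export
tidy.step_model <- function(x, ...) {
  mutate(x$steps, spot_id = x$spot_id, .before = 1)
}

#' One-row summary of a fitted step model
#'
#' @param x A `step_model`.
#' @param ... Unused.
#' @return Tibble: `spot_id`, `n_levels`, `n_steps`, `n_up`, `n_down`,
#'   `first_level`, `last_level`.
#' @method glance step_model
#' @export
glance.step_model <- function(x, ...) {
  tibble(spot_id = x$spot_id,
         n_levels = nrow(x$levels),
         n_steps = nrow(x$steps),
         n_up = sum(x$steps$multiplicity[x$steps$sign == "+"]),
         n_down = sum(x$steps$multiplicity[x$steps$sign == "-"]),
         first_level = x$levels$mean[1],
         last_level = x$levels$mean[nrow(x$levels)])
}

#' Tidy a residence-time fit
#'
#' @param x A `tau_fit`.
#' @param ... Unused.
#' @return Tibble of exponential components: `component`, `amplitude`, `rate`.
#' @method tidy tau_fit
#' @export
tidy.tau_fit <- function(x, ...) {
  mutate(x$components, component = row_number(), .before = 1)
}

#' One-row summary of a residence-time fit
#'
#' @param x A `tau_fit`.
#' @param ... Unused.
#' @return Tibble: `k_tau`, `model`, `n`, `tau_gt_max_fraction`,
#'   `aic_single`, `aic_double`.
#' @method glance tau_fit
#' @export
glance.tau_fit <- function(x, ...) {
  tibble(k_tau = x$k_tau, model = x$model, n = x$n,
         tau_gt_max_fraction = x$tau_gt_max_fraction,
         aic_single = x$aic_single, aic_double = x$aic_double)
}

#' Tidy an occupancy fit
#'
#' @param x An `occupancy_fit`.
#' @param ... Unused.
#' @return Tibble of the fitted histogram with expected counts under the
#'   fitted model.
#' @method tidy occupancy_fit
#' @export
tidy.occupancy_fit <- function(x, ...) {
  h <- x$histogram
  expd <- if (x$model == "two_poisson")
    x$n * (x$w * stats::dpois(h$n_cam, x$lambda1) +
             (1 - x$w) * stats::dpois(h$n_cam, x$lambda2))
  else x$n * stats::dpois(h$n_cam, max(x$lambda, 1e-12))
  mutate(h, expected = expd)
}

#' One-row summary of an occupancy fit
#'
#' @param x An `occupancy_fit`.
#' @param ... Unused.
#' @return Tibble with the model, parameters, GOF and AIC columns.
#' @method glance occupancy_fit
#' @export
glance.occupancy_fit <- function(x, ...) {
  if (x$model == "two_poisson")
    tibble(model = x$model, w = x$w, lambda1 = x$lambda1, lambda2 = x$lambda2,
           mean = x$mean, n = x$n, aic = x$aic,
           delta_aic_vs_single = x$delta_aic_vs_single)
  else
    tibble(model = x$model, lambda = x$lambda, mean = x$mean, se = x$se,
           n = x$n, gof_p = x$gof_p, aic = x$aic,
           delta_aic_vs_single = x$delta_aic_vs_single %||% NA_real_)
}

#' Tidy a shifted cross-correlation matrix
#'
#' @param x A `cc_matrix`.
#' @param ... Unused.
#' @return The 81-row long-format grid (`drow`, `dcol`, `cc`).
#' @method tidy cc_matrix
#' @export
tidy.cc_matrix <- function(x, ...) x$grid

#' One-row summary of a shifted cross-correlation matrix
#'
#' @param x A `cc_matrix`.
#' @param ... Unused.
#' @return Tibble: `peak_cc`, `peak_drow`, `peak_dcol`.
#' @method glance cc_matrix
#' @export
glance.cc_matrix <- function(x, ...) {
  tibble(peak_cc = x$peak_cc, peak_drow = x$peak_shift[1],
         peak_dcol = x$peak_shift[2])
}
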