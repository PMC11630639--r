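#' Up/down event frequencies of a spot record
#'
#' `f_on` is the number of stepwise intensity increases (multiplicity-
#' weighted) divided by the record duration; `f_off` likewise for decreases.
#' Neither takes the occupancy level into account, and `f_off` does not
#' distinguish dissociation from photobleaching.
#'
#' @param model A `step_model` (or anything with a `steps` tibble carrying
#'   `sign` and `multiplicity`).
#' @param duration_s Record duration in seconds; defaults to the trace span.
#' @return One-row tibble: `f_on`, `f_off` (s^-1), `n_plus`, `n_minus`.
#' @export
event_frequencies <- function(model, duration_s = NULL) {
  if (is.null(duration_s)) {
    tr <- model$trace
    if (is.null(tr)) abort("`duration_s` required when the model has no trace.")
    duration_s <- max(tr$time_s) - min(tr$time_s) +
      (model$dt_s %||% diff(tr$time_s[1:2]))
  }
  check_number(duration_s, "duration_s", min = 0, allow_zero = FALSE)
  st <- model$steps
  n_plus <- sum(st$multiplicity[st$sign == "+"])
  n_minus <- sum(st$multiplicity[st$sign == "-"])
  tibble(f_on = n_plus / duration_s, f_off = n_minus / duration_s,
         n_plus = as.integer(n_plus), n_minus = as.integer(n_minus))
}

#' Signed residence intervals of nonzero occupancy levels
#'
#' Each stationary nonzero occupancy level contributes one residence
#' interval. Its duration is signed by the transition that *entered* the
#' level: entered by an upward step (binding) gives tau+, entered by a
#' downward step (dissociation or photobleaching of a higher level) gives
#' tau-. Zero-occupancy intervals are not scored, and intervals open at the
#' record start or end are flagged censored and excluded from rate fits.
#'
#' @param x A `step_model` of an occupancy-resolvable record, or an
#'   `occupancy_trajectory` from the simulator (ground-truth route).
#' @param ... Unused.
#' @return Tibble of class `residence_set`: `spot_id`, `occupancy`, `tau_s`
#'   (signed), `entry_sign` (`"+"`, `"-"`, or `NA` for the censored first
#'   level), `censored`; attribute `record_duration_s`.
#' @export
residence_intervals <- function(x, ...) UseMethod("residence_intervals")

#' @rdname residence_intervals
#' @export
residence_intervals.step_model <- function(x, ...) {
  occ <- occupancy_trajectory(x)
  lv <- x$levels
  # occupancy per level from the trajectory at level starts
  starts <- match(lv$start_s, occ$time_s)
  occ_lv <- occ$n_cam[starts]
  entry <- c(NA_character_, x$steps$sign)
  dur <- lv$end_s - lv$start_s
  n_lv <- nrow(lv)
  censored <- seq_len(n_lv) %in% c(1L, n_lv)
  sign_num <- ifelse(is.na(entry), 1, ifelse(entry == "+", 1, -1))
  out <- tibble(spot_id = x$spot_id, occupancy = occ_lv,
                tau_s = sign_num * dur, entry_sign = entry,
                censored = censored) |>
    filter(.data$occupancy >= 1L)
  attr(out, "record_duration_s") <- sum(lv$end_s - lv$start_s)
  class(out) <- c("residence_set", class(out))
  out
}

#' @rdname residence_intervals
#' @export
residence_intervals.occupancy_trajectory <- function(x, ...) {
  ev <- x$events
  bounds <- c(0, ev$time_s, x$duration_s)
  # occupancy on each inter-event interval; occupancy[1] is sampled at t = 0,
  # before the first event
  occ_seq <- numeric(nrow(ev) + 1L)
  occ_seq[1] <- x$occupancy$n_bound[1]
  if (nrow(ev))
    for (i in seq_len(nrow(ev))) occ_seq[i + 1L] <- occ_seq[i] + ev$delta[i]
  entry <- c(NA_character_, ifelse(ev$delta > 0, "+", "-"))
  dur <- diff(bounds)
  n_int <- length(dur)
  censored <- seq_len(n_int) %in% c(1L, n_int)
  sign_num <- ifelse(is.na(entry), 1, ifelse(entry == "+", 1, -1))
  out <- tibble(spot_id = NA_integer_, occupancy = occ_seq,
                tau_s = sign_num * dur, entry_sign = entry,
                censored = censored) |>
    filter(.data$occupancy >= 1L)
  attr(out, "record_duration_s") <- x$duration_s
  class(out) <- c("residence_set", class(out))
  out
}

#' Fit the residence-time distribution
#'
#' Histograms the absolute residence times `|tau|` of uncensored nonzero-
#' occupancy intervals (bin width twice the frame interval) truncated at
#' `tau_max` (30 s), and fits `A exp(-k tau)` — or a two-component
#' biexponential — to the bin counts by least squares. Model choice is by
#' AIC unless forced. The fraction of intervals beyond `tau_max` is reported
#' but excluded from the fit (it is dominated by photobleaching).
#'
#' @param intervals A `residence_set` (see [residence_intervals()]).
#' @param tau_max Truncation limit in seconds (default 30).
#' @param dt_s Frame interval in seconds; bin width is `2 * dt_s`.
#' @param tau_min Bins centered at or below this dwell are excluded from the
#'   least-squares fit (they stay in the histogram). Defaults to `4 * dt_s`,
#'   the step detector's dwell resolution floor: dwells shorter than the
#'   minimum stationary duration plus the derivative window are not resolved,
#'   so the head of a detected-interval histogram is depleted and would bias
#'   the rate downward. Exponential memorylessness makes the exclusion
#'   unbiased. Set to 0 to fit the full histogram.
#' @param model `"auto"` (AIC), `"single"`, or `"double"`.
#' @param min_intervals Minimum number of uncensored intervals (default 30).
#' @return Object of class `tau_fit`: list with `k_tau` (the reported decay
#'   rate; the faster/major component for a biexponential), `model`,
#'   `components` (tibble `amplitude`, `rate`), `tau_gt_max_fraction`, `n`,
#'   `aic_single`, `aic_double`, `histogram`.
#' @export
fit_tau <- function(intervals, tau_max = 30, dt_s = 0.2, tau_min = 4 * dt_s,
                    model = c("auto", "single", "double"),
                    min_intervals = 30L) {
  model <- match.arg(model)
  tau <- abs(intervals$tau_s[!intervals$censored])
  tau <- tau[tau > 0]
  if (length(tau) < min_intervals)
    abort(sprintf("need >= %d uncensored intervals, got %d.",
                  min_intervals, length(tau)))
  frac_gt <- mean(tau > tau_max)
  tau_fit_data <- tau[tau <= tau_max]
  bw <- 2 * dt_s
  brks <- seq(0, max(tau_fit_data) + bw, by = bw)
  h <- graphics::hist(tau_fit_data, breaks = brks, plot = FALSE)
  # all bins between tau_min and tau_max enter the fit — zero-count bins are
  # informative and dropping them would bias the tail upward
  dfit <- data.frame(t = h$mids, y = h$counts)
  dfit <- dfit[dfit$t > tau_min, , drop = FALSE]
  if (nrow(dfit) < 4L)
    abort("too few histogram bins above `tau_min` to fit.")

  k0 <- 1 / mean(tau_fit_data)
  a0 <- max(dfit$y, 1)
  # Histogram counts are Poisson, so the exponential decay is fitted by
  # Poisson likelihood (a log-linear model for the single exponential);
  # ordinary or empirically weighted least squares on sparse tail bins is
  # badly biased. Rates faster than ~1/bin are not resolvable from a binned
  # histogram, hence the bound on k.
  k_max <- 3 / bw
  fit_single <- tryCatch({
    g <- stats::glm(y ~ t, family = stats::poisson(), data = dfit)
    cf <- stats::coef(g)
    list(a = exp(cf[[1]]), k = min(max(-cf[[2]], 1e-6), k_max),
         ll = as.numeric(stats::logLik(g)))
  }, error = function(e) NULL)

  pois_ll <- function(mu, y) sum(stats::dpois(y, pmax(mu, 1e-12), log = TRUE))
  fit_double <- tryCatch({
    nll <- function(p) {
      mu <- exp(p[1]) * exp(-exp(p[2]) * dfit$t) +
        exp(p[3]) * exp(-exp(p[4]) * dfit$t)
      -pois_ll(mu, dfit$y)
    }
    k1_0 <- min(k0 * 3, k_max / 2); k2_0 <- max(k0 / 3, 1e-4)
    best <- NULL
    for (st in list(c(log(a0 * 0.7), log(k1_0), log(a0 * 0.3), log(k2_0)),
                    c(log(a0 * 0.5), log(min(k0 * 6, k_max)),
                      log(a0 * 0.5), log(max(k0 / 6, 1e-4))))) {
      o <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                                 lower = c(-10, log(1e-5), -10, log(1e-5)),
                                 upper = c(log(20 * a0), log(k_max),
                                           log(20 * a0), log(k_max))),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) NULL else
      list(a1 = exp(best$par[1]), k1 = exp(best$par[2]),
           a2 = exp(best$par[3]), k2 = exp(best$par[4]), ll = -best$value)
  }, error = function(e) NULL)

  a1 <- if (is.null(fit_single)) Inf else -2 * fit_single$ll + 2 * 2
  a2_ <- if (is.null(fit_double)) Inf else -2 * fit_double$ll + 2 * 4
  degenerate2 <- FALSE
  if (!is.null(fit_double)) {
    kk <- c(fit_double$k1, fit_double$k2)
    aa <- c(fit_double$a1, fit_double$a2)
    if (max(kk) / max(min(kk), 1e-9) < 1.5) degenerate2 <- TRUE
    if (min(aa) < 1e-3 * a0) degenerate2 <- TRUE
  }
  # the mixture must beat the single model clearly (dAIC < -4) before the
  # extra component is believed
  use_double <- switch(model,
                       auto = is.finite(a2_) && a2_ < a1 - 4 && !degenerate2,
                       single = FALSE,
                       double = !is.null(fit_double) && !degenerate2)
  if (model == "double" && (is.null(fit_double) || degenerate2))
    warn("biexponential fit degenerate; falling back to single exponential.")
  if (use_double) {
    ord <- order(c(fit_double$k1, fit_double$k2), decreasing = TRUE)
    amps <- c(fit_double$a1, fit_double$a2)[ord]
    rates <- c(fit_double$k1, fit_double$k2)[ord]
    comp <- tibble(amplitude = amps, rate = rates)
    k_tau <- rates[1]
    mdl <- "double"
  } else {
    if (is.null(fit_single)) abort("exponential fit failed to converge.")
    comp <- tibble(amplitude = fit_single$a, rate = fit_single$k)
    k_tau <- fit_single$k
    mdl <- "single"
  }
  structure(list(k_tau = k_tau, model = mdl, components = comp,
                 tau_gt_max_fraction = frac_gt, n = length(tau),
                 aic_single = a1, aic_double = a2_,
                 histogram = tibble(mid_s = h$mids, count = h$counts)),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("<tau_fit> %s exponential, k_tau = %.3g s^-1 (n = %d, %.1f%% > tau_max)\n",
              x$model, x$k_tau, x$n, 100 * x$tau_gt_max_fraction))
  invisible(x)
}

#' Correct an apparent dissociation rate for photobleaching
#'
#' Dissociation and photobleaching are independent competing exponential
#' hazards, so the apparent residence-time decay rate is their sum; the
#' corrected rate is `k_tau - k_pb`, clamped at zero (with a warning) if the
#' photobleaching rate exceeds the apparent rate.
#'
#' @param k_tau Apparent decay rate of the `|tau|` distribution (s^-1).
#' @param k_pb Photobleaching rate from a ligand-only control (s^-1).
#' @return Corrected rate (s^-1), with attribute `clamped` if negative input.
#' @export
photobleach_correct <- function(k_tau, k_pb) {
  check_number(k_tau, "k_tau", min = 0)
  check_number(k_pb, "k_pb", min = 0)
  if (k_pb > k_tau) {
    warn("k_pb exceeds k_tau; corrected rate clamped to 0.")
    return(structure(0, clamped = TRUE))
  }
  k_tau - k_pb
}

#' Affinity index
#'
#' `A_i = cam_conc * k_tau / f_on`, a heuristic substitute for the
#' dissociation constant that allows relative affinity comparisons between
#' assemblies. Reported in the units of `cam_conc`.
#'
#' @param cam_conc Ligand concentration (any concentration unit).
#' @param k_tau Residence-time decay rate (s^-1).
#' @param f_on On-event frequency (s^-1); must be positive.
#' @return The affinity index in the units of `cam_conc`.
#' @export
affinity_index <- function(cam_conc, k_tau, f_on) {
  check_number(cam_conc, "cam_conc", min = 0)
  check_number(k_tau, "k_tau", min = 0)
  if (!is.finite(f_on) || f_on <= 0)
    abort("`f_on` must be positive; affinity index undefined at f_on = 0.")
  cam_conc * k_tau / f_on
}

#' Summarize binding kinetics for one experimental condition
#'
#' Pools per-spot step models: event frequencies are computed per spot and
#' averaged; residence intervals are pooled across spots for the `|tau|`
#' fit; the photobleaching-corrected rate and affinity index are derived.
#'
#' @param models List of `step_model`s (rhodamine channel).
#' @param duration_s Record duration per spot (s).
#' @param cam_conc Ligand concentration (units carried into `a_i`).
#' @param k_pb Photobleaching rate from a ligand-only control (s^-1; 0 skips
#'   the correction).
#' @param dt_s Frame interval (s).
#' @param tau_max Residence-time truncation (s).
#' @param tau_model Exponential model for the residence fit (see [fit_tau()]).
#' @return One-row tibble of class `kinetics_summary`: `f_on`, `f_off`,
#'   `n_plus`, `n_minus`, `k_tau`, `k_tau_model`, `k_pb`, `k_tau_corr`,
#'   `a_i`, `tau_gt30_fraction`, `n_intervals`.
#' @export
kinetics_summary <- function(models, duration_s, cam_conc = NA_real_,
                             k_pb = 0, dt_s = 0.2, tau_max = 30,
                             tau_model = c("auto", "single", "double")) {
  tau_model <- match.arg(tau_model)
  freqs <- list_rbind(map(models, event_frequencies, duration_s = duration_s))
  ints <- list_rbind(map(models, function(m) {
    out <- residence_intervals(m)
    class(out) <- setdiff(class(out), "residence_set")
    out
  }))
  class(ints) <- c("residence_set", class(ints))
  ft <- fit_tau(ints, tau_max = tau_max, dt_s = dt_s, model = tau_model)
  k_corr <- photobleach_correct(ft$k_tau, k_pb)
  f_on <- mean(freqs$f_on)
  out <- tibble(
    f_on = f_on, f_off = mean(freqs$f_off),
    n_plus = sum(freqs$n_plus), n_minus = sum(freqs$n_minus),
    k_tau = ft$k_tau, k_tau_model = ft$model, k_pb = k_pb,
    k_tau_corr = as.numeric(k_corr),
    a_i = if (is.finite(cam_conc) && f_on > 0)
      affinity_index(cam_conc, ft$k_tau, f_on) else NA_real_,
    tau_gt30_fraction = ft$tau_gt_max_fraction,
    n_intervals = ft$n)
  class(out) <- c("kinetics_summary", class(out))
  out
}
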