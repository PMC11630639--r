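#' Step-finder parameters
#'
#' Tunable parameters of the four-pass step finder. `a`, `b` and `q` carry
#' the names used on the interactive analysis sliders they replace: `b` is
#' the running-average smoothing window (three frames by default), `a` the
#' rolling window over which the first derivative is taken, and `q` the
#' quality-index threshold for derivative peaks. Steps are accepted when
#' their amplitude falls within one calibrated standard deviation of an
#' integer multiple of the single-fluorophore step mean; stationary levels
#' must last at least `min_dwell_s` (0.3 s) and differ at significance
#' `alpha` under an unequal-variance t-test.
#'
#' @param step_mean,step_sd Single-fluorophore step calibration (ADU), e.g.
#'   from [calibrate_step_distribution()].
#' @param a Derivative rolling-window length in frames (default 5).
#' @param b Smoothing window length in frames (default 3).
#' @param q Peak quality-index threshold (default 3).
#' @param min_dwell_s Minimum stationary-level duration in seconds (0.3 s).
#' @param alpha Significance level for the level-difference t-test.
#' @param max_multiplicity Largest multi-step ("bunching") multiplicity
#'   reported for one derivative peak.
#' @param channel Optional channel tag; if set, [find_steps()] refuses traces
#'   from a different channel (calibration is channel-specific).
#' @return A list of class `step_params`.
#' @export
step_params <- function(step_mean, step_sd, a = 5L, b = 3L, q = 3,
                        min_dwell_s = 0.3, alpha = 0.05,
                        max_multiplicity = 6L, channel = NULL) {
  check_number(step_mean, "step_mean", min = 0, allow_zero = FALSE)
  check_number(step_sd, "step_sd", min = 0)
  if (a < 1L || b < 1L) abort("`a` and `b` must be >= 1 frame.")
  check_number(q, "q", min = 0, allow_zero = FALSE)
  check_number(min_dwell_s, "min_dwell_s", min = 0, allow_zero = FALSE)
  structure(list(step_mean = step_mean, step_sd = step_sd, a = as.integer(a),
                 b = as.integer(b), q = q, min_dwell_s = min_dwell_s,
                 alpha = alpha, max_multiplicity = as.integer(max_multiplicity),
                 channel = channel),
            class = "step_params")
}

#' Calibrate the single-fluorophore step distribution
#'
#' Estimates the mean and SD of the single-fluorophore intensity step from
#' records of monomeric (or nonspecifically attached) single fluorophores,
#' each showing one bleaching step. For each trace the best single
#' change-point is found by exhaustive least squares and the amplitude taken
#' as the difference of the two level means.
#'
#' @param traces Long tibble with `spot_id`, `intensity` (and optionally
#'   `channel`), one single-fluorophore record per `spot_id`.
#' @param channel Channel tag recorded with the calibration; required so a
#'   calibration cannot silently be reused on the other channel.
#' @param min_traces Minimum number of records (default 20).
#' @return A list of class `step_calibration`: `step_mean`, `step_sd`, `n`,
#'   `channel`, `amplitudes`.
#' @export
calibrate_step_distribution <- function(traces, channel, min_traces = 20L) {
  if (missing(channel) || is.null(channel))
    abort("`channel` is required: step calibrations are channel-specific.")
  ids <- unique(traces$spot_id)
  if (length(ids) < min_traces)
    abort(sprintf("need >= %d single-fluorophore traces, got %d.",
                  min_traces, length(ids)))
  amp <- vapply(ids, function(id) {
    x <- traces$intensity[traces$spot_id == id]
    cp <- best_single_changepoint(x)
    a <- mean(x[seq_len(cp - 1L)]) - mean(x[cp:length(x)])
    # records that never bleach in-record fit a spurious near-zero change
    # point; exclude amplitudes indistinguishable from the trace noise
    noise <- robust_sd(diff(x)) / sqrt(2)
    if (is.finite(noise) && abs(a) < 5 * noise / sqrt(min(cp - 1, 10)))
      return(NA_real_)
    a
  }, numeric(1))
  amp <- amp[is.finite(amp)]
  if (length(amp) < min_traces / 2)
    abort("too few traces with a detectable bleaching step.")
  structure(list(step_mean = mean(amp), step_sd = stats::sd(amp),
                 n = length(amp), channel = channel, amplitudes = amp),
            class = "step_calibration")
}

# Exhaustive least-squares single change-point (used for calibration).
best_single_changepoint <- function(x) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- 2:(n - 1)
  sse <- (cs2[k - 1] - (cs[k - 1])^2 / (k - 1)) +
    ((cs2[n] - cs2[k - 1]) - (cs[n] - cs[k - 1])^2 / (n - k + 1))
  k[which.min(sse)]
}

# Local maxima and their topographic prominences.
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3L) return(tibble(index = integer(0), height = numeric(0),
                            prominence = numeric(0)))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    h <- v[i]
    lmin <- h; j <- i
    while (j > 1L && v[j - 1L] <= h) { j <- j - 1L; lmin <- min(lmin, v[j]) }
    left <- if (j == 1L && v[j] <= h) min(lmin, v[1L]) else lmin
    rmin <- h; j <- i
    while (j < n && v[j + 1L] <= h) { j <- j + 1L; rmin <- min(rmin, v[j]) }
    right <- if (j == n && v[j] <= h) min(rmin, v[n]) else rmin
    h - max(left, right)
  }, numeric(1))
  tibble(index = idx, height = v[idx], prominence = prom)
}

# SD of the rolling-window derivative of a b-smoothed unit-variance white
# trace: the L2 norm of the composite linear filter, computed from impulse
# responses at the window center.
derivative_noise_factor <- function(a, b) {
  len <- 4L * (a + b) + 1L
  i <- 2L * (a + b) + 1L
  w <- vapply(seq_len(len), function(k) {
    e <- numeric(len); e[k] <- 1
    s <- moving_average(e, b)
    cs <- cumsum(c(0, s))
    (cs[i + a] - cs[i]) / a - (cs[i] - cs[i - a]) / a
  }, numeric(1))
  sqrt(sum(w^2))
}

# Welch t-test p-value between two level samples, robust to degenerate input.
level_p_value <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L ||
      (stats::var(x1) == 0 && stats::var(x2) == 0)) {
    return(if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else 0)
  }
  tryCatch(stats::t.test(x1, x2, var.equal = FALSE)$p.value,
           error = function(e) 0)
}

#' Four-pass step detection on a single-spot intensity trace
#'
#' Pass 1 removes high-frequency fluctuations with a `b`-point running
#' average. Pass 2 takes the first derivative over a rolling window of `a`
#' frames and calls prominent peaks of its magnitude with a quality index
#' (peak prominence over the robust SD of the derivative) above `q`. Pass 3
#' accepts candidate change points whose raw-intensity jump lies within one
#' calibrated SD of the single-fluorophore step mean — or, for merged
#' ("bunched") multi-steps, within `m` SDs of `m` times the step mean — and
#' records the multiplicity `m`. Pass 4 refits level means between accepted
#' change points on the raw trace, merging stationary levels shorter than
#' `min_dwell_s` or not significantly different under an unequal-variance
#' t-test at `alpha`.
#'
#' @param trace A trace tibble (`time_s`, `intensity`) as produced by
#'   [extract_trace()] or [simulate_bleach_staircase()].
#' @param params A [step_params()] with the channel's step calibration.
#' @param spot_id Optional identifier carried into the result.
#' @return An object of class `step_model`: list with `levels` (tibble
#'   `level`, `start_s`, `end_s`, `mean`, `n_frames`), `steps` (tibble
#'   `frame`, `time_s`, `delta_i`, `sign`, `multiplicity`, `p_value`),
#'   `params`, `trace`, `spot_id`.
#' @export
find_steps <- function(trace, params, spot_id = NA_integer_) {
  if (!inherits(params, "step_params")) abort("`params` must be step_params().")
  ch <- attr(trace, "channel")
  if (!is.null(params$channel) && !is.null(ch) && !identical(ch, params$channel))
    abort(sprintf("calibration is for channel '%s' but trace is '%s'.",
                  params$channel, ch))
  x <- trace$intensity
  n <- length(x)
  a <- params$a; b <- params$b
  if (n < 2L * a + 2L * b)
    abort(sprintf("trace too short: need >= %d frames, got %d.", 2 * a + 2 * b, n))
  dt <- attr(trace, "dt_s") %||%
    (if (n > 1) diff(trace$time_s[1:2]) else 0.2)
  min_dwell_f <- max(1L, ceiling(params$min_dwell_s / dt))

  # Pass 1: smoothing
  s <- moving_average(x, b)

  # Pass 2: rolling-window derivative and quality-indexed peak calling.
  # d[i] is the step estimate for a change between frames i-1 and i; the
  # windows shrink near the record edges so early and late steps stay visible.
  d <- rep(NA_real_, n)
  cs <- cumsum(c(0, s))
  for (i in 2L:n) {
    lo <- max(1L, i - a); hi <- min(n, i + a - 1L)
    d[i] <- (cs[hi + 1L] - cs[i]) / (hi - i + 1L) -
      (cs[i] - cs[lo]) / (i - lo)
  }
  dav <- abs(d)
  dav[is.na(dav)] <- 0
  # Noise scale of the derivative, propagated from the raw trace noise
  # through the smoothing + rolling-derivative filter. Estimating it from
  # the derivative itself would inflate it on event-dense records.
  sigma_x <- robust_sd(diff(x)) / sqrt(2)
  sd_d <- sigma_x * derivative_noise_factor(a, b)
  if (!is.finite(sd_d) || sd_d == 0) sd_d <- 1e-12  # noiseless record
  pk <- find_peaks(dav)
  # quality index: peak magnitude over the robust SD of the derivative trace.
  # (Topographic prominence is not used for the threshold: in a photobleaching
  # cascade the |derivative| does not return to baseline between nearby steps,
  # so intermediate peaks have near-zero prominence however large they are.)
  pk$quality <- pk$height / sd_d
  pk <- pk[pk$quality >= params$q, , drop = FALSE]
  # ties closer than the minimum dwell: keep the higher peak
  if (nrow(pk) > 1L) {
    pk <- pk[order(-pk$height), ]
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))[-1]) {
      prev <- which(keep[seq_len(i - 1L)])
      if (length(prev) && min(abs(pk$index[prev] - pk$index[i])) < min_dwell_f)
        keep[i] <- FALSE
    }
    pk <- pk[keep, ]
    pk <- pk[order(pk$index), ]
  }
  cand <- pk$index

  # Pass 3: amplitude-calibrated acceptance with multi-step multiplicity
  accepted <- integer(0); mult <- integer(0)
  if (length(cand)) {
    bounds <- c(1L, cand, n + 1L)
    # level windows span the inter-candidate gaps; frames adjacent to the
    # candidate are trimmed as a guard band against +/- few-frame offsets in
    # the called change-point position
    guarded <- function(idx, from_end) {
      trim <- if (length(idx) > 8L) 2L else if (length(idx) > 4L) 1L else 0L
      if (trim > 0L)
        idx <- if (from_end) idx[seq_len(length(idx) - trim)] else
          idx[-seq_len(trim)]
      idx
    }
    for (j in seq_along(cand)) {
      i <- cand[j]
      pre <- x[guarded(bounds[j]:(i - 1L), from_end = TRUE)]
      post <- x[guarded(i:(bounds[j + 2L] - 1L), from_end = FALSE)]
      dI <- median(post) - median(pre)
      m <- round(abs(dI) / params$step_mean)
      if (m >= 1L && m <= params$max_multiplicity &&
          abs(abs(dI) - m * params$step_mean) <= m * params$step_sd) {
        accepted <- c(accepted, i); mult <- c(mult, as.integer(m))
      }
    }
  }

  # Refine accepted change-point positions by local least squares: the
  # smoothed derivative can peak a frame or two off the true transition.
  if (length(accepted)) {
    bounds <- c(1L, accepted, n + 1L)
    for (j in seq_along(accepted)) {
      lo <- max(bounds[j] + 1L, accepted[j] - 2L)
      hi <- min(bounds[j + 2L] - 1L, accepted[j] + 2L)
      if (hi <= lo) next
      cand_pos <- lo:hi
      sse <- vapply(cand_pos, function(i) {
        pre <- x[bounds[j]:(i - 1L)]; post <- x[i:(bounds[j + 2L] - 1L)]
        sum((pre - mean(pre))^2) + sum((post - mean(post))^2)
      }, numeric(1))
      accepted[j] <- cand_pos[which.min(sse)]
      bounds[j + 1L] <- accepted[j]
    }
  }

  # Pass 4: level refinement on the raw trace with dwell and significance merge
  repeat {
    bounds <- c(1L, accepted, n + 1L)
    nlev <- length(bounds) - 1L
    if (nlev <= 1L) break
    lens <- diff(bounds)
    means <- vapply(seq_len(nlev), function(k)
      mean(x[bounds[k]:(bounds[k + 1L] - 1L)]), numeric(1))
    drop_j <- 0L
    short <- which(lens < min_dwell_f)
    if (length(short)) {
      k <- short[1]
      # merge the short level across its weaker boundary
      cand_b <- c(if (k > 1L) k - 1L, if (k < nlev) k)
      gaps <- abs(means[cand_b + 1L] - means[cand_b])
      drop_j <- cand_b[which.min(gaps)]
    } else {
      pvals <- vapply(seq_len(nlev - 1L), function(k)
        level_p_value(x[bounds[k]:(bounds[k + 1L] - 1L)],
                      x[bounds[k + 1L]:(bounds[k + 2L] - 1L)]), numeric(1))
      bad <- which(pvals >= params$alpha)
      if (length(bad)) drop_j <- bad[which.max(pvals[bad])]
    }
    if (drop_j == 0L) break
    accepted <- accepted[-drop_j]
    mult <- mult[-drop_j]
  }

  bounds <- c(1L, accepted, n + 1L)
  nlev <- length(bounds) - 1L
  levels <- tibble(
    level = seq_len(nlev),
    start_s = trace$time_s[bounds[-length(bounds)]],
    end_s = trace$time_s[pmin(bounds[-1L] - 1L, n)] + dt,
    mean = vapply(seq_len(nlev), function(k)
      mean(x[bounds[k]:(bounds[k + 1L] - 1L)]), numeric(1)),
    n_frames = diff(bounds))
  if (length(accepted)) {
    delta <- diff(levels$mean)
    mult_final <- pmax(1L, pmin(params$max_multiplicity,
                                as.integer(round(abs(delta) / params$step_mean))))
    pv <- vapply(seq_along(accepted), function(k)
      level_p_value(x[bounds[k]:(bounds[k + 1L] - 1L)],
                    x[bounds[k + 1L]:(bounds[k + 2L] - 1L)]), numeric(1))
    steps <- tibble(frame = accepted,
                    time_s = trace$time_s[accepted],
                    delta_i = delta,
                    sign = ifelse(delta > 0, "+", "-"),
                    multiplicity = mult_final,
                    p_value = pv)
  } else {
    steps <- tibble(frame = integer(0), time_s = numeric(0),
                    delta_i = numeric(0), sign = character(0),
                    multiplicity = integer(0), p_value = numeric(0))
  }
  new_step_model(levels, steps, params = params, trace = trace,
                 spot_id = spot_id, dt_s = dt,
                 channel = ch %||% params$channel)
}

# Low-level constructor, also used to wrap simulator ground truth.
new_step_model <- function(levels, steps, params = NULL, trace = NULL,
                           spot_id = NA_integer_, dt_s = NA_real_,
                           channel = NULL) {
  structure(list(levels = levels, steps = steps, params = params,
                 trace = trace, spot_id = spot_id, dt_s = dt_s,
                 channel = channel),
            class = "step_model")
}

#' @export
print.step_model <- function(x, ...) {
  cat(sprintf("<step_model> %d levels, %d steps (%d up, %d down)\n",
              nrow(x$levels), nrow(x$steps),
              sum(x$steps$sign == "+"), sum(x$steps$sign == "-")))
  invisible(x)
}

#' Count photobleaching steps to estimate subunit stoichiometry
#'
#' The subunit stoichiometry of a green (Venus) spot is the total
#' multiplicity of downward steps until the trace reaches its terminal,
#' near-zero level. If the record ends before full bleaching the estimate is
#' flagged censored.
#'
#' @param model A `step_model` of a Venus-channel photobleaching trace.
#' @param zero_tol Intensity below which the terminal level counts as fully
#'   bleached; defaults to half the calibrated step mean.
#' @return Integer count with attribute `censored` (logical).
#' @export
count_bleach_steps <- function(model, zero_tol = NULL) {
  if (is.null(zero_tol))
    zero_tol <- if (!is.null(model$params)) model$params$step_mean / 2 else
      abort("`zero_tol` required when the model carries no calibration.")
  down <- model$steps$sign == "-"
  s <- sum(model$steps$multiplicity[down]) - sum(model$steps$multiplicity[!down])
  censored <- abs(model$levels$mean[nrow(model$levels)]) > zero_tol
  structure(as.integer(s), censored = censored)
}
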