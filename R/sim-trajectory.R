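#' Simulate per-spot ligand occupancy as a continuous-time Markov chain
#'
#' Each of the `S` subunits binds ligand independently at `kon * cam_conc`
#' and releases it at `koff`; under illumination every bound fluorophore also
#' photobleaches with hazard `kpb_red`. Steady-state occupancy is reached in
#' the dark before recording, so the initial state is drawn from the
#' stationary law with photobleaching off, `Binomial(S, p)` with
#' `p = kon*C / (kon*C + koff)`. A photobleached ligand stays bound — it
#' still blocks its subunit — but is invisible; it later dissociates silently.
#' Event times are exact (Gillespie); the visible occupancy is then sampled
#' onto the camera frame grid.
#'
#' @param S Subunit count (binding sites) per spot.
#' @param cam_conc Ligand concentration (M).
#' @param kon Association rate constant (M^-1 s^-1).
#' @param koff Dissociation rate (s^-1).
#' @param kpb_red Per-fluorophore photobleaching hazard (s^-1), applied only
#'   for t >= 0 (laser on).
#' @param duration_s Record duration (s).
#' @param dt_s Frame interval of the sampled grid (s); the per-channel
#'   effective interval after deinterleaving is 0.2 s.
#' @param seed Optional integer seed.
#' @return An object of class `occupancy_trajectory`: a list with
#'   `occupancy` (tibble: `frame`, `time_s`, `n_bound` — visible occupancy),
#'   `events` (tibble: `time_s`, `delta` in {+1, -1}, `cause` in
#'   {"bind", "unbind", "photobleach"}), plus `S`, `duration_s` and the rates.
#' @export
simulate_binding_trajectory <- function(S, cam_conc, kon, koff, kpb_red = 0,
                                        duration_s = 40, dt_s = 0.2,
                                        seed = NULL) {
  if (S < 1L || S != round(S)) abort("`S` must be a positive integer.")
  for (nm in c("cam_conc", "kon", "koff", "kpb_red"))
    check_number(get(nm), nm, min = 0)
  check_number(duration_s, "duration_s", min = 0, allow_zero = FALSE)
  check_number(dt_s, "dt_s", min = 0, allow_zero = FALSE)

  with_seed(seed, {
    kon_c <- kon * cam_conc
    p <- if (kon_c + koff > 0) kon_c / (kon_c + koff) else 0
    n_vis <- rbinom(1L, S, p)     # visible (fluorescent) bound ligands
    n_dark <- 0L                  # photobleached but still bound
    t <- 0
    ev_t <- numeric(0); ev_d <- integer(0); ev_c <- character(0)
    times <- seq(0, duration_s, by = dt_s)
    occ <- integer(length(times)); occ_i <- 1L

    repeat {
      r_bind <- (S - n_vis - n_dark) * kon_c
      r_unb <- n_vis * koff
      r_pb <- n_vis * kpb_red
      r_dark <- n_dark * koff
      r_tot <- r_bind + r_unb + r_pb + r_dark
      t_next <- if (r_tot > 0) t + rexp(1L, r_tot) else Inf
      while (occ_i <= length(times) && times[occ_i] < min(t_next, Inf)) {
        occ[occ_i] <- n_vis; occ_i <- occ_i + 1L
      }
      if (t_next > duration_s || !is.finite(t_next)) break
      t <- t_next
      u <- runif(1L) * r_tot
      if (u < r_bind) {
        n_vis <- n_vis + 1L
        ev_t <- c(ev_t, t); ev_d <- c(ev_d, 1L); ev_c <- c(ev_c, "bind")
      } else if (u < r_bind + r_unb) {
        n_vis <- n_vis - 1L
        ev_t <- c(ev_t, t); ev_d <- c(ev_d, -1L); ev_c <- c(ev_c, "unbind")
      } else if (u < r_bind + r_unb + r_pb) {
        n_vis <- n_vis - 1L; n_dark <- n_dark + 1L
        ev_t <- c(ev_t, t); ev_d <- c(ev_d, -1L); ev_c <- c(ev_c, "photobleach")
      } else {
        n_dark <- n_dark - 1L   # dark ligand dissociates; not visible
      }
    }
    if (occ_i <= length(times)) occ[occ_i:length(times)] <- n_vis

    structure(list(
      occupancy = tibble(frame = seq_along(times), time_s = times, n_bound = occ),
      events = tibble(time_s = ev_t, delta = ev_d, cause = ev_c),
      S = as.integer(S), duration_s = duration_s,
      rates = c(kon_c = kon_c, koff = koff, kpb_red = kpb_red)
    ), class = "occupancy_trajectory")
  })
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  cat(sprintf("<occupancy_trajectory> S = %d, %.3g s, %d events\n",
              x$S, x$duration_s, nrow(x$events)))
  invisible(x)
}

#' Simulate a stepwise photobleaching staircase trace
#'
#' Each of `n_fluor` fluorophores contributes an intensity step drawn from
#' the calibrated single-fluorophore distribution and bleaches once at an
#' exponential time with hazard `kpb`; a `dark_fraction` of tags never
#' fluoresces. The expected trace is therefore a monotone non-increasing
#' staircase, to which Gaussian per-frame noise of SD `noise_sd` is added.
#'
#' @param n_fluor Number of fluorophore tags (>= 0).
#' @param kpb Photobleaching hazard (s^-1).
#' @param step_mean,step_sd Single-fluorophore step amplitude mean and SD (ADU).
#' @param noise_sd Additive per-frame noise SD (ADU).
#' @param duration_s Record duration (s).
#' @param dt_s Frame interval (s).
#' @param dark_fraction Probability a tag is dark from the start.
#' @param seed Optional integer seed.
#' @return A tibble of class `sm_trace` with columns `frame`, `time_s`,
#'   `intensity`, and attributes `events` (tibble `time_s`, `delta = -1`,
#'   `amplitude` for each bleach of an active fluorophore), `n_active`
#'   (fluorescent tag count after dark-fraction thinning), `dt_s`.
#' @export
simulate_bleach_staircase <- function(n_fluor, kpb, step_mean, step_sd,
                                      noise_sd, duration_s = 60, dt_s = 0.2,
                                      dark_fraction = 0, seed = NULL) {
  if (n_fluor < 0L || n_fluor != round(n_fluor))
    abort("`n_fluor` must be a non-negative integer.")
  check_number(kpb, "kpb", min = 0)
  check_number(dt_s, "dt_s", min = 0, allow_zero = FALSE)
  check_number(duration_s, "duration_s", min = 0, allow_zero = FALSE)

  with_seed(seed, {
    times <- seq(0, duration_s, by = dt_s)
    n_active <- if (dark_fraction > 0 && n_fluor > 0)
      rbinom(1L, n_fluor, 1 - dark_fraction) else as.integer(n_fluor)
    if (n_active > 0) {
      t_bleach <- if (kpb > 0) rexp(n_active, kpb) else rep(Inf, n_active)
      amp <- rnorm(n_active, step_mean, step_sd)
      alive <- outer(times, t_bleach, `<`)           # frame x fluor
      signal <- as.numeric(alive %*% amp)
      ev <- tibble(time_s = t_bleach, delta = -1L, amplitude = amp) |>
        filter(is.finite(.data$time_s), .data$time_s <= duration_s) |>
        arrange(.data$time_s)
    } else {
      signal <- rep(0, length(times))
      ev <- tibble(time_s = numeric(0), delta = integer(0), amplitude = numeric(0))
    }
    intensity <- signal + rnorm(length(times), 0, noise_sd)
    out <- tibble(frame = seq_along(times), time_s = times, intensity = intensity)
    attr(out, "events") <- ev
    attr(out, "n_active") <- n_active
    attr(out, "dt_s") <- dt_s
    class(out) <- c("sm_trace", class(out))
    out
  })
}
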