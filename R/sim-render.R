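#' Pixel-integrated Gaussian point-spread function
#'
#' Evaluates the mass of a symmetric 2-D Gaussian PSF integrated over pixel
#' areas on a window around a (possibly sub-pixel) center.
#'
#' @param sigma_px PSF sigma in pixels.
#' @param center Numeric `(row, col)` center, may be fractional.
#' @param radius Half-width of the stamp window in pixels.
#' @return A `(2*radius+1)^2` matrix summing to the PSF mass inside the window
#'   (close to 1 for `radius >~ 4*sigma_px`), plus attributes `rows`, `cols`
#'   with the absolute pixel indices.
#' @keywords internal
psf_stamp <- function(sigma_px, center = c(0, 0), radius = 5L) {
  rows <- (round(center[1]) - radius):(round(center[1]) + radius)
  cols <- (round(center[2]) - radius):(round(center[2]) + radius)
  # pixel i covers [i - 0.5, i + 0.5]
  mass <- function(idx, mu) stats::pnorm(idx + 0.5, mu, sigma_px) -
    stats::pnorm(idx - 0.5, mu, sigma_px)
  m <- outer(mass(rows, center[1]), mass(cols, center[2]))
  attr(m, "rows") <- rows
  attr(m, "cols") <- cols
  m
}

#' Fraction of spot intensity captured by a centered square ROI
#'
#' Analytic integral of the Gaussian PSF over an `roi_px` x `roi_px` window
#' centered on the spot.
#'
#' @param psf_sigma_nm PSF sigma in nm.
#' @param pixel_nm Pixel size in nm.
#' @param roi_px ROI side length in pixels (default 5).
#' @return Capture fraction in (0, 1).
#' @export
roi_capture_fraction <- function(psf_sigma_nm, pixel_nm = 100, roi_px = 5L) {
  s <- psf_sigma_nm / pixel_nm
  half <- roi_px / 2
  (stats::pnorm(half, 0, s) - stats::pnorm(-half, 0, s))^2
}

#' Smooth multiplicative illumination profile
#'
#' Radially symmetric Gaussian falloff, peak-normalized to 1 at the field
#' center — the low-spatial-frequency unevenness the rolling-ball correction
#' removes.
#'
#' @param dims `(rows, cols)` field size.
#' @param sigma_frac Gaussian sigma as a fraction of the mean field dimension.
#' @return A `dims` matrix in (0, 1].
#' @export
illumination_profile <- function(dims, sigma_frac = 1.5) {
  ctr <- (dims + 1) / 2
  s <- sigma_frac * mean(dims)
  r2 <- outer((seq_len(dims[1]) - ctr[1])^2, (seq_len(dims[2]) - ctr[2])^2, `+`)
  exp(-r2 / (2 * s^2))
}

#' Apply the EMCCD readout model to an expected-intensity image
#'
#' Expected ADU are converted to expected photons at the gain, Poisson photon
#' shot noise is drawn, the electron-multiplying register is modelled as a
#' gamma draw `Gamma(shape = photons, scale = gain)`, and Gaussian read noise
#' is added. The output mean equals the input.
#'
#' @param expected_adu Non-negative numeric array of expected intensities (ADU).
#' @param gain EMCCD gain (ADU per photon).
#' @param read_noise Read noise SD (ADU).
#' @return Array of the same shape with noise applied.
#' @export
emccd_readout <- function(expected_adu, gain = 30, read_noise = 10) {
  lambda <- pmax(expected_adu, 0) / gain
  n <- rpois(length(lambda), lambda)
  out <- numeric(length(n))
  pos <- n > 0L
  out[pos] <- rgamma(sum(pos), shape = n[pos], scale = gain)
  out <- out + rnorm(length(out), 0, read_noise)
  dim(out) <- dim(expected_adu)
  out
}

#' Place spot centers uniformly with a minimum pairwise separation
#'
#' @param n Number of spots.
#' @param dims `(rows, cols)` field size in pixels.
#' @param min_sep_px Minimum center-to-center distance in pixels.
#' @param margin Margin kept free at the field edge, in pixels.
#' @param max_tries Rejection-sampling budget.
#' @return Tibble `spot_id`, `row`, `col` (fractional pixel coordinates).
#'   Fewer than `n` rows (with a warning) if the field cannot hold them.
#' @export
place_spots <- function(n, dims, min_sep_px = 20, margin = 8, max_tries = 200L) {
  rows <- numeric(0); cols <- numeric(0)
  tries <- 0L
  while (length(rows) < n && tries < max_tries * n) {
    tries <- tries + 1L
    r <- runif(1, 1 + margin, dims[1] - margin)
    c_ <- runif(1, 1 + margin, dims[2] - margin)
    if (!length(rows) || min((rows - r)^2 + (cols - c_)^2) >= min_sep_px^2) {
      rows <- c(rows, r); cols <- c(cols, c_)
    }
  }
  if (length(rows) < n)
    warn(sprintf("placed %d of %d spots before exhausting tries", length(rows), n))
  tibble(spot_id = seq_along(rows), row = rows, col = cols)
}

# Add amplitude * PSF stamps to a frame in place; spots is a tibble with
# row/col; amplitudes one value per spot.
add_spots_to_frame <- function(frame, spots, amplitudes, sigma_px, radius = 5L) {
  for (i in seq_len(nrow(spots))) {
    a <- amplitudes[i]
    if (a == 0) next
    st <- psf_stamp(sigma_px, c(spots$row[i], spots$col[i]), radius)
    rr <- attr(st, "rows"); cc <- attr(st, "cols")
    ok_r <- rr >= 1 & rr <= nrow(frame)
    ok_c <- cc >= 1 & cc <= ncol(frame)
    frame[rr[ok_r], cc[ok_c]] <- frame[rr[ok_r], cc[ok_c]] + a * st[ok_r, ok_c]
  }
  frame
}

# Expected per-pixel background at time t (ADU), before the illumination
# profile is applied.
background_level <- function(cfg, t) {
  cfg$bg_amp1 * exp(-cfg$bg_k1 * t) + cfg$bg_amp2 * exp(-cfg$bg_k2 * t) +
    cfg$bg_offset
}

#' Render a single-channel spot field movie
#'
#' Renders `n_frames` frames of a field containing the given spots at the
#' given per-frame amplitudes, over a decaying autofluorescent background
#' shaped by the illumination profile, through the EMCCD readout model.
#'
#' @param spots Tibble with `row`, `col` (from [place_spots()]).
#' @param amplitudes Matrix `(n_frames, n_spots)` of expected spot intensities
#'   (ADU, total over the PSF), or a single vector recycled over frames.
#' @param config A [sim_config()]; supplies field size, PSF, background,
#'   illumination, and camera noise parameters.
#' @param n_frames Number of frames.
#' @param frame_times Times (s) of the frames; default
#'   `(0:(n_frames-1)) * config$frame_interval_s`.
#' @param channel Channel tag for the output stack.
#' @return A `movie_stack`.
#' @export
render_spot_field <- function(spots, amplitudes, config, n_frames,
                              frame_times = NULL, channel = "venus") {
  dims <- config$field_size_px
  sigma_px <- config$psf_sigma_nm / config$pixel_nm
  if (is.null(frame_times))
    frame_times <- (seq_len(n_frames) - 1) * config$frame_interval_s
  if (is.vector(amplitudes))
    amplitudes <- matrix(amplitudes, n_frames, length(amplitudes), byrow = TRUE)
  illum <- illumination_profile(dims, config$illum_sigma_frac)
  out <- array(0, dim = c(dims, n_frames))
  for (f in seq_len(n_frames)) {
    expected <- matrix(background_level(config, frame_times[f]), dims[1], dims[2])
    expected <- add_spots_to_frame(expected, spots, amplitudes[f, ], sigma_px)
    expected <- expected * illum
    out[, , f] <- emccd_readout(expected, config$emccd_gain, config$read_noise)
  }
  movie_stack(out, frame_interval_s = if (n_frames > 1)
    diff(frame_times[1:2]) else config$frame_interval_s, channel = channel)
}

#' Simulate an interleaved two-camera virtual movie
#'
#' The full virtual experiment: sparse immobilized multi-subunit green spots
#' with stepwise photobleaching, stochastic per-subunit red-ligand
#' binding/unbinding, green-to-mixed-channel spectral leakage, decaying
#' autofluorescent background, uneven illumination and EMCCD noise. Returns
#' the two synchronized camera stacks with alternating-excitation frame
#' parity (odd recorded frames blue-excited, even frames olive-excited, with
#' the default `parity = "odd"`), plus the complete ground truth.
#'
#' @param config A [sim_config()].
#' @param parity `"odd"` or `"even"`: which recorded frames are blue-excited.
#' @return A list of class `virtual_movie` with `green_cam` and `red_cam`
#'   `movie_stack`s, the `config`, `parity`, and `truth`: a list with `spots`
#'   (positions), `green_events`/`red_events` (per-spot event tables),
#'   `green_signal`/`red_signal` (expected ADU per spot per recorded frame),
#'   `red_occupancy` (visible ligand count per spot per recorded frame).
#' @export
simulate_movie <- function(config, parity = c("odd", "even")) {
  parity <- match.arg(parity)
  cfg <- config
  with_seed(cfg$seed, {
    dims <- cfg$field_size_px
    min_sep_px <- cfg$min_separation_um * 1000 / cfg$pixel_nm
    spots <- place_spots(cfg$n_spots, dims, min_sep_px)
    n_rec <- cfg$n_frames
    t_rec <- (seq_len(n_rec) - 1) * cfg$frame_interval_s
    blue <- if (parity == "odd") seq(1L, n_rec, 2L) else seq(2L, n_rec, 2L)
    is_blue <- seq_len(n_rec) %in% blue

    n_spots <- nrow(spots)
    green_sig <- matrix(0, n_rec, max(n_spots, 1L))
    red_occ <- matrix(0L, n_rec, max(n_spots, 1L))
    green_events <- list(); red_events <- list()

    for (i in seq_len(n_spots)) {
      stair <- simulate_bleach_staircase(
        cfg$subunits, cfg$kpb_green_s, cfg$step_mean, cfg$step_sd,
        noise_sd = 0, duration_s = max(t_rec) + cfg$frame_interval_s,
        dt_s = cfg$frame_interval_s, dark_fraction = cfg$dark_fraction)
      green_sig[, i] <- stair$intensity[seq_len(n_rec)]
      green_events[[i]] <- attr(stair, "events") |> mutate(spot_id = i)

      traj <- simulate_binding_trajectory(
        cfg$subunits, cfg$cam_conc, cfg$kon_per_M_s, cfg$koff_s,
        cfg$kpb_red_s, duration_s = max(t_rec) + cfg$frame_interval_s,
        dt_s = cfg$frame_interval_s)
      red_occ[, i] <- traj$occupancy$n_bound[seq_len(n_rec)]
      red_events[[i]] <- traj$events |> mutate(spot_id = i)
    }
    red_sig <- red_occ * cfg$step_mean

    green_frames <- array(0, dim = c(dims, n_rec))
    red_frames <- array(0, dim = c(dims, n_rec))
    sigma_px <- cfg$psf_sigma_nm / cfg$pixel_nm
    illum <- illumination_profile(dims, cfg$illum_sigma_frac)
    dark_level <- 2  # camera offset on non-excited frames (ADU)

    for (f in seq_len(n_rec)) {
      t <- t_rec[f]
      bg <- background_level(cfg, t)
      if (is_blue[f]) {
        gexp <- matrix(bg, dims[1], dims[2])
        if (n_spots) gexp <- add_spots_to_frame(gexp, spots, green_sig[f, ], sigma_px)
        gexp <- gexp * illum
        # red camera during blue excitation: leakage + FRET + background
        rexp_ <- matrix(bg * 0.5, dims[1], dims[2])
        if (n_spots) {
          mixed_amp <- cfg$leak_fraction * green_sig[f, ] +
            cfg$fret_per_bound * red_occ[f, ]
          rexp_ <- add_spots_to_frame(rexp_, spots, mixed_amp, sigma_px)
        }
        rexp_ <- rexp_ * illum
      } else {
        gexp <- matrix(dark_level, dims[1], dims[2])  # blank record
        rexp_ <- matrix(bg * 0.3, dims[1], dims[2])
        if (n_spots) rexp_ <- add_spots_to_frame(rexp_, spots, red_sig[f, ], sigma_px)
        rexp_ <- rexp_ * illum
      }
      green_frames[, , f] <- emccd_readout(gexp, cfg$emccd_gain, cfg$read_noise)
      red_frames[, , f] <- emccd_readout(rexp_, cfg$emccd_gain, cfg$read_noise)
    }

    structure(list(
      green_cam = movie_stack(green_frames, cfg$frame_interval_s, "green_cam"),
      red_cam = movie_stack(red_frames, cfg$frame_interval_s, "red_cam"),
      config = cfg, parity = parity,
      truth = list(
        spots = spots,
        green_events = list_rbind(green_events),
        red_events = list_rbind(red_events),
        green_signal = green_sig, red_signal = red_sig,
        red_occupancy = red_occ)
    ), class = "virtual_movie")
  })
}

#' @export
print.virtual_movie <- function(x, ...) {
  cat(sprintf("<virtual_movie> %d spots, %d recorded frames/camera, parity %s\n",
              nrow(x$truth$spots), n_frames(x$green_cam), x$parity))
  invisible(x)
}

#' Write a virtual movie to disk
#'
#' Writes the two camera stacks as multi-page 16-bit TIFFs, the configuration
#' as a JSON sidecar, and the ground-truth event tables as CSV.
#'
#' @param movie A `virtual_movie` from [simulate_movie()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_virtual_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_movie_tiff(movie$green_cam, file.path(dir, "green_cam.tif"))
  write_movie_tiff(movie$red_cam, file.path(dir, "red_cam.tif"))
  cfg <- movie$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- bind_rows(
    movie$truth$green_events |> mutate(channel = "venus", amplitude = NULL),
    movie$truth$red_events |> mutate(channel = "rhodamine"))
  utils::write.csv(truth[, c("spot_id", "time_s", "delta", "cause", "channel")] |>
                     (\(d) {d$cause[is.na(d$cause)] <- "photobleach"; d})(),
                   file.path(dir, "truth_events.csv"), row.names = FALSE)
  utils::write.csv(movie$truth$spots, file.path(dir, "truth_spots.csv"),
                   row.names = FALSE)
  invisible(dir)
}
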