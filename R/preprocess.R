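#' Spatially register a movie stack
#'
#' Applies a rigid transform (rotation about the field center, then a
#' translation) to every frame with bilinear interpolation, as done when the
#' two cameras are registered with parameters pre-calibrated on multicolor
#' beads. Out-of-field pixels become `NA` and are treated as masked by all
#' downstream operations.
#'
#' @param stack A `movie_stack`.
#' @param rotation_deg Rotation in degrees (counter-clockwise, about the
#'   field center).
#' @param translation_px Length-2 numeric `(rows, cols)` translation in
#'   pixels: positive values move content toward larger indices.
#' @return The registered `movie_stack`.
#' @export
register_stack <- function(stack, rotation_deg = 0, translation_px = c(0, 0)) {
  check_number(rotation_deg, "rotation_deg")
  if (length(translation_px) != 2L || any(!is.finite(translation_px)))
    abort("`translation_px` must be two finite numbers (rows, cols).")
  if (rotation_deg == 0 && all(translation_px == 0)) return(stack)
  d <- dim(stack$frames)[1:2]
  ctr <- (d + 1) / 2
  th <- rotation_deg * pi / 180
  # inverse mapping: for each output pixel find its source location
  out_idx <- cbind(rep(seq_len(d[1]), times = d[2]),
                   rep(seq_len(d[2]), each = d[1]))
  shifted <- sweep(out_idx, 2, ctr + translation_px)
  src <- cbind(cos(th) * shifted[, 1] + sin(th) * shifted[, 2],
               -sin(th) * shifted[, 1] + cos(th) * shifted[, 2])
  src <- sweep(src, 2, ctr, `+`)
  r0 <- floor(src[, 1]); c0 <- floor(src[, 2])
  fr <- src[, 1] - r0; fc <- src[, 2] - c0
  inside <- r0 >= 1 & r0 + 1 <= d[1] & c0 >= 1 & c0 + 1 <= d[2]
  map_frames(stack, function(f) {
    out <- rep(NA_real_, length(f))
    i <- inside
    i00 <- cbind(r0[i], c0[i]); i10 <- cbind(r0[i] + 1L, c0[i])
    i01 <- cbind(r0[i], c0[i] + 1L); i11 <- cbind(r0[i] + 1L, c0[i] + 1L)
    out[i] <- f[i00] * (1 - fr[i]) * (1 - fc[i]) +
      f[i10] * fr[i] * (1 - fc[i]) +
      f[i01] * (1 - fr[i]) * fc[i] +
      f[i11] * fr[i] * fc[i]
    matrix(out, d[1], d[2])
  })
}

#' Deinterleave the two camera records into emission channels
#'
#' Alternating two-laser excitation interleaves the channels in time: on
#' blue-excited frames the green camera records the Venus channel and the red
#' camera a mixed leakage + FRET signal; on olive-excited frames the red
#' camera records the rhodamine channel and the green camera records nothing
#' (the blank, returned but flagged for discard). Each output channel has the
#' frame interval doubled.
#'
#' @param green_cam,red_cam `movie_stack`s with equal frame counts.
#' @param parity `"odd"` or `"even"`: which recorded frames (1-based) are
#'   blue-excited.
#' @return List with `movie_stack`s `venus`, `mixed`, `rhodamine`, `blank`;
#'   `blank` carries attribute `discard = TRUE`.
#' @export
deinterleave <- function(green_cam, red_cam, parity = c("odd", "even")) {
  parity <- match.arg(parity)
  n <- n_frames(green_cam)
  if (n != n_frames(red_cam))
    abort("green and red camera stacks must have the same frame count.")
  blue <- if (parity == "odd") seq(1L, n, 2L) else seq(2L, n, 2L)
  olive <- setdiff(seq_len(n), blue)
  take <- function(stack, idx, channel) {
    out <- movie_stack(stack$frames[, , idx, drop = FALSE],
                       frame_interval_s = 2 * stack$frame_interval_s,
                       channel = channel)
    out
  }
  blank <- take(green_cam, olive, "blank")
  attr(blank, "discard") <- TRUE
  list(venus = take(green_cam, blue, "venus"),
       mixed = take(red_cam, blue, "mixed"),
       rhodamine = take(red_cam, olive, "rhodamine"),
       blank = blank)
}

#' Re-interleave deinterleaved channels into camera records
#'
#' Inverse of [deinterleave()]; mainly used for round-trip validation.
#'
#' @param channels List as returned by [deinterleave()].
#' @param parity Parity used when deinterleaving.
#' @return List with `green_cam` and `red_cam` `movie_stack`s.
#' @export
interleave <- function(channels, parity = c("odd", "even")) {
  parity <- match.arg(parity)
  nb <- n_frames(channels$venus); no <- n_frames(channels$rhodamine)
  n <- nb + no
  blue <- if (parity == "odd") seq(1L, n, 2L) else seq(2L, n, 2L)
  olive <- setdiff(seq_len(n), blue)
  d <- dim(channels$venus$frames)[1:2]
  g <- array(0, dim = c(d, n)); r <- array(0, dim = c(d, n))
  g[, , blue] <- channels$venus$frames
  g[, , olive] <- channels$blank$frames
  r[, , blue] <- channels$mixed$frames
  r[, , olive] <- channels$rhodamine$frames
  dt <- channels$venus$frame_interval_s / 2
  list(green_cam = movie_stack(g, dt, "green_cam"),
       red_cam = movie_stack(r, dt, "red_cam"))
}

#' Estimate the green-to-mixed spectral leakage fraction
#'
#' From a ligand-free record (immobilized green molecules only), the mixed
#' channel contains only leakage of the Venus emission. The estimate is the
#' ratio of locally background-subtracted, ROI-integrated mixed to Venus
#' intensity, aggregated as the median over all (spot, frame) pairs.
#'
#' @param venus,mixed `movie_stack`s of the two channels.
#' @param spots Spot table with `row`, `col` (e.g. from [detect_spots()]).
#' @param halfwidth ROI half-width in pixels (default 2 for a 5x5 ROI).
#' @param min_intensity Minimum ROI-integrated Venus intensity for a
#'   (spot, frame) pair to enter the median; guards the ratio's denominator.
#' @return The leakage fraction estimate, with attribute `n_pairs`.
#' @export
estimate_leakage <- function(venus, mixed, spots, halfwidth = 2L,
                             min_intensity = NULL) {
  if (!nrow(spots)) abort("no spots supplied for leakage estimation.")
  v <- roi_sums(venus, spots, halfwidth, local_bg = TRUE)
  m <- roi_sums(mixed, spots, halfwidth, local_bg = TRUE)
  if (is.null(min_intensity)) {
    # Ratio estimates with a noisy denominator are biased upward at low
    # intensity, so keep only reasonably bright (spot, frame) pairs: above
    # both 5x the trace noise (from first differences, immune to the
    # staircase structure) and 20% of the bright-end intensity.
    noise <- v |>
      summarise(s = robust_sd(diff(.data$intensity)) / sqrt(2),
                .by = "spot_id")
    q95 <- stats::quantile(v$intensity, 0.95, na.rm = TRUE)
    min_intensity <- max(5 * median(noise$s, na.rm = TRUE), 0.2 * q95)
  }
  ok <- is.finite(v$intensity) & is.finite(m$intensity) &
    v$intensity > max(min_intensity, 0)
  if (!any(ok)) abort("Venus ROI intensity too low to define a leakage ratio.")
  est <- median(m$intensity[ok] / v$intensity[ok])
  structure(est, n_pairs = sum(ok))
}

#' Subtract spectral leakage to obtain the FRET channel
#'
#' The residual of the mixed channel after subtracting the leakage fraction
#' of the Venus channel, frame by frame.
#'
#' @param mixed,venus `movie_stack`s with identical geometry and frame count.
#' @param leak_fraction Leakage fraction (default 0.10, the global calibration
#'   used when no ligand-free record is available).
#' @return A `movie_stack` tagged `"fret"`.
#' @export
correct_leakage <- function(mixed, venus, leak_fraction = 0.10) {
  if (!identical(dim(mixed$frames), dim(venus$frames)))
    abort("`mixed` and `venus` must have identical dimensions.")
  check_number(leak_fraction, "leak_fraction", min = 0)
  out <- mixed
  out$frames <- mixed$frames - leak_fraction * venus$frames
  out$channel <- "fret"
  out
}

#' Correct uneven illumination with a rolling-ball background filter
#'
#' Removes low-spatial-frequency intensity variation by subtracting a
#' morphological (grayscale opening with a disc) background, the classic
#' rolling-ball filter. As in ImageJ for large radii, the image is
#' downsampled before the opening and the background upsampled back, which
#' leaves diffraction-limited spots untouched while flattening illumination
#' gradients.
#'
#' @param image 2-D numeric matrix (typically a z-projection).
#' @param radius_px Ball radius in pixels (default 100).
#' @param shrink Downsampling factor before the opening (default 8).
#' @return The corrected matrix, with the estimated background in attribute
#'   `background`.
#' @export
correct_uneven_field <- function(image, radius_px = 100, shrink = 8L) {
  d <- dim(image)
  na_mask <- !is.finite(image)
  img <- image
  if (any(na_mask)) img[na_mask] <- median(image[!na_mask])
  shrink <- max(1L, min(as.integer(shrink), floor(min(d) / 8)))
  r_small <- max(1L, round(radius_px / shrink))
  small <- EBImage::resize(img, w = max(8L, floor(d[1] / shrink)),
                           h = max(8L, floor(d[2] / shrink)))
  brush_size <- min(2L * r_small + 1L, 2L * (min(dim(small)) %/% 2L) - 1L)
  if (brush_size >= 3L) {
    # replicate-pad before the morphology: erosion would otherwise pull the
    # border toward the (zero) out-of-image padding
    pad <- (brush_size - 1L) %/% 2L + 2L
    ds <- dim(small)
    ri <- c(rep(1L, pad), seq_len(ds[1]), rep(ds[1], pad))
    ci <- c(rep(1L, pad), seq_len(ds[2]), rep(ds[2], pad))
    padded <- small[ri, ci]
    kern <- EBImage::makeBrush(brush_size, shape = "disc")
    # EBImage grayscale morphology assumes intensities in [0, 1]
    lo <- min(padded); hi <- max(padded)
    scale <- if (hi > lo) hi - lo else 1
    norm <- (padded - lo) / scale
    bg_pad <- EBImage::gblur(EBImage::opening(norm, kern), sigma = 2) *
      scale + lo
    bg_small <- bg_pad[pad + seq_len(ds[1]), pad + seq_len(ds[2])]
  } else {
    bg_small <- small * 0 + min(small)
  }
  bg <- EBImage::resize(bg_small, w = d[1], h = d[2])
  out <- image - bg
  attr(out, "background") <- bg
  out
}

# ROI-integrated intensities per spot per frame; optional local background
# subtraction from the median of an annulus (box minus inner region).
roi_sums <- function(stack, spots, halfwidth = 2L, local_bg = FALSE,
                     annulus = c(4L, 7L)) {
  d <- dim(stack$frames)
  n <- n_frames(stack)
  tvec <- frame_times(stack)
  res <- vector("list", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    r <- round(spots$row[i]); c_ <- round(spots$col[i])
    rr <- (r - halfwidth):(r + halfwidth)
    cc <- (c_ - halfwidth):(c_ + halfwidth)
    if (min(rr) < 1 || max(rr) > d[1] || min(cc) < 1 || max(cc) > d[2]) {
      res[[i]] <- tibble(spot_id = spots$spot_id[i], frame = seq_len(n),
                         time_s = tvec, intensity = NA_real_)
      next
    }
    block <- stack$frames[rr, cc, , drop = FALSE]
    intensity <- apply(block, 3, sum)
    if (local_bg) {
      ra <- max(1, r - annulus[2]):min(d[1], r + annulus[2])
      ca <- max(1, c_ - annulus[2]):min(d[2], c_ + annulus[2])
      dr_m <- matrix(abs(ra - r), length(ra), length(ca))
      dc_m <- matrix(abs(ca - c_), length(ra), length(ca), byrow = TRUE)
      ring_sel <- !(dr_m <= annulus[1] & dc_m <= annulus[1])
      big <- stack$frames[ra, ca, , drop = FALSE]
      # EMCCD pixel noise is right-skewed, so a median background estimate
      # under-subtracts; the mean is unbiased (spot separation keeps
      # neighbouring PSF tails out of the ring).
      bg_est <- apply(big, 3, function(fr) {
        ring <- fr[ring_sel]
        mean(ring[is.finite(ring)])
      })
      intensity <- intensity - bg_est * (2 * halfwidth + 1)^2
    }
    res[[i]] <- tibble(spot_id = spots$spot_id[i], frame = seq_len(n),
                       time_s = tvec, intensity = intensity)
  }
  list_rbind(res)
}

#' Fit and subtract the autofluorescence decay
#'
#' The per-frame mean background intensity (over non-ROI, unmasked pixels) is
#' fitted to a dual-exponential with a constant offset,
#' `A1 exp(-k1 t) + A2 exp(-k2 t) + C`, and the fitted per-pixel background is
#' subtracted from every pixel — ROI pixels included — in every frame. Falls
#' back to a single exponential plus offset when the dual-exponential fit
#' does not converge.
#'
#' @param stack A `movie_stack`.
#' @param roi_mask Optional logical matrix, `TRUE` on ROI pixels to exclude
#'   from the background fit (the subtraction is still applied everywhere).
#' @return A list: `stack` (corrected), `fit` (tibble with `a1`, `k1`, `a2`,
#'   `k2`, `c0`, `rms`, `model`).
#' @export
correct_autofluorescence <- function(stack, roi_mask = NULL) {
  n <- n_frames(stack)
  if (n < 10L) abort("need at least 10 frames to fit the background decay.")
  t <- frame_times(stack)
  sel <- if (is.null(roi_mask)) rep(TRUE, prod(dim(stack$frames)[1:2])) else
    !as.vector(roi_mask)
  y <- vapply(seq_len(n), function(i) {
    fr <- as.vector(stack$frames[, , i])[sel]
    mean(fr[is.finite(fr)])
  }, numeric(1))
  fit <- fit_dual_exponential(t, y)
  bg <- fit$fitted
  out <- stack
  for (i in seq_len(n)) out$frames[, , i] <- out$frames[, , i] - bg[i]
  list(stack = out,
       fit = tibble(a1 = fit$a1, k1 = fit$k1, a2 = fit$a2, k2 = fit$k2,
                    c0 = fit$c0, rms = fit$rms, model = fit$model))
}

# Dual-exponential + offset least squares with log-linear initialization from
# the early/late thirds of the decay; falls back to single exponential, then
# to a constant.
fit_dual_exponential <- function(t, y) {
  c0_init <- min(y)
  amp <- y - c0_init + 1e-9
  n <- length(t)
  third <- max(2L, floor(n / 3))
  amax <- max(amp)
  loglin <- function(idx) {
    z <- log(pmax(amp[idx], 1e-9 * amax))
    cf <- stats::coef(stats::lm(z ~ t[idx]))
    # clamp to sane ranges: log-linear fits on near-zero tails explode
    c(a = min(max(exp(cf[1]), 1e-3 * amax), 2 * amax),
      k = min(max(-cf[2], 1e-6), 10 / max(diff(range(t)), 1e-9)))
  }
  early <- loglin(seq_len(third)); late <- loglin((n - third + 1):n)
  df <- data.frame(t = t, y = y)
  dual <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-k1 * t) + a2 * exp(-k2 * t) + c0, data = df,
                      start = list(a1 = unname(early["a"]), k1 = unname(early["k"]),
                                   a2 = unname(late["a"]), k2 = unname(late["k"]),
                                   c0 = c0_init),
                      lower = c(0, 0, 0, 0, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(dual)) {
    cf <- stats::coef(dual)
    return(list(a1 = cf[["a1"]], k1 = cf[["k1"]], a2 = cf[["a2"]], k2 = cf[["k2"]],
                c0 = cf[["c0"]], fitted = stats::fitted(dual),
                rms = sqrt(mean(stats::resid(dual)^2)), model = "dual"))
  }
  single <- tryCatch(
    minpack.lm::nlsLM(y ~ a1 * exp(-k1 * t) + c0, data = df,
                      start = list(a1 = unname(early["a"]), k1 = unname(early["k"]),
                                   c0 = c0_init),
                      lower = c(0, 0, -Inf)),
    error = function(e) NULL)
  if (!is.null(single)) {
    cf <- stats::coef(single)
    return(list(a1 = cf[["a1"]], k1 = cf[["k1"]], a2 = 0, k2 = 0,
                c0 = cf[["c0"]], fitted = stats::fitted(single),
                rms = sqrt(mean(stats::resid(single)^2)), model = "single"))
  }
  list(a1 = 0, k1 = 0, a2 = 0, k2 = 0, c0 = mean(y),
       fitted = rep(mean(y), length(y)),
       rms = stats::sd(y), model = "constant")
}
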