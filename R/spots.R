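#' Z-project a movie stack to its temporal mean
#'
#' @param stack A `movie_stack`.
#' @return A 2-D matrix, the pixelwise mean over frames (`NA`s removed
#'   pixelwise).
#' @export
zproject_mean <- function(stack) {
  if (n_frames(stack) == 1L) return(stack$frames[, , 1])
  apply(stack$frames, c(1, 2), function(v) mean(v[is.finite(v)]))
}

#' Laplacian-of-Gaussian spot filter kernel
#'
#' A 7x7 kernel approximating the (negated) Laplacian of a Gaussian, so that
#' bright diffraction-limited blobs give positive responses. The kernel is
#' zero-sum, which makes the response invariant to local background offsets.
#'
#' @param sigma_px Gaussian sigma in pixels (default the PSF sigma, 0.735 px
#'   at 100 nm pixels).
#' @param size Kernel side length (default 7).
#' @return A `size` x `size` matrix.
#' @export
log_kernel <- function(sigma_px = 0.735, size = 7L) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  g <- outer(x, x, function(i, j) {
    r2 <- i^2 + j^2
    (1 - r2 / (2 * sigma_px^2)) * exp(-r2 / (2 * sigma_px^2))
  })
  g - mean(g)
}

#' Detect diffraction-limited spots on a projected image
#'
#' The image is filtered with a 7x7 Laplacian-of-Gaussian kernel; local
#' maxima of the response above a robust threshold (`median + threshold_k *
#' MAD`) become spot candidates, each assigned a 5x5 ROI centered on its
#' (integer) peak pixel. Candidates closer than `min_separation_px` are
#' merged to the brighter one and flagged `overlap`; spots whose ROI integral
#' exceeds `aggregate_cutoff * aggregate_ref` are flagged `aggregate`; ROIs
#' touching the field edge are flagged `edge`.
#'
#' @param image Background-corrected 2-D average image.
#' @param sigma_px LoG sigma in pixels.
#' @param threshold_k Robust threshold multiplier (default 5).
#' @param min_separation_px Minimum center separation (default 5).
#' @param halfwidth ROI half-width (default 2, a 5x5 ROI).
#' @param aggregate_ref Reference intensity of the largest expected assembly
#'   (e.g. calibrated 14-mer ROI intensity); `NULL` disables the flag.
#' @param aggregate_cutoff Multiplier on `aggregate_ref` (default 2).
#' @return Tibble of class `spot_table`: `spot_id`, `row`, `col` (integer
#'   peak), `row_centroid`, `col_centroid` (sub-pixel, QC only), `response`,
#'   `intensity` (5x5 ROI sum on `image`), `edge`, `overlap`, `aggregate`.
#' @export
detect_spots <- function(image, sigma_px = 0.735, threshold_k = 5,
                         min_separation_px = 5, halfwidth = 2L,
                         aggregate_ref = NULL, aggregate_cutoff = 2) {
  d <- dim(image)
  img <- image
  na_mask <- !is.finite(img)
  if (any(na_mask)) img[na_mask] <- median(img[!na_mask])
  resp <- EBImage::filter2(img, log_kernel(sigma_px))
  thr <- median(resp) + threshold_k * stats::mad(resp)
  # local maxima over a 3x3 neighbourhood
  dil <- EBImage::dilate(resp, EBImage::makeBrush(3L, "box"))
  peaks <- which(resp >= dil - 1e-12 & resp > thr & !na_mask, arr.ind = TRUE)
  if (!nrow(peaks)) {
    return(structure(tibble(
      spot_id = integer(0), row = integer(0), col = integer(0),
      row_centroid = numeric(0), col_centroid = numeric(0),
      response = numeric(0), intensity = numeric(0),
      edge = logical(0), overlap = logical(0), aggregate = logical(0)
    ), class = c("spot_table", class(tibble()))))
  }
  pk <- tibble(row = peaks[, 1], col = peaks[, 2],
               response = resp[peaks]) |>
    arrange(desc(.data$response))
  # merge-to-brighter within min_separation
  keep <- rep(TRUE, nrow(pk)); overlap <- rep(FALSE, nrow(pk))
  for (i in seq_len(nrow(pk))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    if (length(prev)) {
      d2 <- (pk$row[prev] - pk$row[i])^2 + (pk$col[prev] - pk$col[i])^2
      if (min(d2) < min_separation_px^2) {
        keep[i] <- FALSE
        overlap[prev[which.min(d2)]] <- TRUE
      }
    }
  }
  pk <- pk[keep, ]
  pk$overlap <- overlap[keep]
  hw <- halfwidth
  pk$edge <- pk$row - hw < 1 | pk$row + hw > d[1] |
    pk$col - hw < 1 | pk$col + hw > d[2]
  roi_int <- function(r, c_, e) {
    if (e) return(NA_real_)
    sum(image[(r - hw):(r + hw), (c_ - hw):(c_ + hw)], na.rm = TRUE)
  }
  pk$intensity <- mapply(roi_int, pk$row, pk$col, pk$edge)
  cen <- function(r, c_, e) {
    if (e) return(c(r, c_))
    w <- img[(r - hw):(r + hw), (c_ - hw):(c_ + hw)]
    w <- w - min(w)
    if (sum(w) <= 0) return(c(r, c_))
    c(sum(((r - hw):(r + hw)) * rowSums(w)) / sum(w),
      sum(((c_ - hw):(c_ + hw)) * colSums(w)) / sum(w))
  }
  cents <- mapply(cen, pk$row, pk$col, pk$edge)
  pk$row_centroid <- cents[1, ]
  pk$col_centroid <- cents[2, ]
  pk$aggregate <- if (!is.null(aggregate_ref))
    !is.na(pk$intensity) & pk$intensity > aggregate_cutoff * aggregate_ref
  else FALSE
  out <- pk |>
    arrange(.data$row, .data$col) |>
    mutate(spot_id = row_number()) |>
    select("spot_id", "row", "col", "row_centroid", "col_centroid",
           "response", "intensity", "edge", "overlap", "aggregate")
  class(out) <- c("spot_table", class(out))
  out
}

#' Extract a per-spot intensity trace
#'
#' Sums the 5x5 ROI around the spot center in every frame.
#'
#' @param stack A `movie_stack`.
#' @param row,col Spot center (integer pixel).
#' @param halfwidth ROI half-width (default 2).
#' @param allow_edge Permit ROIs clipped by the field edge (padded pixels are
#'   ignored); default `FALSE` (error).
#' @return Tibble of class `sm_trace`: `frame`, `time_s`, `intensity`, with
#'   attribute `dt_s` and `channel`.
#' @export
extract_trace <- function(stack, row, col, halfwidth = 2L, allow_edge = FALSE) {
  d <- dim(stack$frames)
  r <- round(row); c_ <- round(col)
  rr <- (r - halfwidth):(r + halfwidth)
  cc <- (c_ - halfwidth):(c_ + halfwidth)
  if (min(rr) < 1 || max(rr) > d[1] || min(cc) < 1 || max(cc) > d[2]) {
    if (!allow_edge) abort("ROI extends past the field edge (see `allow_edge`).")
    rr <- rr[rr >= 1 & rr <= d[1]]
    cc <- cc[cc >= 1 & cc <= d[2]]
  }
  block <- stack$frames[rr, cc, , drop = FALSE]
  out <- tibble(frame = seq_len(n_frames(stack)),
                time_s = frame_times(stack),
                intensity = apply(block, 3, function(m) sum(m, na.rm = TRUE)))
  attr(out, "dt_s") <- stack$frame_interval_s
  attr(out, "channel") <- stack$channel
  class(out) <- c("sm_trace", class(out))
  out
}

#' Extract traces for a table of spots
#'
#' @param stack A `movie_stack`.
#' @param spots A spot table with `spot_id`, `row`, `col`.
#' @param ... Passed to [extract_trace()].
#' @return Long tibble: `spot_id`, `frame`, `time_s`, `intensity`, `channel`.
#' @export
extract_traces <- function(stack, spots, ...) {
  res <- map(seq_len(nrow(spots)), function(i) {
    tr <- extract_trace(stack, spots$row[i], spots$col[i], ...)
    tibble(spot_id = spots$spot_id[i], frame = tr$frame, time_s = tr$time_s,
           intensity = tr$intensity)
  })
  out <- list_rbind(res)
  out$channel <- stack$channel
  attr(out, "dt_s") <- stack$frame_interval_s
  out
}
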