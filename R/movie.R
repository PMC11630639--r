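#' Movie stack container
#'
#' A `movie_stack` wraps a time series of fluorescence frames together with
#' the acquisition metadata the downstream corrections need: the per-frame
#' interval and a channel tag. Pixel values are stored as doubles; corrected
#' stacks may legitimately contain negative values (they arise from leakage
#' and background subtraction) and masked pixels are `NA`.
#'
#' @param frames 3-D numeric array `(rows, cols, frames)`, or a matrix for a
#'   single frame.
#' @param frame_interval_s Time between recorded frames in seconds.
#' @param channel Channel tag, one of `"green_cam"`, `"red_cam"`, `"venus"`,
#'   `"rhodamine"`, `"mixed"`, `"fret"`, `"blank"`.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_interval_s = 0.1, channel = "green_cam") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort("`frames` must be a (rows, cols, frames) array.")
  check_number(frame_interval_s, "frame_interval_s", min = 0, allow_zero = FALSE)
  channel <- match.arg(channel, c("green_cam", "red_cam", "venus", "rhodamine",
                                  "mixed", "fret", "blank"))
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s, channel = channel),
    class = "movie_stack"
  )
}

#' @export
dim.movie_stack <- function(x) dim(x$frames)

#' Number of frames in a movie stack
#' @param x A `movie_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$frames)[3L]

#' Frame acquisition times
#'
#' Times are zero-based: frame `i` was recorded at `(i - 1) * frame_interval_s`.
#'
#' @param x A `movie_stack`.
#' @return Numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) * x$frame_interval_s

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %s, %d x %d px, %d frames @ %.3g s/frame\n",
              x$channel, d[1], d[2], d[3], x$frame_interval_s))
  invisible(x)
}

# Apply a per-frame function, keeping metadata.
map_frames <- function(x, f) {
  out <- x
  for (i in seq_len(n_frames(x))) out$frames[, , i] <- f(x$frames[, , i])
  out
}

#' Write a movie stack as a multi-page 16-bit TIFF
#'
#' Intensities are clipped to `[0, 2^16 - 1]` and rounded; `NA` pixels are
#' written as 0. Requires the `tiff` package.
#'
#' @param x A `movie_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("Writing TIFF requires the `tiff` package.")
  pages <- lapply(seq_len(n_frames(x)), function(i) {
    fr <- x$frames[, , i]
    fr[!is.finite(fr)] <- 0
    pmin(pmax(round(fr), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a movie stack
#'
#' @param path TIFF file path.
#' @param frame_interval_s Time between frames in seconds.
#' @param channel Channel tag (see [movie_stack()]).
#' @return A `movie_stack` with intensities on the original 16-bit scale.
#' @export
read_movie_tiff <- function(path, frame_interval_s = 0.1, channel = "green_cam") {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("Reading TIFF requires the `tiff` package.")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * 65535
  movie_stack(frames, frame_interval_s = frame_interval_s, channel = channel)
}
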