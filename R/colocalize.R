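#' Shifted cross-correlation matrix between two channel projections
#'
#' Computes the Pearson correlation between `image_a` and `image_b`
#' translated by every integer shift in `[-max_shift, max_shift]^2` (a 9x9
#' grid at the default +/- 4 px), on the overlapping unmasked pixels. The
#' peak value measures global colocalization; ties are broken toward the
#' smaller shift magnitude.
#'
#' @param image_a,image_b Equal-shape 2-D matrices (projected mean images);
#'   `NA` pixels are excluded pairwise.
#' @param max_shift Maximum shift in pixels (default 4).
#' @return An object of class `cc_matrix`: list with `grid` (tibble `drow`,
#'   `dcol`, `cc`), `peak_cc`, `peak_shift` (c(drow, dcol)).
#' @export
cc_matrix <- function(image_a, image_b, max_shift = 4L) {
  if (!identical(dim(image_a), dim(image_b)))
    abort("images must have identical dimensions.")
  d <- dim(image_a)
  shifts <- expand.grid(drow = -max_shift:max_shift, dcol = -max_shift:max_shift)
  cc <- numeric(nrow(shifts))
  for (i in seq_len(nrow(shifts))) {
    dr <- shifts$drow[i]; dc <- shifts$dcol[i]
    # peak at (dr, dc) means b is displaced by (dr, dc) relative to a:
    # b[r, c] ~ a[r - dr, c - dc]
    rb <- max(1, 1 + dr):min(d[1], d[1] + dr)
    cb <- max(1, 1 + dc):min(d[2], d[2] + dc)
    b <- image_b[rb, cb]
    a <- image_a[rb - dr, cb - dc]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      abort("cross-correlation undefined: constant or empty overlap region.")
    cc[i] <- stats::cor(a[ok], b[ok])
  }
  ord <- order(-cc, shifts$drow^2 + shifts$dcol^2)
  peak <- ord[1]
  structure(list(
    grid = tibble(drow = shifts$drow, dcol = shifts$dcol, cc = cc),
    peak_cc = cc[peak],
    peak_shift = c(shifts$drow[peak], shifts$dcol[peak])
  ), class = "cc_matrix")
}

#' @export
print.cc_matrix <- function(x, ...) {
  cat(sprintf("<cc_matrix> peak CC = %.4f at shift (%d, %d)\n",
              x$peak_cc, x$peak_shift[1], x$peak_shift[2]))
  invisible(x)
}

#' Colocalization summary across the three channel pairs
#'
#' Peak shifted cross-correlations of the green (Venus) projection with the
#' red (rhodamine) projection, and of the FRET projection with each.
#'
#' @param venus,rhodamine,fret Projected mean images (FRET optional).
#' @param max_shift Maximum shift in pixels.
#' @return List with `cc_gr`, `cc_gfret`, `cc_rfret` (`cc_matrix` objects;
#'   FRET entries `NULL` when `fret` is missing) and `summary`, a one-row
#'   tibble of the peak values.
#' @export
colocalization_summary <- function(venus, rhodamine, fret = NULL,
                                   max_shift = 4L) {
  gr <- cc_matrix(venus, rhodamine, max_shift)
  gf <- if (!is.null(fret)) cc_matrix(venus, fret, max_shift) else NULL
  rf <- if (!is.null(fret)) cc_matrix(rhodamine, fret, max_shift) else NULL
  list(cc_gr = gr, cc_gfret = gf, cc_rfret = rf,
       summary = tibble(
         cc_gr = gr$peak_cc,
         cc_gfret = if (is.null(gf)) NA_real_ else gf$peak_cc,
         cc_rfret = if (is.null(rf)) NA_real_ else rf$peak_cc,
         peak_drow = gr$peak_shift[1], peak_dcol = gr$peak_shift[2]))
}
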