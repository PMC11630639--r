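make_stack <- function(m, k = 3L) {
  movie_stack(array(rep(m, k), dim = c(dim(m), k)), 0.1, "green_cam")
}

test_that("registration with identity parameters is exact", {
  img <- matrix(runif(32 * 32), 32, 32)
  st <- make_stack(img, 2L)
  expect_identical(register_stack(st, 0, c(0, 0))$frames, st$frames)
})

test_that("translation moves an impulse by the requested offset", {
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  st <- movie_stack(img)
  out <- register_stack(st, 0, c(2, -3))$frames[, , 1]
  w <- which(out == max(out, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(as.integer(w), c(19L, 14L))
  # centroid displacement accurate to 0.1 px
  tot <- sum(out, na.rm = TRUE)
  out0 <- out; out0[is.na(out0)] <- 0
  cen <- c(sum(row(out0) * out0), sum(col(out0) * out0)) / tot
  expect_equal(cen, c(19, 14), tolerance = 0.1)
})

test_that("registration round-trips on smooth images", {
  img <- outer(1:48, 1:48, function(i, j) sin(i / 6) + cos(j / 7))
  st <- movie_stack(img)
  fwd <- register_stack(st, 5, c(1.5, -2))
  # invert: undo translation first, then the rotation
  back <- register_stack(register_stack(fwd, 0, -c(1.5, -2)), -5, c(0, 0))
  ok <- !is.na(back$frames[, , 1])
  expect_gt(mean(ok), 0.7)
  expect_lt(max(abs(back$frames[, , 1][ok] - img[ok])), 0.08)
})

test_that("deinterleaving slices frames by excitation parity", {
  d <- c(8L, 8L)
  g <- array(0, dim = c(d, 6L)); r <- array(0, dim = c(d, 6L))
  # distinct constant value per (camera, excitation) pair; odd frames blue
  g[, , c(1, 3, 5)] <- 11; g[, , c(2, 4, 6)] <- 22
  r[, , c(1, 3, 5)] <- 33; r[, , c(2, 4, 6)] <- 44
  ch <- deinterleave(movie_stack(g, 0.1, "green_cam"),
                     movie_stack(r, 0.1, "red_cam"), parity = "odd")
  expect_true(all(ch$venus$frames == 11))
  expect_true(all(ch$blank$frames == 22))
  expect_true(all(ch$mixed$frames == 33))
  expect_true(all(ch$rhodamine$frames == 44))
  expect_equal(n_frames(ch$venus), 3L)
  expect_equal(ch$venus$frame_interval_s, 0.2)
  expect_true(isTRUE(attr(ch$blank, "discard")))
  # round trip
  back <- interleave(ch, parity = "odd")
  expect_equal(back$green_cam$frames, g)
  expect_equal(back$red_cam$frames, r)
  # frame-count mismatch is an error
  expect_error(deinterleave(movie_stack(g, 0.1, "green_cam"),
                            movie_stack(r[, , 1:4], 0.1, "red_cam")),
               "frame count")
})

test_that("leakage subtraction is exact algebra", {
  d <- c(16L, 16L)
  venus <- movie_stack(array(runif(prod(d) * 4, 0, 100), dim = c(d, 4L)),
                       0.2, "venus")
  fret_true <- array(runif(prod(d) * 4, 0, 5), dim = c(d, 4L))
  mixed <- movie_stack(0.1 * venus$frames + fret_true, 0.2, "mixed")
  fret <- correct_leakage(mixed, venus, 0.10)
  expect_equal(fret$frames, fret_true, tolerance = 1e-10)
  expect_equal(fret$channel, "fret")
  # leak_fraction = 0 returns the mixed channel unchanged
  expect_equal(correct_leakage(mixed, venus, 0)$frames, mixed$frames)
  expect_error(correct_leakage(movie_stack(fret_true[, , 1:2], 0.2, "mixed"),
                               venus), "identical dimensions")
})

test_that("corrections are linear per frame", {
  d <- c(16L, 16L)
  a <- array(runif(prod(d) * 3, 0, 50), dim = c(d, 3L))
  b <- array(runif(prod(d) * 3, 0, 50), dim = c(d, 3L))
  va <- movie_stack(a, 0.2, "venus"); vb <- movie_stack(b, 0.2, "venus")
  vs <- movie_stack(a + b, 0.2, "venus")
  mx <- movie_stack(a * 0.5, 0.2, "mixed")
  lhs <- correct_leakage(mx, vs, 0.1)$frames
  rhs <- correct_leakage(mx, va, 0.1)$frames +
    correct_leakage(movie_stack(array(0, dim = c(d, 3L)), 0.2, "mixed"),
                    vb, 0.1)$frames
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("rolling-ball correction flattens backgrounds and keeps spots", {
  # flat image -> ~0 everywhere
  flat <- matrix(50, 128, 128)
  out <- correct_uneven_field(flat, radius_px = 100)
  expect_lt(max(abs(out)), 1e-6)
  # flat + one PSF spot: spot integral preserved within 5%
  img <- matrix(20, 128, 128)
  st <- tirfkin:::psf_stamp(0.735, c(64, 64), 5L)
  img[attr(st, "rows"), attr(st, "cols")] <-
    img[attr(st, "rows"), attr(st, "cols")] + 3000 * st
  cor1 <- correct_uneven_field(img, radius_px = 100)
  roi <- cor1[62:66, 62:66]
  expect_equal(sum(roi), 3000 * roi_capture_fraction(73.5, 100),
               tolerance = 0.05)
  # slowly varying gradient removed: residual RMS < 5% of amplitude
  grad <- outer(seq(0, 40, length.out = 128), seq(0, 20, length.out = 128), `+`)
  cor2 <- correct_uneven_field(grad + img, radius_px = 100)
  bgres <- cor2[-(55:75), -(55:75)]
  expect_lt(sqrt(mean(bgres^2)), 0.05 * 60)
})

test_that("autofluorescence correction recovers injected decay parameters", {
  d <- c(24L, 24L)
  tt <- (0:149) * 0.2
  truth <- 30 * exp(-0.5 * tt) + 12 * exp(-0.05 * tt) + 8
  set.seed(9)
  fr <- array(rep(truth, each = prod(d)) + rnorm(prod(d) * 150, 0, 2),
              dim = c(d, 150L))
  st <- movie_stack(fr, 0.2, "venus")
  af <- correct_autofluorescence(st)
  expect_equal(af$fit$model, "dual")
  ks <- sort(c(af$fit$k1, af$fit$k2), decreasing = TRUE)
  expect_equal(ks[1], 0.5, tolerance = 0.1)
  expect_equal(ks[2], 0.05, tolerance = 0.1)
  expect_equal(af$fit$c0, 8, tolerance = 0.1)
  # constant background: amplitudes ~ 0, offset recovered, mean residual ~ 0
  fr2 <- array(40 + rnorm(prod(d) * 30, 0, 1), dim = c(d, 30L))
  af2 <- correct_autofluorescence(movie_stack(fr2, 0.2, "venus"))
  expect_equal(af2$fit$a1 + af2$fit$a2 + af2$fit$c0, 40, tolerance = 0.025)
  expect_lt(abs(mean(af2$stack$frames)), 0.2)
  expect_error(correct_autofluorescence(movie_stack(fr2[, , 1:5], 0.2, "venus")),
               "10 frames")
})
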