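test_that("occupancy trajectories integrate signed steps anchored at zero", {
  tr <- signed_trace(c(5, 12, 20), c(2000, 2000, -2000), start = 0)
  m <- find_steps(tr, step_params(2000, 600))
  occ <- occupancy_trajectory(m)
  expect_equal(min(occ$n_cam), 0L)
  expect_equal(max(occ$n_cam), 2L)
  expect_equal(occ$n_cam[occ$time_s < 5][1], 0L)
  expect_equal(occ$n_cam[occ$time_s > 25][1], 1L)
  # an all-photobleach record is monotone non-increasing
  m2 <- find_steps(staircase_trace(c(5, 15, 25), amp = 2000),
                   step_params(2000, 600))
  occ2 <- occupancy_trajectory(m2)
  expect_true(all(diff(occ2$n_cam) <= 0))
  expect_equal(occ2$n_cam[1], 3L)
})

test_that("recovered occupancy matches simulator truth frame by frame", {
  set.seed(61)
  ok_frames <- 0L; all_frames <- 0L
  for (r in 1:8) {
    traj <- simulate_binding_trajectory(4, 1e-6, 1e5, 0.05, 0.02,
                                        duration_s = 40, dt_s = 0.2)
    x <- traj$occupancy$n_bound * 2000 +
      rnorm(nrow(traj$occupancy), 0, 300)
    tr <- tibble::tibble(frame = traj$occupancy$frame,
                         time_s = traj$occupancy$time_s, intensity = x)
    attr(tr, "dt_s") <- 0.2
    m <- find_steps(tr, step_params(2000, 600))
    occ <- occupancy_trajectory(m)
    truth <- traj$occupancy$n_bound
    if (min(truth) > 0) next  # anchor undefined without a zero visit
    ok_frames <- ok_frames + sum(occ$n_cam == truth)
    all_frames <- all_frames + length(truth)
  }
  expect_gte(ok_frames / all_frames, 0.9)
})

test_that("Poisson fits are the histogram mean and accept Poisson data", {
  expect_equal(fit_poisson(rep(0L, 50))$lambda, 0)
  set.seed(62)
  x <- rpois(500, 3)
  f <- fit_poisson(x)
  expect_equal(f$lambda, mean(x), tolerance = 1e-12)  # MLE identity
  expect_equal(f$lambda, 3, tolerance = 3 * sqrt(3 / 500) / 3)
  expect_gt(f$gof_p, 0.01)
  # sparse binomial occupancy passes a Poisson goodness-of-fit
  xb <- rbinom(500, 14, 0.05)
  fb <- fit_poisson(xb)
  expect_gt(fb$gof_p, 0.01)
  # histogram input equivalent to vector input
  fh <- fit_poisson(table(x))
  expect_equal(fh$lambda, f$lambda)
})

test_that("two-Poisson mixtures are recovered and simple ones rejected", {
  set.seed(63)
  x <- c(rpois(500, 1), rpois(500, 8))
  f <- fit_two_poisson(x, seed = 1)
  expect_equal(f$model, "two_poisson")
  expect_equal(f$w, 0.5, tolerance = 0.15)
  expect_equal(f$lambda1, 1, tolerance = 0.25)
  expect_equal(f$lambda2, 8, tolerance = 0.15)
  expect_lt(f$delta_aic_vs_single, 0)
  # pure Poisson: AIC favors the single model, flagged fallback
  y <- rpois(500, 2.6)
  fy <- fit_two_poisson(y, seed = 1)
  expect_equal(fy$model, "poisson")
  expect_true(fy$fallback)
})

test_that("subpopulation comparison runs F then Welch t tests", {
  set.seed(64)
  rec_same <- tibble::tibble(s_camkii = c(rnorm(50, 10, 2), rnorm(50, 10, 2)),
                             n_cam = rep(c(0L, 1L), each = 50))
  r1 <- compare_subpopulations(rec_same)
  expect_gt(r1$p_t, 0.05)
  # equal means, unequal variances: small p_F, large p_t
  rec_var <- tibble::tibble(s_camkii = c(rnorm(60, 10, 1), rnorm(60, 10, 3)),
                            n_cam = rep(c(0L, 1L), each = 60))
  r2 <- compare_subpopulations(rec_var)
  expect_lt(r2$p_f, 0.01)
  expect_gt(r2$p_t, 0.05)
  # shifted means are detected
  rec_shift <- tibble::tibble(s_camkii = c(rnorm(50, 8, 2), rnorm(50, 10, 2)),
                              n_cam = rep(c(0L, 1L), each = 50))
  expect_lt(compare_subpopulations(rec_shift)$p_t, 0.01)
  expect_error(compare_subpopulations(
    tibble::tibble(s_camkii = rnorm(10), n_cam = rep(1L, 10))), ">= 3")
})

test_that("cross-check against closed-form test statistics", {
  set.seed(65)
  z <- rnorm(30, 9, 2); p <- rnorm(40, 11, 3)
  rec <- tibble::tibble(s_camkii = c(z, p),
                        n_cam = c(rep(0L, 30), rep(1L, 40)))
  r <- compare_subpopulations(rec)
  f_stat <- var(z) / var(p)
  p_f_manual <- 2 * min(pf(f_stat, 29, 39), 1 - pf(f_stat, 29, 39))
  expect_equal(r$p_f, p_f_manual, tolerance = 1e-9)
  se <- sqrt(var(z) / 30 + var(p) / 40)
  t_stat <- (mean(z) - mean(p)) / se
  df_w <- se^4 / ((var(z) / 30)^2 / 29 + (var(p) / 40)^2 / 39)
  expect_equal(r$p_t, 2 * pt(-abs(t_stat), df_w), tolerance = 1e-9)
})

test_that("stoichiometry filtering separates assemblies by intensity", {
  set.seed(66)
  mono <- 2000
  rec <- tibble::tibble(
    kind = rep(c("dimer", "holo", "aggregate"), times = c(30, 60, 10)),
    intensity = c(rnorm(30, 2 * mono, 0.3 * mono),
                  rnorm(60, 12 * mono, 2 * mono),
                  rnorm(10, 40 * mono, 4 * mono)))
  filt <- stoichiometry_filter(rec, mono, band = c(6, 28))
  expect_gte(mean(filt$kind == "holo"), 0.9)
  expect_gte(sum(filt$kind == "holo") / 60, 0.9)
  ex <- attr(filt, "excluded")
  expect_gt(ex$below, 0); expect_gt(ex$above, 0)
  # identity band
  all_in <- stoichiometry_filter(rec, mono, band = c(0, Inf))
  expect_equal(nrow(all_in), nrow(rec))
  # monomer-intensity spot excluded under the holoenzyme band
  one <- stoichiometry_filter(tibble::tibble(intensity = mono), mono)
  expect_equal(nrow(one), 0)
  expect_error(stoichiometry_filter(rec, 0), "monomer_intensity")
})

test_that("tidiers and plots expose fit results", {
  set.seed(67)
  f <- fit_poisson(rpois(200, 2))
  g <- glance(f)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$lambda, f$lambda)
  td <- tidy(f)
  expect_true(all(c("n_cam", "count", "expected") %in% names(td)))
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  m <- find_steps(staircase_trace(c(5, 15), amp = 100), step_params(100, 10))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  expect_equal(nrow(tidy(m)), 2)
  expect_equal(glance(m)$n_down, 2)
})
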