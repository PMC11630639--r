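test_that("event frequencies are step counts over duration", {
  tr <- signed_trace(c(5, 12, 20, 30), rep(2000, 4), start = 0,
                     duration_s = 39.8)
  m <- find_steps(tr, step_params(2000, 600))
  f <- event_frequencies(m, duration_s = 40)
  expect_equal(f$f_on, 0.1)       # 4 up steps in a 40 s record
  expect_equal(f$f_off, 0)
  expect_equal(f$n_plus, 4L)
  # no steps at all
  m0 <- find_steps(staircase_trace(numeric(0), amp = 100),
                   step_params(100, 10))
  f0 <- event_frequencies(m0, duration_s = 40)
  expect_equal(unlist(f0), c(f_on = 0, f_off = 0, n_plus = 0, n_minus = 0))
})

test_that("residence intervals carry the entry-transition sign", {
  # monomer-like 0 <-> 1 cycling: every scored interval is tau+
  tr <- signed_trace(c(4, 9, 15, 22, 28, 33), rep(c(2000, -2000), 3),
                     start = 0)
  m <- find_steps(tr, step_params(2000, 600))
  ri <- residence_intervals(m)
  uncens <- ri[!ri$censored, ]
  expect_true(all(uncens$entry_sign == "+"))
  expect_true(all(uncens$tau_s > 0))
  expect_true(all(uncens$occupancy == 1))
  # saturated dimer cycling 2 <-> 1: alternating tau+ (level 2), tau- (level 1)
  tr2 <- signed_trace(c(4, 9, 15, 22, 28, 33), rep(c(-2000, 2000), 3),
                      start = 4000)
  m2 <- find_steps(tr2, step_params(2000, 600))
  ri2 <- residence_intervals(m2)
  u2 <- ri2[!ri2$censored, ]
  expect_true(all(u2$entry_sign[u2$occupancy == 1] == "-"))
  expect_true(all(u2$entry_sign[u2$occupancy == 2] == "+"))
  expect_lte(abs(sum(u2$tau_s > 0) - sum(u2$tau_s < 0)), 1)
})

test_that("censoring and zero-occupancy exclusion follow the contract", {
  # one up step at 5 s, record to 40 s: the occupied interval is open-ended
  tr <- signed_trace(5, 2000, start = 0)
  m <- find_steps(tr, step_params(2000, 600))
  ri <- residence_intervals(m)
  expect_equal(nrow(ri), 1)          # the zero level before 5 s is not scored
  expect_true(all(ri$censored))
  # bookkeeping: tau+ + tau- + censored = number of nonzero levels
  set.seed(51)
  for (r in 1:5) {
    traj <- simulate_binding_trajectory(3, 1e-6, 3e5, 0.1, 0.02, 60)
    ri <- residence_intervals(traj)
    occ_levels <- nrow(ri)
    expect_equal(sum(ri$entry_sign == "+", na.rm = TRUE) +
                   sum(ri$entry_sign == "-", na.rm = TRUE) +
                   sum(is.na(ri$entry_sign)),
                 occ_levels)
  }
})

test_that("exponential residence fits recover known rates", {
  set.seed(52)
  ints <- as_residence_set(rexp(2000, 0.5))
  f <- fit_tau(ints, dt_s = 0.2)
  expect_equal(f$k_tau, 0.5, tolerance = 0.05 / 0.5)
  expect_equal(f$model, "single")
  # biexponential mixture selected and rates recovered within 20%
  tau2 <- c(rexp(2500, 3.0), rexp(2500, 0.3))
  f2 <- fit_tau(as_residence_set(tau2), dt_s = 0.2, tau_min = 0)
  expect_equal(f2$model, "double")
  ks <- sort(f2$components$rate, decreasing = TRUE)
  expect_equal(ks[1], 3.0, tolerance = 0.2)
  expect_equal(ks[2], 0.3, tolerance = 0.2)
  expect_lt(f2$aic_double, f2$aic_single)
  # too few intervals
  expect_error(fit_tau(as_residence_set(rexp(5, 1))), ">= 30")
})

test_that("the 30 s truncation changes fast rates by under 5%", {
  set.seed(53)
  tau <- rexp(4000, 0.2)
  full <- fit_tau(as_residence_set(tau), tau_max = Inf, dt_s = 0.2)
  trunc <- fit_tau(as_residence_set(tau), tau_max = 30, dt_s = 0.2)
  expect_equal(trunc$k_tau, full$k_tau, tolerance = 0.05)
  expect_equal(trunc$tau_gt_max_fraction, mean(tau > 30), tolerance = 1e-9)
})

test_that("photobleaching correction subtracts competing hazards", {
  expect_equal(photobleach_correct(0.5, 0), 0.5)
  expect_equal(photobleach_correct(0.5, 0.2), 0.3)
  expect_equal(photobleach_correct(0.3, 0.3), 0)
  expect_warning(out <- photobleach_correct(0.2, 0.5), "clamped")
  expect_equal(as.numeric(out), 0)
  # competing-hazard simulation: koff 0.3 + kpb 0.2 -> apparent 0.5
  set.seed(54)
  ints <- NULL
  for (i in 1:600) {
    traj <- simulate_binding_trajectory(1, 1e-6, 2e4, 0.3, 0.2, 40)
    ri <- residence_intervals(traj)
    ints <- rbind(ints, as.data.frame(ri))
  }
  class(ints) <- c("residence_set", class(ints))
  f <- fit_tau(ints, dt_s = 0.2, tau_min = 0)
  expect_equal(f$k_tau, 0.5, tolerance = 0.15)
  expect_equal(as.numeric(photobleach_correct(f$k_tau, 0.2)), 0.3,
               tolerance = 0.25)
})

test_that("the affinity index reproduces printed arithmetic", {
  # concentration times k_tau over f_on, in concentration units
  expect_equal(affinity_index(300e-9, 0.7, 0.0512195), 4.1e-6,
               tolerance = 1e-3)
  expect_equal(affinity_index(30e-9, 0.315, 0.045), 210e-9,
               tolerance = 1e-6)
  expect_equal(affinity_index(1e-6, 0.25, 0.25), 1e-6)
  expect_error(affinity_index(1e-6, 0.5, 0), "f_on")
})

test_that("corrected rates recover koff across the simulation grid", {
  set.seed(55)
  grid <- expand.grid(koff = c(0.1, 0.3, 1.0), kpb = c(0, 0.1, 0.3),
                      S = c(1, 2, 14))
  # low occupancy regime: S * kon * C = koff / 20 so level exits ~ koff + kpb
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    kon_c <- g$koff / 20 / g$S
    ints <- NULL; n_unc <- 0L
    reps <- 0L
    while (n_unc < 3500L && reps < 5000L) {
      reps <- reps + 1L
      traj <- simulate_binding_trajectory(g$S, 1e-6, kon_c * 1e6, g$koff,
                                          g$kpb, duration_s = 100 / g$koff)
      ri <- residence_intervals(traj)
      ints <- rbind(ints, as.data.frame(ri))
      n_unc <- sum(!ints$censored & abs(ints$tau_s) > 0)
    }
    class(ints) <- c("residence_set", class(ints))
    # trajectory-level intervals have no detection resolution floor
    f <- fit_tau(ints, tau_max = 30, dt_s = 0.2, tau_min = 0,
                 model = "single")
    k_corr <- as.numeric(photobleach_correct(f$k_tau, g$kpb))
    expect_equal(k_corr, g$koff, tolerance = 0.2,
                 label = sprintf("koff=%.1f kpb=%.1f S=%d recovered %.3f",
                                 g$koff, g$kpb, g$S, k_corr))
  }
})

test_that("up/down balance degrades with photobleaching", {
  set.seed(56)
  ratios <- vapply(c(0, 0.1, 0.3), function(kpb) {
    up <- 0L; dn <- 0L
    for (i in 1:60) {
      traj <- simulate_binding_trajectory(2, 1e-6, 3e5, 0.3, kpb, 60)
      up <- up + sum(traj$events$delta > 0)
      dn <- dn + sum(traj$events$delta < 0)
    }
    up / dn
  }, numeric(1))
  expect_equal(ratios[1], 1, tolerance = 0.1)
  expect_true(all(diff(ratios) < 0))
})

test_that("pooled kinetics summary combines spots coherently", {
  set.seed(57)
  models <- purrr::map(1:25, function(i) {
    tr <- signed_trace(sort(runif(4, 2, 30)),
                       c(2000, -2000, 2000, -2000), start = 0,
                       noise_sd = 300)
    find_steps(tr, step_params(2000, 600), spot_id = i)
  })
  ks <- kinetics_summary(models, duration_s = 40, cam_conc = 30e-9,
                         k_pb = 0.01)
  expect_s3_class(ks, "kinetics_summary")
  expect_gt(ks$f_on, 0)
  expect_equal(ks$k_tau_corr, ks$k_tau - 0.01, tolerance = 1e-9)
  expect_true(ks$a_i > 0)
})
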