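test_that("calibration recovers the injected single-step distribution", {
  set.seed(41)
  traces <- purrr::map(1:40, function(i) {
    s <- simulate_bleach_staircase(1, 0.05, 100, 15, 3, duration_s = 40,
                                   dt_s = 0.2)
    tibble::tibble(spot_id = i, intensity = s$intensity)
  }) |> purrr::list_rbind()
  cal <- calibrate_step_distribution(traces, channel = "venus")
  expect_equal(cal$step_mean, 100, tolerance = 0.05)
  expect_equal(cal$step_sd, 15, tolerance = 0.15)
  # noiseless identical steps: SD ~ 0
  tr0 <- purrr::map(1:25, function(i) {
    s <- staircase_trace(times = 10 + i / 10, amp = 100)
    tibble::tibble(spot_id = i, intensity = s$intensity)
  }) |> purrr::list_rbind()
  cal0 <- calibrate_step_distribution(tr0, channel = "venus")
  expect_equal(cal0$step_mean, 100, tolerance = 1e-6)
  expect_lt(cal0$step_sd, 1e-6)
  # contracts
  expect_error(calibrate_step_distribution(traces), "channel")
  expect_error(calibrate_step_distribution(traces[traces$spot_id <= 5, ],
                                           channel = "venus"), ">= 20")
})

test_that("calibration cannot be reused across channels", {
  tr <- staircase_trace(c(5, 15, 25), amp = 100)
  attr(tr, "channel") <- "rhodamine"
  pars <- step_params(100, 10, channel = "venus")
  expect_error(find_steps(tr, pars), "channel")
})

test_that("a noiseless staircase is recovered exactly", {
  tr <- staircase_trace(c(5, 15, 25), amp = 100)
  m <- find_steps(tr, step_params(100, 10))
  expect_equal(nrow(m$steps), 3)
  expect_true(all(m$steps$sign == "-"))
  expect_equal(m$steps$time_s, c(5, 15, 25), tolerance = 0.21)
  expect_equal(m$levels$mean, c(300, 200, 100, 0), tolerance = 1e-9)
  expect_equal(as.integer(count_bleach_steps(m)), 3L)
  expect_false(attr(count_bleach_steps(m), "censored"))
})

test_that("trivial stoichiometry counts are exact on noiseless staircases", {
  m14 <- find_steps(staircase_trace(seq(2, 28, by = 2), amp = 100,
                                    duration_s = 40),
                    step_params(100, 10))
  expect_equal(as.integer(count_bleach_steps(m14)), 14L)
  m2 <- find_steps(staircase_trace(c(8, 20), amp = 100), step_params(100, 10))
  expect_equal(as.integer(count_bleach_steps(m2)), 2L)
  # unfinished bleaching is flagged censored
  mc <- find_steps(staircase_trace(c(8), amp = 100, duration_s = 40) |>
                     dplyr::mutate(intensity = intensity + 100),
                   step_params(100, 10))
  expect_true(attr(count_bleach_steps(mc), "censored"))
})

test_that("detected step times and signs are accurate at SNR >= 5", {
  set.seed(42)
  hits <- 0L; tot <- 0L
  for (r in 1:30) {
    repeat {
      times <- sort(runif(3, 2, 35))
      if (min(diff(c(0, times, 40))) > 2) break
    }
    deltas <- sample(c(-2000, 2000), 3, replace = TRUE)
    tr <- signed_trace(times, deltas, start = 6000, noise_sd = 400)
    m <- find_steps(tr, step_params(2000, 600))
    for (k in seq_len(nrow(m$steps))) {
      tot <- tot + 1L
      j <- which.min(abs(times - m$steps$time_s[k]))
      ok_time <- abs(times[j] - m$steps$time_s[k]) <= 0.2 + 1e-9
      ok_sign <- (deltas[j] > 0) == (m$steps$sign[k] == "+")
      if (ok_time && ok_sign) hits <- hits + 1L
    }
  }
  expect_gte(hits / tot, 0.95)
})

test_that("detected change points match the exhaustive least-squares oracle", {
  set.seed(43)
  agree <- 0L; n_rep <- 40L
  for (r in seq_len(n_rep)) {
    k <- sample(1:4, 1)
    repeat {
      times <- sort(runif(k, 3, 36))
      if (min(diff(c(0, times, 40))) > 2.5) break
    }
    deltas <- sample(c(-2000, 2000), k, replace = TRUE)
    tr <- signed_trace(times, deltas, start = 8000, noise_sd = 400)
    m <- find_steps(tr, step_params(2000, 600))
    if (nrow(m$steps) == k) {
      oracle <- ls_changepoints(tr$intensity, k)
      if (all(abs(m$steps$frame - oracle) <= 1)) agree <- agree + 1L
    }
  }
  expect_gte(agree / n_rep, 0.95)
})

test_that("signed step amplitudes reconstruct the net intensity change", {
  set.seed(44)
  for (r in 1:10) {
    s <- simulate_bleach_staircase(6, 0.1, 2000, 600, 300, duration_s = 60,
                                   dt_s = 0.2)
    m <- find_steps(s, step_params(2000, 600))
    net <- sum(m$steps$delta_i)
    lvl <- m$levels$mean[nrow(m$levels)] - m$levels$mean[1]
    expect_equal(net, lvl, tolerance = 1e-6)
  }
})

test_that("step detection recall degrades monotonically with noise", {
  set.seed(45)
  recall <- vapply(c(200, 600, 1200, 2400), function(ns) {
    found <- vapply(1:25, function(r) {
      tr <- signed_trace(c(10, 25), c(-2000, -2000), start = 4000,
                         noise_sd = ns)
      nrow(find_steps(tr, step_params(2000, 600))$steps)
    }, numeric(1))
    mean(found) / 2
  }, numeric(1))
  expect_true(all(diff(recall) <= 0.05))
  expect_gt(recall[1], 0.9)
})

test_that("fourteen-fluorophore staircases are undercounted by about two", {
  set.seed(46)
  cnt <- replicate(60, {
    s <- simulate_bleach_staircase(14, kpb = 0.15, step_mean = 2000,
                                   step_sd = 600, noise_sd = 300,
                                   duration_s = 60, dt_s = 0.2)
    as.integer(count_bleach_steps(find_steps(s, step_params(2000, 600))))
  })
  expect_equal(mean(cnt), 12, tolerance = 1 / 12)
})

test_that("a 20% dark fraction thins the counted stoichiometry", {
  set.seed(47)
  cnt <- replicate(60, {
    s <- simulate_bleach_staircase(14, kpb = 0.15, step_mean = 2000,
                                   step_sd = 600, noise_sd = 300,
                                   duration_s = 60, dt_s = 0.2,
                                   dark_fraction = 0.2)
    as.integer(count_bleach_steps(find_steps(s, step_params(2000, 600))))
  })
  # binomial thinning to 11.2 active tags, minus the detection undercount
  expect_lt(mean(cnt), 11.2)
  expect_equal(mean(cnt), 11.2 * 12 / 14, tolerance = 0.13)
})

test_that("photobleaching traces give monotone non-increasing levels", {
  set.seed(48)
  for (r in 1:10) {
    s <- simulate_bleach_staircase(8, 0.1, 2000, 600, 300, duration_s = 60,
                                   dt_s = 0.2)
    m <- find_steps(s, step_params(2000, 600))
    up <- sum(m$steps$sign == "+")
    expect_lte(up, 1)  # violations are rare noise artefacts and are visible
  }
})

test_that("short traces and missing calibration are rejected", {
  tr <- staircase_trace(5, amp = 100, duration_s = 1)
  expect_error(find_steps(tr, step_params(100, 10)), "too short")
  expect_error(find_steps(staircase_trace(5, 100), list(a = 5)),
               "step_params")
})
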