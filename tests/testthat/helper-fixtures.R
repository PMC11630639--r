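# Shared fixtures, built in code at test time.

# A small configuration that renders quickly but keeps the default physics.
small_config <- function(...) {
  args <- utils::modifyList(
    list(field_size_px = c(128L, 128L), n_frames = 80L, n_spots = 8L,
         subunits = 14L, seed = 101L),
    list(...))
  do.call(sim_config, args)
}

# Deterministic noiseless staircase trace with steps of `amp` at `times`.
staircase_trace <- function(times, amp = 100, duration_s = 40, dt_s = 0.2,
                            noise_sd = 0, start = NULL) {
  tt <- seq(0, duration_s, by = dt_s)
  x <- vapply(tt, function(t) amp * sum(times > t), numeric(1)) +
    rnorm(length(tt), 0, noise_sd)
  tr <- tibble::tibble(frame = seq_along(tt), time_s = tt, intensity = x)
  attr(tr, "dt_s") <- dt_s
  class(tr) <- c("sm_trace", class(tr))
  tr
}

# Trace from explicit signed steps: list of (time, delta_intensity).
signed_trace <- function(times, deltas, start = 0, duration_s = 40, dt_s = 0.2,
                         noise_sd = 0) {
  tt <- seq(0, duration_s, by = dt_s)
  x <- vapply(tt, function(t) start + sum(deltas[times <= t]), numeric(1)) +
    rnorm(length(tt), 0, noise_sd)
  tr <- tibble::tibble(frame = seq_along(tt), time_s = tt, intensity = x)
  attr(tr, "dt_s") <- dt_s
  class(tr) <- c("sm_trace", class(tr))
  tr
}

# Exhaustive least-squares piecewise-constant fit with a fixed number of
# change points (independent oracle for the step finder). Returns the
# change-point indices (step between cp-1 and cp). O(k n^2) dynamic program.
ls_changepoints <- function(x, k) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_sse <- function(i, j) { # segment x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # dp[m, j]: best SSE for x[1..j] with m segments
  dp <- matrix(Inf, k + 1, n)
  back <- matrix(0L, k + 1, n)
  for (j in 1:n) dp[1, j] <- seg_sse(1, j)
  for (m in 2:(k + 1)) {
    for (j in m:n) {
      best <- Inf; bi <- 0L
      for (i in (m - 1):(j - 1)) {
        v <- dp[m - 1, i] + seg_sse(i + 1, j)
        if (v < best) { best <- v; bi <- i }
      }
      dp[m, j] <- best; back[m, j] <- bi
    }
  }
  cps <- integer(0); j <- n
  for (m in (k + 1):2) {
    i <- back[m, j]
    cps <- c(i + 1L, cps)
    j <- i
  }
  cps
}

# Residence set directly from a vector of |tau| draws (for fit tests).
as_residence_set <- function(tau, occupancy = 1L) {
  out <- tibble::tibble(spot_id = 1L, occupancy = occupancy, tau_s = tau,
                        entry_sign = "+", censored = FALSE)
  class(out) <- c("residence_set", class(out))
  out
}

derive_seed_for_test <- function(seed, i) (seed * 1000L + i) %% 2147483587L
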