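#' Reconstruct the occupancy trajectory from a fitted step model
#'
#' The bound-ligand count over time is the cumulative signed step
#' multiplicity. The absolute level is anchored from the calibrated
#' single-ligand intensity when a calibration is available (first level mean
#' over the step mean, the background-subtracted trace being proportional to
#' occupancy); otherwise — and whenever that estimate would imply a negative
#' occupancy — the minimum observed level is anchored at zero
#' (photobleaching only lowers the visible occupancy after the laser comes
#' on, so the record's minimum is the natural floor).
#'
#' @param model A `step_model` of a rhodamine-channel record.
#' @return Tibble: `frame`, `time_s`, `n_cam` (integer occupancy). The value
#'   at the first frame is the initial occupancy estimate.
#' @export
occupancy_trajectory <- function(model) {
  tr <- model$trace
  if (is.null(tr)) abort("step model carries no trace.")
  n <- nrow(tr)
  delta <- rep(0L, n)
  if (nrow(model$steps)) {
    sgn <- ifelse(model$steps$sign == "+", 1L, -1L)
    delta[model$steps$frame] <- sgn * model$steps$multiplicity
  }
  lev <- cumsum(delta)
  n0 <- if (!is.null(model$params))
    as.integer(round(model$levels$mean[1] / model$params$step_mean))
  else 0L
  lev <- lev + max(n0, 0L)
  if (min(lev) < 0L) lev <- lev - min(lev)
  tibble(frame = tr$frame, time_s = tr$time_s, n_cam = as.integer(lev))
}

#' Poisson fit to an occupancy distribution
#'
#' Maximum-likelihood Poisson fit (lambda equals the sample mean) with a
#' chi-squared goodness of fit computed after pooling bins to expected
#' counts of at least 5.
#'
#' @param n_cam Integer vector of per-spot occupancies, or a named/table
#'   histogram of counts per occupancy.
#' @return Object of class `occupancy_fit`: list with `model = "poisson"`,
#'   `lambda`, `mean`, `se`, `n`, `gof_chi2`, `gof_df`, `gof_p`, `aic`,
#'   `histogram`.
#' @export
fit_poisson <- function(n_cam) {
  x <- occupancy_vector(n_cam)
  n <- length(x)
  if (n < 1L) abort("empty occupancy set.")
  lambda <- mean(x)
  ll <- sum(stats::dpois(x, max(lambda, 1e-12), log = TRUE))
  gof <- poisson_gof(x, lambda)
  structure(list(model = "poisson", lambda = lambda, mean = lambda,
                 se = stats::sd(x) / sqrt(n), n = n,
                 gof_chi2 = gof$chi2, gof_df = gof$df, gof_p = gof$p,
                 aic = -2 * ll + 2,
                 histogram = occupancy_histogram(x)),
            class = "occupancy_fit")
}

occupancy_vector <- function(n_cam) {
  if (is.table(n_cam)) {
    vals <- as.integer(names(n_cam))
    return(rep(vals, times = as.integer(n_cam)))
  }
  n_cam <- unname(n_cam)
  if (any(n_cam != round(n_cam) | n_cam < 0, na.rm = TRUE))
    abort("occupancies must be non-negative integers.")
  as.integer(n_cam[!is.na(n_cam)])
}

occupancy_histogram <- function(x) {
  tb <- table(factor(x, levels = 0:max(x, 0)))
  tibble(n_cam = as.integer(names(tb)), count = as.integer(tb))
}

# Chi-squared GOF against Poisson(lambda) with bins pooled to expected >= 5;
# one df lost for the estimated mean.
poisson_gof <- function(x, lambda, min_expected = 5) {
  if (lambda <= 0) return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  n <- length(x)
  kmax <- max(x, stats::qpois(0.999, lambda))
  obs <- tabulate(x + 1L, nbins = kmax + 1L)
  expd <- n * c(stats::dpois(0:(kmax - 1), lambda),
                1 - stats::ppois(kmax - 1, lambda))
  # pool adjacent bins until every expected count reaches the floor
  ob <- numeric(0); ex <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= min_expected) { ob <- c(ob, co); ex <- c(ex, ce); co <- 0; ce <- 0 }
  }
  if (co > 0 || ce > 0) {
    if (length(ob)) { ob[length(ob)] <- ob[length(ob)] + co
      ex[length(ex)] <- ex[length(ex)] + ce
    } else { ob <- co; ex <- ce }
  }
  df <- length(ob) - 2L
  if (df < 1L) return(list(chi2 = NA_real_, df = df, p = NA_real_))
  chi2 <- sum((ob - ex)^2 / ex)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-component Poisson mixture fit to an occupancy distribution
#'
#' EM fit of `w Pois(lambda1) + (1 - w) Pois(lambda2)` with seeded random
#' restarts. Components are labelled low/high by rate. Degenerate solutions
#' (vanishing weight or indistinguishable rates) fall back to the single
#' Poisson fit, flagged.
#'
#' @param n_cam Integer occupancy vector (or histogram, see [fit_poisson()]).
#' @param n_restarts Number of EM restarts (default 10).
#' @param seed Seed for the restarts.
#' @param max_iter,tol EM iteration controls.
#' @return Object of class `occupancy_fit`: `model = "two_poisson"` (or
#'   `"poisson"` with `fallback = TRUE`), `w`, `lambda1` (low), `lambda2`
#'   (high), `mean`, `n`, `aic`, `delta_aic_vs_single` (negative favors the
#'   mixture), `histogram`.
#' @export
fit_two_poisson <- function(n_cam, n_restarts = 10L, seed = 1L,
                            max_iter = 500L, tol = 1e-8) {
  x <- occupancy_vector(n_cam)
  n <- length(x)
  if (n < 2L) abort("need at least 2 observations.")
  single <- fit_poisson(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      q1 <- stats::runif(1, 0.1, 0.5)
      l1 <- stats::quantile(x, q1) + stats::runif(1, 0, 0.5)
      l2 <- stats::quantile(x, 1 - q1 / 2) + stats::runif(1, 0, 0.5)
      w <- stats::runif(1, 0.2, 0.8)
      l1 <- max(as.numeric(l1), 0.05); l2 <- max(as.numeric(l2), l1 + 0.1)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        p1 <- w * stats::dpois(x, l1)
        p2 <- (1 - w) * stats::dpois(x, l2)
        tot <- p1 + p2
        tot[tot == 0] <- 1e-300
        g <- p1 / tot
        w <- mean(g)
        if (w < 1e-6 || w > 1 - 1e-6) break
        l1 <- sum(g * x) / sum(g)
        l2 <- sum((1 - g) * x) / sum(1 - g)
        ll <- sum(log(tot))
        if (is.finite(ll) && ll - ll_old < tol) { ll_old <- ll; break }
        ll_old <- ll
      }
      if (is.finite(ll_old) &&
          (is.null(best) || ll_old > best$ll)) best <- list(w = w, l1 = l1,
                                                            l2 = l2, ll = ll_old)
    }
  })
  degenerate <- is.null(best) || best$w < 0.02 || best$w > 0.98 ||
    abs(best$l1 - best$l2) < 0.25
  aic2 <- if (is.null(best)) Inf else -2 * best$ll + 2 * 3
  if (degenerate || aic2 > single$aic + 1e-9) {
    out <- single
    out$fallback <- TRUE
    out$delta_aic_vs_single <- aic2 - single$aic
    return(out)
  }
  lo <- min(best$l1, best$l2); hi <- max(best$l1, best$l2)
  w_lo <- if (best$l1 <= best$l2) best$w else 1 - best$w
  structure(list(model = "two_poisson", w = w_lo, lambda1 = lo, lambda2 = hi,
                 mean = mean(x), se = stats::sd(x) / sqrt(n), n = n,
                 aic = aic2, delta_aic_vs_single = aic2 - single$aic,
                 fallback = FALSE,
                 histogram = occupancy_histogram(x)),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  if (x$model == "poisson")
    cat(sprintf("<occupancy_fit> Poisson, lambda = %.3g (n = %d, GOF p = %.3g)\n",
                x$lambda, x$n, x$gof_p %||% NA))
  else
    cat(sprintf("<occupancy_fit> two-Poisson, w = %.2f, lambda = (%.3g, %.3g), dAIC = %.2f\n",
                x$w, x$lambda1, x$lambda2, x$delta_aic_vs_single))
  invisible(x)
}

#' Compare subunit stoichiometry between occupancy subpopulations
#'
#' Tests whether spots with zero bound ligand are smaller assemblies than
#' spots with nonzero occupancy: an F-test for variance equality followed by
#' an unequal-variance (Welch) two-sample t-test on the step-counted subunit
#' stoichiometries.
#'
#' @param records Tibble with `s_camkii` (subunit count per spot) and `n_cam`
#'   (initial occupancy per spot).
#' @param min_per_group Minimum spots per subpopulation (default 3).
#' @return One-row tibble: `n_zero`, `n_pos`, `mean_zero`, `mean_pos`,
#'   `sd_zero`, `sd_pos`, `p_f` (F-test), `p_t` (Welch t-test).
#' @export
compare_subpopulations <- function(records, min_per_group = 3L) {
  z <- records$s_camkii[records$n_cam == 0]
  p <- records$s_camkii[records$n_cam > 0]
  if (length(z) < min_per_group || length(p) < min_per_group)
    abort(sprintf("each subpopulation needs >= %d spots (have %d and %d).",
                  min_per_group, length(z), length(p)))
  ftest <- stats::var.test(z, p)
  ttest <- stats::t.test(z, p, var.equal = FALSE)
  tibble(n_zero = length(z), n_pos = length(p),
         mean_zero = mean(z), mean_pos = mean(p),
         sd_zero = stats::sd(z), sd_pos = stats::sd(p),
         p_f = ftest$p.value, p_t = ttest$p.value)
}

#' Filter spots to a stoichiometry band in monomer units
#'
#' Separates holoenzymes from smaller assemblies and aggregates by intensity
#' filtration: a spot passes when its projected green intensity lies within
#' `band * monomer_intensity`.
#'
#' @param records Tibble with an `intensity` column (projected Venus ROI
#'   intensity per spot).
#' @param monomer_intensity Calibrated single-fluorophore (monomer) projected
#'   intensity.
#' @param band Length-2 numeric band in monomer units (default `c(6, 28)`
#'   for 12-14-subunit holoenzymes with partial photobleaching/dark tags).
#' @return The rows that pass, with attribute `excluded` = tibble counts of
#'   `below` (smaller assemblies) and `above` (aggregates).
#' @export
stoichiometry_filter <- function(records, monomer_intensity, band = c(6, 28)) {
  check_number(monomer_intensity, "monomer_intensity", min = 0,
               allow_zero = FALSE)
  lo <- band[1] * monomer_intensity
  hi <- band[2] * monomer_intensity
  pass <- records$intensity >= lo & records$intensity <= hi
  out <- records[pass, , drop = FALSE]
  attr(out, "excluded") <- tibble(below = sum(records$intensity < lo),
                                  above = sum(records$intensity > hi))
  out
}
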