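#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap imap list_rbind
#' @importFrom tidyr unnest pivot_longer
#' @importFrom stats rnorm rpois rgamma rexp rbinom runif median mad sd var
#'   t.test var.test nls coef dpois chisq.test quantile setNames optimize
#'   dbinom complete.cases
#' @importFrom graphics hist
NULL

# Centered moving average; shrinks the window at the edges so length is kept.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Robust SD via median absolute deviation (consistent for a normal law).
robust_sd <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  stats::mad(x, constant = 1.4826)
}

check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (x < min || (!allow_zero && x == min))
    abort(sprintf("`%s` must be %s %s.", name,
                  if (allow_zero) ">=" else ">", format(min)))
  invisible(x)
}

# One RNG stream per logical task, derived from a user seed; keeps every
# consumer below .Machine$integer.max so seeds survive 32-bit storage.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483587L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483587))
  force(code)
}
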