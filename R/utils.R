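# Shared numerical helpers and the piecewise-constant rate representation
# used across the likelihood and MCMC machinery.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(1 - exp(-x)) for x > 0
#'
#' Branches at x = log(2): below, `log(-expm1(-x))` is accurate; above,
#' `log1p(-exp(-x))` is.
#'
#' @param x positive numeric vector.
#' @return log(1 - exp(-x)), elementwise.
#' @keywords internal
log1mexp <- function(x) {
  out <- numeric(length(x))
  small <- x <= log(2)
  out[small] <- log(-expm1(-x[small]))
  out[!small] <- log1p(-exp(-x[!small]))
  out
}

# log(mean(exp(x))) with max-shift stabilization
logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Highest posterior density interval
#'
#' Shortest interval containing a fraction `prob` of the sample
#' (empirical shortest-interval search on the sorted draws).
#'
#' @param x numeric sample.
#' @param prob coverage probability (default 0.95).
#' @return length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

# -- piecewise-constant rate functions ---------------------------------------
# A rate function is a list with components:
#   shifts: strictly decreasing ages (Ma) at which the rate changes
#   values: length(shifts) + 1 non-negative rates; values[1] applies to the
#           oldest interval [shifts[1], Inf), values[j] to [shifts[j], shifts[j-1])
#           and values[k+1] to [0, shifts[k]).
# An age exactly at a shift takes the value in force on its older side's
# segment, i.e. segment j covers [shifts[j], shifts[j-1]).

#' Piecewise-constant rate function
#'
#' @param values non-negative rates, one more than `shifts`; `values[1]`
#'   applies to the oldest interval.
#' @param shifts strictly decreasing shift ages in Ma (may be empty for a
#'   constant rate).
#' @return an object of class `rate_fn`.
#' @export
rate_fn <- function(values, shifts = numeric(0)) {
  values <- as.numeric(values)
  shifts <- as.numeric(shifts)
  if (length(values) != length(shifts) + 1L)
    stop("rate_fn: need exactly length(shifts) + 1 values")
  if (any(values < 0)) stop("rate_fn: rates must be non-negative")
  if (length(shifts) > 1L && any(diff(shifts) >= 0))
    stop("rate_fn: shift ages must be strictly decreasing")
  structure(list(shifts = shifts, values = values), class = "rate_fn")
}

as_rate_fn <- function(x) {
  if (inherits(x, "rate_fn")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(rate_fn(x))
  stop("cannot interpret object as a rate function")
}

# Merge adjacent segments with identical values; guarantees that a rate
# function modulated by a constant factor of 1 collapses to its base form.
canonicalize_rate_fn <- function(fn) {
  k <- length(fn$shifts)
  if (k == 0L) return(fn)
  keep <- fn$values[seq_len(k)] != fn$values[seq_len(k) + 1L]
  rate_fn(c(fn$values[seq_len(k)][keep], fn$values[k + 1L]), fn$shifts[keep])
}

#' Evaluate a piecewise-constant rate function at given ages
#' @param fn a `rate_fn`.
#' @param t ages in Ma.
#' @return rate values at `t`.
#' @export
rate_at <- function(fn, t) {
  k <- length(fn$shifts)
  if (k == 0L) return(rep(fn$values, length(t)))
  n_le <- findInterval(t, rev(fn$shifts))   # shifts <= t
  fn$values[k + 1L - n_le]
}

#' Cumulative rate integral
#'
#' Integral of a piecewise-constant rate function from age 0 up to `t`
#' (vectorized); the exposure building block of the birth-death
#' likelihood.
#'
#' @param fn a `rate_fn`.
#' @param t ages in Ma.
#' @return the cumulative integral at each `t`.
#' @export
cum_rate <- function(fn, t) {
  k <- length(fn$shifts)
  if (k == 0L) return(fn$values * t)
  b <- c(0, rev(fn$shifts))                # ascending breakpoints
  v <- rev(fn$values)                      # v[j] on [b[j], b[j+1])
  cums <- c(0, cumsum(v[seq_len(k)] * diff(b)))
  j <- pmax(findInterval(t, b), 1L)
  cums[j] + (t - b[j]) * v[j]
}

# Deterministic per-stage seed derived from a master seed and a stage name
# by a small polynomial hash; kept below .Machine$integer.max so that one
# master seed reproduces every stage.
derive_seed <- function(master, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(master) %% 1000003) * 2099 + h) %% 2147483399L + 1L
}
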