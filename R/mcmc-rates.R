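# Reversible-jump MCMC over the number, location and magnitude of
# speciation/extinction rate shifts, for fixed per-lineage lifespans
# ("fixed-times" estimation). The same move machinery is reused by the
# joint lifespan sampler.
#
# Priors: rate values ~ Gamma(1.1, 1); number of shifts ~ Poisson(mean
# rj_poisson_mean); shift ages uniform over the data span (order
# statistics). Moves, chosen with equal probability among those
# available: rate scale (log-random-walk), shift move (uniform slide
# between neighbours), birth (new shift splits a segment, younger part
# perturbed multiplicatively), death (merge, keeping the older value).

# unvalidated rate_fn builder for the samplers' inner loops
new_rate_fn <- function(values, shifts) {
  structure(list(shifts = shifts, values = values), class = "rate_fn")
}

# log-likelihood contribution of one rate block (lambda or mu):
# event terms at `ev` plus the exposure integral over all lifespans.
block_ll <- function(fn, ev, ts, te) {
  r <- rate_at(fn, ev)
  if (any(r <= 0)) return(-Inf)
  sum(log(r)) - sum(cum_rate(fn, ts)) + sum(cum_rate(fn, te))
}

block_logprior <- function(fn, span, mean_shifts) {
  k <- length(fn$shifts)
  sum(stats::dgamma(fn$values, 1.1, 1, log = TRUE)) +
    stats::dpois(k, mean_shifts, log = TRUE) +
    lfactorial(k) - k * log(span)
}

# probability of picking the birth / death move at a state with k shifts
p_birth <- function(k) if (k == 0L) 1 / 2 else 1 / 4
p_death <- function(k) if (k == 0L) 0 else 1 / 4

# One reversible-jump update of a rate block. `st` is a list with
# components fn (rate_fn) and ll (cached block log-likelihood).
update_rate_block <- function(st, ev, ts, te, span, cfg, scale_now) {
  fn <- st$fn; k <- length(fn$shifts)
  m <- cfg$rj_poisson_mean
  move <- if (k == 0L) sample(c("scale", "birth"), 1L)
          else sample(c("scale", "move", "birth", "death"), 1L)
  acc <- FALSE

  if (move == "scale") {
    j <- sample.int(k + 1L, 1L)
    u <- stats::runif(1L, -scale_now, scale_now)
    v_new <- fn$values[j] * exp(u)
    fn2 <- fn; fn2$values[j] <- v_new
    ll2 <- block_ll(fn2, ev, ts, te)
    logA <- ll2 - st$ll +
      stats::dgamma(v_new, 1.1, 1, log = TRUE) -
      stats::dgamma(fn$values[j], 1.1, 1, log = TRUE) + u
    if (is.finite(logA) && log(stats::runif(1L)) < logA) {
      st$fn <- fn2; st$ll <- ll2; acc <- TRUE
    }
  } else if (move == "move") {
    j <- sample.int(k, 1L)
    hi <- if (j == 1L) span else fn$shifts[j - 1L]
    lo <- if (j == k) 0 else fn$shifts[j + 1L]
    s_new <- stats::runif(1L, lo, hi)
    fn2 <- fn; fn2$shifts[j] <- s_new
    ll2 <- block_ll(fn2, ev, ts, te)
    if (is.finite(ll2) && log(stats::runif(1L)) < ll2 - st$ll) {
      st$fn <- fn2; st$ll <- ll2; acc <- TRUE
    }
  } else if (move == "birth") {
    s_star <- stats::runif(1L, 0, span)
    idx <- k + 1L - findInterval(s_star, rev(fn$shifts))
    v <- fn$values[idx]
    z <- stats::rnorm(1L, 0, cfg$prop_scales$rj_sigma)
    v_new <- v * exp(z)
    fn2 <- new_rate_fn(append(fn$values, v_new, after = idx),
                       sort(c(fn$shifts, s_star), decreasing = TRUE))
    ll2 <- block_ll(fn2, ev, ts, te)
    logA <- ll2 - st$ll +
      stats::dpois(k + 1L, m, log = TRUE) - stats::dpois(k, m, log = TRUE) +
      stats::dgamma(v_new, 1.1, 1, log = TRUE) -
      stats::dnorm(z, 0, cfg$prop_scales$rj_sigma, log = TRUE) + log(v_new) +
      log(p_death(k + 1L)) - log(p_birth(k))
    if (is.finite(logA) && log(stats::runif(1L)) < logA) {
      st$fn <- fn2; st$ll <- ll2; acc <- TRUE
    }
  } else { # death
    j <- sample.int(k, 1L)
    v_drop <- fn$values[j + 1L]
    v_keep <- fn$values[j]
    z <- log(v_drop / v_keep)
    fn2 <- new_rate_fn(fn$values[-(j + 1L)], fn$shifts[-j])
    ll2 <- block_ll(fn2, ev, ts, te)
    logA <- ll2 - st$ll +
      stats::dpois(k - 1L, m, log = TRUE) - stats::dpois(k, m, log = TRUE) -
      stats::dgamma(v_drop, 1.1, 1, log = TRUE) +
      stats::dnorm(z, 0, cfg$prop_scales$rj_sigma, log = TRUE) - log(v_drop) +
      log(p_birth(k - 1L)) - log(p_death(k))
    if (is.finite(logA) && log(stats::runif(1L)) < logA) {
      st$fn <- fn2; st$ll <- ll2; acc <- TRUE
    }
  }
  st$acc <- acc
  st$scale_move <- move == "scale"
  st
}

#' Reversible-jump MCMC for speciation/extinction rates with fixed lifespans
#'
#' Samples the number, ages and magnitudes of shifts in piecewise-constant
#' speciation and extinction rates, conditioning on a fixed table of
#' per-lineage origination/extinction times (the merged median Ts/Te
#' workflow). Identical seed and input give an identical sample stream.
#'
#' @param lifespans a `lifespan_table` (non-empty).
#' @param cfg an [mcmc_config()].
#' @return object of class `bd_rate_posterior` with retained post-burn-in
#'   samples, log-likelihood/prior traces, shift counts, acceptance rates
#'   and a convergence report (ESS on the log-likelihood and on the
#'   time-averaged rates).
#' @export
rj_mcmc_rates <- function(lifespans, cfg = mcmc_config()) {
  if (!inherits(lifespans, "lifespan_table") || nrow(lifespans) == 0L)
    stop("non-empty lifespan table required")
  set.seed(cfg$seed)
  ts <- lifespans$ts; te <- lifespans$te
  ev_l <- ts
  ev_m <- te[!lifespans$extant]
  span <- max(ts)
  expo <- sum(ts - te)

  st_l <- list(fn = rate_fn(max(length(ev_l) / expo, 1e-4)), ll = NA_real_)
  st_m <- list(fn = rate_fn(max(length(ev_m) / expo, 1e-4)), ll = NA_real_)
  st_l$ll <- block_ll(st_l$fn, ev_l, ts, te)
  st_m$ll <- block_ll(st_m$fn, ev_m, ts, te)

  n_samp <- cfg$n_generations %/% cfg$sample_every
  samples <- vector("list", n_samp)
  trace <- matrix(NA_real_, n_samp, 6,
                  dimnames = list(NULL, c("iteration", "logL", "logPrior",
                                          "n_shifts_lambda", "n_shifts_mu",
                                          "mean_lambda")))
  scale_l <- cfg$prop_scales$rate
  scale_m <- cfg$prop_scales$rate
  acc_l <- att_l <- acc_m <- att_m <- 0L
  adapt_until <- cfg$burn_in_fraction * cfg$n_generations
  si <- 0L
  for (g in seq_len(cfg$n_generations)) {
    st_l <- update_rate_block(st_l, ev_l, ts, te, span, cfg, scale_l)
    if (st_l$scale_move) { att_l <- att_l + 1L; acc_l <- acc_l + st_l$acc }
    st_m <- update_rate_block(st_m, ev_m, ts, te, span, cfg, scale_m)
    if (st_m$scale_move) { att_m <- att_m + 1L; acc_m <- acc_m + st_m$acc }

    if (cfg$adapt && g < adapt_until && att_l >= 50L) {
      scale_l <- min(max(scale_l * exp((acc_l / att_l - 0.35) * 0.5), 0.01), 5)
      acc_l <- att_l <- 0L
    }
    if (cfg$adapt && g < adapt_until && att_m >= 50L) {
      scale_m <- min(max(scale_m * exp((acc_m / att_m - 0.35) * 0.5), 0.01), 5)
      acc_m <- att_m <- 0L
    }

    if (g %% cfg$sample_every == 0L) {
      si <- si + 1L
      lp <- block_logprior(st_l$fn, span, cfg$rj_poisson_mean) +
        block_logprior(st_m$fn, span, cfg$rj_poisson_mean)
      samples[[si]] <- list(lambda = st_l$fn, mu = st_m$fn)
      mean_l <- sum(cum_rate(st_l$fn, span)) / span
      trace[si, ] <- c(g, st_l$ll + st_m$ll, lp,
                       length(st_l$fn$shifts), length(st_m$fn$shifts),
                       mean_l)
    }
  }
  drop <- floor(cfg$burn_in_fraction * si)
  keep <- if (drop > 0L) seq.int(drop + 1L, si) else seq_len(si)
  trace <- as.data.frame(trace[keep, , drop = FALSE])
  samples <- samples[keep]
  conv <- list(logL = ess(trace$logL), mean_lambda = ess(trace$mean_lambda))
  conv$flags <- unlist(conv[c("logL", "mean_lambda")]) < 200
  structure(list(samples = samples, trace = trace, span = span,
                 cfg = cfg, convergence = conv,
                 n_lineages = nrow(lifespans)),
            class = "bd_rate_posterior")
}

#' Posterior shift ages for one rate
#' @param posterior a `bd_rate_posterior`.
#' @param which `"lambda"` or `"mu"`.
#' @return numeric vector pooling every sampled shift age.
#' @export
shift_times <- function(posterior, which = c("lambda", "mu")) {
  which <- match.arg(which)
  unlist(lapply(posterior$samples, function(s) s[[which]]$shifts))
}

#' Summarize a rate posterior on an age grid
#'
#' Evaluates each retained sample's piecewise rates on a regular grid and
#' reports, per grid age, the median and 95\% HPD of speciation,
#' extinction and (sample-wise) net diversification `r = lambda - mu`.
#'
#' @param posterior a `bd_rate_posterior`.
#' @param step grid step in Myr (default 0.1).
#' @param prob HPD coverage.
#' @return data frame of class `rate_summary` with ages descending.
#' @export
summarize_rates <- function(posterior, step = 0.1, prob = 0.95) {
  grid <- seq(ceiling(posterior$span), 0, by = -step)
  L <- vapply(posterior$samples, function(s) rate_at(s$lambda, grid),
              numeric(length(grid)))
  M <- vapply(posterior$samples, function(s) rate_at(s$mu, grid),
              numeric(length(grid)))
  R <- L - M
  sumfun <- function(X) {
    med <- apply(X, 1L, stats::median)
    hpd <- apply(X, 1L, hpd_interval, prob = prob)
    list(med = med, lo = hpd[1L, ], hi = hpd[2L, ])
  }
  sl <- sumfun(L); sm <- sumfun(M); sr <- sumfun(R)
  out <- data.frame(age = grid,
                    lambda_med = sl$med, lambda_lo = sl$lo, lambda_hi = sl$hi,
                    mu_med = sm$med, mu_lo = sm$lo, mu_hi = sm$hi,
                    r_med = sr$med, r_lo = sr$lo, r_hi = sr$hi)
  class(out) <- c("rate_summary", "data.frame")
  out
}

#' @export
print.bd_rate_posterior <- function(x, ...) {
  cat(sprintf("Birth-death rate posterior: %d retained samples, %d lineages\n",
              length(x$samples), x$n_lineages))
  cat(sprintf("  P(>=1 lambda shift) = %.3f; P(>=1 mu shift) = %.3f\n",
              mean(x$trace$n_shifts_lambda >= 1),
              mean(x$trace$n_shifts_mu >= 1)))
  cat(sprintf("  ESS(logL) = %.0f, ESS(mean lambda) = %.0f\n",
              x$convergence$logL, x$convergence$mean_lambda))
  if (any(x$convergence$flags))
    cat("  warning: ESS below 200 for some parameters\n")
  invisible(x)
}

#' @export
summary.bd_rate_posterior <- function(object, step = 0.5, ...) {
  summarize_rates(object, step = step)
}

#' @export
plot.bd_rate_posterior <- function(x, step = 0.1, ...) {
  s <- summarize_rates(x, step = step)
  plot(s$age, s$lambda_med, type = "l", xlim = rev(range(s$age)),
       ylim = range(0, s$lambda_hi, s$mu_hi),
       xlab = "Age (Ma)", ylab = "Rate (events/lineage/Myr)", ...)
  graphics::lines(s$age, s$mu_med, lty = 2)
  graphics::polygon(c(s$age, rev(s$age)), c(s$lambda_lo, rev(s$lambda_hi)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::polygon(c(s$age, rev(s$age)), c(s$mu_lo, rev(s$mu_hi)),
                    border = NA, col = grDevices::adjustcolor("firebrick", 0.3))
  graphics::legend("topleft", legend = c("speciation", "extinction"),
                   lty = c(1, 2), bty = "n")
  invisible(s)
}

#' Write a rate posterior trace as tab-separated text
#' @param posterior a `bd_rate_posterior`.
#' @param path output path.
#' @export
write_rate_trace <- function(posterior, path) {
  tr <- posterior$trace
  tr$lambda_shifts <- vapply(posterior$samples, function(s)
    paste(signif(s$lambda$shifts, 6), collapse = ","), "")
  tr$lambda_values <- vapply(posterior$samples, function(s)
    paste(signif(s$lambda$values, 6), collapse = ","), "")
  tr$mu_shifts <- vapply(posterior$samples, function(s)
    paste(signif(s$mu$shifts, 6), collapse = ","), "")
  tr$mu_values <- vapply(posterior$samples, function(s)
    paste(signif(s$mu$values, 6), collapse = ","), "")
  utils::write.table(tr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
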