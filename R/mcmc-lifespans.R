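# Joint Bayesian estimation of per-lineage origination (Ts) and
# extinction (Te) times together with preservation parameters, while
# speciation/extinction rates are sampled under the reversible-jump
# scheme. Conditional on the shared rate and preservation parameters the
# lineages are independent, so the per-lineage Ts/Te updates are run as
# vectorized independent Metropolis steps (one full sweep per
# generation).

# reflect proposals into [lo, hi] by triangle folding (symmetric)
fold_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Sample lifespans and preservation parameters jointly
#'
#' MCMC over per-lineage origination/extinction times, preservation
#' rate(s) and piecewise-constant speciation/extinction rates. The target
#' is the product of the conditioned preservation likelihood
#' (per-lineage Poisson process, given >= 1 find), the birth-death
#' likelihood of the lifespans, and the priors. Hard constraints:
#' `Ts >= oldest occurrence`, `Te <= youngest occurrence`, `Te = 0` for
#' extant lineages.
#'
#' @param table an `occurrence_table`.
#' @param replicate optional `age_replicate` fixing point ages (default:
#'   range midpoints).
#' @param model preservation model kind: `"TPP"`, `"HPP"` or `"NHPP"`,
#'   or a `preservation_model` whose parameters seed the chain.
#' @param epochs TPP epoch boundaries; defaults to [cenozoic_epochs()]
#'   clipped/extended to the data span.
#' @param cfg an [mcmc_config()].
#' @return object of class `lifespan_posterior`.
#' @export
sample_lifespans <- function(table, replicate = NULL, model = "TPP",
                             epochs = NULL, cfg = mcmc_config()) {
  lin <- if (inherits(table, "lineage_set")) table
         else build_lineages(table, replicate)
  n <- length(lin$species)
  if (n < 1L) stop("no lineages")
  kind <- if (inherits(model, "preservation_model")) model$kind else model
  kind <- match.arg(kind, c("TPP", "HPP", "NHPP"))
  set.seed(cfg$seed)

  init <- padded_lifespans(lin)
  ts <- init$ts; te <- init$te
  fa <- lin$fa; la <- lin$la
  extinct <- !lin$extant
  la_pos <- extinct & la > 0        # lineages whose Te is sampled

  if (kind == "TPP") {
    if (is.null(epochs)) {
      top <- ceiling(max(ts) + 5)
      epochs <- cenozoic_epochs()
      epochs <- c(top, epochs[epochs < top])
      if (utils::tail(epochs, 1L) != 0) epochs <- c(epochs, 0)
    } else if (max(epochs) < max(ts) + 5) {
      epochs <- c(ceiling(max(ts) + 5), epochs[epochs < max(ts) + 5])
    }
    E <- length(epochs) - 1L
    K <- tpp_k_matrix(lin, epochs)
    theta <- list(q = rep(sum(lin$k) / sum(ts - te), E), epochs = epochs)
  } else if (kind == "HPP") {
    K <- NULL
    theta <- list(q = sum(lin$k) / sum(ts - te))
  } else {
    K <- NULL
    theta <- list(q = sum(lin$k) / sum(ts - te), shape = 1.5)
  }
  if (inherits(model, "preservation_model")) {
    if (kind == "TPP") {
      theta$epochs <- model$epochs
      if (max(model$epochs) < max(ts))
        theta$epochs <- c(ceiling(max(ts) + 5),
                          model$epochs[model$epochs < max(ts)])
      E <- length(theta$epochs) - 1L
      theta$q <- rep(mean(model$q), E)
      K <- tpp_k_matrix(lin, theta$epochs)
    } else {
      theta$q <- model$q
      if (kind == "NHPP") theta$shape <- model$shape %||% 1.5
    }
  }

  pres_vec <- pres_loglik_set(lin, ts, te, kind, theta, K)

  span <- max(ts) + 5
  st_l <- list(fn = rate_fn(max(n / sum(ts - te), 1e-4)), ll = NA_real_)
  st_m <- list(fn = rate_fn(max(sum(extinct) / sum(ts - te), 1e-4)),
               ll = NA_real_)

  n_samp <- cfg$n_generations %/% cfg$sample_every
  ts_s <- matrix(NA_real_, n_samp, n)
  te_s <- matrix(NA_real_, n_samp, n)
  q_s <- matrix(NA_real_, n_samp, length(theta$q))
  rate_s <- vector("list", n_samp)
  trace <- matrix(NA_real_, n_samp, 4,
                  dimnames = list(NULL, c("iteration", "logL", "q_mean",
                                          "mean_lambda")))
  d_ts <- cfg$prop_scales$ts
  d_te <- cfg$prop_scales$te
  d_q <- cfg$prop_scales$q
  acc_ts <- att_ts <- acc_te <- att_te <- 0
  tot_acc_ts <- tot_att_ts <- tot_acc_te <- tot_att_te <- 0
  adapt_until <- cfg$burn_in_fraction * cfg$n_generations
  si <- 0L

  for (g in seq_len(cfg$n_generations)) {
    lam <- st_l$fn; mu <- st_m$fn

    # --- Ts sweep (vectorized independent MH per lineage) ---
    # reflect at the oldest find below and at the (generous) span above,
    # keeping Ts inside the epoch table's reach
    prop <- fold_into(ts + stats::runif(n, -d_ts, d_ts), fa, span)
    pres_prop <- pres_loglik_set(lin, prop, te, kind, theta, K)
    dll <- log(rate_at(lam, prop)) - log(rate_at(lam, ts)) -
      (cum_rate(lam, prop) - cum_rate(lam, ts)) -
      (cum_rate(mu, prop) - cum_rate(mu, ts)) +
      pres_prop - pres_vec
    ok <- log(stats::runif(n)) < dll
    ok[!is.finite(dll)] <- FALSE
    ts[ok] <- prop[ok]; pres_vec[ok] <- pres_prop[ok]
    att_ts <- att_ts + 1; acc_ts <- acc_ts + mean(ok)
    if (g >= adapt_until) {
      tot_att_ts <- tot_att_ts + 1; tot_acc_ts <- tot_acc_ts + mean(ok)
    }

    # --- Te sweep (extinct lineages with la > 0) ---
    if (any(la_pos)) {
      prop <- te
      prop[la_pos] <- fold_into(te[la_pos] +
                                  stats::runif(sum(la_pos), -d_te, d_te),
                                0, la[la_pos])
      pres_prop <- pres_loglik_set(lin, ts, prop, kind, theta, K)
      mu_new <- rate_at(mu, prop); mu_old <- rate_at(mu, te)
      dll <- log(mu_new) - log(mu_old) +
        (cum_rate(lam, prop) - cum_rate(lam, te)) +
        (cum_rate(mu, prop) - cum_rate(mu, te)) +
        pres_prop - pres_vec
      ok <- la_pos & log(stats::runif(n)) < dll
      ok[!is.finite(dll)] <- FALSE
      te[ok] <- prop[ok]; pres_vec[ok] <- pres_prop[ok]
      att_te <- att_te + 1; acc_te <- acc_te + mean(ok[la_pos])
      if (g >= adapt_until) {
        tot_att_te <- tot_att_te + 1
        tot_acc_te <- tot_acc_te + mean(ok[la_pos])
      }
    }

    # --- preservation parameter update (one component per generation) ---
    j <- sample.int(length(theta$q), 1L)
    u <- stats::runif(1L, -d_q, d_q)
    theta2 <- theta
    theta2$q[j] <- theta$q[j] * exp(u)
    pres_prop <- pres_loglik_set(lin, ts, te, kind, theta2, K)
    logA <- sum(pres_prop) - sum(pres_vec) +
      stats::dgamma(theta2$q[j], 1.1, 1, log = TRUE) -
      stats::dgamma(theta$q[j], 1.1, 1, log = TRUE) + u
    if (is.finite(logA) && log(stats::runif(1L)) < logA) {
      theta <- theta2; pres_vec <- pres_prop
    }
    if (kind == "NHPP") {      # shape update
      u <- stats::runif(1L, -d_q, d_q)
      theta2 <- theta
      theta2$shape <- 1 + (theta$shape - 1) * exp(u)
      if (theta2$shape > 1) {
        pres_prop <- pres_loglik_set(lin, ts, te, kind, theta2, K)
        logA <- sum(pres_prop) - sum(pres_vec) +
          stats::dexp(theta2$shape - 1, 1, log = TRUE) -
          stats::dexp(theta$shape - 1, 1, log = TRUE) + u
        if (is.finite(logA) && log(stats::runif(1L)) < logA) {
          theta <- theta2; pres_vec <- pres_prop
        }
      }
    }

    # --- rate blocks under the reversible-jump scheme ---
    ev_m <- te[extinct]
    st_l$ll <- block_ll(st_l$fn, ts, ts, te)
    st_m$ll <- block_ll(st_m$fn, ev_m, ts, te)
    st_l <- update_rate_block(st_l, ts, ts, te, span, cfg,
                              cfg$prop_scales$rate)
    st_m <- update_rate_block(st_m, ev_m, ts, te, span, cfg,
                              cfg$prop_scales$rate)

    if (cfg$adapt && g < adapt_until && att_ts >= 50) {
      d_ts <- min(max(d_ts * exp((acc_ts / att_ts - 0.3) * 0.5), 0.02), 10)
      acc_ts <- att_ts <- 0
      if (att_te > 0) {
        d_te <- min(max(d_te * exp((acc_te / max(att_te, 1) - 0.3) * 0.5),
                        0.02), 10)
        acc_te <- att_te <- 0
      }
    }

    if (g %% cfg$sample_every == 0L) {
      si <- si + 1L
      ts_s[si, ] <- ts; te_s[si, ] <- te
      q_s[si, ] <- theta$q
      rate_s[[si]] <- list(lambda = st_l$fn, mu = st_m$fn)
      trace[si, ] <- c(g, sum(pres_vec) + st_l$ll + st_m$ll, mean(theta$q),
                       sum(cum_rate(st_l$fn, span)) / span)
    }
  }

  drop <- floor(cfg$burn_in_fraction * si)
  keep <- if (drop > 0L) seq.int(drop + 1L, si) else seq_len(si)
  trace <- as.data.frame(trace[keep, , drop = FALSE])
  conv <- list(logL = ess(trace$logL), q_mean = ess(trace$q_mean),
               mean_lambda = ess(trace$mean_lambda))
  conv$flags <- unlist(conv[c("logL", "q_mean", "mean_lambda")]) < 200
  low_info <- all(lin$k == 1L)
  structure(list(species = lin$species, extant = lin$extant,
                 fa = fa, la = la,
                 ts_samples = ts_s[keep, , drop = FALSE],
                 te_samples = te_s[keep, , drop = FALSE],
                 q_samples = q_s[keep, , drop = FALSE],
                 rate_samples = rate_s[keep],
                 trace = trace, cfg = cfg, kind = kind,
                 epochs = theta$epochs, convergence = conv,
                 acceptance = list(
                   ts = if (tot_att_ts > 0) tot_acc_ts / tot_att_ts else NA,
                   te = if (tot_att_te > 0) tot_acc_te / tot_att_te else NA),
                 low_information = low_info),
            class = "lifespan_posterior")
}

#' Posterior median lifespans
#' @param posterior a `lifespan_posterior`.
#' @return a `lifespan_table` of per-species posterior medians
#'   (extant lineages keep `Te = 0`).
#' @export
median_lifespans <- function(posterior) {
  ts <- apply(posterior$ts_samples, 2L, stats::median)
  te <- apply(posterior$te_samples, 2L, stats::median)
  te[posterior$extant] <- 0
  lifespan_table(posterior$species, ts, te, posterior$extant)
}

#' Per-species HPD intervals for Ts and Te
#' @param posterior a `lifespan_posterior`.
#' @param prob coverage probability.
#' @return data frame with species, ts/te medians and interval bounds.
#' @export
lifespan_hpd <- function(posterior, prob = 0.95) {
  hts <- apply(posterior$ts_samples, 2L, hpd_interval, prob = prob)
  hte <- apply(posterior$te_samples, 2L, hpd_interval, prob = prob)
  data.frame(species_name = posterior$species,
             ts_med = apply(posterior$ts_samples, 2L, stats::median),
             ts_lo = hts[1L, ], ts_hi = hts[2L, ],
             te_med = apply(posterior$te_samples, 2L, stats::median),
             te_lo = hte[1L, ], te_hi = hte[2L, ],
             stringsAsFactors = FALSE)
}

#' @export
print.lifespan_posterior <- function(x, ...) {
  cat(sprintf(
    "Lifespan posterior: %d lineages, %d retained samples (%s preservation)\n",
    length(x$species), nrow(x$ts_samples), x$kind))
  cat(sprintf("  ESS: logL %.0f, q %.0f, mean lambda %.0f\n",
              x$convergence$logL, x$convergence$q_mean,
              x$convergence$mean_lambda))
  if (any(x$convergence$flags))
    cat("  warning: ESS below 200 for some parameters\n")
  if (x$low_information)
    cat("  note: all lineages are singletons; lifespans weakly informed\n")
  invisible(x)
}
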