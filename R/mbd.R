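# Multivariate birth-death model: speciation and extinction rates linked
# (exponentially or linearly) to covariate time series -- other clades'
# rescaled diversity trajectories and environmental series -- under a
# horseshoe shrinkage prior on the per-covariate correlation parameters.

#' Covariate time series
#'
#' @param age strictly decreasing ages in Ma.
#' @param value finite numeric values, one per age.
#' @param label series label.
#' @return data frame of class `covariate_series`.
#' @export
covariate_series <- function(age, value, label = "covariate") {
  if (any(diff(age) >= 0)) stop("ages must be strictly decreasing")
  if (any(!is.finite(value))) stop("covariate values must be finite")
  out <- data.frame(age = as.numeric(age), value = as.numeric(value))
  attr(out, "label") <- label
  class(out) <- c("covariate_series", "data.frame")
  out
}

#' Read/write a covariate series as 2-column CSV (age, value)
#' @param path file path.
#' @param label series label.
#' @export
read_covariate <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  covariate_series(df[[1L]], df[[2L]], label = label)
}

#' @rdname read_covariate
#' @param series a `covariate_series`.
#' @export
write_covariate <- function(series, path) {
  utils::write.csv(data.frame(age = series$age, value = series$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Rescale a covariate series to [0, 1]
#'
#' `(x - min) / (max - min)`, keeping all predictors on the same relative
#' scale. A constant series maps to all zeros and is flagged via the
#' `constant` attribute.
#'
#' @param series a `covariate_series`.
#' @return the rescaled series.
#' @export
rescale01 <- function(series) {
  rng <- range(series$value)
  if (rng[1L] == rng[2L]) {
    out <- covariate_series(series$age, rep(0, nrow(series)),
                            label = attr(series, "label"))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- covariate_series(series$age,
                          (series$value - rng[1L]) / (rng[2L] - rng[1L]),
                          label = attr(series, "label"))
  attr(out, "constant") <- FALSE
  out
}

#' Rate of sea-level change
#'
#' Average absolute change per Myr between subsequent values backwards in
#' time, assigned to the younger age of each pair; requires a uniform age
#' grid (resample first otherwise). Optionally block-averages the result
#' into windows of `average_to` Myr.
#'
#' @param sealevel a `covariate_series` on a uniform grid (>= 2 points).
#' @param average_to optional window width in Myr for block averaging.
#' @return a `covariate_series` of change rates (per Myr).
#' @export
sealevel_change_rate <- function(sealevel, average_to = NULL) {
  if (nrow(sealevel) < 2L) stop("need at least 2 points")
  steps <- -diff(sealevel$age)
  if (max(abs(steps - steps[1L])) > 1e-6 * steps[1L])
    stop("non-uniform age grid; resample first")
  step <- steps[1L]
  rate <- abs(diff(sealevel$value)) / step
  age <- sealevel$age[-1L]
  if (!is.null(average_to)) {
    grp <- floor(age / average_to)
    age <- as.numeric(tapply(age, grp, max))
    rate <- as.numeric(tapply(rate, grp, mean))
    o <- order(age, decreasing = TRUE)
    age <- age[o]; rate <- rate[o]
  }
  covariate_series(age, rate,
                   label = paste0(attr(sealevel, "label"), "_change_rate"))
}

#' Assemble covariates on a common grid, rescaled to [0, 1]
#'
#' All series must share the same descending age grid; each is rescaled
#' with [rescale01()]. The value at a grid age applies over the cell
#' extending down to the next (younger) grid age.
#'
#' @param series_list named list of `covariate_series` (names override
#'   series labels when given).
#' @return object of class `covariate_set` with the grid `ages`, labels
#'   and the point-value matrix `X` (grid ages x covariates).
#' @export
covariate_set <- function(series_list) {
  if (!length(series_list)) stop("need at least one covariate")
  ages <- series_list[[1L]]$age
  for (s in series_list)
    if (length(s$age) != length(ages) || any(abs(s$age - ages) > 1e-9))
      stop("covariates must share a common age grid")
  labels <- names(series_list)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(series_list, function(s)
      attr(s, "label") %||% "covariate", "")
  scaled <- lapply(series_list, rescale01)
  X <- vapply(scaled, function(s) s$value, numeric(length(ages)))
  colnames(X) <- labels
  structure(list(ages = ages, labels = labels, X = X),
            class = "covariate_set")
}

#' MBD parameter set
#'
#' @param lambda0,mu0 baseline speciation and extinction rates (> 0).
#' @param gamma_lambda,gamma_mu per-covariate correlation parameters.
#' @param link `"exponential"` or `"linear"`.
#' @return object of class `mbd_params`.
#' @export
mbd_params <- function(lambda0, mu0, gamma_lambda, gamma_mu,
                       link = c("exponential", "linear")) {
  link <- match.arg(link)
  stopifnot(lambda0 > 0, mu0 > 0,
            length(gamma_lambda) == length(gamma_mu))
  structure(list(lambda0 = lambda0, mu0 = mu0,
                 gamma_lambda = gamma_lambda, gamma_mu = gamma_mu,
                 link = link), class = "mbd_params")
}

# Per-cell rates, event-cell lookups and exposure integrals shared by the
# public likelihood and the sampler.
mbd_cells <- function(covariates, lifespans) {
  ages <- covariates$ages
  m <- length(ages)
  if (max(lifespans$ts) > ages[1L] + 1e-9 ||
      min(lifespans$te) < ages[m] - 1e-9)
    stop("covariate grid does not cover the lifespan span")
  Xc <- covariates$X[-m, , drop = FALSE]   # older-point value per cell
  # cell i spans (ages[i+1], ages[i]]
  cell_of <- function(t) {
    i <- findInterval(-t, -ages, left.open = TRUE)
    pmin(pmax(i, 1L), m - 1L)
  }
  upper <- ages[-m]; lower <- ages[-1L]
  # exposure per cell: sum over lineages of max(0, min(ts, up) - max(te, lo))
  ov <- pmax(outer(lifespans$ts, upper, pmin) -
               outer(lifespans$te, lower, pmax), 0)
  E <- colSums(ov)
  ts_cell <- cell_of(lifespans$ts)
  te_cell <- cell_of(lifespans$te[!lifespans$extant])
  list(Xc = Xc, exposure = E, ts_cell = ts_cell, te_cell = te_cell,
       # per-cell event counts make each likelihood evaluation O(cells)
       ts_counts = tabulate(ts_cell, nbins = m - 1L),
       te_counts = tabulate(te_cell, nbins = m - 1L))
}

mbd_cell_rates <- function(base, gamma, Xc, link) {
  eta <- as.numeric(Xc %*% gamma)
  if (link == "exponential") base * exp(eta)
  else pmax(base * (1 + eta), 1e-5)
}

#' Multivariate birth-death log-likelihood
#'
#' Rates are piecewise-constant on the covariate grid:
#' `lambda(t) = lambda0 * exp(sum_j gamma_lambda_j x_j(t))` (and
#' correspondingly for `mu`) under the exponential link, or
#' `lambda0 * (1 + sum_j gamma_lambda_j x_j(t))` floored at `1e-5` under
#' the linear link. These plug into the birth-death likelihood for fixed
#' lifespans (event terms plus exposure integral, computed cell by cell).
#' With all `gamma = 0` this equals [bd_loglik()] with constant rates
#' exactly.
#'
#' @param lifespans a `lifespan_table`.
#' @param covariates a `covariate_set` covering the lifespan span.
#' @param params an [mbd_params()].
#' @return log-likelihood (scalar).
#' @export
mbd_loglik <- function(lifespans, covariates, params) {
  cells <- mbd_cells(covariates, lifespans)
  lam <- mbd_cell_rates(params$lambda0, params$gamma_lambda, cells$Xc,
                        params$link)
  mu <- mbd_cell_rates(params$mu0, params$gamma_mu, cells$Xc, params$link)
  if (any(lam <= 0) || any(mu <= 0)) return(-Inf)
  sum(log(lam[cells$ts_cell])) + sum(log(mu[cells$te_cell])) -
    sum((lam + mu) * cells$exposure)
}

#' Shrinkage weight from horseshoe scales
#'
#' `w = 1 - 1 / (1 + localScale^2 * globalScale^2)`, in `[0, 1]`:
#' near 0 the coefficient is shrunk to noise, near 1 it is kept as
#' signal.
#'
#' @param localScale,globalScale positive horseshoe scales.
#' @return shrinkage weight(s) in `[0, 1]`.
#' @export
shrinkage_weight <- function(localScale, globalScale) {
  if (any(localScale <= 0) || any(globalScale <= 0))
    stop("scales must be positive")
  1 - 1 / (1 + localScale^2 * globalScale^2)
}

rinvgamma1 <- function(shape, scale) scale / stats::rgamma(1L, shape)

#' MCMC for the multivariate birth-death model
#'
#' Samples baseline rates, per-covariate correlation parameters for
#' speciation and extinction, and horseshoe scales. The prior is
#' `gamma_j ~ N(0, localScale_j^2 * globalScale^2)` with half-Cauchy(0,1)
#' local and global scales, sampled by the inverse-gamma auxiliary
#' variable scheme (Gibbs); baselines and gammas move by
#' Metropolis-Hastings. By default each gamma block (speciation,
#' extinction) carries its own global scale, so a real effect in one
#' channel is not shrunk by the other channel's noise;
#' `separate_global = FALSE` shares a single global scale.
#'
#' @param lifespans a `lifespan_table`.
#' @param covariates a `covariate_set`.
#' @param link `"exponential"` or `"linear"`.
#' @param cfg an [mcmc_config()].
#' @param prior_only sample from the prior alone (likelihood identically
#'   zero); used to inspect the induced shrinkage-weight distribution.
#' @param separate_global one global scale per gamma block (default) or
#'   a single shared scale.
#' @return object of class `mbd_fit` with a `samples` data frame
#'   (baselines, gammas, scales, per-covariate shrinkage weights `w`,
#'   log-likelihood) and metadata.
#' @export
mbd_mcmc <- function(lifespans, covariates, link = c("exponential", "linear"),
                     cfg = mcmc_config(25e6, 25e3), prior_only = FALSE,
                     separate_global = TRUE) {
  link <- match.arg(link)
  set.seed(cfg$seed)
  J <- length(covariates$labels)
  cells <- mbd_cells(covariates, lifespans)
  n_ev_l <- nrow(lifespans); n_ev_m <- sum(!lifespans$extant)
  tot_expo <- sum(lifespans$ts - lifespans$te)

  ll_fun <- function(l0, m0, gl, gm) {
    if (prior_only) return(0)
    lam <- mbd_cell_rates(l0, gl, cells$Xc, link)
    mu <- mbd_cell_rates(m0, gm, cells$Xc, link)
    sum(cells$ts_counts * log(lam)) + sum(cells$te_counts * log(mu)) -
      sum((lam + mu) * cells$exposure)
  }

  l0 <- max(n_ev_l / tot_expo, 1e-4)
  m0 <- max(n_ev_m / tot_expo, 1e-4)
  gl <- rep(0, J); gm <- rep(0, J)
  psi_l <- rep(1, J); psi_m <- rep(1, J)   # local scales
  nu_l <- rep(1, J); nu_m <- rep(1, J)     # local auxiliaries
  tau2 <- c(1, 1); xi <- c(1, 1)           # global scale(s)^2 + auxiliaries
  gi <- function(block) if (separate_global) block else 1L

  ll <- ll_fun(l0, m0, gl, gm)
  n_samp <- cfg$n_generations %/% cfg$sample_every
  cols <- c("iteration", "logL", "lambda0", "mu0",
            paste0("gamma_lambda_", covariates$labels),
            paste0("gamma_mu_", covariates$labels),
            paste0("psi_lambda_", covariates$labels),
            paste0("psi_mu_", covariates$labels),
            "globalScale",
            paste0("w_lambda_", covariates$labels),
            paste0("w_mu_", covariates$labels))
  S <- matrix(NA_real_, n_samp, length(cols), dimnames = list(NULL, cols))
  sg <- cfg$prop_scales$gamma
  sb <- cfg$prop_scales$base
  si <- 0L

  for (g in seq_len(cfg$n_generations)) {
    # baselines (log random walk, Gamma(1.1, 1) prior)
    for (wb in 1:2) {
      u <- stats::runif(1L, -sb, sb)
      if (wb == 1L) { l0p <- l0 * exp(u); m0p <- m0 } else {
        l0p <- l0; m0p <- m0 * exp(u)
      }
      llp <- ll_fun(l0p, m0p, gl, gm)
      old <- if (wb == 1L) l0 else m0
      new <- if (wb == 1L) l0p else m0p
      logA <- llp - ll + stats::dgamma(new, 1.1, 1, log = TRUE) -
        stats::dgamma(old, 1.1, 1, log = TRUE) + u
      if (is.finite(logA) && log(stats::runif(1L)) < logA) {
        l0 <- l0p; m0 <- m0p; ll <- llp
      }
    }
    # gamma components: random-walk MH under the horseshoe prior
    # (direct Gibbs draw from the prior when there is no likelihood)
    for (j in seq_len(J)) {
      if (prior_only) {
        gl[j] <- stats::rnorm(1L, 0, sqrt(psi_l[j]^2 * tau2[gi(1L)]))
        gm[j] <- stats::rnorm(1L, 0, sqrt(psi_m[j]^2 * tau2[gi(2L)]))
        next
      }
      z <- stats::rnorm(1L, 0, sg)
      glp <- gl; glp[j] <- gl[j] + z
      llp <- ll_fun(l0, m0, glp, gm)
      v <- psi_l[j]^2 * tau2[gi(1L)]
      logA <- llp - ll + (gl[j]^2 - glp[j]^2) / (2 * v)
      if (is.finite(logA) && log(stats::runif(1L)) < logA) {
        gl <- glp; ll <- llp
      }
      z <- stats::rnorm(1L, 0, sg)
      gmp <- gm; gmp[j] <- gm[j] + z
      llp <- ll_fun(l0, m0, gl, gmp)
      v <- psi_m[j]^2 * tau2[gi(2L)]
      logA <- llp - ll + (gm[j]^2 - gmp[j]^2) / (2 * v)
      if (is.finite(logA) && log(stats::runif(1L)) < logA) {
        gm <- gmp; ll <- llp
      }
    }
    # horseshoe scales: inverse-gamma auxiliary Gibbs updates
    for (j in seq_len(J)) {
      psi_l[j] <- sqrt(rinvgamma1(1, 1 / nu_l[j] +
                                    gl[j]^2 / (2 * tau2[gi(1L)])))
      nu_l[j] <- rinvgamma1(1, 1 + 1 / psi_l[j]^2)
      psi_m[j] <- sqrt(rinvgamma1(1, 1 / nu_m[j] +
                                    gm[j]^2 / (2 * tau2[gi(2L)])))
      nu_m[j] <- rinvgamma1(1, 1 + 1 / psi_m[j]^2)
    }
    if (separate_global) {
      tau2[1L] <- rinvgamma1((J + 1) / 2,
                             1 / xi[1L] + sum(gl^2 / psi_l^2) / 2)
      xi[1L] <- rinvgamma1(1, 1 + 1 / tau2[1L])
      tau2[2L] <- rinvgamma1((J + 1) / 2,
                             1 / xi[2L] + sum(gm^2 / psi_m^2) / 2)
      xi[2L] <- rinvgamma1(1, 1 + 1 / tau2[2L])
    } else {
      tau2[1L] <- rinvgamma1((2 * J + 1) / 2,
                             1 / xi[1L] + (sum(gl^2 / psi_l^2) +
                                             sum(gm^2 / psi_m^2)) / 2)
      xi[1L] <- rinvgamma1(1, 1 + 1 / tau2[1L])
    }

    if (g %% cfg$sample_every == 0L) {
      si <- si + 1L
      tau_l <- sqrt(tau2[gi(1L)]); tau_m <- sqrt(tau2[gi(2L)])
      S[si, ] <- c(g, ll, l0, m0, gl, gm, psi_l, psi_m, tau_l,
                   shrinkage_weight(psi_l, tau_l),
                   shrinkage_weight(psi_m, tau_m))
    }
  }
  if (si < 2L) stop("fewer than 2 retained samples")
  drop <- floor(cfg$burn_in_fraction * si)
  keep <- if (drop > 0L) seq.int(drop + 1L, si) else seq_len(si)
  structure(list(samples = as.data.frame(S[keep, , drop = FALSE]),
                 labels = covariates$labels, link = link, cfg = cfg,
                 prior_only = prior_only),
            class = "mbd_fit")
}

#' Pool MBD fits across age replicates
#'
#' Equal-weight pooling of posterior samples from per-replicate runs,
#' prior to computing medians and HPD intervals across replicates.
#'
#' @param fits list of `mbd_fit` objects with identical covariates/link.
#' @return a pooled `mbd_fit`.
#' @export
pool_mbd <- function(fits) {
  stopifnot(length(fits) >= 1L)
  structure(list(samples = do.call(rbind, lapply(fits, `[[`, "samples")),
                 labels = fits[[1L]]$labels, link = fits[[1L]]$link,
                 cfg = fits[[1L]]$cfg,
                 prior_only = fits[[1L]]$prior_only),
            class = "mbd_fit")
}

#' Turnover effect of a covariate
#'
#' Per posterior sample, the covariate's effect on lineage turnover is
#' the sum of its effects on speciation and extinction,
#' `T_j = gamma_lambda_j + gamma_mu_j`.
#'
#' @param fit an `mbd_fit`.
#' @param covariate covariate label.
#' @param prob HPD coverage.
#' @return list with `samples`, `median` and `hpd`.
#' @export
turnover_effect <- function(fit, covariate, prob = 0.95) {
  if (!covariate %in% fit$labels)
    stop(sprintf("unknown covariate '%s'", covariate))
  s <- fit$samples[[paste0("gamma_lambda_", covariate)]] +
    fit$samples[[paste0("gamma_mu_", covariate)]]
  list(samples = s, median = stats::median(s),
       hpd = hpd_interval(s, prob))
}

#' Harmonic-mean log marginal likelihood
#'
#' Posterior harmonic mean of the likelihood:
#' `-log mean(exp(-logL))`, computed with max-shift stabilization.
#' Used to compare the linear and exponential link models.
#'
#' @param loglik_samples numeric vector of posterior log-likelihoods
#'   (>= 2 values).
#' @return scalar log marginal-likelihood estimate.
#' @export
harmonic_mean_logml <- function(loglik_samples) {
  stopifnot(length(loglik_samples) >= 2L)
  -logmeanexp(-loglik_samples)
}

#' Per-covariate MBD summary
#'
#' Median and 95\% HPD of the correlation parameters, median shrinkage
#' weights, turnover effects, and the significance flag
#' (median `w` above `w_threshold`, the conservative detection rule).
#'
#' @param fit an `mbd_fit` (typically pooled across replicates).
#' @param w_threshold shrinkage-weight significance threshold.
#' @param prob HPD coverage.
#' @return data frame, one row per covariate.
#' @export
mbd_summary <- function(fit, w_threshold = 0.7, prob = 0.95) {
  s <- fit$samples
  rows <- lapply(fit$labels, function(lb) {
    glj <- s[[paste0("gamma_lambda_", lb)]]
    gmj <- s[[paste0("gamma_mu_", lb)]]
    wl <- s[[paste0("w_lambda_", lb)]]
    wm <- s[[paste0("w_mu_", lb)]]
    Tj <- glj + gmj
    hl <- hpd_interval(glj, prob); hm <- hpd_interval(gmj, prob)
    hT <- hpd_interval(Tj, prob)
    data.frame(covariate = lb,
               gamma_lambda_med = stats::median(glj),
               gamma_lambda_lo = hl[1L], gamma_lambda_hi = hl[2L],
               w_lambda_med = stats::median(wl),
               gamma_mu_med = stats::median(gmj),
               gamma_mu_lo = hm[1L], gamma_mu_hi = hm[2L],
               w_mu_med = stats::median(wm),
               turnover_med = stats::median(Tj),
               turnover_lo = hT[1L], turnover_hi = hT[2L],
               sig_lambda = stats::median(wl) > w_threshold,
               sig_mu = stats::median(wm) > w_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an MBD posterior trace as tab-separated text
#' @param fit an `mbd_fit`.
#' @param path output path.
#' @export
write_mbd_trace <- function(fit, path) {
  utils::write.table(fit$samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.mbd_fit <- function(x, ...) {
  cat(sprintf("MBD fit (%s link%s): %d covariates, %d samples\n",
              x$link, if (x$prior_only) ", prior only" else "",
              length(x$labels), nrow(x$samples)))
  print(mbd_summary(x)[, c("covariate", "gamma_lambda_med", "w_lambda_med",
                           "gamma_mu_med", "w_mu_med", "turnover_med")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.mbd_fit <- function(object, w_threshold = 0.7, ...) {
  mbd_summary(object, w_threshold = w_threshold)
}

#' @export
coef.mbd_fit <- function(object, ...) {
  s <- mbd_summary(object)
  out <- c(stats::median(object$samples$lambda0),
           stats::median(object$samples$mu0),
           s$gamma_lambda_med, s$gamma_mu_med)
  names(out) <- c("lambda0", "mu0",
                  paste0("gamma_lambda_", s$covariate),
                  paste0("gamma_mu_", s$covariate))
  out
}

#' @export
plot.mbd_fit <- function(x, channel = c("turnover", "lambda", "mu"), ...) {
  channel <- match.arg(channel)
  s <- x$samples
  J <- length(x$labels)
  graphics::par(mfrow = c(ceiling(J / 2), min(J, 2)))
  for (lb in x$labels) {
    v <- switch(channel,
      turnover = s[[paste0("gamma_lambda_", lb)]] +
        s[[paste0("gamma_mu_", lb)]],
      lambda = s[[paste0("gamma_lambda_", lb)]],
      mu = s[[paste0("gamma_mu_", lb)]])
    graphics::hist(v, breaks = 40, main = lb,
                   xlab = sprintf("effect on %s", channel), ...)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}
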