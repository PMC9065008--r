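# Multivariate birth-death: covariate handling, likelihood identities,
# horseshoe shrinkage behavior and model comparison.

make_covset <- function(grid = seq(12, 0, by = -0.5), seed = 1) {
  covariate_set(list(
    x1 = simulate_covariate(grid, "random_walk", list(sd = 1), seed = seed),
    x2 = simulate_covariate(grid, "sine", list(amplitude = 2, period = 6),
                            seed = seed + 1)))
}

test_that("rescale01 maps to [0,1], flags constants and is idempotent", {
  s <- covariate_series(c(5, 3, 1), c(2, 4, 6))
  r <- rescale01(s)
  expect_equal(r$value, c(0, 0.5, 1))
  expect_false(attr(r, "constant"))
  cst <- rescale01(covariate_series(c(2, 1), c(5, 5)))
  expect_equal(cst$value, c(0, 0))
  expect_true(attr(cst, "constant"))
  expect_equal(rescale01(r)$value, r$value)
})

test_that("sea-level change rate matches closed forms", {
  grid <- seq(10, 0, by = -0.5)
  cst <- covariate_series(grid, rep(40, length(grid)))
  expect_true(all(sealevel_change_rate(cst)$value == 0))
  lin <- covariate_series(grid, 3 * grid)   # trend of 3 per Myr
  expect_true(all(abs(sealevel_change_rate(lin)$value - 3) < 1e-9))
  saw <- covariate_series(grid, rep(c(0, 2), length.out = length(grid)))
  expect_true(all(abs(sealevel_change_rate(saw)$value - 4) < 1e-9))
  irr <- covariate_series(c(5, 3, 2), c(1, 2, 3))
  expect_error(sealevel_change_rate(irr), "uniform")
})

test_that("MBD likelihood reduces to constant-rate bd at gamma = 0", {
  lf <- lifespan_table(c("a", "b", "c"), c(10, 6, 8), c(4, 0, 2),
                       c(FALSE, TRUE, FALSE))
  covs <- make_covset()
  p0 <- mbd_params(0.4, 0.2, c(0, 0), c(0, 0))
  expect_equal(mbd_loglik(lf, covs, p0),
               bd_loglik(lf, rate_series(0.4, 0.2)), tolerance = 1e-12)
  # a covariate fixed at its maximum with gamma_mu = ln 2 doubles mu
  grid <- seq(12, 0, by = -0.5)
  one <- covariate_set(list(
    flat = covariate_series(grid, c(0, rep(1, length(grid) - 1)))))
  p1 <- mbd_params(0.4, 0.2, 0, log(2))
  # the covariate equals 1 on every cell that the lifespans touch
  expect_equal(mbd_loglik(lf, one, p1),
               bd_loglik(lf, rate_series(0.4, 0.4)), tolerance = 1e-9)
})

test_that("MBD likelihood agrees with a fine-grid quadrature oracle", {
  set.seed(51)
  lf <- lifespan_table(c("a", "b", "c"), c(9.5, 6.1, 7.8), c(3.2, 0, 1.1),
                       c(FALSE, TRUE, FALSE))
  grid <- seq(10, 0, by = -0.5)
  covs <- make_covset(grid, seed = 7)
  p <- mbd_params(0.5, 0.25, c(0.8, -0.4), c(-0.3, 0.6))
  got <- mbd_loglik(lf, covs, p)
  # oracle: evaluate rates on a very fine grid via the cell convention
  X <- make_covset(grid, seed = 7)$X
  xval <- function(t, j) {
    i <- pmin(pmax(findInterval(-t, -grid, left.open = TRUE), 1),
              length(grid) - 1)
    X[i, j]
  }
  lamf <- function(t) 0.5 * exp(0.8 * xval(t, 1) - 0.4 * xval(t, 2))
  muf <- function(t) 0.25 * exp(-0.3 * xval(t, 1) + 0.6 * xval(t, 2))
  # both rates and N(t) are piecewise constant, so integrating exactly
  # between consecutive breakpoints is an independent exact oracle
  brk <- sort(unique(c(grid, lf$ts, lf$te)))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  Nt <- vapply(mids, function(t) sum(lf$te <= t & t <= lf$ts), 0)
  quad <- sum((lamf(mids) + muf(mids)) * Nt * diff(brk))
  oracle <- sum(log(lamf(lf$ts))) + sum(log(muf(lf$te[!lf$extant]))) - quad
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("exponential link obeys the gauge identity", {
  # shifting covariate j by c while multiplying lambda0 by exp(-gamma_j c)
  # leaves the likelihood unchanged
  lf <- lifespan_table(c("a", "b"), c(8, 5), c(2, 0), c(FALSE, TRUE))
  grid <- seq(9, 0, by = -0.5)
  x <- simulate_covariate(grid, "random_walk", list(sd = 0.5), seed = 3)
  covs1 <- list(ages = grid, labels = "x", X = cbind(x = x$value))
  class(covs1) <- "covariate_set"
  covs2 <- list(ages = grid, labels = "x", X = cbind(x = x$value + 0.37))
  class(covs2) <- "covariate_set"
  g <- 0.9
  p1 <- mbd_params(0.5, 0.2, g, 0.4)
  p2 <- mbd_params(0.5 * exp(-g * 0.37), 0.2 * exp(-0.4 * 0.37), g, 0.4)
  expect_equal(mbd_loglik(lf, covs1, p1), mbd_loglik(lf, covs2, p2),
               tolerance = 1e-9)
})

test_that("linear link floors rates instead of going negative", {
  lf <- lifespan_table(c("a", "b"), c(8, 5), c(2, 0), c(FALSE, TRUE))
  grid <- seq(9, 0, by = -0.5)
  one <- covariate_set(list(
    flat = covariate_series(grid, c(0, rep(1, length(grid) - 1)))))
  p <- mbd_params(0.4, 0.2, -5, 0, link = "linear")
  ll <- mbd_loglik(lf, one, p)
  expect_true(is.finite(ll))
})

test_that("shrinkage weights follow the closed form and its limits", {
  expect_equal(shrinkage_weight(1, 1), 0.5)
  expect_equal(shrinkage_weight(3, 1), 0.9)
  expect_lt(shrinkage_weight(1e-4, 1e-4), 1e-6)
  expect_gt(shrinkage_weight(100, 1), 0.999)
  expect_error(shrinkage_weight(-1, 1), "positive")
})

test_that("harmonic-mean log marginal likelihood matches closed forms", {
  expect_equal(harmonic_mean_logml(rep(-3.2, 10)), -3.2)
  expect_equal(harmonic_mean_logml(c(0, -log(2))), -log(1.5),
               tolerance = 1e-12)
  set.seed(9)
  x <- rnorm(100)
  expect_equal(harmonic_mean_logml(x), harmonic_mean_logml(rev(x)))
  expect_error(harmonic_mean_logml(1), ">= 2")
})

test_that("turnover effect is the samplewise sum of the two channels", {
  fit <- structure(list(
    samples = data.frame(gamma_lambda_x = c(0.5, 0.2),
                         gamma_mu_x = c(0.3, -0.2)),
    labels = "x", link = "exponential", prior_only = FALSE),
    class = "mbd_fit")
  tv <- turnover_effect(fit, "x")
  expect_equal(tv$samples, c(0.8, 0))
  expect_equal(tv$median, 0.4)
  expect_error(turnover_effect(fit, "zzz"), "unknown")
})

test_that("prior-only horseshoe weights pile up near 0 and 1", {
  lf <- lifespan_table(c("a", "b"), c(8, 5), c(2, 0), c(FALSE, TRUE))
  covs <- make_covset(seq(9, 0, by = -0.5), seed = 5)
  fit <- mbd_mcmc(lf, covs, cfg = mcmc_config(4e3, 2, seed = 6),
                  prior_only = TRUE)
  w <- unlist(fit$samples[grep("^w_", names(fit$samples))])
  expect_gt(mean(w < 0.1), 0.2)
  expect_gt(mean(w > 0.9), 0.2)
})

test_that("MBD with zero-effect covariates matches constant-rate estimation", {
  h <- simulate_bd(sim_params(16, 4, 0.35, 0.18, seed = 55))
  lf <- lifespans_from_history(h)
  grid <- seq(17, 0, by = -0.5)
  covs <- covariate_set(list(
    n1 = simulate_covariate(grid, "random_walk", list(sd = 1), seed = 56)))
  fit <- mbd_mcmc(lf, covs, cfg = mcmc_config(1e4, 10, seed = 57))
  mle_l <- nrow(lf) / sum(lf$ts - lf$te)
  mle_m <- sum(!lf$extant) / sum(lf$ts - lf$te)
  # baseline posteriors bracket the constant-rate point estimates
  hl <- hpd_interval(fit$samples$lambda0)
  hm <- hpd_interval(fit$samples$mu0)
  expect_true(hl[1] <= mle_l && mle_l <= hl[2])
  expect_true(hm[1] <= mle_m && mle_m <= hm[2])
  expect_lt(abs(median(fit$samples$lambda0) - mle_l) / mle_l, 0.25)
  expect_lt(median(fit$samples$w_lambda_n1), 0.5)
  expect_lt(median(fit$samples$w_mu_n1), 0.5)
})

test_that("harmonic mean favors the generating link on strong-effect data", {
  sim <- simulate_coupled_clades(
    paramsA = sim_params(20, 1, 0.22, 0.06, seed = 21),
    baseB = sim_params(20, 2, 0.35, 0.15, seed = 22),
    gamma_lambda = 0, gamma_mu = 1.5, link = "exponential")
  lf <- lifespans_from_history(sim$historyB)
  grid <- seq(21, 0, by = -0.5)
  dA <- covariate_series(grid, approx(sim$covariate$age, sim$covariate$value,
                                      xout = grid, rule = 2)$y)
  covs <- covariate_set(list(cladeA = dA))
  wins <- 0
  for (i in 1:3) {
    fe <- mbd_mcmc(lf, covs, link = "exponential",
                   cfg = mcmc_config(8e3, 10, seed = 60 + i))
    fl <- mbd_mcmc(lf, covs, link = "linear",
                   cfg = mcmc_config(8e3, 10, seed = 60 + i))
    wins <- wins + (harmonic_mean_logml(fe$samples$logL) >
                      harmonic_mean_logml(fl$samples$logL))
  }
  expect_gte(wins, 2)
})

test_that("per-channel global scales shrink a real effect less than a shared scale", {
  sim <- simulate_coupled_clades(
    paramsA = sim_params(20, 1, 0.22, 0.06, seed = 21),
    baseB = sim_params(20, 2, 0.35, 0.15, seed = 22),
    gamma_lambda = 0, gamma_mu = 1.0, link = "exponential")
  lf <- lifespans_from_history(sim$historyB)
  grid <- seq(21, 0, by = -0.5)
  covs <- covariate_set(list(
    cladeA = covariate_series(grid, approx(sim$covariate$age,
                                           sim$covariate$value,
                                           xout = grid, rule = 2)$y),
    noise = simulate_covariate(grid, "random_walk", list(sd = 1),
                               seed = 31)))
  sep <- mbd_mcmc(lf, covs, cfg = mcmc_config(1.5e4, 15, seed = 901),
                  separate_global = TRUE)
  sha <- mbd_mcmc(lf, covs, cfg = mcmc_config(1.5e4, 15, seed = 901),
                  separate_global = FALSE)
  expect_gt(median(sep$samples$w_mu_cladeA),
            median(sha$samples$w_mu_cladeA))
  expect_lt(max(median(sep$samples$w_mu_noise),
                median(sha$samples$w_mu_noise)), 0.5)
})

test_that("MBD runs are seed-deterministic", {
  lf <- lifespan_table(c("a", "b", "c"), c(9, 6, 7), c(3, 0, 1),
                       c(FALSE, TRUE, FALSE))
  covs <- make_covset(seq(9, 0, by = -0.5), seed = 8)
  f1 <- mbd_mcmc(lf, covs, cfg = mcmc_config(2e3, 5, seed = 99))
  f2 <- mbd_mcmc(lf, covs, cfg = mcmc_config(2e3, 5, seed = 99))
  expect_identical(f1$samples, f2$samples)
})
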