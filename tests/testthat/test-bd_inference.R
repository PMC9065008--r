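# Birth-death likelihood, reversible-jump rate inference, the joint
# lifespan sampler, ESS and posterior summaries.

test_that("bd log-likelihood matches closed forms", {
  one <- lifespan_table("a", 10, 0, TRUE)
  expect_equal(bd_loglik(one, rate_series(0.4, 0.2)),
               log(0.4) - 0.6 * 10, tolerance = 1e-10)
  two <- lifespan_table(c("a", "b"), c(10, 6), c(4, 0), c(FALSE, TRUE))
  expect_equal(bd_loglik(two, rate_series(0.5, 0.25)),
               2 * log(0.5) + log(0.25) - 0.75 * 12, tolerance = 1e-10)
  # zero rate at an event time -> -Inf, flagged
  z <- bd_loglik(two, rate_series(0.5, rate_fn(c(0.25, 0), shifts = 5)))
  expect_identical(z, structure(-Inf, flagged = TRUE))
})

test_that("piecewise bd likelihood agrees with fine-grid quadrature", {
  set.seed(5)
  lf <- lifespan_table(sprintf("s%d", 1:40), runif(40, 5, 15),
                       runif(40, 0, 4))
  lam <- rate_fn(c(0.3, 0.7, 0.4), shifts = c(9, 3.5))
  mu <- rate_fn(c(0.1, 0.25), shifts = 6.2)
  got <- bd_loglik(lf, rate_series(lam, mu))
  grid <- seq(0, 16, by = 1e-3)
  Nt <- vapply(grid, function(t) sum(lf$te <= t & t <= lf$ts), 0)
  integrand <- (rate_at(lam, grid) + rate_at(mu, grid)) * Nt
  quad <- sum((integrand[-1] + integrand[-length(grid)]) / 2) * 1e-3
  oracle <- sum(log(rate_at(lam, lf$ts))) +
    sum(log(rate_at(mu, lf$te[!lf$extant]))) - quad
  expect_equal(got, oracle, tolerance = 1e-5)
})

test_that("bd likelihood is invariant to lineage order and additive", {
  set.seed(6)
  lf <- lifespan_table(sprintf("s%d", 1:30), runif(30, 4, 12),
                       runif(30, 0, 3))
  r <- rate_series(rate_fn(c(0.2, 0.5), 6), 0.15)
  perm <- lf[sample(30), ]
  class(perm) <- class(lf)
  expect_equal(bd_loglik(lf, r), bd_loglik(perm, r))
})

test_that("ESS matches closed forms for iid and AR(1) sequences", {
  set.seed(8)
  x <- rnorm(1000)
  expect_gt(ess(x), 800)
  expect_lte(ess(x), 1200)
  # AR(1), phi = 0.9 -> ESS/n = (1-phi)/(1+phi) ~ 0.0526
  phi <- 0.9
  n <- 20000
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n))
  expect_lt(abs(ess(ar) / n - (1 - phi) / (1 + phi)),
            0.3 * (1 - phi) / (1 + phi))
  cst <- ess(rep(2, 100))
  expect_equal(as.numeric(cst), 100)
  expect_true(attr(cst, "zero_variance"))
  expect_error(ess(1:5), "at least 10")
})

test_that("rjMCMC on constant-rate lifespans recovers rates without shifts", {
  h <- simulate_bd(sim_params(18, 3, 0.4, 0.2, seed = 3))
  lf <- lifespans_from_history(h)
  post <- rj_mcmc_rates(lf, mcmc_config(6e4, 60, seed = 2))
  # constant-rate data must not add shift support beyond the prior:
  # posterior mean shift count below the Poisson(1) prior mean, posterior
  # P(k >= 2) below the prior's 0.264, and extinction keeps mode 0
  expect_lt(mean(post$trace$n_shifts_lambda), 1)
  expect_lt(mean(post$trace$n_shifts_lambda >= 2), 0.264)
  expect_lt(mean(post$trace$n_shifts_mu), 1)
  expect_equal(as.integer(names(which.max(table(
    post$trace$n_shifts_mu)))), 0L)
  s <- summarize_rates(post, step = 1)
  mid <- which(s$age == 9)
  expect_lt(abs(s$lambda_med[mid] - 0.4), 0.1)
  expect_lt(abs(s$mu_med[mid] - 0.2), 0.08)
  expect_true(s$lambda_lo[mid] <= 0.4 && 0.4 <= s$lambda_hi[mid])
  expect_true(s$mu_lo[mid] <= 0.2 && 0.2 <= s$mu_hi[mid])
  # net diversification is computed sample-wise
  expect_equal(s$r_med[mid], median(vapply(post$samples, function(x)
    rate_at(x$lambda, 9) - rate_at(x$mu, 9), 0)), tolerance = 1e-9)
})

test_that("rjMCMC is deterministic given the seed and errors on empty input", {
  h <- simulate_bd(sim_params(12, 4, 0.3, 0.15, seed = 5))
  lf <- lifespans_from_history(h)
  p1 <- rj_mcmc_rates(lf, mcmc_config(2e3, 10, seed = 77))
  p2 <- rj_mcmc_rates(lf, mcmc_config(2e3, 10, seed = 77))
  expect_identical(p1$trace, p2$trace)
  expect_identical(p1$samples, p2$samples)
  empty <- lifespan_table(character(0), numeric(0), numeric(0), logical(0))
  expect_error(rj_mcmc_rates(empty, mcmc_config(1e3, 10)), "non-empty")
})

test_that("retained sample count follows the thinning/burn-in contract", {
  h <- simulate_bd(sim_params(10, 4, 0.3, 0.2, seed = 6))
  lf <- lifespans_from_history(h)
  p1 <- rj_mcmc_rates(lf, mcmc_config(4e3, 20, seed = 1,
                                      burn_in_fraction = 0.2))
  expect_equal(nrow(p1$trace), 160L)
  # doubling generations and thinning together leaves the count unchanged
  p2 <- rj_mcmc_rates(lf, mcmc_config(8e3, 40, seed = 1,
                                      burn_in_fraction = 0.2))
  expect_lte(abs(nrow(p2$trace) - nrow(p1$trace)), 1L)
})

test_that("within-model proposal acceptance is tuned into the 20-50% band", {
  h <- simulate_bd(sim_params(18, 3, 0.4, 0.2, seed = 3))
  occ <- simulate_preservation(h, pres_hpp(1.5), seed = 103)
  post <- sample_lifespans(occ, model = "HPP",
                           cfg = mcmc_config(6e3, 20, seed = 4))
  expect_gt(post$acceptance$ts, 0.2)
  expect_lt(post$acceptance$ts, 0.5)
})

test_that("lifespan posterior respects hard constraints and tight-q limits", {
  h <- simulate_bd(sim_params(12, 4, 0.3, 0.15, seed = 9))
  occ <- simulate_preservation(h, pres_hpp(1), seed = 10)
  post <- sample_lifespans(occ, model = "HPP",
                           cfg = mcmc_config(4e3, 20, seed = 12))
  # every retained sample satisfies Ts >= oldest occurrence, Te <= youngest
  expect_true(all(sweep(post$ts_samples, 2, post$fa, `>=`)))
  ext <- !post$extant
  expect_true(all(sweep(post$te_samples[, ext, drop = FALSE], 2,
                        post$la[ext], `<=`)))
  expect_true(all(post$te_samples[, !ext, drop = FALSE] == 0))

  # with a very large preservation rate the lifespan hugs the range
  h2 <- h[h$ts - h$te > 1, ]
  class(h2) <- class(h)
  occ2 <- simulate_preservation(h2, pres_hpp(50), seed = 13)
  post2 <- sample_lifespans(occ2, model = "HPP",
                            cfg = mcmc_config(4e3, 20, seed = 14))
  med_gap <- apply(post2$ts_samples, 2, median) - post2$fa
  expect_lt(median(med_gap), 0.1)
})

test_that("subset merging preserves per-subset medians", {
  h <- simulate_bd(sim_params(12, 4, 0.35, 0.15, seed = 15))
  lf <- lifespans_from_history(h)
  half <- nrow(lf) %/% 2
  a <- lf[seq_len(half), ]; b <- lf[-seq_len(half), ]
  class(a) <- class(b) <- class(lf)
  merged <- merge_lifespans(list(a, b))
  expect_equal(nrow(merged), nrow(lf))
  expect_setequal(merged$species_name, lf$species_name)
  i <- match(a$species_name, merged$species_name)
  expect_equal(merged$ts[i], a$ts)
})

test_that("HPD utility finds the shortest interval", {
  set.seed(20)
  x <- c(rnorm(2000), rnorm(50, 10))  # contaminated: HPD should hug N(0,1)
  h <- hpd_interval(x, 0.9)
  # brute-force shortest-interval search
  xs <- sort(x); m <- ceiling(0.9 * length(x))
  w <- xs[m:length(x)] - xs[1:(length(x) - m + 1)]
  i <- which.min(w)
  expect_equal(h, c(xs[i], xs[i + m - 1]))
  expect_lt(h[2], 4)
  # degenerate posterior: width zero
  expect_equal(hpd_interval(rep(3, 50)), c(3, 3))
})
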